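# Stage 4: peak-level count matrix, the four size-factor schemes, and
# NB differential analysis against dHAZ under spike-in vs median-of-ratios
# normalization, plus PCA, clustering and TSS-proximity of the hits.

source("analysis/00_config.R")
suppressMessages(library(ggplot2))

co <- demo_cohort()
m <- counts_in_peaks(co$coverage, co$peaks)
bg <- fit_cohort_background(co$coverage)

sf <- list(total = size_factors_total(m),
           median_of_ratios = size_factors_median_of_ratios(m),
           spikein = size_factors_spikein(
             setNames(co$metadata$spikein_reads, co$metadata$sample_id)),
           expfit = size_factors_expfit(bg))
sf_tab <- dplyr::bind_rows(lapply(names(sf), function(meth)
  tibble::tibble(sample_id = colnames(m), method = meth,
                 factor = as.numeric(sf[[meth]]))))
readr::write_tsv(sf_tab, "results/tables/size_factors.tsv")

res_sp <- fit_feature_models(m, co$metadata, sf$spikein)
res_mor <- fit_feature_models(m, co$metadata, sf$median_of_ratios)
readr::write_tsv(res_sp, "results/tables/differential_peaks_spikein.tsv")
readr::write_tsv(res_mor, "results/tables/differential_peaks_mor.tsv")

n_sig_sp <- sum(res_sp$fdr < 0.05, na.rm = TRUE)
n_sig_mor <- sum(res_mor$fdr < 0.05, na.rm = TRUE)
message(sprintf("differential peaks (FDR < 0.05): %d spike-in, %d median-of-ratios",
                n_sig_sp, n_sig_mor))
message(sprintf("median TSS-peak log2FC/dHAZ: %.3f spike-in vs %.3f median-of-ratios",
                median(res_sp$log2fc_per_dhaz[co$peaks$at_tss], na.rm = TRUE),
                median(res_mor$log2fc_per_dhaz[co$peaks$at_tss], na.rm = TRUE)))

pos <- co$peaks[which(res_sp$fdr < 0.05 & res_sp$log2fc_per_dhaz > 0), ]
if (nrow(pos) > 0)
  message(sprintf(
    "%.0f%% of significant positive peaks lie within 2 kb of a TSS (n = %d)",
    100 * proximal_fraction(pos, co$tss, 2000), nrow(pos)))

fig_ma <- ggplot(res_sp, aes(base_mean, log2fc_per_dhaz,
                             colour = fdr < 0.05)) +
  geom_point(size = 0.7) + scale_x_log10() +
  labs(x = "mean normalized signal", y = "log2 fold-change per dHAZ unit",
       title = "MA plot (spike-in normalization)")
save_figure(fig_ma, "ma_plot_spikein.png")

pc <- pca_samples(m, sf$spikein, n_top_features = 300)
readr::write_tsv(
  dplyr::bind_cols(pc$coordinates[, c("sample_id", "PC1", "PC2")],
                   co$metadata[, c("delta_haz", "sex", "stunted")]),
  "results/tables/pca_coordinates.tsv")
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of the variance",
                100 * pc$var_explained[1], 100 * pc$var_explained[2]))
fig_pc <- ggplot(dplyr::bind_cols(pc$coordinates, co$metadata[, -1]),
                 aes(PC1, PC2, colour = delta_haz, shape = sex)) +
  geom_point(size = 2) + scale_colour_gradient(low = "red", high = "blue") +
  labs(title = "Sample PCA (spike-in normalized peaks)")
save_figure(fig_pc, "pca_samples.png")

cl <- correlation_cluster(m, sf$spikein)
readr::write_tsv(tibble::as_tibble(cl$correlation, rownames = "sample_id"),
                 "results/tables/sample_correlations.tsv")
message("sample order after Ward clustering on 1 - Pearson r: ",
        paste(cl$order, collapse = " "))

# Negative-peak layer: concentrate part of the mistargeted mass in narrow
# distal sites. Their occupancy rises as dHAZ falls, so they surface as
# negative "peaks" far from any TSS, while positive peaks stay TSS-proximal.
p_neg <- redistribution_params(distal_mistarget_fraction = 0.3)
co2 <- simulate_cohort(demo_genome(), cohort_design(N_SAMPLES,
                                                    seed = COHORT_SEED),
                       p_neg, demo_spikein(), seed = COHORT_SEED)
distal_iv <- co2$layout$bins[co2$layout$distal_bins, ]
distal_iv$name <- sprintf("distal_%03d", seq_len(nrow(distal_iv)))
features <- dplyr::bind_rows(co2$peaks[, c("chrom", "start", "end", "name")],
                             distal_iv)
m2 <- counts_in_peaks(co2$coverage, features)
res2 <- fit_feature_models(m2, co2$metadata,
                           size_factors_spikein(co2$metadata$spikein_reads))
sig_pos <- features[which(res2$fdr < 0.05 & res2$log2fc_per_dhaz > 0), ]
sig_neg <- features[which(res2$fdr < 0.05 & res2$log2fc_per_dhaz < 0), ]
prox <- function(x) if (nrow(x) > 0)
  100 * proximal_fraction(x, co2$tss, 2000) else NA_real_
readr::write_tsv(
  tibble::tibble(direction = c("positive", "negative"),
                 n_significant = c(nrow(sig_pos), nrow(sig_neg)),
                 pct_within_2kb_of_tss = c(prox(sig_pos), prox(sig_neg))),
  "results/tables/tss_proximity_by_direction.tsv")
message(sprintf(
  "with a distal layer: %d positive peaks (%.0f%% TSS-proximal) vs %d negative (%.1f%% TSS-proximal)",
  nrow(sig_pos), prox(sig_pos), nrow(sig_neg), prox(sig_neg)))
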