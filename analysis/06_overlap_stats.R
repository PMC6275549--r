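# Stage 6: set-overlap statistics. Two uses: (i) the reported maternal-gene
# overlap arithmetic (658 of 829 genes, with no universe stated, so only the
# percentage is computed); (ii) a fully specified hypergeometric test on the
# synthetic cohort -- differential peaks found independently in two halves
# of the cohort should broadly overlap, with the full peak set as the
# universe.

source("analysis/00_config.R")

maternal <- hypergeometric_overlap(n_a = 829, n_b = NA, n_overlap = 658,
                                   n_universe = NA)
print(maternal)

co <- demo_cohort()
m <- counts_in_peaks(co$coverage, co$peaks)
sf <- size_factors_spikein(setNames(co$metadata$spikein_reads,
                                    co$metadata$sample_id))
half <- list(a = 1:(N_SAMPLES / 2), b = (N_SAMPLES / 2 + 1):N_SAMPLES)
sig <- lapply(half, function(idx) {
  r <- fit_feature_models(m[, idx], co$metadata[idx, ], sf[idx])
  r$feature_id[which(r$fdr < 0.05)]
})
ov <- hypergeometric_overlap(n_a = length(sig$a), n_b = length(sig$b),
                             n_overlap = length(intersect(sig$a, sig$b)),
                             n_universe = nrow(m))
print(ov)

sets_a <- co$peaks[co$peaks$name %in% sig$a, ]
sets_b <- co$peaks[co$peaks$name %in% sig$b, ]
interval_ov <- if (nrow(sets_a) > 0 && nrow(sets_b) > 0)
  peak_set_overlap(sets_a, sets_b)$fraction else NA_real_

out <- tibble::tibble(
  comparison = c("maternal genes: child vs mother height-associated",
                 "differential peaks: cohort half A vs half B"),
  n_a = c(maternal$n_a, ov$n_a),
  n_b = c(maternal$n_b, ov$n_b),
  n_overlap = c(maternal$n_overlap, ov$n_overlap),
  n_universe = c(maternal$n_universe, ov$n_universe),
  percent_of_a = c(maternal$percent_of_a, ov$percent_of_a),
  p_value = c(maternal$p_value, ov$p_value))
readr::write_tsv(out, "results/tables/overlap_statistics.tsv")
message(sprintf("interval-level overlap fraction of the two hit sets: %.2f",
                interval_ov))
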