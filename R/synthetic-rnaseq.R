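# Synthetic RNA-seq with ERCC-style spike-ins, and a generic NB count
# simulator used for calibration studies of the differential module.

#' Simulate an ERCC spike-in RNA-seq cohort
#'
#' Identical spike-in amounts are added to every sample while the endogenous
#' transcriptome shifts globally by `rna_global_shift_slope` log2 units per
#' unit dHAZ (on top of per-gene differential effects). Libraries are
#' sequenced to a fixed depth, so under total-count normalization the
#' spike-ins appear to change with dHAZ in the opposite direction of the
#' endogenous shift -- the signature the spike-in shift test detects.
#'
#' @param design A `cohort_design()` tibble.
#' @param spikein A `k4_spikein_params` (requires `n_ercc >= 10`).
#' @param n_genes Number of endogenous genes (>= 100).
#' @param de_fraction Fraction of genes with a per-gene differential effect
#'   (log2 fold-change per unit dHAZ drawn uniformly from +/-[0.3, 1]).
#' @param seed Integer seed.
#' @param depth Expected sequenced reads per sample.
#' @param ercc_fraction Fraction of each library arising from spike-ins at
#'   dHAZ = 0.
#' @param gene_dispersion NB dispersion of endogenous genes (spike-ins carry
#'   Poisson counting noise only).
#' @return A list with `counts` (features x samples integer matrix),
#'   `features` (tibble `feature_id`, `is_ercc`, `true_log2fc_per_dhaz`; the
#'   per-gene effect excludes the global shift, `NA` for spike-ins) and
#'   `metadata` (the design).
#' @export
simulate_ercc_rnaseq <- function(design, spikein, n_genes = 1000,
                                 de_fraction = 0.1, seed = 1,
                                 depth = 1.5e6, ercc_fraction = 0.02,
                                 gene_dispersion = 0.05) {
  stopifnot(inherits(spikein, "k4_spikein_params"))
  if (spikein$n_ercc < 10) stop("`n_ercc` must be at least 10")
  if (n_genes < 100) stop("`n_genes` must be at least 100")
  if (de_fraction < 0 || de_fraction > 1)
    stop("`de_fraction` must lie in [0, 1]")
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids")
  n <- nrow(design)
  dhaz <- design$delta_haz

  ercc_amount <- rep_len(spikein$ercc_mean_grid, spikein$n_ercc)
  ercc_amount <- ercc_amount / sum(ercc_amount) * ercc_fraction

  withr::with_seed(seed, {
    w <- rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
    w <- w / sum(w) * (1 - ercc_fraction)
    n_de <- round(de_fraction * n_genes)
    beta <- numeric(n_genes)
    if (n_de > 0) {
      de_idx <- sample(n_genes, n_de)
      beta[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        runif(n_de, 0.3, 1)
    }
    counts <- matrix(0L, nrow = n_genes + spikein$n_ercc, ncol = n)
    for (j in seq_len(n)) {
      w_j <- w * 2^((spikein$rna_global_shift_slope + beta) * dhaz[j])
      lib <- c(w_j, ercc_amount)
      mu <- depth * lib / sum(lib)
      counts[seq_len(n_genes), j] <-
        rnbinom(n_genes, size = 1 / gene_dispersion, mu = mu[seq_len(n_genes)])
      counts[n_genes + seq_len(spikein$n_ercc), j] <-
        rpois(spikein$n_ercc, mu[n_genes + seq_len(spikein$n_ercc)])
    }
  })

  feature_id <- c(sprintf("gene_%04d", seq_len(n_genes)),
                  sprintf("ERCC-%05d", seq_len(spikein$n_ercc)))
  rownames(counts) <- feature_id
  colnames(counts) <- design$sample_id
  features <- tibble::tibble(
    feature_id = feature_id,
    is_ercc = c(rep(FALSE, n_genes), rep(TRUE, spikein$n_ercc)),
    true_log2fc_per_dhaz = c(beta, rep(NA_real_, spikein$n_ercc)))
  list(counts = counts, features = features, metadata = design)
}

#' Simulate a negative-binomial count matrix
#'
#' Generic NB generator for calibration and recovery studies of the
#' differential module: `mu_ij = sf_j * q_i * 2^(beta_i * dHAZ_j +
#' sex_effect * [sex_j == M])` with gamma-Poisson (NB) noise.
#'
#' @param n_features Number of features.
#' @param meta Metadata tibble with `sample_id`, `delta_haz`, `sex`.
#' @param beta_log2 Per-feature log2 fold-change per unit dHAZ (recycled).
#' @param dispersion NB dispersion (recycled per feature).
#' @param size_factors Per-sample size factors; drawn uniformly from
#'   [0.7, 1.4] when `NULL` to exercise the offsets.
#' @param base_mean_meanlog,base_mean_sdlog Lognormal parameters of the
#'   per-feature baseline mean.
#' @param sex_effect_log2 Additive log2 sex effect (M vs F).
#' @param seed Integer seed.
#' @return List with `counts` (features x samples), `features` (tibble with
#'   the true `beta_log2` per feature), `size_factors` and `meta`.
#' @export
simulate_nb_counts <- function(n_features, meta, beta_log2 = 0,
                               dispersion = 0.1, size_factors = NULL,
                               base_mean_meanlog = log(100),
                               base_mean_sdlog = 1,
                               sex_effect_log2 = 0, seed = 1) {
  n <- nrow(meta)
  beta <- rep_len(beta_log2, n_features)
  disp <- rep_len(dispersion, n_features)
  withr::with_seed(seed, {
    if (is.null(size_factors)) size_factors <- runif(n, 0.7, 1.4)
    q <- rlnorm(n_features, base_mean_meanlog, base_mean_sdlog)
    sexM <- as.numeric(meta$sex == "M")
    lfc <- outer(beta, meta$delta_haz) +
      matrix(sex_effect_log2 * sexM, n_features, n, byrow = TRUE)
    mu <- (q %o% size_factors) * 2^lfc
    counts <- matrix(
      rnbinom(n_features * n, size = rep(1 / disp, n), mu = as.vector(mu)),
      nrow = n_features)
  })
  rownames(counts) <- sprintf("f_%04d", seq_len(n_features))
  colnames(counts) <- meta$sample_id
  list(counts = counts,
       features = tibble::tibble(feature_id = rownames(counts),
                                 beta_log2 = beta, dispersion = disp),
       size_factors = setNames(size_factors, meta$sample_id),
       meta = meta)
}
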