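# Small fixtures and independent oracles shared across tests. Oracles are
# deliberately naive (brute force / enumeration) and never reuse package
# internals.

tiny_genome <- function(len = 3e5) {
  genome_model(c(chrA = len, chrB = len), bin_size = 150)
}

tiny_params <- function(...) {
  redistribution_params(total_reads = 2e4, n_peaks = 40,
                        peak_width_bins = 5, ...)
}

# brute-force signed strand-aware peak-to-TSS distance: all pairs, explicit
# case analysis
oracle_distance <- function(peaks, tss) {
  out <- rep(NA_real_, nrow(peaks))
  for (j in seq_len(nrow(peaks))) {
    s <- peaks$start[j]; e <- peaks$end[j]; ch <- peaks$chrom[j]
    best_gap <- Inf; best_d <- NA_real_
    for (i in seq_len(nrow(tss))) {
      if (tss$chrom[i] != ch) next
      t <- tss$position[i]
      if (t >= s && t < e) {
        gap <- 0; d <- 0
      } else if (t < s) {
        gap <- s - t
        d <- if (tss$strand[i] == "+") gap else -gap
      } else {
        gap <- t - e
        d <- if (tss$strand[i] == "-") gap else -gap
      }
      if (gap < best_gap || (gap == best_gap && !is.na(best_d) && d > best_d)) {
        best_gap <- gap; best_d <- d
      }
    }
    out[j] <- best_d
  }
  out
}

# exhaustive hypergeometric upper tail: enumerate every subset of size n_b
# of a universe containing n_a marked elements
oracle_hyper_upper <- function(n_a, n_b, n_overlap, n_universe) {
  sets <- utils::combn(n_universe, n_b)
  hits <- colSums(sets <= n_a)  # elements 1..n_a are the marked ones
  mean(hits >= n_overlap)
}

# per-feature OLS slope of log2 normalized counts on dhaz; a lightweight
# independent estimator for generator-recovery checks
ols_log2_slopes <- function(counts, dhaz, size_factors) {
  ln <- log2(sweep(counts, 2, size_factors, "/") + 0.5)
  apply(ln, 1, function(y) coef(lm(y ~ dhaz))[2])
}
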