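# Size-factor schemes over a features x samples count matrix: total mapped
# reads, median-of-ratios (the "default" count-normalization, which assumes
# no global change in total signal), exogenous spike-in reads, and the
# exponential background fit. All factor vectors are standardized to
# geometric mean 1 so methods are directly comparable.

standardize_geomean <- function(x, method) {
  sf <- x / exp(mean(log(x)))
  attr(sf, "method") <- method
  sf
}

check_count_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("`m` must be a numeric matrix")
  if (any(m < 0)) stop("counts must be non-negative")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    stop("duplicate feature ids")
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m)))
    stop("duplicate sample ids")
  invisible(m)
}

#' Size factors from total counts
#'
#' Factors proportional to per-sample column sums (total mapped reads),
#' standardized to geometric mean 1.
#'
#' @param m Features x samples count matrix.
#' @return Named positive numeric vector with attribute `method = "total"`.
#' @export
size_factors_total <- function(m) {
  check_count_matrix(m)
  tot <- colSums(m)
  if (any(tot <= 0)) stop("every sample must have a positive total count")
  standardize_geomean(tot, "total")
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over features, of the ratio of its
#' count to the feature's geometric-mean reference; features with a zero in
#' any sample are excluded from the reference. This scheme assumes no
#' significant change in total signal across samples, which is exactly the
#' assumption a global redistribution violates -- compare against
#' [size_factors_spikein()].
#'
#' @param m Features x samples count matrix with at least one all-positive
#'   feature.
#' @return Named positive numeric vector, geometric mean 1, attribute
#'   `method = "median_of_ratios"`.
#' @export
size_factors_median_of_ratios <- function(m) {
  check_count_matrix(m)
  pos <- rowSums(m == 0) == 0
  if (!any(pos))
    stop("median-of-ratios needs at least one feature with all-positive counts")
  lg <- log(m[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - ref)))
  if (any(sf <= 0)) stop("non-positive size factor")
  standardize_geomean(sf, "median_of_ratios")
}

#' Size factors from spike-in read counts
#'
#' Factors proportional to the reads mapped to the exogenous spike-in
#' genome; because the spike-in amount per sample is fixed, these factors
#' track sequencing yield rather than endogenous signal and remain valid
#' when total endogenous signal genuinely shifts.
#'
#' @param spike_reads Named (or plain) vector of positive spike-in read
#'   counts, one per sample.
#' @return Named positive numeric vector, geometric mean 1, attribute
#'   `method = "spikein"`.
#' @export
size_factors_spikein <- function(spike_reads) {
  if (length(spike_reads) == 0) stop("`spike_reads` must be non-empty")
  if (any(!is.finite(spike_reads)) || any(spike_reads <= 0))
    stop("all spike-in read counts must be positive")
  standardize_geomean(as.numeric(spike_reads) |>
                        setNames(names(spike_reads)), "spikein")
}

#' Size factors from the exponential background fit
#'
#' Uses each sample's fitted background as a sequencing-depth proxy. The
#' default proxy is the estimated background reads per bin from the capped
#' fitted curve, `background_reads / total_bins` (i.e.
#' `sum_k k * min(N_k, N_hat_k) / total_bins`), which stays stable even when
#' the fitted slope is shallow; the alternative `"lambda"` proxy uses the
#' mean of the fitted geometric distribution, `1 / (exp(lambda) - 1)`.
#'
#' @param fits List of `k4_expfit` objects (or a [fit_cohort_background()]
#'   tibble), one per sample; requires `lambda > 0`.
#' @param proxy `"background_per_bin"` (default) or `"lambda"`.
#' @return Named positive numeric vector, geometric mean 1, attribute
#'   `method = "expfit"`.
#' @export
size_factors_expfit <- function(fits,
                                proxy = c("background_per_bin", "lambda")) {
  proxy <- match.arg(proxy)
  if (is.data.frame(fits)) fits <- attr(fits, "fits")
  if (length(fits) == 0) stop("`fits` must be non-empty")
  lam <- vapply(fits, `[[`, 0, "lambda")
  if (any(lam <= 0))
    stop("exponential-fit normalization requires lambda > 0 for every sample")
  depth <- if (proxy == "background_per_bin") {
    vapply(fits, function(f) f$background_reads / f$total_bins, 0)
  } else {
    1 / expm1(lam)
  }
  sf <- standardize_geomean(depth, "expfit")
  names(sf) <- names(fits)
  sf
}
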