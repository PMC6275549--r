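# Exponential background model for binned read counts.
#
# The read-count histogram of 150-bp bins is approximately log-linear at low
# counts: log N_k = intercept - lambda * k. Fitting that line over the
# low-count regime and capping the fitted curve at the observed histogram
# partitions each sample's reads into "background plus mistargeted" versus
# signal in peaks.

#' Read-count histogram of a binned coverage track
#'
#' @param coverage Binned coverage tibble with a `count` column (bins with
#'   zero reads included).
#' @return Object of class `k4_histogram`: `k` (0..max observed count),
#'   `n_bins` (number of bins at each k), `total_bins`, `total_reads`.
#' @export
build_histogram <- function(coverage) {
  counts <- if (is.data.frame(coverage)) coverage$count else coverage
  if (is.null(counts) || length(counts) == 0)
    stop("`coverage` must be non-empty")
  if (any(counts < 0)) stop("bin counts must be non-negative")
  max_k <- max(counts)
  n_k <- tabulate(counts + 1L, nbins = max_k + 1L)
  structure(
    list(k = 0:max_k, n_bins = n_k,
         total_bins = length(counts),
         total_reads = sum(as.numeric(counts))),
    class = "k4_histogram")
}

#' @export
print.k4_histogram <- function(x, ...) {
  cat(sprintf("k4_histogram: %d bins, %s reads, max count %d\n",
              x$total_bins, format(x$total_reads, big.mark = ","),
              max(x$k)))
  invisible(x)
}

# closed-form OLS of y on x with R^2; avoids lm() overhead inside the
# candidate-range search
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r2 <- if (syy < 1e-12) 1 else (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r_squared = r2)
}

#' Fit the exponential background model to a read-count histogram
#'
#' Ordinary least squares of `log N_k` on `k` over `[0, k_hi]` (histogram
#' points with `N_k > 0`), where the upper end `k_hi` is chosen from
#' `k_hi_candidates` by maximal R^2 -- the low-count regime is typically
#' zero to nine reads per bin but is optimized per dataset. The fitted curve
#' `N_hat_k = exp(intercept + slope * k)` is extrapolated over all observed
#' k and capped at the observed histogram, giving
#' `background_reads = sum_k k * min(N_k, N_hat_k)` and
#' `peak_reads = total_reads - background_reads` (so the partition conserves
#' the total exactly and peak mass is never negative).
#'
#' @param hist A `k4_histogram` with at least 3 occupied count values.
#' @param k_hi_candidates Candidate upper fit bounds (default 3..15).
#' @return Object of class `k4_expfit` with `slope` (<= 0), `intercept`,
#'   `lambda` (= -slope), `fit_range` `c(0, k_hi)`, `r_squared`,
#'   `background_reads`, `peak_reads`, `background_fraction`,
#'   `total_reads`, `total_bins`.
#' @export
fit_exponential <- function(hist, k_hi_candidates = 3:15) {
  stopifnot(inherits(hist, "k4_histogram"))
  occ <- which(hist$n_bins > 0)
  if (length(occ) < 3)
    stop("histogram must have at least 3 occupied count values")
  k_occ <- hist$k[occ]
  logn <- log(hist$n_bins[occ])
  cands <- sort(unique(as.integer(k_hi_candidates)))
  cands <- cands[cands >= 1 & cands <= max(k_occ)]
  best <- NULL
  for (kh in cands) {
    use <- k_occ <= kh
    if (sum(use) < 3 || length(unique(k_occ[use])) < 2) next
    fit <- ols_line(k_occ[use], logn[use])
    if (is.null(best) || fit$r_squared > best$r_squared + 1e-12) {
      best <- fit
      best$k_hi <- kh
    }
  }
  if (is.null(best))
    stop("no candidate fit range contains at least 3 histogram points")
  # a rising log-histogram is not a physical background; flatten it
  if (best$slope > 0) {
    use <- k_occ <= best$k_hi
    best$slope <- 0
    best$intercept <- mean(logn[use])
    best$r_squared <- 0
  }
  n_hat <- exp(best$intercept + best$slope * hist$k)
  background_reads <- sum(hist$k * pmin(hist$n_bins, n_hat))
  peak_reads <- hist$total_reads - background_reads
  structure(
    list(slope = best$slope,
         intercept = best$intercept,
         lambda = -best$slope,
         fit_range = c(0L, best$k_hi),
         r_squared = best$r_squared,
         background_reads = background_reads,
         peak_reads = peak_reads,
         background_fraction =
           if (hist$total_reads > 0) background_reads / hist$total_reads
           else NA_real_,
         total_reads = hist$total_reads,
         total_bins = hist$total_bins),
    class = "k4_expfit")
}

#' @export
print.k4_expfit <- function(x, ...) {
  cat(sprintf(paste0("k4_expfit: lambda %.4f, fit range [0, %d], R^2 %.4f\n",
                     "  background %.0f / peak %.0f of %.0f reads ",
                     "(background fraction %.3f)\n"),
              x$lambda, x$fit_range[2], x$r_squared, x$background_reads,
              x$peak_reads, x$total_reads, x$background_fraction))
  invisible(x)
}

#' Fit the background model across a cohort
#'
#' @param coverages Named list of binned coverage tibbles.
#' @param k_hi_candidates Passed to [fit_exponential()].
#' @return Tibble with one row per sample: `sample_id`, `lambda`,
#'   `intercept`, `k_hi`, `r2`, `background_reads`, `peak_reads`,
#'   `background_fraction`, plus the list of fits as attribute `"fits"`.
#' @export
fit_cohort_background <- function(coverages, k_hi_candidates = 3:15) {
  fits <- lapply(coverages, function(cov)
    fit_exponential(build_histogram(cov), k_hi_candidates))
  out <- tibble::tibble(
    sample_id = names(coverages) %||% as.character(seq_along(coverages)),
    lambda = vapply(fits, `[[`, 0, "lambda"),
    intercept = vapply(fits, `[[`, 0, "intercept"),
    k_hi = vapply(fits, function(f) f$fit_range[2], 0),
    r2 = vapply(fits, `[[`, 0, "r_squared"),
    background_reads = vapply(fits, `[[`, 0, "background_reads"),
    peak_reads = vapply(fits, `[[`, 0, "peak_reads"),
    background_fraction = vapply(fits, `[[`, 0, "background_fraction"))
  attr(out, "fits") <- fits
  out
}

#' Linear trend of the read partition against growth trajectory
#'
#' Ordinary least squares of the per-sample background (or peak) read
#' fraction on dHAZ, as in the partition-versus-growth panels: a negative
#' background-fraction slope means signal moves out of the background and
#' into peaks as growth improves.
#'
#' @param fits List of `k4_expfit` objects (or a `fit_cohort_background()`
#'   result carrying them).
#' @param delta_haz Per-sample dHAZ values, same length as `fits`.
#' @param quantity `"background_fraction"` or `"peak_fraction"`.
#' @return Object of class `k4_trend`: `slope_vs_dhaz`, `slope_se`,
#'   `intercept`, `n_samples`, `quantity`, and the per-sample `fractions`.
#' @export
partition_trend <- function(fits, delta_haz,
                            quantity = c("background_fraction",
                                         "peak_fraction")) {
  quantity <- match.arg(quantity)
  if (is.data.frame(fits)) fits <- attr(fits, "fits")
  if (length(fits) != length(delta_haz))
    stop("`fits` and `delta_haz` must have equal length")
  if (length(fits) < 3) stop("at least 3 samples are required")
  if (any(!is.finite(delta_haz))) stop("`delta_haz` must be finite")
  if (diff(range(delta_haz)) < 1e-12)
    stop("`delta_haz` is constant; the trend slope is undefined")
  bg <- vapply(fits, `[[`, 0, "background_fraction")
  frac <- if (quantity == "background_fraction") bg else 1 - bg
  fit <- lm(frac ~ delta_haz)
  sm <- suppressWarnings(summary(fit))$coefficients  # noiseless fits warn
  structure(
    list(slope_vs_dhaz = unname(sm["delta_haz", "Estimate"]),
         slope_se = unname(sm["delta_haz", "Std. Error"]),
         intercept = unname(sm["(Intercept)", "Estimate"]),
         n_samples = length(fits),
         quantity = quantity,
         fractions = frac,
         delta_haz = delta_haz),
    class = "k4_trend")
}

#' @export
print.k4_trend <- function(x, ...) {
  cat(sprintf("k4_trend (%s): slope %.4f +/- %.4f per dHAZ unit (n = %d)\n",
              x$quantity, x$slope_vs_dhaz, x$slope_se, x$n_samples))
  invisible(x)
}
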