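# Set-overlap and distributional significance tests: upper-tail
# hypergeometric overlap (one-sided Fisher), Wilcoxon rank-sum with an
# exact-enumeration mode, and the one-sample signed-rank test for a global
# spike-in shift.

#' Hypergeometric overlap test for two sets
#'
#' Upper-tail probability `P(X >= n_overlap)` of drawing at least the
#' observed overlap when `n_b` elements are sampled from a universe of
#' `n_universe` containing `n_a` marked elements (exact summation;
#' equivalent to a one-sided Fisher test for enrichment). `n_b` and
#' `n_universe` may be `NA` when only the overlap percentage is of
#' interest; the p-value is then `NA` -- no default universe is assumed.
#'
#' @param n_a,n_b Set sizes.
#' @param n_overlap Observed overlap (<= min(n_a, n_b)).
#' @param n_universe Universe size (>= n_a, n_b).
#' @return List of class `k4_overlap`: `n_a`, `n_b`, `n_overlap`,
#'   `n_universe`, `percent_of_a` (= 100 * n_overlap / n_a), `p_value`.
#' @examples
#' hypergeometric_overlap(829, NA, 658, NA)$percent_of_a  # 79.4%
#' @export
hypergeometric_overlap <- function(n_a, n_b, n_overlap, n_universe) {
  stop_if_not_count(n_a, "n_a")
  stop_if_not_count(n_overlap, "n_overlap")
  if (n_a == 0) stop("`n_a` must be positive")
  if (n_overlap > n_a) stop("`n_overlap` cannot exceed `n_a`")
  have_b <- length(n_b) == 1 && !is.na(n_b)
  have_u <- length(n_universe) == 1 && !is.na(n_universe)
  p <- NA_real_
  if (have_b) {
    stop_if_not_count(n_b, "n_b")
    if (n_overlap > n_b) stop("`n_overlap` cannot exceed `n_b`")
  }
  if (have_b && have_u) {
    stop_if_not_count(n_universe, "n_universe")
    if (n_a > n_universe || n_b > n_universe)
      stop("set sizes cannot exceed `n_universe`")
    if (n_a + n_b - n_overlap > n_universe)
      stop("sets of these sizes cannot fit the universe with this overlap")
    kk <- n_overlap:min(n_a, n_b)
    p <- sum(dhyper(kk, n_a, n_universe - n_a, n_b))
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(
    list(n_a = as.integer(n_a),
         n_b = if (have_b) as.integer(n_b) else NA_integer_,
         n_overlap = as.integer(n_overlap),
         n_universe = if (have_u) as.integer(n_universe) else NA_integer_,
         percent_of_a = 100 * n_overlap / n_a,
         p_value = p),
    class = "k4_overlap")
}

#' @export
print.k4_overlap <- function(x, ...) {
  cat(sprintf("k4_overlap: %d of %d (%.1f%%)%s\n",
              x$n_overlap, x$n_a, x$percent_of_a,
              if (is.na(x$p_value)) " (no universe: p not computed)"
              else sprintf(", P = %.3g (hypergeometric upper tail)",
                           x$p_value)))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with midranks for ties. In `exact` mode the p-value
#' is obtained by full enumeration of the rank assignments (requires
#' `length(x) + length(y) <= 20`); in `normal_approx` mode by normal
#' approximation with tie-corrected variance and continuity correction.
#' `auto` picks exact when feasible.
#'
#' @param x,y Non-empty numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List: `p_value`, `statistic` (rank sum of `x`), `mode`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact",
                                             "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  nx <- length(x)
  ny <- length(y)
  N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  if (mode == "auto") mode <- if (N <= 20) "exact" else "normal_approx"
  if (mode == "exact") {
    if (N > 20) stop("exact mode requires length(x) + length(y) <= 20")
    sums <- utils::combn(N, nx, FUN = function(ii) sum(r[ii]))
    eps <- 1e-9
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    tab <- table(r)
    tie_term <- sum(tab^3 - tab)
    m_w <- nx * (N + 1) / 2
    v_w <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (v_w <= 0) {
      p <- 1
    } else {
      num <- W - m_w
      num <- num - sign(num) * 0.5  # continuity correction
      p <- min(1, 2 * pnorm(-abs(num) / sqrt(v_w)))
    }
  }
  list(p_value = p, statistic = W, mode = mode)
}

# exact distribution of the signed-rank statistic by convolution over
# doubled midranks (integers even with ties); exact under H0 sign symmetry
signed_rank_exact_p <- function(ranks2, v2) {
  dist <- numeric(sum(ranks2) + 1)  # index i = statistic value i - 1
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), dist[seq_len(length(dist) - r)])
    dist <- (dist + shifted) / 2
  }
  vals <- seq_along(dist) - 1
  p_lo <- sum(dist[vals <= v2 + 1e-9])
  p_hi <- sum(dist[vals >= v2 - 1e-9])
  min(1, 2 * min(p_lo, p_hi))
}

#' One-sample test for a global spike-in shift
#'
#' Two-sided Wilcoxon signed-rank test of per-spike-in log2 fold-changes
#' per unit dHAZ against zero. A nonzero location indicates that, under the
#' chosen normalization, spike-in levels drift systematically with growth
#' trajectory -- the signature of a global endogenous shift. Zeros are
#' dropped; the p-value is exact (sign-flip enumeration over midranks) for
#' up to 50 nonzero values, else a tie-corrected normal approximation with
#' continuity correction.
#'
#' @param ercc_log2fc_per_dhaz Per-spike-in slopes (>= 6 values).
#' @return List: `median`, `p_value`, `n` (nonzero values used).
#' @export
spikein_shift_test <- function(ercc_log2fc_per_dhaz) {
  x <- ercc_log2fc_per_dhaz[!is.na(ercc_log2fc_per_dhaz)]
  if (length(x) < 6) stop("at least 6 spike-in values are required")
  med <- median(x)
  d <- x[x != 0]
  if (length(d) == 0)
    return(list(median = med, p_value = 1, n = 0L))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (length(d) <= 50) {
    p <- signed_rank_exact_p(as.integer(round(2 * r)), 2 * V)
  } else {
    m_v <- sum(r) / 2
    v_v <- sum(r^2) / 4
    num <- V - m_v
    num <- num - sign(num) * 0.5
    p <- if (v_v <= 0) 1 else min(1, 2 * pnorm(-abs(num) / sqrt(v_v)))
  }
  list(median = med, p_value = p, n = length(d))
}
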