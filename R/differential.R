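# Per-feature differential analysis against the continuous growth covariate
# dHAZ (negative-binomial log-linear models with size-factor offsets, Wald
# tests, BH-FDR), plus sample-level PCA and Pearson/Ward clustering.
#
# The Wald statistic is referred to a t distribution with residual degrees
# of freedom: with a per-feature plug-in dispersion and a few dozen samples
# the normal reference is anti-conservative in the far tail, which is where
# BH discoveries come from.

build_design_matrix <- function(meta, design = c("dhaz", "stunted"),
                                adjust_sex = TRUE) {
  design <- match.arg(design)
  x <- if (design == "dhaz") meta$delta_haz else as.numeric(meta$stunted)
  X <- if (adjust_sex) {
    cbind("(Intercept)" = 1, sexM = as.numeric(meta$sex == "M"), covariate = x)
  } else {
    cbind("(Intercept)" = 1, covariate = x)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

# NB fit of one feature: Poisson fit for a method-of-moments dispersion
# (df-corrected, floored at 1e-8), then an NB GLM with that dispersion and
# a Wald test on the last design column.
fit_nb_feature <- function(y, X, off) {
  n <- length(y)
  p <- ncol(X)
  pois <- suppressWarnings(
    glm.fit(X, y, family = poisson(), offset = off))
  mu <- pmax(pois$fitted.values, 1e-8)
  alpha <- sum(((y - mu)^2 - mu) / mu^2) / max(1, n - p)
  alpha <- min(max(alpha, 1e-8), 100)
  fit <- suppressWarnings(
    glm.fit(X, y, family = MASS::negative.binomial(theta = 1 / alpha),
            offset = off, start = pois$coefficients))
  rk <- fit$rank
  p1 <- seq_len(rk)
  covu <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  se <- rep(NA_real_, p)
  se[fit$qr$pivot[p1]] <- sqrt(diag(covu))
  list(coef = fit$coefficients, se = se, alpha = alpha)
}

#' Negative-binomial differential analysis per feature
#'
#' For each feature, fits a negative-binomial log-linear model of counts on
#' the chosen covariate (dHAZ by default, optionally a categorical
#' stunted-vs-control contrast) with size factors as offsets and sex as an
#' additive adjustment. Dispersion is a per-feature method-of-moments
#' estimate (floored at 1e-8, no shrinkage across features); the covariate
#' coefficient is assessed by a Wald test referred to a t distribution with
#' residual degrees of freedom and reported in log2 units
#' (natural-log coefficients divided by ln 2). All-zero features are
#' returned with `NA` statistics rather than raising an error.
#'
#' @param m Features x samples count matrix.
#' @param meta Metadata tibble with `sample_id`, `delta_haz`, `sex`, and
#'   `stunted` when `design = "stunted"`; rows must match the columns of
#'   `m` (matched by `sample_id` when column names are present).
#' @param size_factors Positive per-sample size factors.
#' @param design `"dhaz"` (per-unit-dHAZ slope) or `"stunted"`.
#' @param adjust_sex Include sex as an additive covariate (default TRUE;
#'   must be disabled for single-sex cohorts, where it would make the
#'   design rank deficient).
#' @return Tibble: `feature_id`, `base_mean` (mean normalized count),
#'   `log2fc_per_dhaz`, `se`, `stat`, `p_value`, `fdr`.
#' @export
fit_feature_models <- function(m, meta, size_factors,
                               design = c("dhaz", "stunted"),
                               adjust_sex = TRUE) {
  check_count_matrix(m)
  n <- ncol(m)
  if (n < 6) stop("at least 6 samples are required")
  if (nrow(meta) != n) stop("metadata rows must match matrix columns")
  if (!is.null(colnames(m)) && !is.null(meta$sample_id)) {
    idx <- match(colnames(m), meta$sample_id)
    if (any(is.na(idx))) stop("metadata is missing samples present in `m`")
    meta <- meta[idx, ]
  }
  if (length(size_factors) != n || any(size_factors <= 0))
    stop("`size_factors` must be positive, one per sample")
  X <- build_design_matrix(meta, design, adjust_sex)
  off <- log(as.numeric(size_factors))
  norm <- sweep(m, 2, size_factors, "/")

  res <- lapply(seq_len(nrow(m)), function(i) {
    y <- m[i, ]
    if (all(y == 0)) {
      return(list(coef = NA_real_, se = NA_real_))
    }
    tryCatch({
      f <- fit_nb_feature(y, X, off)
      list(coef = f$coef[ncol(X)], se = f$se[ncol(X)])
    }, error = function(e) list(coef = NA_real_, se = NA_real_))
  })
  coef_ln <- vapply(res, `[[`, 0, "coef")
  se_ln <- vapply(res, `[[`, 0, "se")
  stat <- coef_ln / se_ln
  p <- 2 * pt(-abs(stat), df = n - ncol(X))
  tibble::tibble(
    feature_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    base_mean = rowMeans(norm),
    log2fc_per_dhaz = coef_ln / log(2),
    se = se_ln / log(2),
    stat = stat,
    p_value = p,
    fdr = bh_fdr(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` p-values are left `NA` and do not count
#' toward the number of tests.
#'
#' @param p_values Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted values, same length and order; empty in, empty out.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Sample-level PCA of log-normalized counts
#'
#' PCA of `log2(count / size_factor + 1)` over the most variable features,
#' samples as observations.
#'
#' @param m Features x samples count matrix (>= 3 samples).
#' @param size_factors Positive per-sample size factors.
#' @param n_top_features Number of most-variable features used (>= 2).
#' @return List with `coordinates` (tibble `sample_id`, `PC1`, `PC2`, ...),
#'   `var_explained` (fractions, non-increasing, summing to <= 1) and
#'   `n_features`.
#' @export
pca_samples <- function(m, size_factors, n_top_features = 500) {
  check_count_matrix(m)
  if (ncol(m) < 3) stop("at least 3 samples are required")
  if (n_top_features < 2) stop("`n_top_features` must be at least 2")
  ln <- log2(sweep(m, 2, size_factors, "/") + 1)
  rv <- apply(ln, 1, var)
  top <- order(rv, decreasing = TRUE)[seq_len(min(n_top_features, nrow(ln)))]
  pr <- prcomp(t(ln[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  coords <- tibble::as_tibble(pr$x)
  coords <- dplyr::bind_cols(
    tibble::tibble(sample_id = colnames(m) %||%
                     as.character(seq_len(ncol(m)))),
    coords)
  list(coordinates = coords, var_explained = ve, n_features = length(top))
}

#' Pearson correlation and Ward clustering of samples
#'
#' Pearson correlations of `log2(normalized count + 1)` across all features,
#' hierarchically clustered with Ward linkage on distance `1 - r`. Samples
#' are ordered by id before clustering so leaf order is deterministic.
#'
#' @param m Features x samples count matrix (>= 3 samples).
#' @param size_factors Positive per-sample size factors.
#' @param linkage Agglomeration method (default `"ward.D"`).
#' @return List with `correlation` (samples x samples matrix), `hclust`,
#'   and `order` (leaf order as sample ids).
#' @export
correlation_cluster <- function(m, size_factors, linkage = "ward.D") {
  check_count_matrix(m)
  if (ncol(m) < 3) stop("at least 3 samples are required")
  if (!is.null(colnames(m))) {
    ord <- order(colnames(m))
    m <- m[, ord, drop = FALSE]
    size_factors <- size_factors[ord]
  }
  ln <- log2(sweep(m, 2, size_factors, "/") + 1)
  if (any(apply(ln, 2, var) < 1e-12))
    stop("constant sample vector; correlation is undefined")
  r <- cor(ln, method = "pearson")
  hc <- hclust(as.dist(1 - r), method = linkage)
  list(correlation = r, hclust = hc,
       order = (colnames(m) %||% as.character(seq_len(ncol(m))))[hc$order])
}
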