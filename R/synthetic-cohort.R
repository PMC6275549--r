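# Synthetic ChIP-seq cohort generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: per-bin background counts drawn from a geometric distribution (the
# discrete analogue of an exponential, so the log-linear histogram fit is
# well-specified), TSS-localized peak enrichment, and a "mistargeted" signal
# fraction that varies linearly with the growth covariate dHAZ while the
# expected total read count is identical across samples.

#' Genome model for binned coverage simulation
#'
#' Describes the (synthetic) genome over which per-bin read counts are
#' simulated: named chromosome lengths and a fixed bin width.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (150 by default, the resolution at which
#'   the background model operates).
#' @return An object of class `k4_genome` with elements `chrom_sizes`,
#'   `bin_size` and `n_bins` (bins per chromosome, `ceiling(length/bin_size)`).
#' @examples
#' genome_model(c(chr1 = 3e5), bin_size = 150)
#' @export
genome_model <- function(chrom_sizes = c(chr1 = 7.5e6, chr2 = 7.5e6),
                         bin_size = 150) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("`chrom_sizes` must be a named vector of chromosome lengths")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicate chromosome names in `chrom_sizes`")
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("chromosome lengths must be positive")
  if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0)
    stop("`bin_size` must be a single positive number")
  structure(
    list(chrom_sizes = chrom_sizes,
         bin_size = as.integer(bin_size),
         n_bins = setNames(as.integer(ceiling(chrom_sizes / bin_size)),
                           names(chrom_sizes))),
    class = "k4_genome")
}

#' Genome-wide bin table
#'
#' @param genome A `k4_genome` object.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open,
#'   sorted), one row per bin.
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "k4_genome"))
  bs <- genome$bin_size
  out <- lapply(names(genome$chrom_sizes), function(ch) {
    n <- genome$n_bins[[ch]]
    start <- (seq_len(n) - 1) * bs
    tibble::tibble(chrom = ch, start = start,
                   end = pmin(start + bs, genome$chrom_sizes[[ch]]))
  })
  dplyr::bind_rows(out)
}

#' Redistribution parameters for the cohort generator
#'
#' Controls how a sample's fixed read budget is split between peaks and the
#' genome-wide background as a function of the growth covariate dHAZ. The
#' mistargeted (non-peak) fraction of signal is
#' `m(s) = clip(mistarget_base - mistarget_slope * dHAZ_s, 0, 1)`, so samples
#' with poorer growth trajectories (more negative dHAZ) carry more dispersed
#' signal while the expected total read count is conserved.
#'
#' @param total_reads Expected total reads per sample. The default, together
#'   with the default genome (100,000 bins), keeps the non-peak component in
#'   the low-count regime (a few reads per 150-bp bin) where the log-linear
#'   background fit operates.
#' @param background_rate Exponential rate (per read) of the baseline
#'   background bin-count distribution; background counts are geometric with
#'   `P(k) ~ exp(-background_rate * k)`.
#' @param n_peaks Number of peaks.
#' @param peak_width_bins Peak width in bins.
#' @param peak_height_dispersion Coefficient of variation of per-peak height
#'   weights (gamma distributed, mean 1); 0 gives equal peaks.
#' @param mistarget_base Mistargeted signal fraction at dHAZ = 0.
#' @param mistarget_slope Decrease in mistargeted fraction per unit dHAZ.
#' @param tss_fraction_positive Fraction of peaks placed at a TSS.
#' @param distal_mistarget_fraction Optional fraction of the mistargeted mass
#'   concentrated in narrow distal ("enhancer-like") single-bin sites rather
#'   than spread uniformly; 0 disables the layer.
#' @param n_distal_sites Number of distal sites used when
#'   `distal_mistarget_fraction > 0`.
#' @return A list of class `k4_redist_params`.
#' @export
redistribution_params <- function(total_reads = 5e5,
                                  background_rate = 0.7,
                                  n_peaks = 300,
                                  peak_width_bins = 5,
                                  peak_height_dispersion = 0.5,
                                  mistarget_base = 0.3,
                                  mistarget_slope = 0.1,
                                  tss_fraction_positive = 0.8,
                                  distal_mistarget_fraction = 0,
                                  n_distal_sites = 200) {
  if (!is.finite(total_reads) || total_reads <= 0)
    stop("`total_reads` must be positive")
  if (!is.finite(background_rate) || background_rate <= 0)
    stop("`background_rate` must be positive")
  if (n_peaks < 0 || n_peaks != round(n_peaks))
    stop("`n_peaks` must be a non-negative integer")
  if (peak_width_bins < 1 || peak_width_bins != round(peak_width_bins))
    stop("`peak_width_bins` must be a positive integer")
  if (peak_height_dispersion < 0) stop("`peak_height_dispersion` must be >= 0")
  if (mistarget_base < 0 || mistarget_base > 1)
    stop("`mistarget_base` must lie in [0, 1]")
  if (tss_fraction_positive < 0 || tss_fraction_positive > 1)
    stop("`tss_fraction_positive` must lie in [0, 1]")
  if (distal_mistarget_fraction < 0 || distal_mistarget_fraction > 1)
    stop("`distal_mistarget_fraction` must lie in [0, 1]")
  structure(
    list(total_reads = total_reads,
         background_rate = background_rate,
         n_peaks = as.integer(n_peaks),
         peak_width_bins = as.integer(peak_width_bins),
         peak_height_dispersion = peak_height_dispersion,
         mistarget_base = mistarget_base,
         mistarget_slope = mistarget_slope,
         tss_fraction_positive = tss_fraction_positive,
         distal_mistarget_fraction = distal_mistarget_fraction,
         n_distal_sites = as.integer(n_distal_sites)),
    class = "k4_redist_params")
}

#' Mistargeted signal fraction for a given growth trajectory
#'
#' @param params A `k4_redist_params` object.
#' @param delta_haz Change in height-for-age z-score from birth to 1 y.
#' @return `clip(mistarget_base - mistarget_slope * delta_haz, 0, 1)`.
#' @export
mistarget_fraction <- function(params, delta_haz) {
  stopifnot(inherits(params, "k4_redist_params"))
  if (any(!is.finite(delta_haz))) stop("`delta_haz` must be finite")
  pmin(1, pmax(0, params$mistarget_base - params$mistarget_slope * delta_haz))
}

#' Spike-in parameters
#'
#' Parameters for exogenous normalization controls: ChIP spike-in chromatin
#' read counts (independent of dHAZ in expectation) and ERCC-style RNA
#' spike-ins together with a global endogenous-RNA shift along dHAZ.
#'
#' @param chip_spikein_mean Expected spike-in reads per ChIP sample.
#' @param chip_spikein_cv Technical coefficient of variation of the spike-in
#'   read yield (lognormal, on top of Poisson counting noise).
#' @param n_ercc Number of ERCC-style spike-in species (>= 10).
#' @param ercc_mean_grid Relative abundance grid recycled across spike-in
#'   species (the ERCC mix spans a wide concentration range).
#' @param rna_global_shift_slope Global shift of endogenous RNA output in
#'   log2 units per unit dHAZ; under total-count normalization this drives the
#'   apparent ERCC fold-change away from zero in the opposite direction.
#' @return A list of class `k4_spikein_params`.
#' @export
spikein_params <- function(chip_spikein_mean = 1e5,
                           chip_spikein_cv = 0.01,
                           n_ercc = 92,
                           ercc_mean_grid = 2^seq(0, 7, length.out = 23),
                           rna_global_shift_slope = 0.5) {
  if (!is.finite(chip_spikein_mean) || chip_spikein_mean <= 0)
    stop("`chip_spikein_mean` must be positive")
  if (chip_spikein_cv < 0) stop("`chip_spikein_cv` must be >= 0")
  if (n_ercc < 10) stop("`n_ercc` must be at least 10")
  if (any(ercc_mean_grid <= 0)) stop("`ercc_mean_grid` must be positive")
  structure(
    list(chip_spikein_mean = chip_spikein_mean,
         chip_spikein_cv = chip_spikein_cv,
         n_ercc = as.integer(n_ercc),
         ercc_mean_grid = ercc_mean_grid,
         rna_global_shift_slope = rna_global_shift_slope),
    class = "k4_spikein_params")
}

#' Cohort design: growth trajectories and covariates
#'
#' Draws (or accepts) per-sample height-for-age z-scores at birth and 52
#' weeks. `delta_haz = haz_52wk - haz_birth` is the growth-trajectory
#' covariate; `stunted` is `haz_52wk < -2` (strict inequality, so a child at
#' exactly -2 is classified control). Defaults emulate a growth-faltering
#' birth cohort in which stunting emerges during the first year.
#'
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param haz_birth,delta_haz,sex,sample_id Optional explicit per-sample
#'   values; drawn from cohort defaults when `NULL`.
#' @return A tibble with columns `sample_id`, `haz_birth`, `haz_52wk`,
#'   `delta_haz`, `sex`, `stunted`, carrying the seed as an attribute.
#' @export
cohort_design <- function(n_samples = 24, seed = 1, haz_birth = NULL,
                          delta_haz = NULL, sex = NULL, sample_id = NULL) {
  if (n_samples < 2) stop("`n_samples` must be at least 2")
  withr::with_seed(seed, {
    if (is.null(haz_birth))
      haz_birth <- rnorm(n_samples, mean = -0.7, sd = 0.7)
    if (is.null(delta_haz))
      delta_haz <- rnorm(n_samples, mean = -0.6, sd = 0.9)
    if (is.null(sex))
      sex <- sample(rep_len(c("F", "M"), n_samples))
  })
  if (is.null(sample_id)) sample_id <- sprintf("S%02d", seq_len(n_samples))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  stopifnot(length(haz_birth) == n_samples, length(delta_haz) == n_samples,
            length(sex) == n_samples, all(sex %in% c("F", "M")))
  haz_52wk <- haz_birth + delta_haz
  design <- tibble::tibble(
    sample_id = sample_id,
    haz_birth = haz_birth,
    haz_52wk = haz_52wk,
    delta_haz = delta_haz,
    sex = sex,
    stunted = haz_52wk < -2)
  attr(design, "seed") <- as.integer(seed)
  design
}

#' Peak and TSS layout for a synthetic cohort
#'
#' Places non-overlapping peaks (a fraction centred on TSSs, the remainder
#' distal), draws per-peak height weights, and fixes a within-peak triangular
#' kernel. The layout is shared by all samples of a cohort so that the same
#' loci are enriched in every sample.
#'
#' @param genome A `k4_genome`.
#' @param params A `k4_redist_params`.
#' @param seed Integer seed.
#' @return A list with `bins`, `peaks` (tibble with `at_tss` flag and height
#'   `weight`), `tss` (tibble `chrom`, `position`, `strand`, `gene_id`),
#'   `peak_bins` (global bin indices), `w_bin` (expected signal weight per
#'   bin, summing to 1 over peak bins) and `distal_bins`.
#' @export
peak_layout <- function(genome, params, seed = 1) {
  stopifnot(inherits(genome, "k4_genome"), inherits(params, "k4_redist_params"))
  bins <- genome_bins(genome)
  total_bins <- nrow(bins)
  w <- params$peak_width_bins
  half <- (w - 1L) %/% 2L
  spacing <- w + 4L
  cand <- integer(0)
  offset <- 0L
  for (ch in names(genome$chrom_sizes)) {
    n <- genome$n_bins[[ch]]
    lo <- half + 2L
    hi <- n - (w - 1L - half) - 2L
    if (hi >= lo) cand <- c(cand, offset + seq.int(lo, hi, by = spacing))
    offset <- offset + n
  }
  n_at_tss <- round(params$tss_fraction_positive * params$n_peaks)
  n_distal <- params$n_peaks - n_at_tss
  n_free_tss <- n_distal  # genes whose TSS carries no simulated peak
  n_distal_sites <- if (params$distal_mistarget_fraction > 0)
    params$n_distal_sites else 0L
  need <- params$n_peaks + n_free_tss + n_distal_sites
  if (length(cand) < need)
    stop("genome too small for the requested peak layout")
  withr::with_seed(seed, {
    slots <- if (need > 0) sample(cand, need) else integer(0)
    strand <- sample(c("+", "-"), n_at_tss + n_free_tss, replace = TRUE)
    weight <- if (params$n_peaks == 0) numeric(0)
    else if (params$peak_height_dispersion > 0) {
      shape <- 1 / params$peak_height_dispersion^2
      rgamma(params$n_peaks, shape = shape, scale = 1 / shape)
    } else rep(1, params$n_peaks)
  })
  peak_centres <- slots[seq_len(params$n_peaks)]
  tss_centres <- c(slots[seq_len(n_at_tss)],
                   slots[params$n_peaks + seq_len(n_free_tss)])
  distal_bins <- slots[params$n_peaks + n_free_tss + seq_len(n_distal_sites)]

  # triangular within-peak kernel, maximal at the centre bin
  rel <- seq_len(w) - (w + 1) / 2
  kern <- (w + 1) / 2 - abs(rel)
  kern <- kern / sum(kern)

  w_bin <- numeric(total_bins)
  peak_bins <- integer(0)
  if (params$n_peaks > 0) {
    starts <- peak_centres - half
    idx <- rep(starts, each = w) + rep.int(seq_len(w) - 1L, params$n_peaks)
    vals <- rep(weight, each = w) * rep.int(kern, params$n_peaks)
    w_bin[idx] <- vals
    w_bin <- w_bin / sum(w_bin)
    peak_bins <- sort(idx)
  }

  peaks <- if (params$n_peaks > 0) tibble::tibble(
    chrom = bins$chrom[peak_centres - half],
    start = bins$start[peak_centres - half],
    end = bins$end[peak_centres - half + (w - 1L)],
    name = sprintf("peak_%04d", seq_len(params$n_peaks)),
    weight = weight,
    at_tss = seq_len(params$n_peaks) <= n_at_tss)
  else tibble::tibble(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      weight = numeric(), at_tss = logical())

  n_tss <- length(tss_centres)
  tss <- tibble::tibble(
    chrom = bins$chrom[tss_centres],
    position = bins$start[tss_centres] + genome$bin_size %/% 2L,
    strand = strand[seq_len(n_tss)],
    gene_id = sprintf("gene_%04d", seq_len(n_tss)))

  list(bins = bins, peaks = peaks, tss = tss, peak_bins = peak_bins,
       w_bin = w_bin, distal_bins = distal_bins)
}

#' Simulate binned read counts for one sample
#'
#' Expected reads are split into a flat geometric background (rate
#' `background_rate` in every bin), a mistargeted component
#' `m(dHAZ) * signal` added uniformly to non-peak bins (keeping non-peak
#' counts geometric, with an optionally concentrated distal layer), and an
#' in-peak component `(1 - m) * signal` distributed over peak bins by the
#' layout weights. The expected total equals `total_reads` for every sample
#' regardless of dHAZ, so signal is redistributed, not lost.
#'
#' @param genome A `k4_genome`.
#' @param params A `k4_redist_params`; requires `total_reads >= n_peaks` and
#'   enough reads to cover the baseline background.
#' @param delta_haz Single finite growth-trajectory value.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param layout Optional shared `peak_layout()`; built from `seed` when
#'   missing.
#' @return Tibble `chrom`, `start`, `end`, `count` (a bedGraph-style binned
#'   coverage), with attributes `bin_size`, `delta_haz` and
#'   `mistarget_fraction`.
#' @export
simulate_sample_bins <- function(genome, params, delta_haz, seed,
                                 layout = NULL) {
  stopifnot(inherits(genome, "k4_genome"), inherits(params, "k4_redist_params"))
  if (length(delta_haz) != 1 || !is.finite(delta_haz))
    stop("`delta_haz` must be a single finite value")
  if (params$total_reads < params$n_peaks)
    stop("`total_reads` must be at least `n_peaks`")
  if (is.null(layout)) layout <- peak_layout(genome, params, seed)
  bins <- layout$bins
  total_bins <- nrow(bins)
  m <- mistarget_fraction(params, delta_haz)
  mu0 <- 1 / expm1(params$background_rate)
  signal <- params$total_reads - total_bins * mu0
  if (signal <= 0)
    stop("`total_reads` too small for the requested background rate")

  is_peak <- rep(FALSE, total_bins)
  is_peak[layout$peak_bins] <- TRUE
  np_idx <- which(!is_peak)
  counts <- numeric(total_bins)

  if (length(layout$peak_bins) == 0) {
    # no peaks: the whole signal budget is background-like by construction
    mist <- signal
    peak_mass <- 0
  } else {
    mist <- m * signal
    peak_mass <- (1 - m) * signal
  }
  distal_mass <- mist * params$distal_mistarget_fraction
  unif_mass <- mist - distal_mass
  mu_np <- mu0 + unif_mass / length(np_idx)

  wpk <- layout$w_bin[layout$peak_bins]
  withr::with_seed(seed, {
    counts[np_idx] <- rgeom(length(np_idx), prob = 1 / (1 + mu_np))
    if (length(layout$peak_bins) > 0)
      counts[layout$peak_bins] <- rgeom(length(layout$peak_bins),
                                        prob = 1 / (1 + mu0)) +
        rpois(length(layout$peak_bins), peak_mass * wpk)
    if (distal_mass > 0 && length(layout$distal_bins) > 0)
      counts[layout$distal_bins] <- counts[layout$distal_bins] +
        rpois(length(layout$distal_bins),
              distal_mass / length(layout$distal_bins))
  })

  out <- bins
  out$count <- as.integer(counts)
  attr(out, "bin_size") <- genome$bin_size
  attr(out, "delta_haz") <- delta_haz
  attr(out, "mistarget_fraction") <- m
  out
}

#' Simulate a full ChIP-seq cohort
#'
#' Generates one binned coverage track per sample over a shared peak/TSS
#' layout, plus spike-in read counts (independent of dHAZ in expectation) and
#' a metadata table. Deterministic given the seed.
#'
#' @param genome A `k4_genome`.
#' @param design A `cohort_design()` tibble.
#' @param params A `k4_redist_params`.
#' @param spikein A `k4_spikein_params`.
#' @param seed Integer seed; defaults to the design's seed.
#' @param dir Optional directory: when given, writes per-sample bedGraph
#'   files, `peaks.bed`, `tss.bed` and `metadata.csv`.
#' @return A list of class `k4_cohort` with elements `coverage` (named list
#'   of binned-coverage tibbles), `peaks`, `tss`, `metadata` (including
#'   `spikein_reads` and the `stunted` flag `haz_52wk < -2`), `layout`,
#'   `genome`, `params`, `spikein`.
#' @export
simulate_cohort <- function(genome, design, params, spikein,
                            seed = NULL, dir = NULL) {
  stopifnot(inherits(spikein, "k4_spikein_params"))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids")
  if (any(abs(design$haz_52wk - design$haz_birth - design$delta_haz) > 1e-8))
    stop("`delta_haz` must equal `haz_52wk - haz_birth`")
  seed <- seed %||% attr(design, "seed") %||% 1L
  layout <- peak_layout(genome, params, seed)
  n <- nrow(design)
  coverage <- vector("list", n)
  names(coverage) <- design$sample_id
  for (i in seq_len(n)) {
    coverage[[i]] <- simulate_sample_bins(genome, params, design$delta_haz[i],
                                          seed = sample_seed(seed, i),
                                          layout = layout)
  }
  spikein_reads <- withr::with_seed(sample_seed(seed, 0), {
    mu <- spikein$chip_spikein_mean *
      exp(rnorm(n, -spikein$chip_spikein_cv^2 / 2, spikein$chip_spikein_cv))
    rpois(n, mu)
  })
  metadata <- design
  metadata$spikein_reads <- spikein_reads
  metadata$stunted <- metadata$haz_52wk < -2

  cohort <- structure(
    list(coverage = coverage, peaks = layout$peaks, tss = layout$tss,
         metadata = metadata, layout = layout, genome = genome,
         params = params, spikein = spikein, seed = as.integer(seed)),
    class = "k4_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.k4_cohort <- function(x, ...) {
  cat(sprintf("k4_cohort: %d samples, %d peaks, %d TSS, %d bins (seed %d)\n",
              nrow(x$metadata), nrow(x$peaks), nrow(x$tss),
              nrow(x$layout$bins), x$seed))
  invisible(x)
}
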