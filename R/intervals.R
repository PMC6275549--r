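# Interval arithmetic and positional summaries: strand-aware TSS distances,
# TSS-proximity fractions, peak-set overlap, and metagene profiles.
# Coordinates are 0-based half-open (BED convention) throughout; a TSS is a
# single bp.

#' Signed strand-aware distance from peaks to the nearest TSS
#'
#' Returns 0 when a TSS lies within `[start, end)`; otherwise the smallest
#' gap between the peak edge and a TSS, signed positive when the peak lies
#' downstream of that TSS in the TSS's strand orientation (right of a `+`
#' TSS, left of a `-` TSS). Ties are broken toward the smaller absolute
#' distance, then toward the positive sign. Peaks on chromosomes with no
#' TSS get `NA` (a "no neighbor" sentinel, not an error).
#'
#' @param peaks Tibble/data frame with `chrom`, `start`, `end`.
#' @param tss Tibble with `chrom`, `position`, `strand` (non-empty).
#' @return Numeric vector of signed distances, one per peak.
#' @export
distance_to_nearest_tss <- function(peaks, tss) {
  if (is.null(tss) || nrow(tss) == 0) stop("`tss` must be non-empty")
  stopifnot(all(tss$strand %in% c("+", "-")))
  out <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    sel <- tss$chrom == ch
    if (!any(sel)) next
    ord <- order(tss$position[sel])
    pos <- tss$position[sel][ord]
    str <- tss$strand[sel][ord]
    for (j in which(peaks$chrom == ch)) {
      s <- peaks$start[j]
      e <- peaks$end[j]
      n_le_em1 <- findInterval(e - 1, pos)
      n_le_sm1 <- findInterval(s - 1, pos)
      if (n_le_em1 > n_le_sm1) {        # a TSS falls inside [s, e)
        out[j] <- 0
        next
      }
      cand <- integer(0)
      if (n_le_sm1 >= 1)
        cand <- c(cand, which(pos == pos[n_le_sm1]))      # nearest on the left
      if (n_le_sm1 + 1 <= length(pos))
        cand <- c(cand, which(pos == pos[n_le_sm1 + 1]))  # nearest on the right
      best_gap <- Inf
      best_d <- NA_real_
      for (ci in unique(cand)) {
        t <- pos[ci]
        gap <- if (t < s) s - t else t - e
        gap <- max(gap, 0)
        downstream <- if (str[ci] == "+") t < s else t >= e
        d <- if (downstream) gap else -gap
        if (gap < best_gap || (gap == best_gap && !is.na(best_d) && d > best_d)) {
          best_gap <- gap
          best_d <- d
        }
      }
      out[j] <- best_d
    }
  }
  out
}

#' Fraction of peaks within a radius of a TSS
#'
#' Distance is measured from the nearest peak edge (peaks are intervals
#' without guaranteed summits); peaks with no TSS on their chromosome count
#' as non-proximal.
#'
#' @param peaks Non-empty peak table (`chrom`, `start`, `end`).
#' @param tss TSS table (`chrom`, `position`, `strand`).
#' @param radius Proximity radius in bp (default 2000, i.e. "within 2 kb").
#' @return Fraction in [0, 1].
#' @export
proximal_fraction <- function(peaks, tss, radius = 2000) {
  if (is.null(peaks) || nrow(peaks) == 0) stop("`peaks` must be non-empty")
  if (radius < 0) stop("`radius` must be non-negative")
  d <- distance_to_nearest_tss(peaks, tss)
  prox <- !is.na(d) & abs(d) <= radius
  mean(prox)
}

#' Overlap between two peak sets
#'
#' A peak of `a` overlaps `b` when it shares at least 1 bp with any interval
#' of `b`; each peak is counted once.
#'
#' @param a,b Peak tables (`chrom`, `start`, `end`), 0-based half-open.
#' @return List with `n_a`, `n_b`, `n_a_overlapping_b`, `fraction`
#'   (`n_a_overlapping_b / n_a`).
#' @export
peak_set_overlap <- function(a, b) {
  as_gr <- function(x) {
    if (is.null(x) || nrow(x) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(
      seqnames = x$chrom,
      ranges = IRanges::IRanges(start = x$start + 1, end = x$end))
  }
  ga <- as_gr(a)
  gb <- as_gr(b)
  n_hit <- if (length(ga) == 0 || length(gb) == 0) 0L
  else sum(IRanges::overlapsAny(ga, gb))
  list(n_a = length(ga), n_b = length(gb),
       n_a_overlapping_b = n_hit,
       fraction = if (length(ga) > 0) n_hit / length(ga) else NA_real_)
}

#' Metagene profile of binned coverage around TSSs
#'
#' Averages read density over a symmetric offset grid centred on each TSS,
#' orienting minus-strand TSSs so that positive offsets always point in the
#' direction of transcription. Only TSSs whose full window lies inside the
#' covered chromosome are used. Values are the per-bin read counts at each
#' offset, optionally scaled to reads per million mapped reads.
#'
#' @param coverage Binned coverage tibble (`chrom`, `start`, `end`, `count`)
#'   with regular bins (e.g. from [simulate_sample_bins()] or
#'   [read_bedgraph()]).
#' @param tss TSS table (`chrom`, `position`, `strand`).
#' @param window Half-window in bp (profile spans -window..+window).
#' @param step Offset grid step in bp; `window` must be a multiple of it.
#' @param normalize Scale by `1e6 / total mapped reads` (default). Disable
#'   to obtain a profile that is additive across coverage tracks.
#' @return Object of class `k4_metagene`: `offsets`, `mean_signal`, `n_tss`,
#'   `normalized`.
#' @export
metagene_profile <- function(coverage, tss, window = 2000, step = 50,
                             normalize = TRUE) {
  if (window <= 0 || step <= 0 || window %% step != 0)
    stop("`window` must be a positive multiple of `step`")
  shared <- intersect(unique(coverage$chrom), unique(tss$chrom))
  if (length(shared) == 0)
    stop("no TSS on covered chromosomes")
  bin_size <- attr(coverage, "bin_size") %||%
    max(coverage$end - coverage$start)
  offsets <- seq(-window, window, by = step)
  acc <- numeric(length(offsets))
  n_used <- 0L
  total_reads <- sum(as.numeric(coverage$count))
  for (ch in shared) {
    cov_ch <- coverage[coverage$chrom == ch, ]
    counts <- cov_ch$count[order(cov_ch$start)]
    chrom_span <- max(cov_ch$end)
    tss_ch <- tss[tss$chrom == ch, ]
    for (i in seq_len(nrow(tss_ch))) {
      p0 <- tss_ch$position[i]
      pos <- if (tss_ch$strand[i] == "+") p0 + offsets else p0 - offsets
      if (min(pos) < 0 || max(pos) >= chrom_span) next
      acc <- acc + counts[pos %/% bin_size + 1L]
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L)
    stop("no TSS with a full window inside the covered chromosomes")
  mean_signal <- acc / n_used
  if (normalize) {
    if (total_reads <= 0) stop("cannot normalize a coverage with no reads")
    mean_signal <- mean_signal * 1e6 / total_reads
  }
  structure(
    list(offsets = offsets, mean_signal = mean_signal, n_tss = n_used,
         normalized = normalize),
    class = "k4_metagene")
}

#' @export
print.k4_metagene <- function(x, ...) {
  cat(sprintf("k4_metagene: %d offsets (%d..%d bp), %d TSS, max %.3f at %+d bp\n",
              length(x$offsets), min(x$offsets), max(x$offsets), x$n_tss,
              max(x$mean_signal), x$offsets[which.max(x$mean_signal)]))
  invisible(x)
}

#' Peak-level count matrix from binned coverage tracks
#'
#' Sums the bin counts falling inside each peak for every sample. All
#' coverage tracks must share the same bin grid.
#'
#' @param coverages Named list of binned coverage tibbles.
#' @param peaks Peak table (`chrom`, `start`, `end`, optional `name`).
#' @return Integer matrix peaks x samples with peak names as rownames.
#' @export
counts_in_peaks <- function(coverages, peaks) {
  if (length(coverages) == 0) stop("`coverages` must be non-empty")
  if (nrow(peaks) == 0) stop("`peaks` must be non-empty")
  template <- coverages[[1]]
  bin_size <- attr(template, "bin_size") %||%
    max(template$end - template$start)
  key <- paste0(template$chrom, ":", template$start)
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    starts <- seq((peaks$start[i] %/% bin_size) * bin_size,
                  peaks$end[i] - 1, by = bin_size)
    idx <- match(paste0(peaks$chrom[i], ":", starts), key)
    idx[!is.na(idx)]
  })
  out <- vapply(coverages, function(cov) {
    vapply(rows, function(r) sum(cov$count[r]), 0)
  }, numeric(nrow(peaks)))
  nm <- if ("name" %in% names(peaks)) peaks$name
  else sprintf("peak_%04d", seq_len(nrow(peaks)))
  matrix(as.integer(out), nrow = nrow(peaks),
         dimnames = list(nm, names(coverages)))
}
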