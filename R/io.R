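# Readers/writers for the plain-text interchange formats: bedGraph binned
# coverage, BED6 peaks/TSS, count-matrix TSV and metadata CSV. Genomic file
# parsing is delegated to rtracklayer; tables use readr.

#' Read binned coverage from a bedGraph file
#'
#' @param path bedGraph file (chrom, start, end, count; 0-based half-open).
#' @return Sorted tibble `chrom`, `start`, `end`, `count` with a `bin_size`
#'   attribute inferred from the bin widths.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    count = as.integer(gr$score))
  out <- out[order(out$chrom, out$start), ]
  attr(out, "bin_size") <- max(out$end - out$start)
  out
}

#' Write binned coverage to a bedGraph file
#'
#' @param coverage Tibble `chrom`, `start`, `end`, `count`.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = coverage$chrom,
    ranges = IRanges::IRanges(start = coverage$start + 1,
                              end = coverage$end),
    score = coverage$count)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file (up to 6 columns, no header).
#' @return Tibble `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (strand `"."` where absent).
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = strand)
}

#' Write intervals to a BED6 file
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed6 <- function(x, path) {
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = strand)
  gr$name <- if ("name" %in% names(x)) x$name
  else sprintf("feature_%04d", seq_len(nrow(x)))
  gr$score <- if ("score" %in% names(x)) x$score else 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Convert a TSS table to/from BED6 intervals
#'
#' A TSS is stored as the 1-bp interval `[position, position + 1)`.
#'
#' @param tss Tibble `chrom`, `position`, `strand`, `gene_id`.
#' @return BED6-style tibble.
#' @export
tss_to_bed <- function(tss) {
  tibble::tibble(chrom = tss$chrom, start = tss$position,
                 end = tss$position + 1, name = tss$gene_id,
                 score = 0, strand = tss$strand)
}

#' @rdname tss_to_bed
#' @param bed BED6-style tibble of 1-bp TSS intervals.
#' @export
bed_to_tss <- function(bed) {
  tibble::tibble(chrom = bed$chrom, position = bed$start,
                 strand = bed$strand, gene_id = bed$name)
}

#' Read/write a features x samples count matrix as TSV
#'
#' @param path TSV with a `feature_id` column and one column per sample.
#' @return Integer matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_count_matrix
#' @param m Count matrix.
#' @export
write_count_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read/write the sample metadata CSV
#'
#' Columns: `sample_id`, `haz_birth`, `haz_52wk`, `delta_haz`, `sex`,
#' `spikein_reads`, `stunted`.
#'
#' @param path CSV path.
#' @return Metadata tibble.
#' @export
read_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(sample_id = "c", sex = "c",
                                          stunted = "l", .default = "d"))
}

#' @rdname read_metadata
#' @param metadata Metadata tibble.
#' @export
write_metadata <- function(metadata, path) {
  cols <- c("sample_id", "haz_birth", "haz_52wk", "delta_haz", "sex",
            "spikein_reads", "stunted")
  readr::write_csv(metadata[, intersect(cols, names(metadata))], path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes one bedGraph per sample plus `peaks.bed`, `tss.bed` and
#' `metadata.csv` into `dir`.
#'
#' @param cohort A `k4_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "k4_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$coverage))
    write_bedgraph(cohort$coverage[[id]],
                   file.path(dir, paste0(id, ".bedGraph")))
  write_bed6(dplyr::mutate(cohort$peaks, score = weight),
             file.path(dir, "peaks.bed"))
  write_bed6(tss_to_bed(cohort$tss), file.path(dir, "tss.bed"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  invisible(dir)
}
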