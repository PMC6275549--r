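peak_df <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}
tss_df <- function(chrom, position, strand) {
  tibble::tibble(chrom = chrom, position = position, strand = strand,
                 gene_id = sprintf("g%02d", seq_along(position)))
}

test_that("TSS distance is zero on containment and signed by strand", {
  tss <- tss_df("chr1", 150, "+")
  expect_equal(distance_to_nearest_tss(peak_df("chr1", 100, 200), tss), 0)
  # peak downstream of a + TSS: positive
  expect_equal(distance_to_nearest_tss(peak_df("chr1", 300, 400), tss), 150)
  # peak downstream of a - TSS (peak left of TSS): positive
  expect_equal(
    distance_to_nearest_tss(peak_df("chr1", 300, 400),
                            tss_df("chr1", 500, "-")), 100)
  # peak upstream of a + TSS: negative
  expect_equal(
    distance_to_nearest_tss(peak_df("chr1", 300, 400),
                            tss_df("chr1", 500, "+")), -100)
  # no TSS on the chromosome: NA sentinel, not an error
  expect_true(is.na(distance_to_nearest_tss(peak_df("chr2", 0, 100), tss)))
  expect_error(distance_to_nearest_tss(peak_df("chr1", 0, 100), tss[0, ]),
               "non-empty")
})

test_that("TSS distances match the brute-force oracle on random layouts", {
  withr::with_seed(99, {
    for (rep in 1:40) {
      n_p <- sample(3:12, 1)
      n_t <- sample(1:8, 1)
      st <- sample(0:5000, n_p) * 10
      peaks <- peak_df(sample(c("c1", "c2"), n_p, TRUE), st, st + 500)
      tss <- tss_df(sample(c("c1", "c2"), n_t, TRUE),
                    sample(0:50000, n_t), sample(c("+", "-"), n_t, TRUE))
      expect_equal(distance_to_nearest_tss(peaks, tss),
                   oracle_distance(peaks, tss))
    }
  })
})

test_that("proximal fraction counts peaks within the radius", {
  tss <- tss_df("chr1", c(1000, 50000), c("+", "-"))
  # gaps to nearest TSS: 0 (contained), 1400, 1100, ~149600
  peaks <- peak_df("chr1",
                   c(500, 2500, 48500, 200000),
                   c(1100, 2900, 48900, 200400))
  expect_equal(proximal_fraction(peaks, tss, radius = 2000), 0.75)
  expect_equal(proximal_fraction(peaks, tss, radius = 0), 0.25)
  expect_error(proximal_fraction(peaks[0, ], tss), "non-empty")
  # monotone non-decreasing in radius
  radii <- c(0, 100, 1000, 2000, 1e5)
  fr <- vapply(radii, function(r) proximal_fraction(peaks, tss, r), 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("peak set overlap counts each peak once", {
  a <- peak_df("chr1", c(0, 200), c(100, 300))
  expect_equal(peak_set_overlap(a, a)$fraction, 1.0)
  b_far <- peak_df("chr1", c(1000, 2000), c(1100, 2100))
  expect_equal(peak_set_overlap(a, b_far)$fraction, 0.0)
  b <- peak_df("chr1", 90, 110)
  ov <- peak_set_overlap(a, b)
  expect_equal(ov$n_a_overlapping_b, 1)
  expect_equal(ov$fraction, 0.5)
  # half-open: [0,100) does not overlap [100,200)
  expect_equal(
    peak_set_overlap(peak_df("chr1", 0, 100),
                     peak_df("chr1", 100, 200))$n_a_overlapping_b, 0)
})

test_that("metagene profile is flat for uniform coverage and centred on
          TSS-localized signal", {
  g <- genome_model(c(chrU = 6e4), bin_size = 150)
  cov <- genome_bins(g)
  attr(cov, "bin_size") <- 150
  cov$count <- 7L
  tss <- tss_df("chrU", c(10000, 30000, 50000), c("+", "-", "+"))
  pr <- metagene_profile(cov, tss, window = 2000, step = 50)
  expect_equal(pr$offsets, seq(-2000, 2000, 50))
  expect_equal(pr$mean_signal, rep(7 * 1e6 / sum(cov$count),
                                   length(pr$offsets)))
  expect_equal(pr$n_tss, 3)

  # one sharp peak at every TSS: maximum at offset 0
  cov2 <- cov
  cov2$count <- 1L
  for (p in tss$position) cov2$count[p %/% 150 + 1] <- 500L
  pr2 <- metagene_profile(cov2, tss, window = 2000, step = 50)
  # offset 0 attains the maximum (offsets inside the TSS bin tie with it)
  expect_equal(pr2$mean_signal[pr2$offsets == 0], max(pr2$mean_signal))
  expect_lt(pr2$mean_signal[pr2$offsets == 2000],
            pr2$mean_signal[pr2$offsets == 0])

  # signal 500 bp downstream of a minus-strand TSS appears at +500
  cov3 <- cov
  cov3$count <- 0L
  cov3$count[(30000 - 500) %/% 150 + 1] <- 100L
  pr3 <- metagene_profile(cov3, tss_df("chrU", 30000, "-"),
                          window = 2000, step = 50, normalize = FALSE)
  expect_gt(pr3$mean_signal[pr3$offsets == 500], 0)
  expect_equal(pr3$mean_signal[pr3$offsets == -500], 0)

  expect_error(metagene_profile(cov, tss_df("chrZ", 100, "+")),
               "covered chromosomes")
  expect_error(metagene_profile(cov, tss, window = 2000, step = 300),
               "multiple")
})

test_that("mirroring coordinates and flipping strands leaves distances
          invariant", {
  withr::with_seed(7, {
    L <- 1e5
    s <- sample(0:900, 20) * 100
    peaks <- peak_df("c1", s, s + 300)
    tss <- tss_df("c1", sample(0:L, 10), sample(c("+", "-"), 10, TRUE))
    d <- distance_to_nearest_tss(peaks, tss)
    m_peaks <- peak_df("c1", L - peaks$end, L - peaks$start)
    m_tss <- tss_df("c1", L - tss$position,
                    ifelse(tss$strand == "+", "-", "+"))
    expect_equal(distance_to_nearest_tss(m_peaks, m_tss), d)
  })
})

test_that("unnormalized metagene profiles are additive", {
  g <- genome_model(c(chrU = 6e4), bin_size = 150)
  tss <- tss_df("chrU", c(10000, 30000), c("+", "-"))
  mk <- function(seed) {
    cov <- genome_bins(g)
    attr(cov, "bin_size") <- 150
    cov$count <- withr::with_seed(seed, rpois(nrow(cov), 5))
    cov
  }
  a <- mk(1); b <- mk(2)
  ab <- a; ab$count <- a$count + b$count
  pa <- metagene_profile(a, tss, 1000, 50, normalize = FALSE)
  pb <- metagene_profile(b, tss, 1000, 50, normalize = FALSE)
  pab <- metagene_profile(ab, tss, 1000, 50, normalize = FALSE)
  expect_equal(pab$mean_signal, pa$mean_signal + pb$mean_signal)
})

test_that("counts_in_peaks sums the bins inside each peak", {
  g <- genome_model(c(chrA = 3000), bin_size = 150)
  cov <- genome_bins(g)
  attr(cov, "bin_size") <- 150
  cov$count <- seq_len(nrow(cov))  # bin i holds i reads
  peaks <- tibble::tibble(chrom = "chrA", start = c(0, 600),
                          end = c(300, 900), name = c("p1", "p2"))
  m <- counts_in_peaks(list(s1 = cov), peaks)
  expect_equal(unname(m[, "s1"]), c(1 + 2, 5 + 6))
})
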