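test_that("mistargeted fraction is linear in dHAZ and clipped to [0, 1]", {
  p <- redistribution_params(mistarget_base = 0.3, mistarget_slope = 0.1)
  expect_equal(mistarget_fraction(p, 0), 0.30)
  expect_equal(mistarget_fraction(p, -1), 0.40)
  expect_equal(mistarget_fraction(p, 3), 0.0)   # clipped at 0
  expect_equal(mistarget_fraction(p, -10), 1.0) # clipped at 1
  expect_error(mistarget_fraction(p, NaN), "finite")
})

test_that("total reads are conserved across samples with opposite dHAZ", {
  g <- genome_model()
  p <- redistribution_params()
  layout <- peak_layout(g, p, seed = 42)
  a <- simulate_sample_bins(g, p, delta_haz = -2, seed = 1, layout = layout)
  b <- simulate_sample_bins(g, p, delta_haz = 1, seed = 2, layout = layout)
  expect_lt(abs(sum(a$count) - sum(b$count)) / p$total_reads, 0.02)
  expect_lt(abs(sum(a$count) - p$total_reads) / p$total_reads, 0.02)
  expect_lt(abs(sum(b$count) - p$total_reads) / p$total_reads, 0.02)
})

test_that("non-peak read fraction decreases with dHAZ across a cohort", {
  g <- genome_model()
  p <- redistribution_params()
  d <- cohort_design(24, seed = 5)
  co <- simulate_cohort(g, d, p, spikein_params())
  in_peak <- rep(FALSE, nrow(co$layout$bins))
  in_peak[co$layout$peak_bins] <- TRUE
  np_frac <- vapply(co$coverage,
                    function(cov) sum(cov$count[!in_peak]) / sum(cov$count), 0)
  ct <- suppressWarnings(
    cor.test(np_frac, d$delta_haz, method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("the distal layer concentrates mistargeted mass away from TSSs
          and grows as dHAZ falls", {
  g <- genome_model()
  p <- redistribution_params(distal_mistarget_fraction = 0.3,
                             n_distal_sites = 200)
  layout <- peak_layout(g, p, seed = 3)
  lo <- simulate_sample_bins(g, p, delta_haz = -2, seed = 4, layout = layout)
  hi <- simulate_sample_bins(g, p, delta_haz = 1, seed = 5, layout = layout)
  expect_length(layout$distal_bins, 200)
  # distal sites gain occupancy in the poorer growth trajectory
  expect_gt(sum(lo$count[layout$distal_bins]),
            1.5 * sum(hi$count[layout$distal_bins]))
  # distal sites are far from every TSS
  distal_iv <- layout$bins[layout$distal_bins, ]
  expect_equal(proximal_fraction(distal_iv, layout$tss, radius = 450), 0)
  # and the total budget is still conserved
  expect_lt(abs(sum(lo$count) - sum(hi$count)) / p$total_reads, 0.02)
})

test_that("identical seeds give bit-identical cohorts", {
  g <- tiny_genome()
  p <- tiny_params()
  d <- cohort_design(6, seed = 9)
  co1 <- simulate_cohort(g, d, p, spikein_params(), seed = 9)
  co2 <- simulate_cohort(g, d, p, spikein_params(), seed = 9)
  expect_identical(co1$coverage, co2$coverage)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$peaks, co2$peaks)
})

test_that("stunting flag uses strict HAZ < -2 at 52 weeks", {
  d <- cohort_design(n_samples = 3, seed = 1,
                     haz_birth = c(0, 0, 0),
                     delta_haz = c(-2.5, 0, -2.0))
  expect_equal(d$haz_52wk, c(-2.5, 0, -2.0))
  expect_equal(d$stunted, c(TRUE, FALSE, FALSE))
})

test_that("generator rejects invalid inputs", {
  g <- tiny_genome()
  p <- tiny_params()
  expect_error(simulate_sample_bins(g, p, delta_haz = Inf, seed = 1), "finite")
  expect_error(
    simulate_sample_bins(g, redistribution_params(total_reads = 10,
                                                  n_peaks = 40),
                         delta_haz = 0, seed = 1),
    "at least")
  expect_error(cohort_design(4, seed = 1,
                             sample_id = c("a", "a", "b", "c")),
               "duplicate")
  expect_error(spikein_params(n_ercc = 5), "at least 10")
  expect_error(
    simulate_ercc_rnaseq(cohort_design(6, seed = 1), spikein_params(),
                         de_fraction = 1.5),
    "de_fraction")
})

test_that("ERCC spike-ins are flat without a global shift and recover the
          injected shift under total-count normalization", {
  des <- cohort_design(12, seed = 21)
  flat <- simulate_ercc_rnaseq(des, spikein_params(rna_global_shift_slope = 0),
                               n_genes = 400, seed = 31)
  sf <- colSums(flat$counts) / exp(mean(log(colSums(flat$counts))))
  sl <- ols_log2_slopes(flat$counts[flat$features$is_ercc, ],
                        des$delta_haz, sf)
  expect_lt(abs(median(sl)), 0.05)

  meds <- vapply(1:20, function(s) {
    des <- cohort_design(12, seed = 100 + s)
    sim <- simulate_ercc_rnaseq(des,
                                spikein_params(rna_global_shift_slope = 0.5),
                                n_genes = 400, seed = 300 + s)
    sf <- colSums(sim$counts) / exp(mean(log(colSums(sim$counts))))
    median(ols_log2_slopes(sim$counts[sim$features$is_ercc, ],
                           des$delta_haz, sf))
  }, 0)
  expect_lt(abs(mean(meds) - (-0.5)), 0.1)
  expect_true(all(abs(meds - (-0.5)) < 0.15))
})

test_that("cohort files round-trip through bedGraph/BED/CSV", {
  dir <- withr::local_tempdir()
  g <- tiny_genome()
  co <- simulate_cohort(g, cohort_design(3, seed = 2), tiny_params(),
                        spikein_params(), dir = dir)
  expect_true(file.exists(file.path(dir, "S01.bedGraph")))
  cov <- read_bedgraph(file.path(dir, "S01.bedGraph"))
  # bedGraph drops zero-count runs on export/import round trips only if the
  # writer omits them; ours writes every bin, so the grids must match
  expect_equal(nrow(cov), nrow(co$coverage$S01))
  expect_equal(cov$count, co$coverage$S01$count)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(md$sample_id, co$metadata$sample_id)
  expect_equal(md$stunted, co$metadata$stunted)
  tss <- bed_to_tss(read_bed6(file.path(dir, "tss.bed")))
  expect_equal(nrow(tss), nrow(co$tss))
  expect_setequal(tss$gene_id, co$tss$gene_id)
})
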