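test_that("the bundled table covers the grid symmetrically", {
  tbl <- default_lsc_table()
  expect_equal(nrow(tbl$entries), 210)  # 20 * 21 / 2 unordered pairs
  expect_equal(lookup_lsc(tbl, 37000, 120000), lookup_lsc(tbl, 120000, 37000))
  # floor-and-clamp lookup
  e <- tbl$entries
  expect_equal(lookup_lsc(tbl, 10000, 10000),
               e$lsc[e$s1_kb == 10 & e$s2_kb == 10])
  expect_equal(lookup_lsc(tbl, 512340, 512340),
               e$lsc[e$s1_kb == 200 & e$s2_kb == 200])
  expect_equal(lookup_lsc(tbl, 37500, 37500),
               e$lsc[e$s1_kb == 30 & e$s2_kb == 30])
  expect_true(all(e$lsc <= e$intra_mean - tbl$z_quantile * e$intra_sd + 1e-12))
  expect_true(all(e$lsc <= e$inter_mean + tbl$z_quantile * e$inter_sd + 1e-12))
})

test_that("intraspecies mean rises and SD falls with fragment size", {
  d <- default_lsc_table()$entries
  d <- d[d$s1_kb == d$s2_kb, ]
  expect_gt(cor(d$s1_kb, d$intra_mean, method = "spearman"), 0.9)
  expect_lt(cor(d$s1_kb, d$intra_sd, method = "spearman"), -0.9)
})

test_that("normal fits report sample moments and honor the size gate", {
  expect_equal(fit_normal(rep(0.8, 100))$sd, 0)
  set.seed(131)
  x <- rnorm(10000, mean = 0.8, sd = 0.05)
  f <- fit_normal(x, ks = TRUE)
  expect_lt(abs(f$mean - 0.8), 3 * 0.05 / sqrt(10000))
  expect_lt(abs(f$sd - 0.05), 3 * 0.05 / sqrt(2 * 10000))
  expect_gte(f$ks_stat, 0)
  expect_error(fit_normal(rnorm(10)), "below the minimum")
})

test_that("the cutoff is the smaller of the two 95% quantile cutoffs", {
  st <- list(intra_mean = 0.90, intra_sd = 0.02,
             inter_mean = 0.60, inter_sd = 0.10)
  z <- qnorm(0.95)
  expect_equal(lsc_from_stats(st), min(0.90 - z * 0.02, 0.60 + z * 0.10))
  expect_lt(abs(lsc_from_stats(st) - 0.7645), 5e-5)
  st0 <- list(intra_mean = 0.9, intra_sd = 0, inter_mean = 0.6, inter_sd = 0)
  expect_equal(lsc_from_stats(st0), 0.6)
})

test_that("fragment PCCD sampling is seeded and separates the classes", {
  sc <- small_scenario()
  s1 <- sample_fragment_pccds(sc, size_pair = c(20, 30), n_samples = 25,
                              seed = 5)
  s2 <- sample_fragment_pccds(sc, size_pair = c(20, 30), n_samples = 25,
                              seed = 5)
  expect_identical(s1, s2)
  expect_length(s1$intra, 25)
  expect_length(s1$inter, 25)
  expect_gt(mean(s1$intra), mean(s1$inter))
  # fragments larger than every genome
  expect_error(sample_fragment_pccds(sc, size_pair = c(200, 200),
                                     n_samples = 5, seed = 1),
               "too few genomes")
})

test_that("calibration is deterministic and errors on uncoverable bins", {
  sc <- small_scenario()
  t1 <- calibrate_lsc(sc, bins = c(10, 20, 30), n_samples = 40, min_n = 20,
                      frags_per_genome = 4, seed = 17)
  t2 <- calibrate_lsc(sc, bins = c(10, 20, 30), n_samples = 40, min_n = 20,
                      frags_per_genome = 4, seed = 17)
  expect_identical(t1$entries, t2$entries)
  expect_equal(nrow(t1$entries), 6)  # 3 * 4 / 2 pairs
  expect_equal(lookup_lsc(t1, 12000, 28000), lookup_lsc(t1, 28000, 12000))
  # 200 kb fragments cannot be drawn from ~150 kb genomes
  expect_error(
    calibrate_lsc(sc, bins = c(10, 200), n_samples = 40, min_n = 20,
                  seed = 17),
    "calibration failed")
})

test_that("calibration samples pass their own cutoff at the nominal rate", {
  sc <- small_scenario()
  tbl <- calibrate_lsc(sc, bins = c(10, 20, 30), n_samples = 60, min_n = 30,
                       frags_per_genome = 4, seed = 19)
  for (s in attr(tbl, "samples")) {
    expect_gte(s$intra_pass, 0.93)
  }
})

test_that("cutoff tables round-trip exactly through TSV", {
  tbl <- default_lsc_table()
  f <- tempfile(fileext = ".tsv")
  write_lsc_table(tbl, f)
  back <- read_lsc_table(f)
  expect_identical(tbl$entries, back$entries)
  expect_identical(tbl$table_id, back$table_id)
  expect_equal(tbl$z_quantile, back$z_quantile)
})
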