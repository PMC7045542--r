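test_that("pairs traverse the three decision stages correctly", {
  tbl <- toy_lsc_table(lsc = 0.25)
  basis <- unit_profile_basis()
  u <- basis$u

  # identical profiles: P1 = 1 passes everything
  a <- make_sketch("a", u, gsc = 0.9, table = tbl)
  b <- make_sketch("b", u, gsc = 0.9, table = tbl)
  d <- sieve_pair(a, b, tbl)
  expect_equal(d$p1, 1)
  expect_equal(d$stage, "p1_pass")
  expect_equal(d$decision, "sieved")
  expect_true(is.na(d$p2))

  # P1 just below the length-specific cutoff: rejected regardless of GSCs
  p_low <- profile_with_cor(basis, 0.249)
  c1 <- make_sketch("c1", u, gsc = 0.0, table = tbl)
  c2 <- make_sketch("c2", p_low, gsc = 0.0, table = tbl)
  d2 <- sieve_pair(c1, c2, tbl)
  expect_equal(d2$stage, "lsc_reject")
  expect_equal(d2$decision, "rejected")

  # P1 between LSC and GSC_p, P2 above GSC_p: sieved at stage two
  p_mid <- profile_with_cor(basis, 0.6)
  e1 <- make_sketch("e1", p_mid, zlf = u, gsc = 0.9, len = 250000,
                    zlf_len = 500000, table = tbl)
  e2 <- make_sketch("e2", u, zlf = u, gsc = 0.9, len = 250000,
                    zlf_len = 500000, table = tbl)
  d3 <- sieve_pair(e1, e2, tbl)
  expect_equal(d3$stage, "p2_pass")
  expect_equal(d3$decision, "sieved")
  expect_equal(d3$p2, 1)

  # ... and rejected when P2 also falls short
  f1 <- make_sketch("f1", p_mid, zlf = p_mid, gsc = 0.9, len = 250000,
                    zlf_len = 500000, table = tbl)
  f2 <- make_sketch("f2", u, zlf = u, gsc = 0.9, len = 250000,
                    zlf_len = 500000, table = tbl)
  d4 <- sieve_pair(f1, f2, tbl)
  expect_equal(d4$stage, "p2_reject")
  expect_equal(d4$decision, "rejected")
})

test_that("thresholds are inclusive and decisions monotone in P1", {
  tbl <- toy_lsc_table(lsc = 0.25)
  basis <- unit_profile_basis(seed = 405)
  u <- basis$u
  gsc <- 0.8
  ref <- make_sketch("r", u, zlf = profile_with_cor(basis, 0), gsc = gsc,
                     len = 250000, zlf_len = 500000, table = tbl)
  decisions <- vapply(seq(-0.5, 1, by = 0.05), function(r) {
    q <- make_sketch("q", profile_with_cor(basis, r),
                     zlf = profile_with_cor(basis, 0), gsc = gsc,
                     len = 250000, zlf_len = 500000, table = tbl)
    sieve_pair(q, ref, tbl)$decision == "sieved"
  }, logical(1))
  expect_false(is.unsorted(decisions))  # FALSE...TRUE, never back

  # exact equality with the pair cutoff sieves (non-strict comparison)
  q_eq <- make_sketch("q", profile_with_cor(basis, gsc),
                      zlf = profile_with_cor(basis, 0), gsc = gsc,
                      len = 250000, zlf_len = 500000, table = tbl)
  d <- sieve_pair(q_eq, ref, tbl)
  expect_equal(d$p1, gsc, tolerance = 1e-12)
  expect_equal(d$decision, "sieved")
})

test_that("pair cutoffs and decisions are symmetric", {
  tbl <- default_lsc_table()
  sc <- small_scenario()
  g <- sc$genomes
  s1 <- sketch_genome(g[[1]], tbl, "s1")
  s2 <- sketch_genome(g[[2]], tbl, "s2")
  s3 <- sketch_genome(g[[3]], tbl, "s3")
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    sk <- list(s1, s2, s3)
    a <- sieve_pair(sk[[pair[1]]], sk[[pair[2]]], tbl)
    b <- sieve_pair(sk[[pair[2]]], sk[[pair[1]]], tbl)
    expect_equal(a$lsc_used, b$lsc_used)
    expect_equal(a$gsc_p, b$gsc_p)
    expect_equal(a$p1, b$p1)
    expect_equal(a$decision, b$decision)
  }
  # self-pair always sieved
  self <- sieve_pair(s1, sketch_genome(g[[1]], tbl, "other_id"), tbl)
  expect_equal(self$decision, "sieved")
  expect_equal(self$p1, 1)
})

test_that("vectorised sieving matches per-pair sieving and skips self-pairs", {
  tbl <- toy_lsc_table(lsc = 0.1)
  set.seed(141)
  mk <- function(id) {
    z <- rnorm(256)
    make_sketch(id, z, zlf = z + rnorm(256, sd = 0.3),
                gsc = runif(1, 0.3, 0.92), len = sample(30000:250000, 1),
                zlf_len = sample(100000:900000, 1), table = tbl)
  }
  queries <- lapply(paste0("q", 1:6), mk)
  refs <- c(lapply(paste0("r", 1:4), mk), queries[2])
  all <- sieve_all(queries, refs, tbl)
  expect_equal(nrow(all), 6 * 5 - 1)  # q2 x q2 self-pair dropped
  for (i in seq_len(nrow(all))) {
    q <- queries[[match(all$query_id[i], paste0("q", 1:6))]]
    r <- refs[[match(all$ref_id[i], vapply(refs, `[[`, "", "genome_id"))]]
    one <- sieve_pair(q, r, tbl)
    expect_equal(all$p1[i], one$p1, tolerance = 1e-12)
    expect_equal(all$lsc_used[i], one$lsc_used)
    expect_equal(all$gsc_p[i], one$gsc_p)
    expect_equal(all$stage[i], one$stage)
    expect_equal(all$decision[i], one$decision)
    expect_equal(is.na(all$p2[i]), is.na(one$p2))
  }
  # mismatched tables are refused
  other <- toy_lsc_table(lsc = 0.2)
  expect_error(sieve_all(queries, refs, other), "LSC table")
  expect_error(sieve_pair(queries[[1]],
                          make_sketch("x", rnorm(256), table = other), tbl),
               "different LSC tables")
})

test_that("whole-genome TETRA matches an end-to-end oracle recomputation", {
  set.seed(151)
  g <- random_seq(20000)
  strain <- mutate_strain(g, substitution_rate = 0.02, indel_rate = 0.002,
                          seed = 3)
  expect_equal(tetra_value(g, g), 1)
  got <- tetra_value(g, strain)
  want <- oracle_pearson(oracle_zscores(g), oracle_zscores(strain))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("TETRA sieving respects the cutoff inclusively", {
  sc <- small_scenario()
  ids <- sc$labels$genome_id[1:4]
  profs <- lapply(ids, function(id) tetra_profile(sc$genomes[[id]], id = id))
  names(profs) <- ids

  all_sieved <- tetra_sieve(profs, profs, cutoff = -1)
  expect_true(all(all_sieved$decision == "sieved"))
  expect_equal(nrow(all_sieved), 4 * 3)  # self-pairs excluded

  none <- tetra_sieve(profs, profs, cutoff = 1)
  expect_true(all(none$decision == "rejected"))

  # a duplicated genome under a second id is a self-pair in content: sieved
  dup <- c(profs[1], list(copy = profs[[1]]))
  d <- tetra_sieve(dup[1], dup[2], cutoff = 0.99)
  expect_equal(d$decision, "sieved")
  expect_equal(d$tetra, 1)

  # cutoff equal to an observed value still sieves (>= comparison)
  v <- tetra_sieve(profs[1], profs[2], cutoff = 0)$tetra
  d2 <- tetra_sieve(profs[1], profs[2], cutoff = v)
  expect_equal(d2$decision, "sieved")
})
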