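# Shared light-weight fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Constant-cutoff LSC table over the standard grid, for tests that need a
# table but not a calibration.
toy_lsc_table <- function(lsc = 0.25, bins = seq(10, 200, by = 10)) {
  grid <- expand.grid(s1_kb = bins, s2_kb = bins)
  grid <- grid[grid$s1_kb <= grid$s2_kb, ]
  entries <- data.frame(grid, intra_mean = 0.9, intra_sd = 0.02,
                        inter_mean = 0.1, inter_sd = 0.1,
                        n_intra = 1000, n_inter = 1000, lsc = lsc)
  lsc_table(entries, bins = bins)
}

# Directly constructed sketch with prescribed profiles and cutoffs.
make_sketch <- function(id, zsel, zlf = zsel, gsc = 0.9, len = 150000,
                        zlf_len = len, table = toy_lsc_table(),
                        L = 600000) {
  fragte:::new_genome_sketch(
    genome_id = id, L = L,
    zrf = fragte:::new_zprofile(zsel, len),
    zlf = fragte:::new_zprofile(zlf, zlf_len),
    rep_length = len, zlf_length = zlf_len, gsc = gsc,
    intragenomic_mean = NA_real_, intragenomic_sd = NA_real_,
    lsc_lower = NA_real_, whole_genome = FALSE, table_id = table$table_id)
}

# Centered orthonormal basis pair: profiles cos(t)*u + sin(t)*v have
# Pearson correlation cos(t) with u, which lets tests prescribe P1/P2.
unit_profile_basis <- function(seed = 404) {
  set.seed(seed)
  u <- rnorm(256); v <- rnorm(256)
  u <- u - mean(u)
  v <- v - mean(v)
  v <- v - sum(u * v) / sum(u^2) * u
  list(u = u / sqrt(sum(u^2)), v = v / sqrt(sum(v^2)))
}

profile_with_cor <- function(basis, r) {
  r * basis$u + sqrt(1 - r^2) * basis$v
}

# Small two-species scenario for module-level tests (genomes ~150 kb).
small_scenario <- function() {
  if (is.null(.fixtures$small_scenario)) {
    .fixtures$small_scenario <- simulate_scenario(
      n_species = 3, n_strains = 2, length = c(140000, 180000), seed = 9001)
  }
  .fixtures$small_scenario
}
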