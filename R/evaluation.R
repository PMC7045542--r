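# Benchmark metrics: sensitivity / specificity / fraction sieved, the
# completeness grid experiment, and matched-sensitivity cutoffs for the
# TETRA baseline.

# Percentages are reported rounded half-up to 2 decimals.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Sieving metrics from confusion counts
#'
#' * sensitivity  = 100 * sieved intraspecies pairs / all intraspecies pairs
#' * specificity  = 100 * filtered interspecies pairs / all interspecies pairs
#' * pct_sieved   = 100 * all sieved pairs / all pairs
#'
#' Percentages are rounded half-up to 2 decimals; the counts are kept exact.
#'
#' @param n_intra_total,n_intra_sieved Intraspecies pair counts.
#' @param n_inter_total,n_inter_filtered Interspecies pair counts.
#' @return An object of class `sieve_metrics` (also a list of counts and the
#'   three percentages).
#' @examples
#' sieve_metrics(61914, 61497, 9095374, 8743496)$sensitivity  # 99.33
#' @export
sieve_metrics <- function(n_intra_total, n_intra_sieved,
                          n_inter_total, n_inter_filtered) {
  stopifnot(n_intra_sieved <= n_intra_total,
            n_inter_filtered <= n_inter_total)
  n_pairs_total <- n_intra_total + n_inter_total
  n_sieved_total <- n_intra_sieved + (n_inter_total - n_inter_filtered)
  structure(
    list(n_intra_total = n_intra_total, n_intra_sieved = n_intra_sieved,
         n_inter_total = n_inter_total, n_inter_filtered = n_inter_filtered,
         n_pairs_total = n_pairs_total, n_sieved_total = n_sieved_total,
         sensitivity = round_half_up(100 * n_intra_sieved / n_intra_total),
         specificity = round_half_up(100 * n_inter_filtered / n_inter_total),
         pct_sieved = round_half_up(100 * n_sieved_total / n_pairs_total)),
    class = "sieve_metrics")
}

#' @export
print.sieve_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<sieve_metrics: sensitivity %.2f%% (%d/%d intra), ",
           "specificity %.2f%% (%d/%d inter), sieved %.2f%% (%d/%d)>\n"),
    x$sensitivity, x$n_intra_sieved, x$n_intra_total,
    x$specificity, x$n_inter_filtered, x$n_inter_total,
    x$pct_sieved, x$n_sieved_total, x$n_pairs_total))
  invisible(x)
}

#' Score sieving decisions against species-label truth
#'
#' Labels every decided pair intraspecies (same species) or interspecies
#' using the truth map, and tallies the metrics.
#'
#' @param decisions Data frame with `query_id`, `ref_id`, `decision`
#'   (`"sieved"` / `"rejected"`), from [sieve_all()] or [tetra_sieve()].
#' @param truth Data frame with `genome_id`, `species_id`; every decided
#'   genome must be labeled.
#' @return A `sieve_metrics` object.
#' @export
score <- function(decisions, truth) {
  stopifnot(all(c("query_id", "ref_id", "decision") %in% names(decisions)))
  intra <- species_of(truth, decisions$query_id) ==
    species_of(truth, decisions$ref_id)
  sieved <- decisions$decision == "sieved"
  sieve_metrics(
    n_intra_total = sum(intra),
    n_intra_sieved = sum(intra & sieved),
    n_inter_total = sum(!intra),
    n_inter_filtered = sum(!intra & !sieved))
}

#' Completeness-grid benchmark
#'
#' Reproduces the two-axis completeness experiment: every query genome is
#' degraded to each completeness on the grid, every reference genome
#' likewise (independently), and each (query completeness, reference
#' completeness) cell is sieved and scored.  Degradation uses contiguous
#' seeded extraction, with one deterministic sub-seed per (genome, level),
#' so the whole grid is reproducible and the 100%/100% cell equals a direct
#' non-degraded run.
#'
#' @param scenario A `genome_scenario`; its `role` column splits queries
#'   from references.
#' @param method `"fragte"` (sketch + two-phase sieve) or `"tetra"`
#'   (whole-genome baseline at `cutoff`).
#' @param table `lsc_table` for the fragte method.
#' @param fractions Completeness grid, default 10-100% by 10.
#' @param cutoff TETRA criterion, default 0.99.
#' @param seed Integer seed for the degradations.
#' @return Data frame with one row per grid cell: `q_completeness`,
#'   `r_completeness` (percent), the three percentages and the underlying
#'   counts.
#' @export
completeness_grid <- function(scenario, method = c("fragte", "tetra"),
                              table = NULL,
                              fractions = seq(0.1, 1, by = 0.1),
                              cutoff = 0.99, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(scenario, "genome_scenario"))
  if (method == "fragte" && is.null(table)) {
    stop("the fragte method requires a calibrated lsc_table")
  }
  labels <- scenario$labels
  q_ids <- labels$genome_id[labels$role == "query"]
  r_ids <- labels$genome_id[labels$role == "ref"]
  if (!length(q_ids) || !length(r_ids)) {
    stop("scenario must contain both query and ref roles")
  }

  # one sketch/profile per (genome, completeness level)
  degraded <- list()
  for (gid in c(q_ids, r_ids)) {
    g <- scenario$genomes[[gid]]
    per_level <- vector("list", length(fractions))
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      part <- subsample_completeness(g, f,
                                     seed = derive_seed(seed, match(gid,
                                       labels$genome_id), round(f * 100)))
      per_level[[fi]] <- if (method == "fragte") {
        sketch_genome(part, table = table, genome_id = gid)
      } else {
        tetra_profile(part, id = gid)
      }
    }
    degraded[[gid]] <- per_level
  }

  cells <- expand.grid(qi = seq_along(fractions), ri = seq_along(fractions))
  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    qi <- cells$qi[ci]; ri <- cells$ri[ci]
    qs <- lapply(q_ids, function(id) degraded[[id]][[qi]])
    rs <- lapply(r_ids, function(id) degraded[[id]][[ri]])
    dec <- if (method == "fragte") {
      sieve_all(qs, rs, table)
    } else {
      names(qs) <- q_ids; names(rs) <- r_ids
      tetra_sieve(qs, rs, cutoff = cutoff)
    }
    m <- score(dec, labels)
    rows[[ci]] <- data.frame(
      q_completeness = round(fractions[qi] * 100),
      r_completeness = round(fractions[ri] * 100),
      sensitivity = m$sensitivity, specificity = m$specificity,
      pct_sieved = m$pct_sieved,
      n_intra_total = m$n_intra_total, n_intra_sieved = m$n_intra_sieved,
      n_inter_total = m$n_inter_total,
      n_inter_filtered = m$n_inter_filtered)
  }
  do.call(rbind, rows)
}

#' Largest TETRA cutoff achieving a target sensitivity
#'
#' Scans the intraspecies TETRA values for the largest cutoff at which the
#' baseline still sieves at least `target_sensitivity` percent of
#' intraspecies pairs; used for specificity-at-matched-sensitivity
#' comparisons.  A target of 0 (nothing need be sieved) returns `Inf`.
#'
#' @param tetra_values Numeric vector of per-pair TETRA values.
#' @param intra Logical vector: is the pair intraspecies?
#' @param target_sensitivity Percent, in `[0, 100]`.
#' @return The cutoff (numeric scalar, possibly `Inf`).
#' @export
matched_sensitivity_cutoff <- function(tetra_values, intra,
                                       target_sensitivity) {
  stopifnot(length(tetra_values) == length(intra))
  if (target_sensitivity > 100) {
    stop("target sensitivity above 100% is unreachable")
  }
  if (target_sensitivity <= 0) return(Inf)
  vals <- sort(tetra_values[intra], decreasing = TRUE)
  if (!length(vals)) stop("no intraspecies pairs to match against")
  k <- ceiling(target_sensitivity / 100 * length(vals))
  vals[k]
}

#' Write a completeness grid as long-format TSV
#'
#' @param grid Data frame from [completeness_grid()].
#' @param path Output file.
#' @param params Optional named list written as `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(grid, path, params = NULL) {
  long <- do.call(rbind, lapply(
    c("sensitivity", "specificity", "pct_sieved"),
    function(metric) data.frame(
      q_completeness = grid$q_completeness,
      r_completeness = grid$r_completeness,
      metric = metric, value = grid[[metric]])))
  write_tsv_with_header(long, path, params)
}
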