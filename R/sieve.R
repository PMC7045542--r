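# Determining phase: pairwise sieving decisions from genome sketches, plus
# the whole-genome TETRA baseline.

# Selection profile rule: the fourfold-fragment profile replaces the
# representative profile whenever its length is <= 200 kb (selection
# sensitivity rises with fragment size; beyond 200 kb the cutoff table does
# not extend).
selection_profile <- function(sketch) {
  if (sketch$zlf_length <= 200000) {
    list(z = sketch$zlf$z, len = sketch$zlf_length)
  } else {
    list(z = sketch$zrf$z, len = sketch$rep_length)
  }
}

check_same_table <- function(a, b) {
  if (!identical(a$table_id, b$table_id)) {
    stop("sketches were built against different LSC tables")
  }
}

#' Sieve one genome pair
#'
#' The determining phase for a single (query, reference) pair:
#' 1. `P1` is the PCCD of the two selection profiles; the pair is dropped
#'    immediately if `P1` falls below the length-specific cutoff looked up at
#'    the two selection-profile lengths (`lsc_reject`).
#' 2. The pair cutoff `GSC_p` is the smaller of the two genome-specific
#'    cutoffs.  `P1 >= GSC_p` sieves the pair (`p1_pass`).
#' 3. Otherwise `P2`, the PCCD of the two fourfold-fragment profiles, is
#'    computed; `P2 >= GSC_p` sieves the pair (`p2_pass`), else it is
#'    rejected (`p2_reject`).
#' All comparisons are non-strict (`>=`).
#'
#' @param q,r `genome_sketch` objects built against the same `lsc_table`.
#' @param table The `lsc_table` both sketches were built with.
#' @return A one-row data frame: `query_id`, `ref_id`, `rep_len_q`,
#'   `rep_len_r` (selection-profile lengths), `lsc_used`, `p1`, `gsc_p`,
#'   `p2` (`NA` unless stage 3 ran), `stage`, `decision`.
#' @export
sieve_pair <- function(q, r, table) {
  stopifnot(inherits(q, "genome_sketch"), inherits(r, "genome_sketch"))
  check_same_table(q, r)
  if (!identical(q$table_id, table$table_id)) {
    stop("sketches were not built against the supplied LSC table")
  }
  sq <- selection_profile(q)
  sr <- selection_profile(r)
  p1 <- pccd(sq$z, sr$z)
  lsc_used <- lookup_lsc(table, sq$len, sr$len)
  gsc_p <- min(q$gsc, r$gsc)
  p2 <- NA_real_
  if (p1 < lsc_used) {
    stage <- "lsc_reject"; decision <- "rejected"
  } else if (p1 >= gsc_p) {
    stage <- "p1_pass"; decision <- "sieved"
  } else {
    p2 <- pccd(q$zlf$z, r$zlf$z)
    if (p2 >= gsc_p) {
      stage <- "p2_pass"; decision <- "sieved"
    } else {
      stage <- "p2_reject"; decision <- "rejected"
    }
  }
  data.frame(query_id = q$genome_id, ref_id = r$genome_id,
             rep_len_q = sq$len, rep_len_r = sr$len,
             lsc_used = lsc_used, p1 = p1, gsc_p = gsc_p, p2 = p2,
             stage = stage, decision = decision,
             stringsAsFactors = FALSE)
}

# 256 x n matrix of unit-normalised centred z columns, so that Pearson
# correlations become plain cross products.  Zero-variance columns (only
# pathological sequences) are zeroed with a warning, giving PCCD 0.
standardize_cols <- function(M) {
  M <- sweep(M, 2, colMeans(M))
  nrm <- sqrt(colSums(M^2))
  if (any(nrm == 0)) {
    warning("zero-variance z-profile; PCCD treated as 0")
    nrm[nrm == 0] <- 1
  }
  sweep(M, 2, nrm, "/")
}

#' Sieve all query x reference pairs
#'
#' Vectorised determining phase over two sketch collections.  One evaluation
#' is produced per ordered (query, reference) pair, except self-pairs
#' (identical `genome_id`), which are skipped so that the same collection can
#' be sieved against itself.  `P2` is only computed for pairs whose `P1`
#' passed the length-specific gate but failed the pair cutoff, and is `NA`
#' elsewhere.
#'
#' @param queries,refs Lists of `genome_sketch` objects built against
#'   `table`.
#' @param table The shared `lsc_table`.
#' @return A data frame with the columns of [sieve_pair()], one row per
#'   evaluated pair.
#' @export
sieve_all <- function(queries, refs, table) {
  stopifnot(length(queries) >= 1L, length(refs) >= 1L)
  ids_q <- vapply(queries, `[[`, character(1), "genome_id")
  ids_r <- vapply(refs, `[[`, character(1), "genome_id")
  for (s in c(queries, refs)) {
    if (!identical(s$table_id, table$table_id)) {
      stop("sketches were not built against the supplied LSC table")
    }
  }
  selq <- lapply(queries, selection_profile)
  selr <- lapply(refs, selection_profile)
  Qs <- standardize_cols(vapply(selq, `[[`, numeric(256), "z"))
  Rs <- standardize_cols(vapply(selr, `[[`, numeric(256), "z"))
  P1 <- pmin(pmax(crossprod(Qs, Rs), -1), 1)

  len_q <- vapply(selq, `[[`, numeric(1), "len")
  len_r <- vapply(selr, `[[`, numeric(1), "len")
  bq <- match(bin_of(table, len_q), table$bins)
  br <- match(bin_of(table, len_r), table$bins)
  LSC <- table$lsc_matrix[bq, br, drop = FALSE]

  gq <- vapply(queries, `[[`, numeric(1), "gsc")
  gr <- vapply(refs, `[[`, numeric(1), "gsc")
  GSCp <- outer(gq, gr, pmin)

  pass_lsc <- P1 >= LSC
  p1_pass <- pass_lsc & (P1 >= GSCp)
  need_p2 <- pass_lsc & !p1_pass

  P2 <- matrix(NA_real_, nrow(P1), ncol(P1))
  p2_pass <- matrix(FALSE, nrow(P1), ncol(P1))
  if (any(need_p2)) {
    Qz <- standardize_cols(vapply(queries, function(s) s$zlf$z,
                                  numeric(256)))
    Rz <- standardize_cols(vapply(refs, function(s) s$zlf$z, numeric(256)))
    P2full <- pmin(pmax(crossprod(Qz, Rz), -1), 1)
    P2[need_p2] <- P2full[need_p2]
    p2_pass <- need_p2 & (P2full >= GSCp)
  }

  stage <- matrix("lsc_reject", nrow(P1), ncol(P1))
  stage[p1_pass] <- "p1_pass"
  stage[p2_pass] <- "p2_pass"
  stage[need_p2 & !p2_pass] <- "p2_reject"

  out <- data.frame(
    query_id = rep(ids_q, times = length(ids_r)),
    ref_id = rep(ids_r, each = length(ids_q)),
    rep_len_q = rep(len_q, times = length(ids_r)),
    rep_len_r = rep(len_r, each = length(ids_q)),
    lsc_used = as.vector(LSC), p1 = as.vector(P1),
    gsc_p = as.vector(GSCp), p2 = as.vector(P2),
    stage = as.vector(stage),
    decision = ifelse(as.vector(p1_pass | p2_pass), "sieved", "rejected"),
    stringsAsFactors = FALSE)
  out[out$query_id != out$ref_id, , drop = FALSE]
}

#' Whole-genome tetranucleotide z-score profile
#'
#' Cleans (if needed), concatenates and profiles a whole genome; the basis of
#' the TETRA baseline.
#'
#' @param contigs A `genome_input`, list of contig sequences, or character
#'   vector; total length must exceed 10 kb.
#' @param id Genome identifier.
#' @return A `zprofile`.
#' @export
tetra_profile <- function(contigs, id = "genome") {
  genome <- concatenate_contigs(contigs, id = id)
  zscores(count_kmers(genome))
}

#' Whole-genome TETRA similarity of two genomes
#'
#' The classic genome-wide baseline: PCCD between the whole-genome
#' tetranucleotide z-score profiles of two genomes.
#'
#' @param genome_a,genome_b Genomes as accepted by [tetra_profile()].
#' @return A number in `[-1, 1]`.
#' @export
tetra_value <- function(genome_a, genome_b) {
  pccd(tetra_profile(genome_a, id = "a"), tetra_profile(genome_b, id = "b"))
}

#' Sieve by whole-genome TETRA at a fixed cutoff
#'
#' Baseline sieving: a pair is sieved iff its whole-genome TETRA value is at
#' least `cutoff` (non-strict).  The conventional criterion is 0.99; other
#' cutoffs support matched-sensitivity comparisons.  Self-pairs (identical
#' ids) are skipped.
#'
#' @param queries,refs Named lists of `zprofile` objects (names are genome
#'   ids), from [tetra_profile()].
#' @param cutoff Sieving criterion, default 0.99.
#' @return Data frame: `query_id`, `ref_id`, `tetra`, `decision`.
#' @export
tetra_sieve <- function(queries, refs, cutoff = 0.99) {
  stopifnot(length(queries) >= 1L, length(refs) >= 1L,
            !is.null(names(queries)), !is.null(names(refs)))
  Qs <- standardize_cols(vapply(queries, as_zvec, numeric(256)))
  Rs <- standardize_cols(vapply(refs, as_zvec, numeric(256)))
  TV <- pmin(pmax(crossprod(Qs, Rs), -1), 1)
  out <- data.frame(
    query_id = rep(names(queries), times = length(refs)),
    ref_id = rep(names(refs), each = length(queries)),
    tetra = as.vector(TV),
    stringsAsFactors = FALSE)
  out$decision <- ifelse(out$tetra >= cutoff, "sieved", "rejected")
  out[out$query_id != out$ref_id, , drop = FALSE]
}
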