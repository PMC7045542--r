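# Fragmenting phase: contig concatenation, sliding-window planning,
# representative / fourfold fragment selection and the genome-specific cutoff.

#' Concatenate the contigs of one genome
#'
#' Joins the contigs of a genome assembly into a single sequence, preserving
#' input order and inserting no separator characters.  Junction words across
#' contig boundaries are accepted: at > 10 kb scale they are a vanishing
#' fraction of all windows.
#'
#' @param contigs A `genome_input`, a list of `clean_sequence` objects, or a
#'   character vector of ACGT strings (at least one contig).
#' @param id Identifier for the concatenated genome.
#' @return A `clean_sequence` holding the concatenated genome.  Genomes of
#'   total length <= 10 kb are rejected with an error: below that size intra-
#'   and inter-species compositional signatures are not separable.
#' @export
concatenate_contigs <- function(contigs, id = "genome") {
  if (inherits(contigs, "genome_input")) {
    id <- contigs$genome_id
    contigs <- contigs$contigs
  }
  if (inherits(contigs, "clean_sequence")) contigs <- list(contigs)
  if (length(contigs) < 1L) stop("at least one contig required")
  seqs <- vapply(contigs, as_sequence, character(1))
  s <- paste(seqs, collapse = "")
  if (nchar(s) <= 10000L) {
    stop("genome '", id, "' rejected: total length ", nchar(s),
         " bp <= 10 kb")
  }
  structure(list(residues = s, source_id = id, length = nchar(s),
                 n_removed = 0L),
            class = "clean_sequence")
}

#' Plan sliding windows over a concatenated genome
#'
#' Windows of length `l` advance by `l/2` (50% overlap).  The window length
#' depends on the concatenated genome length `L`:
#' * `L < 40 kb`: no fragmenting; an empty plan signals whole-genome mode;
#' * `40 kb <= L <= 800 kb`: `l = L/4`, giving exactly 8 windows
#'   (7 full-length plus one trailing half-length window);
#' * `L > 800 kb`: `l` is capped at 200 kb, giving >= 8 windows.
#' A trailing window is kept when its length is at least `l/2`, so every
#' emitted window length lies in `[l/2, l]` and never exceeds 200 kb.
#'
#' @param L Concatenated genome length in bp (must exceed 10 kb).
#' @return An object of class `window_plan`: `L`, `l` (`NA` in whole-genome
#'   mode) and `windows`, a matrix of half-open `[start, end)` intervals in
#'   0-based bp coordinates.
#' @examples
#' nrow(plan_windows(400000)$windows)   # 8
#' plan_windows(1000000)$l              # 200000
#' nrow(plan_windows(30000)$windows)    # 0: whole-genome mode
#' @export
plan_windows <- function(L) {
  L <- as.numeric(L)
  stopifnot(length(L) == 1L, is.finite(L))
  if (L <= 10000) stop("genome length ", L, " bp <= 10 kb: rejected")
  if (L < 40000) {
    return(structure(
      list(L = L, l = NA_real_,
           windows = matrix(numeric(0), 0, 2,
                            dimnames = list(NULL, c("start", "end")))),
      class = "window_plan"))
  }
  l <- if (L <= 800000) floor(L / 4) else 200000
  half <- floor(l / 2)
  starts <- seq(0, L - half, by = half)
  windows <- cbind(start = starts, end = pmin(starts + l, L))
  structure(list(L = L, l = l, windows = windows), class = "window_plan")
}

#' @export
print.window_plan <- function(x, ...) {
  cat(sprintf("<window_plan: L = %s bp, l = %s, %d windows>\n",
              format(x$L, big.mark = ","),
              if (is.na(x$l)) "whole-genome" else format(x$l, big.mark = ","),
              nrow(x$windows)))
  invisible(x)
}

#' Do two windows not overlap?
#'
#' Half-open coordinate test: `[a0, a1)` and `[b0, b1)` are non-overlapping
#' iff `a1 <= b0` or `b1 <= a0`.  Abutting windows do not overlap.
#'
#' @param a,b Numeric length-2 vectors `c(start, end)` in the same
#'   coordinate system.
#' @return Logical scalar.
#' @export
nonoverlapping <- function(a, b) {
  unname(a[2] <= b[1] || b[2] <= a[1])
}

# Pairwise non-overlap mask for a window matrix (TRUE off-diagonal where the
# half-open intervals are disjoint).
nonoverlap_mask <- function(windows) {
  s <- windows[, "start"]; e <- windows[, "end"]
  overlap <- outer(s, e, "<") & outer(e, s, ">")
  mask <- !overlap
  diag(mask) <- FALSE
  mask
}

# Strand-symmetric k-mer count matrices for a set of windows on one genome,
# computed in a single pass per k via XStringViews on both strands.
window_count_matrices <- function(dna, windows) {
  L <- length(dna)
  fw <- Biostrings::Views(dna, start = windows[, "start"] + 1,
                          end = windows[, "end"])
  rdna <- Biostrings::reverseComplement(dna)
  rv <- Biostrings::Views(rdna, start = L - windows[, "end"] + 1,
                          end = L - windows[, "start"])
  cnt <- function(k) {
    m <- Biostrings::oligonucleotideFrequency(fw, k) +
      Biostrings::oligonucleotideFrequency(rv, k)
    matrix(as.numeric(m), nrow = nrow(windows))
  }
  list(c2 = cnt(2), c3 = cnt(3), c4 = cnt(4))
}

# Pearson correlation between all rows of a z-score matrix; non-finite
# entries (zero-variance rows) are mapped to 0.
row_cor <- function(Z) {
  C <- suppressWarnings(stats::cor(t(Z)))
  C[!is.finite(C)] <- 0
  C
}

#' Select the representative and top-4 fragments
#'
#' The representative fragment is the one with the maximal accumulated PCCD
#' (sum of Pearson similarities against all non-overlapping intragenomic
#' fragments); the fourfold fragment is assembled from the fragments with the
#' four largest accumulated PCCDs.  Ties break toward the lowest window
#' index, which makes selection deterministic.
#'
#' @param accumulated Numeric vector of accumulated PCCDs, one per fragment,
#'   in window order (at least 4 fragments).
#' @return List with `rep_index` (argmax) and `top4` (indices of the four
#'   largest values, ascending).
#' @export
select_representative <- function(accumulated) {
  n <- length(accumulated)
  if (n < 4L) stop("need at least 4 fragments to form the fourfold fragment")
  ord <- order(-accumulated, seq_len(n))
  list(rep_index = ord[1], top4 = sort(ord[1:4]))
}

#' Z-score profile of the fourfold-longer fragment
#'
#' Sums the k-mer counts of the four selected fragments and computes z-scores
#' from the summed counts.  Summing per-fragment counts is order-invariant
#' and introduces no junction windows, unlike counting over a literal
#' concatenation.
#'
#' @param counts_list List of `kmer_counts`, one per fragment, window order.
#' @param top4 Indices of the four fragments to combine.
#' @return A `zprofile` whose `effective_length` is the summed fragment
#'   length.
#' @export
build_zlf <- function(counts_list, top4) {
  stopifnot(length(top4) == 4L, all(top4 >= 1L),
            all(top4 <= length(counts_list)))
  zscores(sum_kmer_counts(counts_list[top4]))
}

#' Genome-specific cutoff from intragenomic similarities
#'
#' `GSC = mean - 2 * SD` over the PCCDs between the representative fragment
#' and every non-overlapping intragenomic partner, clamped from below by the
#' length-specific cutoff at the representative fragment's size (a filtering
#' cutoff must not undercut the selection cutoff) and from above by `cap`
#' (default 0.92; beyond that essentially all interspecies pairs are already
#' filtered, and a larger GSC would start to discard intraspecies pairs).
#'
#' @param pccds Numeric vector of the representative fragment's intragenomic
#'   PCCDs (at least 2, so the sample SD is defined).
#' @param lsc_kb Length-specific cutoff at the representative fragment's size
#'   bin (diagonal entry of the calibration table).
#' @param cap Upper clamp, default 0.92.
#' @return List with `gsc`, `mean` and `sd` (sample SD, n-1 denominator).
#' @examples
#' compute_gsc(c(0.88, 0.84, 0.86), lsc_kb = 0.80)
#' @export
compute_gsc <- function(pccds, lsc_kb, cap = 0.92) {
  if (length(pccds) < 2L) {
    stop("need at least 2 non-overlapping partners to compute a GSC")
  }
  m <- mean(pccds)
  s <- stats::sd(pccds)
  list(gsc = min(max(m - 2 * s, lsc_kb), cap), mean = m, sd = s)
}

new_genome_sketch <- function(genome_id, L, zrf, zlf, rep_length, zlf_length,
                              gsc, intragenomic_mean, intragenomic_sd,
                              lsc_lower, whole_genome, table_id) {
  structure(
    list(genome_id = genome_id, L = as.numeric(L), zrf = zrf, zlf = zlf,
         rep_length = as.numeric(rep_length),
         zlf_length = as.numeric(zlf_length), gsc = gsc,
         intragenomic_mean = intragenomic_mean,
         intragenomic_sd = intragenomic_sd, lsc_lower = lsc_lower,
         whole_genome = whole_genome, table_id = table_id),
    class = "genome_sketch"
  )
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf(
    "<genome_sketch %s: L = %s bp, rep = %s bp, 4x = %s bp, GSC = %.4f%s>\n",
    x$genome_id, format(x$L, big.mark = ","),
    format(x$rep_length, big.mark = ","),
    format(x$zlf_length, big.mark = ","), x$gsc,
    if (x$whole_genome) ", whole-genome mode" else ""))
  invisible(x)
}

#' Run the fragmenting phase on one genome
#'
#' Full per-genome pipeline: concatenate contigs, plan sliding windows,
#' compute a z-score profile per window, accumulate PCCDs over
#' non-overlapping window pairs, pick the representative and top-4
#' fragments, build the fourfold-fragment profile (ZLF) and the
#' genome-specific cutoff (GSC).
#'
#' Genomes shorter than 40 kb skip fragmenting: the whole-genome profile
#' serves as both ZRF and ZLF, and the diagonal length-specific cutoff at the
#' genome's size stands in for the GSC (still capped at 0.92).  For genomes
#' up to 200 kb the fourfold-fragment profile replaces the representative
#' profile, because selection sensitivity rises with fragment size.
#'
#' The phase contains no randomness: identical input bytes give an identical
#' sketch.
#'
#' @param contigs A `genome_input`, list of `clean_sequence`s, or character
#'   vector of contig sequences (pre-cleaned; total length > 10 kb).
#' @param table An `lsc_table` used for the GSC clamps.
#' @param genome_id Identifier; defaults to the id carried by `contigs`.
#' @return A `genome_sketch` with the two profiles, their lengths, the GSC
#'   and the intragenomic mean/SD behind it.
#' @export
sketch_genome <- function(contigs, table = default_lsc_table(),
                          genome_id = NULL) {
  genome <- concatenate_contigs(contigs,
                                id = if (is.null(genome_id)) "genome"
                                     else genome_id)
  if (is.null(genome_id)) genome_id <- genome$source_id
  L <- genome$length
  plan <- plan_windows(L)

  if (nrow(plan$windows) == 0L) {
    # whole-genome mode: < 40 kb
    prof <- zscores(count_kmers(genome))
    lsc_diag <- lookup_lsc(table, L, L)
    return(new_genome_sketch(
      genome_id = genome_id, L = L, zrf = prof, zlf = prof,
      rep_length = L, zlf_length = L, gsc = min(lsc_diag, 0.92),
      intragenomic_mean = NA_real_, intragenomic_sd = NA_real_,
      lsc_lower = lsc_diag, whole_genome = TRUE,
      table_id = table$table_id))
  }

  dna <- Biostrings::DNAString(genome$residues)
  counts <- window_count_matrices(dna, plan$windows)
  Z <- zscore_core(counts$c4, counts$c3, counts$c2)
  C <- row_cor(Z)
  mask <- nonoverlap_mask(plan$windows)
  accumulated <- rowSums(C * mask)
  sel <- select_representative(accumulated)

  lens <- plan$windows[, "end"] - plan$windows[, "start"]
  rep_i <- sel$rep_index
  rep_length <- lens[rep_i]

  zlf <- zscores(structure(
    list(counts2 = colSums(counts$c2[sel$top4, , drop = FALSE]),
         counts3 = colSums(counts$c3[sel$top4, , drop = FALSE]),
         counts4 = colSums(counts$c4[sel$top4, , drop = FALSE]),
         total_positions = sum(counts$c4[sel$top4, ]),
         effective_length = sum(lens[sel$top4])),
    class = "kmer_counts"))

  partners <- which(mask[rep_i, ])
  lsc_diag <- lookup_lsc(table, rep_length, rep_length)
  g <- compute_gsc(C[rep_i, partners], lsc_kb = lsc_diag)

  zrf <- new_zprofile(Z[rep_i, ], rep_length)
  if (L <= 200000) zrf <- zlf

  new_genome_sketch(
    genome_id = genome_id, L = L, zrf = zrf, zlf = zlf,
    rep_length = rep_length, zlf_length = zlf$effective_length,
    gsc = g$gsc, intragenomic_mean = g$mean, intragenomic_sd = g$sd,
    lsc_lower = lsc_diag, whole_genome = FALSE, table_id = table$table_id)
}
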