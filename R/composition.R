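# Tetranucleotide z-score signatures: strand-symmetric k-mer counting,
# maximal-order Markov expectations, and Pearson similarity (PCCD).

kmer_alphabet <- c("A", "C", "G", "T")

# All k-mers over A<C<G<T in lexicographic order.
all_kmers <- function(k) {
  idx <- 0:(4^k - 1)
  out <- rep("", length(idx))
  for (pos in seq_len(k)) {
    digit <- (idx %/% 4^(k - pos)) %% 4
    out <- paste0(out, kmer_alphabet[digit + 1])
  }
  out
}

# Index maps from each tetramer w = n1n2n3n4 to its leading trimer n1n2n3,
# trailing trimer n2n3n4 and central dimer n2n3 (1-based, lexicographic).
kmer_index_maps <- function() {
  if (!is.null(.fragte_cache$kmer_maps)) return(.fragte_cache$kmer_maps)
  idx <- 0:255
  .fragte_cache$kmer_maps <- list(
    words4 = all_kmers(4),
    words3 = all_kmers(3),
    words2 = all_kmers(2),
    pre = idx %/% 4L + 1L,
    suf = idx %% 64L + 1L,
    mid = (idx %% 64L) %/% 4L + 1L
  )
  .fragte_cache$kmer_maps
}

# Accept a clean_sequence object or a plain character scalar.
as_sequence <- function(x) {
  if (inherits(x, "clean_sequence")) return(x$residues)
  if (is.character(x) && length(x) == 1L) return(x)
  stop("expected a clean_sequence or a single character string")
}

#' Remove ambiguous nucleotides from a raw sequence
#'
#' Uppercases the input and splices out every character outside `{A,C,G,T}`
#' (IUPAC ambiguity codes, gaps, whitespace).  Flanking segments are joined,
#' so a removed run contributes up to three artifactual junction words to
#' downstream k-mer counts; at genomic scale this is negligible and matches
#' the standard treatment of ambiguous bases in compositional signatures.
#'
#' @param raw Character scalar, the raw nucleotide sequence (case-insensitive).
#' @param id Identifier carried along with the sequence.
#' @return An object of class `clean_sequence`: a list with `residues`
#'   (uppercase ACGT string), `source_id`, `length` (bp) and `n_removed`
#'   (number of characters spliced out).
#' @examples
#' s <- clean_sequence("ACGTNNNacgt", "toy")
#' s$residues   # "ACGTACGT"
#' s$n_removed  # 3
#' @export
clean_sequence <- function(raw, id = "seq") {
  stopifnot(is.character(raw), length(raw) == 1L, nchar(raw) > 0L)
  up <- toupper(unname(raw))
  kept <- gsub("[^ACGT]", "", up)
  if (nchar(kept) == 0L) {
    stop("sequence '", id, "' contains no unambiguous A/C/G/T residues")
  }
  structure(
    list(residues = kept, source_id = id, length = nchar(kept),
         n_removed = nchar(up) - nchar(kept)),
    class = "clean_sequence"
  )
}

#' @export
print.clean_sequence <- function(x, ...) {
  cat(sprintf("<clean_sequence %s: %d bp, %d ambiguous removed>\n",
              x$source_id, x$length, x$n_removed))
  invisible(x)
}

#' Strand-symmetric di-, tri- and tetranucleotide counts
#'
#' Counts every overlapping word of length 2, 3 and 4 in the sequence and in
#' its reverse complement, and sums the two.  The two strands are counted as
#' separate strings, so no window spans the forward/reverse junction and the
#' resulting counts are exactly reverse-complement symmetric:
#' `count(w) == count(revcomp(w))` for every word `w`.
#'
#' @param seq A `clean_sequence` or a character scalar over `{A,C,G,T}`,
#'   at least 4 bp long.
#' @return An object of class `kmer_counts`: named count vectors `counts2`
#'   (16), `counts3` (64), `counts4` (256) in lexicographic order,
#'   `total_positions` (sum of tetramer counts) and `effective_length`
#'   (bp of the underlying single-stranded sequence).
#' @examples
#' count_kmers("ACGT")$counts4[["ACGT"]]  # 2: ACGT is self-complementary
#' @export
count_kmers <- function(seq) {
  s <- as_sequence(seq)
  if (nchar(s) < 4L) stop("sequence shorter than 4 bp: no tetramer window")
  x <- Biostrings::DNAString(s)
  r <- Biostrings::reverseComplement(x)
  cnt <- function(k) {
    as.numeric(Biostrings::oligonucleotideFrequency(x, k) +
                 Biostrings::oligonucleotideFrequency(r, k))
  }
  c2 <- cnt(2); c3 <- cnt(3); c4 <- cnt(4)
  m <- kmer_index_maps()
  names(c2) <- m$words2; names(c3) <- m$words3; names(c4) <- m$words4
  structure(
    list(counts2 = c2, counts3 = c3, counts4 = c4,
         total_positions = sum(c4), effective_length = nchar(s)),
    class = "kmer_counts"
  )
}

# Sum kmer_counts objects component-wise (used for the fourfold fragment:
# summing per-fragment counts is order-invariant and adds no junction words).
sum_kmer_counts <- function(counts_list) {
  stopifnot(length(counts_list) >= 1L)
  out <- counts_list[[1]]
  for (ct in counts_list[-1]) {
    out$counts2 <- out$counts2 + ct$counts2
    out$counts3 <- out$counts3 + ct$counts3
    out$counts4 <- out$counts4 + ct$counts4
    out$total_positions <- out$total_positions + ct$total_positions
    out$effective_length <- out$effective_length + ct$effective_length
  }
  out
}

# Vectorised z-score core.  o4: n x 256 tetramer counts, c3: n x 64,
# c2: n x 16.  Maximal-order Markov expectation and variance per tetramer:
#   E(w)   = C(n1n2n3) * C(n2n3n4) / C(n2n3)
#   Var(w) = E(w) * (C(n2n3) - C(n1n2n3)) * (C(n2n3) - C(n2n3n4)) / C(n2n3)^2
#   z(w)   = (O(w) - E(w)) / sqrt(Var(w))
# with z(w) = 0 wherever C(n2n3) = 0 or Var(w) <= 0.
zscore_core <- function(o4, c3, c2) {
  m <- kmer_index_maps()
  pre <- c3[, m$pre, drop = FALSE]
  suf <- c3[, m$suf, drop = FALSE]
  mid <- c2[, m$mid, drop = FALSE]
  E <- pre * suf / mid
  V <- E * (mid - pre) * (mid - suf) / mid^2
  z <- (o4 - E) / sqrt(V)
  bad <- (mid == 0) | !(V > 0) | !is.finite(z)
  z[bad] <- 0
  z
}

new_zprofile <- function(z, effective_length) {
  z <- as.numeric(z)
  names(z) <- kmer_index_maps()$words4
  structure(list(z = z, effective_length = as.numeric(effective_length)),
            class = "zprofile")
}

#' Tetranucleotide z-score profile from k-mer counts
#'
#' Standardises the 256 observed tetramer counts against their maximal-order
#' Markov expectation, which is conditioned on the trimer and dimer counts of
#' the same sequence.  The resulting signature removes all compositional
#' structure up to trimers, leaving only genuine fourth-order signal, and is
#' invariant under reverse complementation of the input.
#'
#' Degenerate words (central dimer absent, or non-positive variance) get
#' `z = 0`, which keeps every profile finite.
#'
#' @param counts A `kmer_counts` object.
#' @param effective_length Base pairs of the underlying sequence; defaults to
#'   the length recorded in `counts`.
#' @return An object of class `zprofile`: `z`, a named vector of 256 finite
#'   z-scores in lexicographic tetramer order, and `effective_length`.
#' @export
zscores <- function(counts, effective_length = counts$effective_length) {
  stopifnot(inherits(counts, "kmer_counts"))
  z <- zscore_core(rbind(counts$counts4), rbind(counts$counts3),
                   rbind(counts$counts2))[1, ]
  new_zprofile(z, effective_length)
}

#' @export
print.zprofile <- function(x, ...) {
  cat(sprintf("<zprofile: 256 z-scores from %s bp, |z| in [%.3g, %.3g]>\n",
              format(x$effective_length, big.mark = ","),
              min(abs(x$z)), max(abs(x$z))))
  invisible(x)
}

as_zvec <- function(x) {
  if (inherits(x, "zprofile")) return(x$z)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a zprofile or a numeric vector")
}

#' Pearson similarity between two z-score profiles (PCCD)
#'
#' The Pearson correlation coefficient of two 256-component z-score vectors.
#' Despite the field's name "Pearson correlation coefficient distance",
#' larger values mean more similar composition (1 = identical).  A
#' zero-variance profile (only possible for pathological sequences) yields 0
#' with a warning.
#'
#' @param a,b `zprofile` objects or numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
pccd <- function(a, b) {
  x <- as_zvec(a); y <- as_zvec(b)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance z-profile; returning PCCD = 0")
    return(0)
  }
  min(1, max(-1, stats::cor(x, y)))
}
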