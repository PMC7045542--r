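# Independent brute-force oracles: no Biostrings, no package internals.
# Everything here recomputes from first principles so the implementation can
# be checked against a genuinely different code path.

oracle_bases <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# All k-mers, lexicographic (first character most significant).
oracle_words <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(oracle_bases), k), stringsAsFactors = FALSE))
  apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste0, collapse = "")
}

# Sliding-window word counts of one strand.
oracle_count_strand <- function(s, k) {
  n <- nchar(s)
  subs <- substring(s, 1:(n - k + 1), k:n)
  tab <- table(factor(subs, levels = oracle_words(k)))
  as.numeric(tab)
}

# Strand-symmetric counts: forward plus reverse complement, two strings.
oracle_counts <- function(s, k) {
  out <- oracle_count_strand(s, k) + oracle_count_strand(oracle_revcomp(s), k)
  names(out) <- oracle_words(k)
  out
}

# Term-by-term z-scores from the maximal-order Markov formulas.
oracle_zscores <- function(s) {
  c2 <- oracle_counts(s, 2)
  c3 <- oracle_counts(s, 3)
  c4 <- oracle_counts(s, 4)
  w4 <- oracle_words(4)
  z <- numeric(256)
  for (i in seq_along(w4)) {
    w <- w4[i]
    pre <- c3[[substr(w, 1, 3)]]
    suf <- c3[[substr(w, 2, 4)]]
    mid <- c2[[substr(w, 2, 3)]]
    if (mid == 0) next
    E <- pre * suf / mid
    V <- E * (mid - pre) * (mid - suf) / mid^2
    if (!(V > 0)) next
    z[i] <- (c4[[w]] - E) / sqrt(V)
  }
  names(z) <- w4
  z
}

oracle_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

random_seq <- function(n) {
  paste(sample(oracle_bases, n, replace = TRUE), collapse = "")
}

# Brute-force representative selection from a window plan and its z matrix:
# naive interval overlap, oracle Pearson, exhaustive accumulated sums.
oracle_select <- function(windows, Z) {
  n <- nrow(windows)
  acc <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      disjoint <- windows[i, "end"] <= windows[j, "start"] ||
        windows[j, "end"] <= windows[i, "start"]
      if (disjoint) acc[i] <- acc[i] + oracle_pearson(Z[i, ], Z[j, ])
    }
  }
  ord <- order(-acc, seq_len(n))
  list(rep_index = ord[1], top4 = sort(ord[1:4]), acc = acc)
}

# Brute-force matched-sensitivity cutoff: scan every candidate value.
oracle_matched_cutoff <- function(values, intra, target) {
  if (target <= 0) return(Inf)
  cand <- sort(unique(values[intra]), decreasing = TRUE)
  best <- NA_real_
  for (c0 in cand) {
    sens <- 100 * mean(values[intra] >= c0)
    if (sens >= target) { best <- c0; break }
  }
  best
}
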