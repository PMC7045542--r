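# Length-specific cutoffs (LSCs): empirical intra-/inter-species PCCD
# distributions per fragment-size pair, normal approximation, and the
# min-of-two-quantiles rule.

#' Construct a length-specific cutoff table
#'
#' Low-level constructor, mainly used by [calibrate_lsc()] and
#' [read_lsc_table()].  Entries are stored once per unordered size pair
#' (`s1_kb <= s2_kb`) and must cover every pair on the bin grid.
#'
#' @param entries Data frame with columns `s1_kb`, `s2_kb`, `intra_mean`,
#'   `intra_sd`, `inter_mean`, `inter_sd`, `n_intra`, `n_inter`, `lsc`.
#' @param bins Numeric kb grid (default 10, 20, ..., 200).
#' @param z_quantile One-sided normal quantile used when the table was built.
#' @param seed Seed recorded for provenance.
#' @param samples Optional list of per-pair calibration samples (kept in
#'   memory only, never serialized).
#' @return An object of class `lsc_table`.
#' @export
lsc_table <- function(entries, bins = seq(10, 200, by = 10),
                      z_quantile = stats::qnorm(0.95), seed = NA_integer_,
                      samples = NULL) {
  need <- c("s1_kb", "s2_kb", "intra_mean", "intra_sd", "inter_mean",
            "inter_sd", "n_intra", "n_inter", "lsc")
  stopifnot(is.data.frame(entries), all(need %in% names(entries)))
  entries <- entries[order(entries$s1_kb, entries$s2_kb), need]
  if (any(entries$s1_kb > entries$s2_kb)) {
    stop("entries must be stored with s1_kb <= s2_kb")
  }
  grid <- expand.grid(s1 = bins, s2 = bins)
  grid <- grid[grid$s1 <= grid$s2, ]
  key <- function(a, b) paste(a, b, sep = ":")
  missing <- setdiff(key(grid$s1, grid$s2), key(entries$s1_kb, entries$s2_kb))
  if (length(missing)) {
    stop("lsc_table is missing size pairs: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  # dense symmetric lookup matrix over the grid
  n <- length(bins)
  M <- matrix(NA_real_, n, n, dimnames = list(bins, bins))
  i <- match(entries$s1_kb, bins)
  j <- match(entries$s2_kb, bins)
  M[cbind(i, j)] <- entries$lsc
  M[cbind(j, i)] <- entries$lsc
  tbl <- structure(
    list(bins = bins, entries = entries, z_quantile = z_quantile,
         seed = seed, lsc_matrix = M,
         table_id = sprintf("lsc:%d:%s", nrow(entries),
                            format(sum(entries$lsc) + z_quantile,
                                   digits = 17))),
    class = "lsc_table")
  attr(tbl, "samples") <- samples
  tbl
}

#' @export
print.lsc_table <- function(x, ...) {
  cat(sprintf(
    "<lsc_table: %d size pairs over %g-%g kb, z = %.4f, LSC in [%.4f, %.4f]>\n",
    nrow(x$entries), min(x$bins), max(x$bins), x$z_quantile,
    min(x$entries$lsc), max(x$entries$lsc)))
  invisible(x)
}

# Map lengths in bp to the table's kb bin (floor to grid, clamp to range).
bin_of <- function(table, len_bp) {
  kb <- pmin(pmax(len_bp / 1000, min(table$bins)), max(table$bins))
  table$bins[findInterval(kb, table$bins)]
}

#' Look up the length-specific cutoff for a fragment-size pair
#'
#' Lengths are floored to the table's kb grid and clamped to its range; the
#' lookup is symmetric in the two lengths.  Vectorised over pairs.
#'
#' @param table An `lsc_table`.
#' @param len1,len2 Fragment lengths in bp.
#' @return Numeric cutoff(s).
#' @examples
#' \dontrun{
#' lookup_lsc(tbl, 37500, 120000)  # bin pair (30 kb, 120 kb)
#' }
#' @export
lookup_lsc <- function(table, len1, len2) {
  stopifnot(inherits(table, "lsc_table"))
  b1 <- match(bin_of(table, len1), table$bins)
  b2 <- match(bin_of(table, len2), table$bins)
  table$lsc_matrix[cbind(b1, b2)]
}

#' Fit a normal approximation to a PCCD sample
#'
#' Returns the sample mean and sample SD; optionally a one-sample
#' Kolmogorov-Smirnov statistic against the fitted normal, reported purely as
#' a diagnostic (it never gates calibration).
#'
#' @param sample Numeric vector, at least `min_n` values.
#' @param min_n Minimum sample size (default 100).
#' @param ks Whether to compute the KS diagnostic.
#' @return List with `mean`, `sd`, `n` and `ks_stat` (`NA` unless requested).
#' @export
fit_normal <- function(sample, min_n = 100, ks = FALSE) {
  n <- length(sample)
  if (n < min_n) stop("sample of size ", n, " below the minimum of ", min_n)
  m <- mean(sample)
  s <- stats::sd(sample)
  ks_stat <- NA_real_
  if (ks && s > 0) {
    ks_stat <- unname(suppressWarnings(
      stats::ks.test(sample, "pnorm", mean = m, sd = s)$statistic))
  }
  list(mean = m, sd = s, n = n, ks_stat = ks_stat)
}

#' Length-specific cutoff from distribution parameters
#'
#' Two candidate cutoffs are formed under the normal approximation: one that
#' keeps at least 95% of intraspecies pairs (`intra_mean - z * intra_sd`) and
#' one that excludes at least 95% of interspecies pairs
#' (`inter_mean + z * inter_sd`).  The smaller of the two is the LSC, which
#' guarantees the intraspecies inclusion rate while taking the extra
#' specificity whenever the distributions are well separated.
#'
#' @param stats A list or one-row data frame with `intra_mean`, `intra_sd`,
#'   `inter_mean`, `inter_sd`.
#' @param z_quantile One-sided quantile, default `qnorm(0.95)` = 1.6449.
#' @return The cutoff (numeric scalar).
#' @examples
#' lsc_from_stats(list(intra_mean = 0.90, intra_sd = 0.02,
#'                     inter_mean = 0.60, inter_sd = 0.10))  # 0.7645
#' @export
lsc_from_stats <- function(stats, z_quantile = stats::qnorm(0.95)) {
  c_intra <- stats$intra_mean - z_quantile * stats$intra_sd
  c_inter <- stats$inter_mean + z_quantile * stats$inter_sd
  min(c_intra, c_inter)
}

# Coerce a genome collection (named list of character / clean_sequence /
# genome_input) to a named list of plain sequences.
as_genome_list <- function(genomes) {
  stopifnot(length(genomes) >= 1L)
  if (inherits(genomes, "genome_scenario")) genomes <- genomes$genomes
  out <- lapply(genomes, function(g) {
    if (inherits(g, "genome_input")) {
      as_sequence(concatenate_contigs(g))
    } else if (inherits(g, "clean_sequence")) {
      g$residues
    } else {
      as_sequence(g)
    }
  })
  if (is.null(names(out)) || any(names(out) == "")) {
    stop("genomes must be a named collection")
  }
  out
}

species_of <- function(labels, ids) {
  sp <- labels$species_id[match(ids, labels$genome_id)]
  if (anyNA(sp)) stop("species labels missing for: ",
                      paste(ids[is.na(sp)], collapse = ", "))
  sp
}

#' Sample intra- and inter-species fragment PCCDs for one size pair
#'
#' Draws random fragment pairs (one fragment of `size_pair[1]` kb, one of
#' `size_pair[2]` kb, always from two different genomes) and computes their
#' z-score profile similarity.  A pair is labeled intraspecies when the two
#' genomes share a species label, interspecies otherwise.  Genomes shorter
#' than a requested fragment are skipped for that size.
#'
#' @param genomes Named list of genome sequences (or a `genome_scenario`).
#' @param labels Data frame with `genome_id`, `species_id`.
#' @param size_pair Numeric length-2 vector of fragment sizes in kb,
#'   within `[10, 200]`.
#' @param n_samples Number of draws per class.
#' @param seed Integer seed; identical seeds give identical samples.
#' @return List with numeric vectors `intra` and `inter`.
#' @export
sample_fragment_pccds <- function(genomes, labels, size_pair,
                                  n_samples = 100, seed = 1) {
  if (inherits(genomes, "genome_scenario") && missing(labels)) {
    labels <- genomes$labels
  }
  seqs <- as_genome_list(genomes)
  stopifnot(length(size_pair) == 2, all(size_pair >= 10),
            all(size_pair <= 200))
  bp <- round(size_pair * 1000)
  lens <- vapply(seqs, nchar, numeric(1))
  elig1 <- names(seqs)[lens >= bp[1]]
  elig2 <- names(seqs)[lens >= bp[2]]
  if (length(elig1) < 1L || length(elig2) < 1L ||
      length(union(elig1, elig2)) < 2L) {
    stop("too few genomes long enough for fragment sizes ",
         size_pair[1], "/", size_pair[2], " kb")
  }
  pairs <- expand.grid(a = elig1, b = elig2, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  intra <- species_of(labels, pairs$a) == species_of(labels, pairs$b)
  if (!any(intra)) stop("no intraspecies genome pairs available")
  if (all(intra)) stop("no interspecies genome pairs available")
  draw <- function(idx) {
    take <- idx[sample.int(length(idx), n_samples, replace = TRUE)]
    vapply(take, function(k) {
      g1 <- seqs[[pairs$a[k]]]; g2 <- seqs[[pairs$b[k]]]
      s1 <- sample.int(nchar(g1) - bp[1] + 1L, 1L)
      s2 <- sample.int(nchar(g2) - bp[2] + 1L, 1L)
      f1 <- substr(g1, s1, s1 + bp[1] - 1L)
      f2 <- substr(g2, s2, s2 + bp[2] - 1L)
      pccd(zscores(count_kmers(f1)), zscores(count_kmers(f2)))
    }, numeric(1))
  }
  with_seed(seed, list(intra = draw(which(intra)),
                       inter = draw(which(!intra))))
}

#' Calibrate length-specific cutoffs on a labeled training set
#'
#' For every unordered pair of fragment-size bins, samples intra- and
#' inter-species fragment PCCDs from the training genomes, fits normal
#' approximations and derives the LSC via [lsc_from_stats()].  Sampling is
#' pooled for efficiency: `frags_per_genome` seeded random fragments are
#' drawn per genome per size bin, profiled once, and pairs are then drawn
#' from the pool (same-genome pairs are never used).
#'
#' @param genomes Named list of genome sequences, or a `genome_scenario`.
#' @param labels Data frame with `genome_id`, `species_id` (taken from the
#'   scenario when omitted).
#' @param bins Fragment-size grid in kb.
#' @param n_samples Maximum PCCD sample size per class per bin pair.
#' @param frags_per_genome Random fragments drawn per genome per size bin.
#' @param min_n Minimum sample size per class per bin pair; bin pairs that
#'   cannot reach it raise an error listing the gaps.
#' @param z_quantile One-sided normal quantile (default `qnorm(0.95)`).
#' @param seed Integer seed; calibration is fully deterministic under it.
#' @return An `lsc_table`.  The in-memory object additionally carries the
#'   per-pair intraspecies calibration samples and their empirical pass rate
#'   at the LSC (`intra_pass` attribute), used for diagnostics.
#' @export
calibrate_lsc <- function(genomes, labels = NULL,
                          bins = seq(10, 200, by = 10),
                          n_samples = 150, frags_per_genome = 3,
                          min_n = 100, z_quantile = stats::qnorm(0.95),
                          seed = 1) {
  if (inherits(genomes, "genome_scenario") && is.null(labels)) {
    labels <- genomes$labels
  }
  seqs <- as_genome_list(genomes)
  ids <- names(seqs)
  sp <- species_of(labels, ids)
  if (length(unique(sp)) < 2L) stop("need at least 2 species to calibrate")
  if (!any(duplicated(sp))) {
    stop("need at least one species with >= 2 strains to calibrate")
  }

  # --- pooled fragment profiles -------------------------------------------
  pool <- with_seed(seed, {
    meta <- list(); zrows <- list(); r <- 0L
    for (gi in seq_along(seqs)) {
      g <- seqs[[gi]]
      Lg <- nchar(g)
      dna <- Biostrings::DNAString(g)
      starts <- list(); sizes <- list()
      for (b in bins) {
        s_bp <- round(b * 1000)
        if (Lg < s_bp) next
        st <- sample.int(Lg - s_bp + 1L, frags_per_genome, replace = TRUE)
        starts[[length(starts) + 1L]] <- st - 1L
        sizes[[length(sizes) + 1L]] <- rep(s_bp, frags_per_genome)
      }
      if (!length(starts)) next
      st <- unlist(starts); sz <- unlist(sizes)
      win <- cbind(start = st, end = st + sz)
      cm <- window_count_matrices(dna, win)
      Z <- zscore_core(cm$c4, cm$c3, cm$c2)
      for (k in seq_len(nrow(win))) {
        r <- r + 1L
        zrows[[r]] <- Z[k, ]
        meta[[r]] <- data.frame(genome = ids[gi], species = sp[gi],
                                kb = sz[k] / 1000)
      }
    }
    list(Z = do.call(rbind, zrows), meta = do.call(rbind, meta))
  })

  # all-vs-all Pearson over the pooled fragments (unit-normalised rows)
  Zc <- pool$Z - rowMeans(pool$Z)
  nrm <- sqrt(rowSums(Zc^2))
  nrm[nrm == 0] <- 1
  Call <- tcrossprod(Zc / nrm)

  meta <- pool$meta
  same_genome <- outer(meta$genome, meta$genome, "==")
  same_species <- outer(meta$species, meta$species, "==")

  grid <- expand.grid(s1 = bins, s2 = bins)
  grid <- grid[grid$s1 <= grid$s2, ]
  rows <- vector("list", nrow(grid))
  samples <- vector("list", nrow(grid))
  gaps <- character(0)

  with_seed(derive_seed(seed, 2), {
    for (gidx in seq_len(nrow(grid))) {
      s1 <- grid$s1[gidx]; s2 <- grid$s2[gidx]
      A <- which(meta$kb == s1)
      B <- which(meta$kb == s2)
      if (!length(A) || !length(B)) {
        gaps <- c(gaps, sprintf("%g/%g kb: no fragments", s1, s2))
        next
      }
      pr <- expand.grid(a = A, b = B)
      pr <- pr[!same_genome[cbind(pr$a, pr$b)], ]
      if (s1 == s2) pr <- pr[pr$a < pr$b, ]
      is_intra <- same_species[cbind(pr$a, pr$b)]
      pick <- function(idx) {
        if (length(idx) > n_samples) idx <- idx[sample.int(length(idx),
                                                           n_samples)]
        Call[cbind(pr$a[idx], pr$b[idx])]
      }
      intra_v <- pick(which(is_intra))
      inter_v <- pick(which(!is_intra))
      if (length(intra_v) < min_n || length(inter_v) < min_n) {
        gaps <- c(gaps, sprintf("%g/%g kb: %d intra, %d inter (need %d)",
                                s1, s2, length(intra_v), length(inter_v),
                                min_n))
        next
      }
      fi <- fit_normal(intra_v, min_n = min_n)
      fe <- fit_normal(inter_v, min_n = min_n)
      st <- data.frame(s1_kb = s1, s2_kb = s2,
                       intra_mean = fi$mean, intra_sd = fi$sd,
                       inter_mean = fe$mean, inter_sd = fe$sd,
                       n_intra = fi$n, n_inter = fe$n)
      st$lsc <- lsc_from_stats(st, z_quantile)
      rows[[gidx]] <- st
      samples[[gidx]] <- list(s1_kb = s1, s2_kb = s2, intra = intra_v,
                              intra_pass = mean(intra_v >= st$lsc))
    }
  })
  if (length(gaps)) {
    stop("calibration failed for size pairs:\n  ",
         paste(gaps, collapse = "\n  "))
  }
  lsc_table(do.call(rbind, rows), bins = bins, z_quantile = z_quantile,
            seed = seed, samples = samples[!vapply(samples, is.null,
                                                   logical(1))])
}

#' Write a length-specific cutoff table to TSV
#'
#' Plain TSV with `#`-prefixed header lines recording the normal quantile and
#' calibration seed.  Numbers are written with 17 significant digits so the
#' table re-parses exactly.
#'
#' @param table An `lsc_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lsc_table <- function(table, path) {
  stopifnot(inherits(table, "lsc_table"))
  e <- table$entries
  num <- vapply(e, is.numeric, logical(1))
  e[num] <- lapply(e[num], function(x) sprintf("%.17g", x))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fragte lsc_table"),
               sprintf("# z_quantile=%.17g", table$z_quantile),
               sprintf("# seed=%s", table$seed)), con)
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a length-specific cutoff table from TSV
#'
#' @param path File written by [write_lsc_table()].
#' @return An `lsc_table`.
#' @export
read_lsc_table <- function(path) {
  header <- readLines(path, n = 10)
  header <- header[startsWith(header, "#")]
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "="), header, value = TRUE)
    if (!length(ln)) return(NA)
    sub(paste0("^# ", key, "="), "", ln[1])
  }
  e <- utils::read.delim(path, comment.char = "#", sep = "\t",
                         stringsAsFactors = FALSE)
  zq <- as.numeric(getval("z_quantile"))
  sd_ <- getval("seed")
  lsc_table(e, bins = sort(unique(c(e$s1_kb, e$s2_kb))),
            z_quantile = if (is.na(zq)) stats::qnorm(0.95) else zq,
            seed = suppressWarnings(as.integer(sd_)))
}

#' Bundled default cutoff table (synthetic calibration)
#'
#' A ready-to-use `lsc_table` calibrated on the package's own seeded
#' synthetic training set (see `scripts/make_default_lsc.R` in the source
#' repository), so sketching and sieving work out of the box.  It is a
#' synthetic stand-in: for production use on real taxa, calibrate on labeled
#' real genomes with [calibrate_lsc()].
#'
#' @return An `lsc_table`.
#' @export
default_lsc_table <- function() {
  if (is.null(.fragte_cache$default_lsc)) {
    path <- system.file("extdata", "lsc_synthetic_default.tsv",
                        package = "fragte", mustWork = TRUE)
    .fragte_cache$default_lsc <- read_lsc_table(path)
  }
  .fragte_cache$default_lsc
}
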