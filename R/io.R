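# FASTA ingestion and serialization of sketches, decisions and scenarios.

#' Read one genome from a (gzipped) FASTA file
#'
#' Multi-record files are interpreted as the contigs/scaffolds of a single
#' genome, in file order.  Records are uppercased and ambiguous characters
#' spliced out.  Genomes failing the size screens are returned flagged
#' rather than erroring, so batch runs can report every rejection.
#'
#' @param path FASTA or gzipped FASTA file.
#' @param genome_id Identifier; defaults to the file stem.
#' @param min_length,max_length Size screens in bp: genomes with total
#'   cleaned length `<= min_length` (default 10 kb) or `> max_length`
#'   (default unlimited; 10 Mb is a common contamination screen for MAGs)
#'   are flagged `rejected`.
#' @return An object of class `genome_input`: `genome_id`, `path`, `contigs`
#'   (list of `clean_sequence`), `total_length`, `n_removed`, `rejected`,
#'   `reject_reason`.
#' @export
read_genome <- function(path, genome_id = NULL, min_length = 10000,
                        max_length = Inf) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "",
                     basename(path), ignore.case = TRUE)
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  raw <- as.character(set)
  contigs <- list()
  for (i in seq_along(raw)) {
    nm <- if (!is.null(names(raw)) && nzchar(names(raw)[i])) {
      strsplit(names(raw)[i], "\\s+")[[1]][1]
    } else sprintf("%s_contig%d", genome_id, i)
    cleaned <- tryCatch(clean_sequence(raw[i], id = nm),
                        error = function(e) NULL)
    if (!is.null(cleaned)) contigs[[length(contigs) + 1L]] <- cleaned
  }
  total <- sum(vapply(contigs, `[[`, numeric(1), "length"))
  removed <- sum(nchar(raw)) - total
  rejected <- FALSE
  reason <- NA_character_
  if (length(contigs) == 0L) {
    rejected <- TRUE; reason <- "no unambiguous sequence"
  } else if (total <= min_length) {
    rejected <- TRUE
    reason <- sprintf("total length %d bp <= %d bp", total, min_length)
  } else if (total > max_length) {
    rejected <- TRUE
    reason <- sprintf("total length %d bp > %g bp", total, max_length)
  }
  structure(
    list(genome_id = genome_id, path = path, contigs = contigs,
         total_length = total, n_removed = removed, rejected = rejected,
         reject_reason = reason),
    class = "genome_input")
}

#' @export
print.genome_input <- function(x, ...) {
  cat(sprintf("<genome_input %s: %d contigs, %s bp%s>\n", x$genome_id,
              length(x$contigs), format(x$total_length, big.mark = ","),
              if (x$rejected) paste0(", REJECTED: ", x$reject_reason) else ""))
  invisible(x)
}

#' Write genome sequences as FASTA
#'
#' @param seqs Named list/vector of sequences, or a single character scalar.
#' @param path Output FASTA file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  if (is.character(seqs) && length(seqs) == 1L && is.null(names(seqs))) {
    seqs <- stats::setNames(list(seqs), "contig1")
  }
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

sketch_to_list <- function(s) {
  list(genome_id = s$genome_id, L = s$L, rep_length = s$rep_length,
       zlf_length = s$zlf_length, gsc = s$gsc,
       intragenomic_mean = s$intragenomic_mean,
       intragenomic_sd = s$intragenomic_sd, lsc_lower = s$lsc_lower,
       whole_genome = s$whole_genome, table_id = s$table_id,
       zrf = s$zrf$z, zlf = s$zlf$z)
}

#' Serialize genome sketches as JSON-lines
#'
#' One JSON object per line (streamable, diff-able); doubles are written at
#' full precision, so a round-trip through [read_sketches()] is bit-exact.
#'
#' @param sketches List of `genome_sketch` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sketches <- function(sketches, path) {
  if (inherits(sketches, "genome_sketch")) sketches <- list(sketches)
  lines <- vapply(sketches, function(s) {
    as.character(jsonlite::toJSON(sketch_to_list(s), auto_unbox = TRUE,
                                  digits = I(17), na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read genome sketches from JSON-lines
#'
#' @param path File written by [write_sketches()].
#' @return List of `genome_sketch` objects.
#' @export
read_sketches <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    new_genome_sketch(
      genome_id = x$genome_id, L = as.numeric(x$L),
      zrf = new_zprofile(x$zrf, as.numeric(x$rep_length)),
      zlf = new_zprofile(x$zlf, as.numeric(x$zlf_length)),
      rep_length = as.numeric(x$rep_length),
      zlf_length = as.numeric(x$zlf_length), gsc = x$gsc,
      intragenomic_mean = if (is.null(x$intragenomic_mean)) NA_real_
                          else x$intragenomic_mean,
      intragenomic_sd = if (is.null(x$intragenomic_sd)) NA_real_
                        else x$intragenomic_sd,
      lsc_lower = x$lsc_lower, whole_genome = x$whole_genome,
      table_id = x$table_id)
  })
}

# TSV with "# key=value" provenance header lines.
write_tsv_with_header <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(p)
                         paste(format(p), collapse = ","), character(1))),
               con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sieving decisions as TSV
#'
#' @param decisions Data frame from [sieve_all()] or [tetra_sieve()].
#' @param path Output file.
#' @param params Optional named list of run parameters for the header.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path, params = NULL) {
  write_tsv_with_header(decisions, path, params)
}

#' Read a TSV written by the package (decisions, truth, metrics)
#'
#' @param path TSV file, possibly with `#` header lines.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a simulated scenario to disk
#'
#' Standard layout: one multi-FASTA per genome under `dir/genomes/`, a truth
#' TSV (`genome_id`, `species_id`, `role`) and a JSON manifest with the
#' generating parameters and seed.
#'
#' @param scenario A `genome_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "genome_scenario"))
  gdir <- file.path(dir, "genomes")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  for (gid in names(scenario$genomes)) {
    write_genome_fasta(stats::setNames(list(scenario$genomes[[gid]]), gid),
                       file.path(gdir, paste0(gid, ".fasta")))
  }
  write_tsv_with_header(scenario$labels, file.path(dir, "truth.tsv"))
  jsonlite::write_json(scenario$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a scenario directory written by [write_scenario()]
#'
#' @param dir Scenario directory.
#' @return A `genome_scenario` (without the species models).
#' @export
load_scenario <- function(dir) {
  labels <- read_tsv(file.path(dir, "truth.tsv"))
  genomes <- lapply(labels$genome_id, function(gid) {
    gi <- read_genome(file.path(dir, "genomes", paste0(gid, ".fasta")),
                      genome_id = gid)
    as_sequence(concatenate_contigs(gi))
  })
  names(genomes) <- labels$genome_id
  params <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)
  structure(list(genomes = genomes, labels = labels, models = NULL,
                 params = params),
            class = "genome_scenario")
}
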