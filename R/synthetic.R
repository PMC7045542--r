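# Seeded synthetic benchmark generator: species with distinct tetramer-level
# compositional signatures, point-mutated/indel-perturbed strains,
# completeness extraction and MAG-like fragmentation.

#' Generate species models with distinct compositional signatures
#'
#' Each species is an order-3 Markov model over `{A,C,G,T}`: the next base is
#' conditioned on the previous trimer.  Transition weights are drawn as
#' `exp(divergence_control * N(0,1))` per (trimer context, base) and
#' normalised per context, so species sit independently around the uniform
#' chain.  The order matters: the tetranucleotide z-score statistic removes
#' all structure up to trimers, so species separation must come from genuine
#' fourth-order signal, which trimer-conditioned weights inject.
#' `divergence_control = 0` collapses every species to the uniform chain
#' (the adversarial, signature-free case).
#'
#' @param n_species Number of species (>= 1).
#' @param length Base genome length in bp: a scalar, or a length-2 range from
#'   which each species' length is drawn uniformly.
#' @param divergence_control Log-scale spread of the transition weights
#'   (default 0.3).
#' @param seed Integer seed; models are byte-identical under the same seed.
#' @return List of `species_model` objects with `species_id`, `trans`
#'   (64 x 4 row-stochastic matrix), `length` and a per-species `seed`.
#' @export
generate_species <- function(n_species, length = c(1e6, 2e6),
                             divergence_control = 0.3, seed = 1) {
  stopifnot(n_species >= 1)
  with_seed(seed, {
    lapply(seq_len(n_species), function(i) {
      w <- matrix(exp(divergence_control * stats::rnorm(256)), 64, 4)
      trans <- w / rowSums(w)
      len <- if (length(length) == 2L) {
        round(stats::runif(1, length[1], length[2]))
      } else {
        round(length[1])
      }
      structure(
        list(species_id = sprintf("sp%02d", i), trans = trans,
             length = len, markov_order = 3L,
             seed = sample.int(2147483646L, 1)),
        class = "species_model")
    })
  })
}

#' Simulate the base genome of a species model
#'
#' Runs the species' order-3 Markov chain for `length` bases under the
#' model's own seed, so regeneration is deterministic.
#'
#' @param model A `species_model`.
#' @param length Genome length in bp; defaults to the model's length.
#' @return Character scalar (ACGT string).
#' @export
generate_genome <- function(model, length = model$length) {
  stopifnot(inherits(model, "species_model"))
  with_seed(model$seed, markov_generate_cpp(as.integer(length), model$trans))
}

#' Derive a strain by point mutations and short indels
#'
#' Applies per-site substitutions (each mutated site becomes one of the three
#' other bases) and short indels (lengths 1-10 bp, geometric with mean 2,
#' insertions and deletions equally likely).  The defaults (2% substitutions,
#' 0.2% indel events) emulate conspecific strains under the usual > 96% ANI
#' species circumscription.
#'
#' @param genome Character scalar ACGT sequence.
#' @param substitution_rate Per-site substitution probability, in `[0, 0.2]`.
#' @param indel_rate Per-site indel-event probability, in `[0, 0.2]`.
#' @param seed Integer seed.
#' @return Mutated genome (character scalar).
#' @export
mutate_strain <- function(genome, substitution_rate = 0.02,
                          indel_rate = 0.002, seed = 1) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2)
  if (substitution_rate == 0 && indel_rate == 0) return(genome)
  with_seed(seed, {
    v <- strsplit(genome, "", fixed = TRUE)[[1]]
    n <- length(v)
    bases <- c("A", "C", "G", "T")

    sub_idx <- which(stats::runif(n) < substitution_rate)
    if (length(sub_idx)) {
      cur <- match(v[sub_idx], bases)
      shift <- sample.int(3L, length(sub_idx), replace = TRUE)
      v[sub_idx] <- bases[(cur - 1L + shift) %% 4L + 1L]
    }

    ev_idx <- which(stats::runif(n) < indel_rate)
    if (length(ev_idx)) {
      ev_len <- pmin(1L + stats::rgeom(length(ev_idx), prob = 0.5), 10L)
      is_del <- stats::runif(length(ev_idx)) < 0.5
      keep <- rep(TRUE, n)
      for (k in which(is_del)) {
        span <- ev_idx[k]:min(ev_idx[k] + ev_len[k] - 1L, n)
        keep[span] <- FALSE
      }
      ins_idx <- ev_idx[!is_del]
      ins_len <- ev_len[!is_del]
      ins_seq <- vapply(ins_len, function(l) {
        paste(sample(bases, l, replace = TRUE), collapse = "")
      }, character(1))
      # map insertion anchors to post-deletion coordinates
      pos_map <- cumsum(keep)
      v <- v[keep]
      s <- paste(v, collapse = "")
      if (length(ins_idx)) {
        at <- pos_map[ins_idx]           # insert after this position
        ord <- order(at)
        at <- at[ord]; ins_seq <- ins_seq[ord]
        cuts <- c(0L, at, nchar(s))
        pieces <- substring(s, utils::head(cuts, -1) + 1L, cuts[-1])
        # interleave: piece1, ins1, piece2, ins2, ..., last piece
        out <- character(2 * length(at) + 1)
        out[seq(1, length(out), by = 2)] <- pieces
        out[seq(2, length(out) - 1, by = 2)] <- ins_seq
        s <- paste(out, collapse = "")
      }
      s
    } else {
      paste(v, collapse = "")
    }
  })
}

#' Extract a contiguous partial genome at a given completeness
#'
#' Takes one contiguous subsequence of length `round(fraction * L)` starting
#' at a seeded random position, wrapping around the end so the exact length
#' is always honored (bacterial chromosomes are circular, so the wrap is
#' natural).  Fractions low enough to leave <= 10 kb are flagged with a
#' warning; downstream sketching rejects such genomes.
#'
#' @param genome Character scalar ACGT sequence.
#' @param fraction Completeness in `(0, 1]`.
#' @param seed Integer seed.
#' @return Character scalar of length `round(fraction * nchar(genome))`.
#' @export
subsample_completeness <- function(genome, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  L <- nchar(genome)
  len <- round(fraction * L)
  if (len <= 10000) {
    warning("extracted length ", len,
            " bp <= 10 kb; downstream processing will reject this genome")
  }
  if (len == L) return(genome)
  with_seed(seed, {
    start <- sample.int(L, 1)
    if (start + len - 1L <= L) {
      substr(genome, start, start + len - 1L)
    } else {
      paste0(substr(genome, start, L),
             substr(genome, 1L, len - (L - start + 1L)))
    }
  })
}

#' Fragment a genome into a MAG-like multi-contig assembly
#'
#' Cuts the genome at seeded random breakpoints into `n_contigs` pieces and
#' shuffles their order, emulating the fragmentation of metagenome-assembled
#' genomes.  Total length is conserved exactly.  Contig-length spread is
#' controlled by gamma-distributed spacing weights: `length_dispersion = 1`
#' gives uniform random breakpoints; larger values give more uneven contigs.
#'
#' @param genome Character scalar ACGT sequence.
#' @param n_contigs Number of contigs (>= 1).
#' @param length_dispersion Positive spread control, default 1.
#' @param seed Integer seed.
#' @return Character vector of contigs (shuffled order).
#' @export
make_mag_like <- function(genome, n_contigs, length_dispersion = 1,
                          seed = 1) {
  stopifnot(n_contigs >= 1, length_dispersion > 0)
  if (n_contigs == 1L) return(genome)
  L <- nchar(genome)
  with_seed(seed, {
    w <- stats::rgamma(n_contigs, shape = 1 / length_dispersion)
    cuts <- round(cumsum(w) / sum(w) * L)
    cuts <- unique(pmin(pmax(cuts, 1), L))
    if (cuts[length(cuts)] != L) cuts <- c(cuts, L)
    starts <- c(1, utils::head(cuts, -1) + 1)
    pieces <- substring(genome, starts, cuts)
    pieces <- pieces[nchar(pieces) > 0]
    pieces[sample.int(length(pieces))]
  })
}

#' Simulate a labeled species/strain genome collection
#'
#' Builds the standard benchmark scenario: `n_species` species models with
#' distinct compositional signatures, one base genome each, and `n_strains`
#' strains per species.  Strain 1 is the unmutated base genome and plays the
#' reference role (one reference per species, as in type-strain reference
#' sets); the remaining strains are mutated copies and play the query role.
#'
#' @param n_species,n_strains Collection dimensions.
#' @param length Base genome length (scalar or range in bp).
#' @param divergence_control Species signature spread, see
#'   [generate_species()].
#' @param substitution_rate,indel_rate Strain mutation rates, see
#'   [mutate_strain()].
#' @param seed Integer seed; the scenario is fully deterministic under it.
#' @return An object of class `genome_scenario`: `genomes` (named list of
#'   sequences), `labels` (data frame `genome_id`, `species_id`, `role`),
#'   `models`, and the generating parameters.
#' @export
simulate_scenario <- function(n_species = 5, n_strains = 4,
                              length = c(1e6, 2e6),
                              divergence_control = 0.3,
                              substitution_rate = 0.02,
                              indel_rate = 0.002, seed = 1) {
  stopifnot(n_species >= 1, n_strains >= 1)
  models <- generate_species(n_species, length = length,
                             divergence_control = divergence_control,
                             seed = derive_seed(seed, 11))
  genomes <- list()
  labels <- list()
  for (i in seq_along(models)) {
    base <- generate_genome(models[[i]])
    for (j in seq_len(n_strains)) {
      gid <- sprintf("%s_st%02d", models[[i]]$species_id, j)
      genomes[[gid]] <- if (j == 1L) base else {
        mutate_strain(base, substitution_rate = substitution_rate,
                      indel_rate = indel_rate,
                      seed = derive_seed(seed, 13, i, j))
      }
      labels[[gid]] <- data.frame(
        genome_id = gid, species_id = models[[i]]$species_id,
        role = if (j == 1L) "ref" else "query",
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(genomes = genomes, labels = do.call(rbind, c(labels,
                                                      make.row.names = FALSE)),
         models = models,
         params = list(n_species = n_species, n_strains = n_strains,
                       length = length,
                       divergence_control = divergence_control,
                       substitution_rate = substitution_rate,
                       indel_rate = indel_rate, seed = seed)),
    class = "genome_scenario")
}

#' @export
print.genome_scenario <- function(x, ...) {
  cat(sprintf(
    "<genome_scenario: %d species x %d strains, %d genomes, %s-%s bp>\n",
    x$params$n_species, x$params$n_strains, length(x$genomes),
    format(min(vapply(x$genomes, nchar, numeric(1))), big.mark = ","),
    format(max(vapply(x$genomes, nchar, numeric(1))), big.mark = ",")))
  invisible(x)
}
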