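---
title: "Completeness-independent sieving of closely related genomes: methods and design"
author: "fragte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completeness-independent sieving of closely related genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Whole-genome species delineation in prokaryotes (ANI, AAI, MiSI) requires a
pairwise alignment step whose cost grows with the product of query and
reference collection sizes, although only intraspecies pairs — a small
minority — actually need aligning. *Sieving* pre-selects candidate closely
related pairs by genome composition so that alignment is only spent on them.
A sieve must be extremely sensitive (a dropped intraspecies pair is
unrecoverable downstream) and as specific as possible (every surviving
interspecies pair costs an alignment).

The whole-genome tetranucleotide sieve (TETRA, fixed 0.99 criterion) is
sensitive only when both genomes are reasonably complete; draft genomes and
MAGs below roughly 40% completeness fall under the criterion even against
their own conspecifics. `fragte` implements a fragment-based sieve that
compares *representative fragments* of bounded size instead of whole
genomes, so the statistic a pair is judged by does not degrade as
completeness falls.

## Signature model

All k-mer counting is strand-symmetric: the sequence and its reverse
complement are counted as two separate strings and summed, which makes every
profile exactly invariant under reverse complementation and avoids the three
artifactual junction words that literal concatenation of the two strands
would create. Ambiguous residues are spliced out before counting; the few
junction words this creates are negligible above 10 kb and splicing keeps
the effective length well defined.

Each tetramer $w = n_1n_2n_3n_4$ is standardised against the maximal-order
Markov expectation conditioned on the trimer and dimer counts of the same
sequence:

$$E(w) = \frac{C(n_1n_2n_3)\,C(n_2n_3n_4)}{C(n_2n_3)},\qquad
\mathrm{Var}(w) = E(w)\,\frac{(C(n_2n_3)-C(n_1n_2n_3))(C(n_2n_3)-C(n_2n_3n_4))}{C(n_2n_3)^2},$$

$$z(w) = \frac{O(w)-E(w)}{\sqrt{\mathrm{Var}(w)}}.$$

Where the central dimer is absent or the variance is not positive, $z(w)=0$;
this keeps all 256 components finite and is the conventional degenerate
treatment. (Note that near-degenerate sequences need not have $z = 0$: for a
homopolymer the variance of the homopolymeric tetramer is small but
positive, so its z-score is a small negative number — the zero convention
applies only to exactly degenerate denominators.) Similarity between two
profiles is the Pearson correlation of the two 256-vectors, written PCCD;
despite the historical name it is a similarity, with 1 meaning identical
composition. A zero-variance profile yields PCCD 0 with a warning; it can
only arise from pathological inputs.

## Fragmenting phase

Contigs are concatenated in file order (junction words across boundaries are
accepted; above 10 kb they are a vanishing fraction of windows). Genomes of
total length $L \le 10$ kb are rejected: below that size intra- and
inter-species fragment PCCD distributions are not separable. The window
length $l$ is chosen to make fragments as long as possible while keeping at
least the four fragments needed for a credible genome-specific cutoff:

* $L < 40$ kb — no fragmenting; the whole-genome profile serves as both
  representative and fourfold profile, and the diagonal length-specific
  cutoff at $L$ stands in for the GSC.
* $40 \le L \le 800$ kb — $l = L/4$, giving exactly 8 windows at 50%
  overlap: seven of length $l$ and a trailing window of length $l/2$. A
  trailing window is kept whenever its length is at least $l/2$, the only
  enumeration consistent with both the 50% overlap and the 8-fragment
  design.
* $L > 800$ kb — $l$ is capped at 200 kb (the upper end of the cutoff
  grid), which also increases the fragment count and keeps the GSC from
  growing too large on big genomes.

Each window's accumulated PCCD is its summed similarity to all
*non-overlapping* intragenomic windows (half-open coordinate test, so
abutting windows count as disjoint and partial trailing windows are handled
correctly). The argmax is the representative fragment (ZRF); ties break
toward the lowest genomic coordinate, making the phase fully deterministic.
The four largest accumulated PCCDs define the fourfold fragment; its
profile (ZLF) is computed from the *summed k-mer counts* of the four
fragments, which is order-invariant and adds no junction windows.

The genome-specific cutoff is
$\mathrm{GSC} = \overline{\mathrm{PCCD}} - 2\,\mathrm{SD}$ over the
representative fragment's PCCDs to its non-overlapping partners (sample SD,
$n-1$ denominator; the choice between population and sample SD is
immaterial at 5–6 partners but has to be fixed for determinism). Two clamps
apply: from below by the length-specific cutoff at the representative
fragment's size (a filtering cutoff must never undercut the selection
cutoff), and from above by 0.92, adopted as a package constant — beyond it
essentially all interspecies pairs are already filtered and a larger GSC
would start discarding intraspecies pairs whose genomes differ by
accessory content (plasmids being the canonical example).

## Length-specific cutoff calibration

For every unordered pair of fragment sizes on a kb grid (default 10–200 kb
in 10 kb steps), intraspecies and interspecies fragment PCCDs are sampled
from a labeled training set and approximated by normal distributions. Two
candidate cutoffs follow: $\mu_\mathrm{intra} - z\,\sigma_\mathrm{intra}$
(keeps at least 95% of intraspecies pairs) and
$\mu_\mathrm{inter} + z\,\sigma_\mathrm{inter}$ (excludes at least 95% of
interspecies pairs), with $z = 1.6449$, the one-sided 95% normal quantile —
the natural reading of "at least 95%" under a normal approximation. The
LSC is the *smaller* of the two, which protects sensitivity
unconditionally and takes the extra specificity whenever the distributions
are well separated. A one-sample Kolmogorov–Smirnov statistic against the
fitted normal is available as a diagnostic only; it never gates
calibration.

Lookup floors query lengths to the grid and clamps them to its range;
lookups are symmetric in the two lengths. `calibrate_lsc()` samples with a
pooled scheme — a fixed number of seeded random fragments per genome per
size bin, profiled once, pairs then drawn from the pool with same-genome
pairs excluded — which bounds the number of profile computations by
(genomes × bins × fragments) instead of (bin pairs × samples).
`sample_fragment_pccds()` exposes the direct per-size-pair sampler for
diagnostics. The package ships a default table calibrated on its own seeded
synthetic training set (6 species × 3 strains of 450–650 kb;
`scripts/make_default_lsc.R` regenerates it) so the tool works out of the
box; it is a synthetic stand-in, and production use on real taxa should
recalibrate on labeled real genomes.

## Determining phase

Per genome, the fourfold profile replaces the representative profile
whenever the fourfold fragment is at most 200 kb (selection sensitivity
rises with fragment size; for $L \le 200$ kb this makes the substitution
automatic). For a pair:

1. $P_1$, the PCCD of the two selection profiles, is compared with the LSC
   looked up at the lengths of the profiles actually correlated — the
   natural indexing when one genome substituted and the other did not.
   $P_1 < \mathrm{LSC}$ rejects immediately.
2. Otherwise $P_1 \ge \mathrm{GSC}_p$ (the smaller of the two genomes'
   GSCs) sieves the pair.
3. Otherwise $P_2$, the PCCD of the two fourfold profiles, is computed
   (lazily — it is recorded as absent for pairs that never reach this
   stage) and $P_2 \ge \mathrm{GSC}_p$ sieves.

All comparisons are inclusive; the methods text of the source algorithm
states them as $\ge$ and the package follows that throughout, so a pair
sitting exactly on a cutoff is sieved. $\mathrm{GSC}_p$, the LSC lookup and
$P_1/P_2$ are all symmetric in the pair, so decisions are
order-independent. Self-pairs (equal genome ids) are skipped so a
collection can be sieved against itself.

## Synthetic benchmark generator

The generator exists so every stage is testable without downloads, and its
defaults are the package's study conditions:

* **Species** are order-3 Markov chains: the next base conditioned on the
  previous trimer, with weights $\propto \exp(0.3\,N(0,1))$ per (context,
  base). The order is deliberate: the z-score statistic removes all
  structure up to trimers, so species separation must come from genuine
  fourth-order signal — an order-2 generator would make all species look
  identical to the statistic, and injecting the signal at exactly
  tetramer level keeps the benchmark honest rather than trivially easy.
  The spread 0.3 gives strain-vs-strain whole-genome PCCDs near 1 and
  cross-species PCCDs near 0. Real genome pairs of *different* species
  share universal compositional biases and correlate higher than that, so
  the synthetic interspecies separation is easier than reality; the
  sensitivity side of the benchmark (intraspecies signal against sampling
  noise, completeness, and the GSC gates) is the faithful part, and
  absolute specificity numbers should not be read across to real taxa.
* **Strains** are mutated copies of one base genome per species: 2%
  per-site substitutions and 0.2% indel events (lengths 1–10, geometric
  with mean 2), emulating conspecific strains under the usual >96% ANI
  circumscription.
* **Completeness** is one contiguous seeded extraction of the requested
  fraction, wrapping around the end (chromosomes are circular, and the
  wrap honors the exact length). Whether the original degradations were
  contiguous is not documented; contiguous random-start extraction is this
  package's choice and is the harder case for a fragment method, since
  two partial genomes of the same strain may share no sequence at all.
* **MAG-like fragmentation** cuts at seeded breakpoints (gamma-spacing,
  dispersion parameter) and shuffles contig order, conserving total length
  exactly.

Everything is deterministic under an integer seed, and all seeds are kept
below $2^{31}$.

What the generator does *not* emulate: genomic islands and local
compositional heterogeneity (each synthetic genome is homogeneous, so
intragenomic fragment PCCDs are more uniform than in real genomes and GSCs
correspondingly tighter), real phylogenetic structure between species,
assembly error and chimerism, and shared interspecies composition as noted
above. Benchmark results on this generator therefore demonstrate
completeness-independence and the correctness of the decision machinery,
not field performance on any particular taxon set.

## Benchmark experiments and problem sizes

The completeness grid degrades queries and references independently to each
of 10–100% (10% steps) and scores every cell; with one sub-seed per
(genome, level), a genome's sketch at a given completeness is shared across
all cells that use it, and the 100%/100% cell equals a direct non-degraded
run. The package's standard benchmark is 5 species × 4 strains (base
genomes 1–2 Mb; strain 1 of each species plays the reference role, the
other three are queries), giving 15 intraspecies and 60 interspecies pairs
per cell — small enough to run in under a minute on one CPU and large
enough that a single dropped intraspecies pair is visible as a 6.7-point
sensitivity drop. Sensitivity on this grid is 100.00% in every cell for the
fragment method, while the whole-genome baseline at 0.99 collapses below
~40% completeness; with 15 pairs per cell the baseline's per-cell
sensitivities carry visible binomial noise, so its decline is assessed as a
trend rather than cell-by-cell.

Metrics follow the standard definitions (sensitivity over intraspecies
pairs, specificity over interspecies pairs, fraction of all pairs sieved)
with percentages rounded half-up to two decimals, matching the reporting
convention of the sieving literature. `matched_sensitivity_cutoff()`
returns the largest baseline cutoff reaching a target sensitivity, enabling
specificity comparisons at matched sensitivity.

## Numerical and interface choices

* Tetramers are ordered lexicographically over A<C<G<T everywhere,
  including serialization.
* Pearson values are clamped to $[-1, 1]$ after the matrix products that
  compute them in bulk.
* Sketches serialize as JSON-lines with 17 significant digits, which
  round-trips IEEE doubles bit-exactly; cutoff tables serialize as TSV with
  `%.17g` numbers and re-parse exactly.
* Sketches record the identity of the cutoff table they were built
  against, and sieving refuses to mix tables.
* The trailing-window rule (keep iff length ≥ $l/2$) yields 10 windows for
  a 1 Mb genome (starts every 100 kb up to 900 kb); any enumeration that
  dropped the final half-window would break the 8-fragment guarantee at
  $L = 4l$.
* `fit_normal()` requires 100 samples by default; calibration errors out
  listing every size pair that cannot reach the minimum, rather than
  silently extrapolating.

## Known limitations

* The bundled cutoff table is synthetic; real-taxon work should
  recalibrate. The 10 kb floor and 200 kb cap of the grid are structural
  (fragments outside the range are floored/clamped).
* Sieving output is a candidate list, not a species call; pairs still
  require ANI/AF downstream, and compositionally convergent distant pairs
  (e.g. via horizontal transfer) can survive any compositional sieve.
* The fragmenting phase assumes one genome per input; metagenomic bins
  containing mixed species will produce chimeric sketches.
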