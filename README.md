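# fragte

Alignment-free **pre-selection ("sieving") of closely related prokaryotic
genome pairs** ahead of whole-genome comparisons such as average nucleotide
identity (ANI).

Genome-based species delineation needs pairwise whole-genome alignment, which
is prohibitive at database scale: most of the pairs compared are interspecies
pairs that alignment will only reject. A sieve that cheaply discards those
pairs first — while keeping essentially every intraspecies pair — makes the
downstream ANI/AF step tractable. The classic compositional sieve, TETRA
(whole-genome tetranucleotide z-score correlation at a fixed 0.99 criterion),
breaks down on incomplete genomes: draft assemblies and metagenome-assembled
genomes (MAGs) below ~40% completeness slip through it. `fragte` implements
FRAGTE, a fragment-based sieve whose decision is robust to genome
completeness, together with the TETRA baseline, the cutoff calibration
procedure, a seeded synthetic benchmark generator, and
sensitivity/specificity benchmarking.

The package is aimed at microbial taxonomists and metagenomics practitioners
who need to dereplicate or classify large genome collections (isolates,
drafts, MAGs) before an ANI-style comparison.

## Method

**Signatures.** For a sequence, all overlapping di-, tri- and tetranucleotides
are counted on both strands (forward plus reverse complement, so counts are
strand-symmetric). Each tetramer *w* = n1n2n3n4 is standardised against its
maximal-order Markov expectation:

    E(w)   = C(n1n2n3) · C(n2n3n4) / C(n2n3)
    Var(w) = E(w) · (C(n2n3) − C(n1n2n3)) · (C(n2n3) − C(n2n3n4)) / C(n2n3)²
    z(w)   = (O(w) − E(w)) / √Var(w)

yielding a 256-component z-score profile that removes all compositional
structure up to trimers. Similarity between two profiles is their Pearson
correlation, called PCCD in this field (larger = more similar; 1 =
identical composition).

**Fragmenting phase.** Each genome (contigs concatenated, length *L*) is cut
by a sliding window of length *l* with 50% overlap, where *l* = *L*/4 for
40 kb ≤ *L* ≤ 800 kb (giving 8 fragments) and *l* = 200 kb above; genomes
under 40 kb are used whole. Every fragment's PCCD against all
non-overlapping intragenomic fragments is summed; the fragment with the
maximal accumulated PCCD represents the genome (ZRF), and the top-4
fragments form a fourfold-longer fragment (ZLF). A genome-specific cutoff

    GSC = mean(intragenomic PCCDs of the representative) − 2·SD

is clamped to `[LSC_kb, 0.92]`, where LSC_kb is the length-specific cutoff
at the representative fragment's size.

**Length-specific cutoffs (LSC).** For every pair of fragment sizes on a
10–200 kb grid, intra- and inter-species fragment PCCDs from a labeled
training set are approximated by normals; the LSC is the smaller of the
cutoff keeping ≥ 95% of intraspecies pairs and the cutoff excluding ≥ 95%
of interspecies pairs.

**Determining phase.** For a pair, P1 = PCCD of the two selection profiles
(the ZLF stands in for the ZRF when its length is ≤ 200 kb). If
P1 < LSC the pair is rejected; else if P1 ≥ GSC_p (the smaller of the two
GSCs) it is sieved; else P2 = PCCD of the ZLFs decides: sieved iff
P2 ≥ GSC_p. All comparisons are inclusive (≥).

Sieving is deliberately *not* a species call: sieved pairs go on to
ANI/alignment-fraction computation, which is out of scope here.

## Worked example

```r
library(fragte)

# 1. simulate a small labeled collection: 3 species, 2 strains each
sc <- simulate_scenario(n_species = 3, n_strains = 2,
                        length = c(4e5, 6e5), seed = 42)
#> <genome_scenario: 3 species x 2 strains, 6 genomes, 408,433-561,953 bp>

# 2. sketch every genome with the bundled cutoff table
tbl <- default_lsc_table()
#> <lsc_table: 210 size pairs over 10-200 kb, z = 1.6449, LSC in [0.1544, 0.2591]>
sketches <- lapply(names(sc$genomes), function(id)
  sketch_genome(sc$genomes[[id]], table = tbl, genome_id = id))
sketches[[1]]
#> <genome_sketch sp01_st01: L = 561,953 bp, rep = 140,488 bp, 4x = 491,709 bp, GSC = 0.9200>

# 3. degrade one strain to 30% completeness and sieve it against the
#    three species references
partial <- subsample_completeness(sc$genomes$sp01_st02, 0.3, seed = 7)
q <- sketch_genome(partial, table = tbl, genome_id = "sp01_st02_30pct")
refs <- sketches[match(sc$labels$genome_id[sc$labels$role == "ref"],
                       names(sc$genomes))]
sieve_all(list(q), refs, tbl)[, c("query_id", "ref_id", "lsc_used", "p1",
                                  "gsc_p", "stage", "decision")]
#>          query_id    ref_id  lsc_used           p1     gsc_p      stage decision
#> 1 sp01_st02_30pct sp01_st01 0.2205275  0.984537784 0.9003586    p1_pass   sieved
#> 2 sp01_st02_30pct sp02_st01 0.1943458 -0.001975835 0.9003586 lsc_reject rejected
#> 3 sp01_st02_30pct sp03_st01 0.1792029 -0.068699550 0.9003586 lsc_reject rejected

# 4. score the full query set against the references
queries <- sketches[match(sc$labels$genome_id[sc$labels$role == "query"],
                          names(sc$genomes))]
score(sieve_all(queries, refs, tbl), sc$labels)
#> <sieve_metrics: sensitivity 100.00% (3/3 intra), specificity 100.00% (6/6 inter), sieved 33.33% (3/9)>
```

Reading the stage-3 output: the 30%-complete strain still correlates at
P1 = 0.985 with its own species' reference — above both the
length-specific cutoff (0.22 for this size pair) and the pair's
genome-specific cutoff (0.90) — so it is sieved at the first gate, while
both cross-species pairs fall below their LSC and are rejected
immediately. The metrics line counts sieved intraspecies pairs
(sensitivity), correctly rejected interspecies pairs (specificity) and the
fraction of all pairs passed on to downstream alignment.

A command-line wrapper with `simulate`, `calibrate`, `sketch`, `sieve`,
`tetra`, `evaluate` and `grid` subcommands is installed at
`inst/cli/fragte.R` (see `?fragte_cli`).

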