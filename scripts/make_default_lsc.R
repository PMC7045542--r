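#!/usr/bin/env Rscript
# Regenerates the bundled default LSC table (inst/extdata/
# lsc_synthetic_default.tsv) from the package's own seeded synthetic
# training set.  Run from the repository root after installing the package.
suppressPackageStartupMessages(library(fragte))

train <- simulate_scenario(n_species = 6, n_strains = 3,
                           length = c(450000, 650000),
                           seed = 48151)
tbl <- calibrate_lsc(train, seed = 48152)
write_lsc_table(tbl, "inst/extdata/lsc_synthetic_default.tsv")
cat("wrote", nrow(tbl$entries), "size pairs\n")
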