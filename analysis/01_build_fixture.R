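#!/usr/bin/env Rscript
# Step 1 — reconstruct the screening dataset.
#
# The screening covered 84 catfish acquired from private fish farms as
# "pure" P. corruscans, P. reticulatum or L. marmoratus, held by five
# research institutions (A-E). Per-sample genotypes were not deposited, but
# the per-institution category counts were published in full, so the
# dataset is reconstructed deterministically with one canonical genotype
# vector per category (see ?make_table2_fixture). This script writes the
# panel config and the genotype table that the following steps consume.

suppressPackageStartupMessages(library(hybriddiag))
dir.create("results", showWarnings = FALSE)

panel <- default_catfish_panel()
stopifnot(nrow(validate_panel(panel)) == 0)
write_panel(panel, "results/catfish_panel.yaml")

fixture <- make_table2_fixture(panel)
write_genotype_table(fixture, "results/screening_genotypes.csv")

cat("Panel:", panel$name, "-", length(nuclear_loci(panel)),
    "nuclear loci +", mito_locus(panel)$name, "mitochondrial\n")
cat("Wrote", n_samples(fixture), "samples to",
    "results/screening_genotypes.csv\n")
cat("Samples per institution:\n")
print(table(fixture$samples$source))
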