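Package: hybriddiag
Title: Multi-Locus Genetic Diagnosis of Interspecific Fish Hybrids
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individual fish as pure species, F1 hybrids, or
    post-F1 (advanced-generation) hybrids from panels of species-diagnostic
    codominant nuclear markers plus a mitochondrial marker for maternal
    lineage assignment. Includes a Mendelian cross simulator for arbitrary
    pedigrees over unlinked fully-diagnostic loci (with optional genotyping
    error and missingness), exact and Monte Carlo calculators for the
    probability that a given cross is classified into each category, and
    reporting utilities that aggregate classifications into per-source
    summary tables. Motivated by genetic monitoring of Neotropical catfish
    (Pseudoplatystoma corruscans, P. reticulatum, Leiarius marmoratus)
    aquaculture stocks, where morphology-based labelling misses hybrids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
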