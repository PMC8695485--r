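---
title: "Diagnosing fish hybrids from species-diagnostic marker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing fish hybrids from species-diagnostic marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriddiag)
```

## The problem

Neotropical catfish aquaculture crosses *Pseudoplatystoma corruscans*
(pintado), *P. reticulatum* (cachara) and *Leiarius marmoratus* (jundiá) on
purpose, because F1 hybrids grow faster and yield better meat. The trouble
starts when those hybrids — and their descendants — circulate under
pure-species labels: hybrids and pure fish are morphologically similar,
juveniles especially, so stocks bought as pure from fish farms may be
anything from genuine pure species to advanced-generation backcrosses.
`hybriddiag` implements the molecular diagnosis of such stocks: a
multi-locus genotype-pattern classifier, a Mendelian pedigree simulator to
generate test data with known truth, and an exact calculator for what a
finite marker panel can and cannot detect.

## The classification rule

The diagnosis rests on *species-diagnostic codominant markers*: loci at
which each species carries a distinct fixed allele, so that both alleles of
a genotype are observable (on a gel, both species' amplicon bands appear)
and any heterozygote directly proves mixed ancestry. The default panel —
`default_catfish_panel()` — has three such nuclear loci (RAG2, EF1α, β-globin)
plus a 16S rRNA mitochondrial marker.

Writing hom(*s*) for a locus homozygous for species *s* and het(*s₁*,*s₂*)
for a heterozygote, an individual's typed nuclear loci decide its category:

* **PURE(s)** — every locus hom(*s*) for the same *s*. A pure
  representative of species *s*.
* **F1_HYBRID(s₁,s₂)** — every locus het(*s₁*,*s₂*) for the same pair. The
  obligate pattern of a first-generation cross at fully diagnostic loci.
* **POST_F1_HYBRID** — any combination of homozygous and heterozygous
  loci. F2s, backcrosses and later generations segregate, so they show
  mixed patterns.
* **UNRESOLVED** — fewer typed loci than the policy floor (below).

The mitochondrial locus never enters the category decision; it identifies
the maternal species (mitochondria are transmitted strictly through the
dam), and a maternal species incompatible with the nuclear result is
surfaced as a `cytonuclear_discordance` advisory flag.

### Corner patterns the three clauses don't literally cover

Two genotype patterns fall outside the rule as stated, and the package
resolves both by their genetics rather than leaving them undefined:

* **All homozygous, different species at different loci** (e.g. hom(Pcor),
  hom(Pret), hom(Pcor)). Under fully diagnostic unlinked loci this cannot
  arise without hybrid ancestry — some ancestor had to contribute a
  different species' allele that then fixed per locus — so it is classified
  `POST_F1_HYBRID` with flag `all_hom_discordant`. Exhaustive enumeration
  of backcross × backcross offspring confirms the pattern occurs only with
  hybrid ancestry.
* **All heterozygous, but spanning different species pairs** (possible
  with three species). An F1 of two species is heterozygous for the *same*
  pair everywhere, so this is `POST_F1_HYBRID` with flag
  `multispecies_ancestry`, and no species pair is reported.

### Purity is genetic, labels are metadata

A fish homozygous throughout for a species other than its morphological
label is classified `PURE` for the *genetic* species, with
`label_concordant = "no"`. One could instead read "homozygous for the
initially classified species" as presuming the label, making such a fish
unclassifiable; we keep the two readings separable by reporting the
discordance rather than folding the label into the genetics. Concordance is
`"unknown"` when the label is missing or the fish is not pure.

### Missing data

Loci with missing calls are dropped before the rule is applied — the
weakest defensible assumption, since no missingness policy is implied by
the diagnosis itself. `classifier_policy(min_typed_nuclear_loci = k)` lets
users demand more evidence; below `k` typed loci the sample is
`UNRESOLVED`, which is always reported as its own summary column, never
silently pooled with pure or hybrid (mislabelled stock is the entire point
of the exercise, so unclassifiable fish must stay visible). The default is
`k = 1`: a single typed locus can already prove hybridity, though it can
never show the combined pattern (see the power section).

Classification is fully deterministic; there is no randomness anywhere in
the classifier or the reporting.

## The simulator

`simulate_dataset()` generates genotypes forward through explicit pedigrees
(`leaf()`, `cross()`, or the text notation `"(Pret x Pcor) x Pret"`, dam
first) under standard Mendelian transmission: founders are homozygous for
their species' diagnostic allele everywhere; each cross transmits one
uniformly chosen allele per locus per parent, loci assorting independently;
the mitochondrial allele follows the dam lineage. Assumptions, chosen to
mirror the biology of the marker panel and kept deliberately minimal:

* **Unlinked, mutation-free loci.** The panel's markers sit on distinct
  genes; no linkage information exists for them.
* **Fully diagnostic loci.** No shared alleles between species, matching
  the panel model. Partial diagnosticity is out of scope.
* **Fresh parents per offspring.** Each cross node draws new, independent
  parent individuals for every offspring. Real hatcheries reuse
  broodstock, which correlates sibling genotypes; simulated category
  *frequencies* are unaffected (each individual's marginal law is
  identical) but between-sample correlations are not emulated.
* **Genotyping error** replaces a call, with probability
  `genotyping_error_rate` per locus, by a uniformly random valid genotype
  at that locus — whole-call corruption, the way a miscalled multiplex lane
  corrupts a genotype, rather than a single-allele flip. One parameter,
  defaulting to 0 as in the idealised diagnosis. `missing_rate` then drops
  calls independently per locus (default 0).
* **Mandatory seed, one RNG stream per dataset, counter-based sample
  ids** — identical configs produce byte-identical CSV tables.

Because real per-sample genotypes for the 84-fish screening were never
deposited, `make_table2_fixture()` reconstructs that dataset
deterministically from its published per-institution category counts, using
one canonical genotype vector per category (post-F1: homozygous at the
first nuclear locus, heterozygous at the rest). The published counts pin
the category of every sample but not *which* advanced-generation pattern
each post-F1 fish carried; the canonical choice is arbitrary and documented
as such, and nothing downstream depends on it beyond the category.

What passing tests on simulated data do show: the classifier, the exact
power calculator and the simulator agree with each other and with
brute-force enumeration under Mendelian inheritance at diagnostic loci.
What they cannot show: robustness to partially diagnostic markers, null
alleles, linkage, or correlated sibling structure in real farm stocks.

## Panel power: what L loci can detect

For a pedigree, every nuclear locus has the same genotype law *q* over
species-ancestry genotypes (computed exactly by recursion on the pedigree in
`locus_distribution()`), and loci are independent. With L loci:

$$P(\text{F1-looking}) = \sum_{\{s_1,s_2\}} q(\text{het}(s_1,s_2))^L,
\qquad P(\text{PURE-looking } s) = q(\text{hom}(s))^L,$$

and the remaining mass is the post-F1 detection probability
(`category_distribution()`). For a first backcross, *q* puts 1/2 on het and
1/2 on hom, so at L = 3 a BC1 is *misdiagnosed* as F1 with probability 1/8
and as pure with probability 1/8 — a 25% escape rate that is a structural
property of the three-marker design, not a laboratory error.
`detection_curve()` traces this against L: detection is 0 at L = 1 (the
combined pattern needs two loci to exist), rises to 75% at L = 3 and
crosses 99% at 8 loci. `mc_category_distribution()` cross-checks any of
these numbers by simulation, with 95% Wilson score intervals (chosen over
Wald because they behave at proportions of 0 and 1).

Numerical choices: all probabilities are ordinary doubles — at L ≤ 20 the
accumulated error is far below reporting precision, so exact rational
arithmetic would buy nothing. Internally the category probabilities are
computed as per-locus products, so panels whose loci follow different laws
would be handled by the same code path; under this simulator all loci of a
pedigree share one law and the distinction never arises.

## Reporting

`summarize_classifications()` aggregates by any sample field (default
`source`) into per-group counts and percent-hybrids, plus global category
percentages and the post-F1 share among hybrids. Percentages are kept at
full precision in the object and rounded only at render time, half-up to 2
decimals (integer percentages print without decimals) — base `round()`
rounds half to even, which manual tables rarely follow. CSV and markdown
renderings use identical numeric strings and are byte-stable.

## Problem sizes

The test suite enumerates the full 216-vector genotype space of the default
panel against an independently coded literal implementation of the rule,
verifies exact category laws against brute-force genotype-space enumeration
for six pedigrees, and uses 4,000–10,000 simulated individuals (fixed
seeds) for Monte-Carlo agreement at three binomial standard errors; the
whole suite runs in a few seconds. The analysis scripts use 10,000
individuals per Monte-Carlo check.

## Limitations

* The panel cannot distinguish F2 from backcross from later generations —
  all are "post-F1" — and with three loci it misses 25% of BC1s entirely.
  Probabilistic assignment (NewHybrids-style posteriors) is out of scope.
* Diagnosticity is assumed for every pairwise species contrast; that the
  three default markers separate all three species pairs has not been
  established here for every contrast, so the default panel treats it as
  an assumption users should verify for their own assays.
* Band-size decoding (`decode_band_pattern()`) defaults to exact matching;
  gel-dependent tolerances must be supplied explicitly because no expected
  amplicon sizes ship with the default panel.
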