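# hybriddiag

Multi-locus genetic diagnosis of interspecific fish hybrids: classify
individuals as **pure species**, **F1 hybrid** or **post-F1 hybrid**
(advanced generation — F2, backcross or later) from panels of
species-diagnostic codominant nuclear markers, with maternal lineage
assignment from a mitochondrial marker.

The package targets genetic monitoring of aquaculture and research stocks —
the motivating case is Neotropical catfish (*Pseudoplatystoma corruscans*,
*P. reticulatum*, *Leiarius marmoratus*), whose deliberately produced F1
hybrids are morphologically close enough to the pure species that
mislabelled hybrids, and descendants of uncontrolled backcrosses, circulate
through fish farms undetected. It is for geneticists and stock managers who
type a handful of diagnostic loci per fish and need the diagnosis, the
uncertainty it carries, and test data with known truth.

## The rule

At a *fully diagnostic* locus each species carries a distinct fixed allele,
so with codominant markers every genotype is readable as hom(*s*) or
het(*s₁*, *s₂*). Over the typed nuclear loci of an individual:

| pattern | category |
| --- | --- |
| every locus hom(*s*), same *s* | `PURE(s)` |
| every locus het(*s₁*,*s₂*), same pair | `F1_HYBRID(s₁,s₂)` |
| homozygous and heterozygous loci combined | `POST_F1_HYBRID` |
| all hom but different species across loci | `POST_F1_HYBRID` (flag `all_hom_discordant`) |
| all het but different pairs across loci | `POST_F1_HYBRID` (flag `multispecies_ancestry`) |
| too few typed loci | `UNRESOLVED` |

The mitochondrial marker identifies the maternal species and never changes
the category; conflicts surface as a `cytonuclear_discordance` flag.

Because a first backcross (BC1) is heterozygous at each locus with
probability 1/2, an L-locus panel misdiagnoses it as F1 with probability
(1/2)^L and as pure with probability (1/2)^L — the package computes these
detection limits exactly for any pedigree
(`category_distribution()`, `detection_curve()`) and by simulation
(`mc_category_distribution()`), and generates genotype datasets from
arbitrary pedigrees under Mendelian inheritance (`simulate_dataset()`).

## Worked example

```r
library(hybriddiag)
panel <- default_catfish_panel()   # RAG2, EF1a, glob + 16S; Pcor/Pret/Lmar

# a fish bought as cachara (P. reticulatum):
sample <- list(sample_id = "farm_042", source = "farm",
               morph_species = "Pret",
               RAG2_a1 = "Pret", RAG2_a2 = "Pret",
               EF1a_a1 = "Pcor", EF1a_a2 = "Pret",
               glob_a1 = "Pcor", glob_a2 = "Pret",
               `16S` = "Pret")
classify_individual(sample, panel)
#> POST_F1_HYBRID; maternal: Pret
```

One homozygous plus two heterozygous loci: not a pure cachara and not an
F1 either, but an advanced-generation hybrid whose maternal line is
*P. reticulatum* — exactly the fish a morphological check waves through.
How often does the panel catch such a fish? For a first backcross to
*P. reticulatum*:

```r
bc1 <- parse_cross_spec("(Pret x Pcor) x Pret")
category_distribution(bc1, panel)
#>   P(PURE Pcor)     = 0.0000
#>   P(PURE Pret)     = 0.1250
#>   P(F1_HYBRID)   = 0.1250
#>   P(POST_F1)     = 0.7500
```

A BC1 is detected 75% of the time; the other 25% it masquerades as a pure
cachara or an F1. `detection_curve(bc1, panel, L_values = 1:10)` shows what
adding loci buys.

## The analysis

The `analysis/` scripts re-run the stock screening this package grew out
of, writing tables under `results/`:

1. `01_build_fixture.R` — reconstructs the 84-fish, five-institution
   screening dataset from its published per-source category counts
   (per-sample genotypes were never deposited) and writes the panel config
   and genotype CSV.
2. `02_classify_and_report.R` — classifies every fish and renders the
   per-institution summary: 62 pure, 2 F1, 20 post-F1 — 26.2% hybrids,
   90.9% of them already post-F1.
3. `03_panel_power.R` — exact and Monte-Carlo category probabilities for
   F1, F2, BC1, BC2 and F1×BC1, plus the post-F1 detection curve in L.
4. `04_mixture_recovery.R` — simulates a farm-like mixture of known
   composition and checks the classified frequencies against the exact
   expectation.

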