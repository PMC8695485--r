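panel <- default_catfish_panel()
het_PP <- c("Pcor", "Pret")

test_that("the three canonical genotype patterns get their categories", {
  f1 <- classify_individual(uniform_row(panel, het_PP, mito = "Pret"), panel)
  expect_equal(f1$category, "F1_HYBRID")
  expect_setequal(f1$species_pair, c("Pcor", "Pret"))
  expect_equal(f1$maternal_species, "Pret")

  pure <- classify_individual(
    uniform_row(panel, c("Pret", "Pret"), mito = "Pret", morph = "Pret"),
    panel)
  expect_equal(pure$category, "PURE")
  expect_equal(pure$genetic_species, "Pret")
  expect_equal(pure$label_concordant, "yes")
  expect_length(pure$flags, 0L)

  post <- classify_individual(
    make_row(panel, list(RAG2 = c("Pcor", "Pcor"), EF1a = het_PP,
                         glob = het_PP), mito = "Pcor"),
    panel)
  expect_equal(post$category, "POST_F1_HYBRID")
  expect_null(post$genetic_species)
})

test_that("all-homozygous but species-discordant loci mean hybrid ancestry", {
  s <- make_row(panel, list(RAG2 = c("Pcor", "Pcor"),
                            EF1a = c("Pret", "Pret"),
                            glob = c("Pcor", "Pcor")), mito = "Pcor")
  cls <- classify_individual(s, panel)
  expect_equal(cls$category, "POST_F1_HYBRID")
  expect_true("all_hom_discordant" %in% cls$flags)
})

test_that("all-het vectors spanning different species pairs are post-F1", {
  s <- make_row(panel, list(RAG2 = c("Pcor", "Pret"),
                            EF1a = c("Lmar", "Pcor"),
                            glob = c("Pcor", "Pret")), mito = "Pcor")
  cls <- classify_individual(s, panel)
  expect_equal(cls$category, "POST_F1_HYBRID")
  expect_true("multispecies_ancestry" %in% cls$flags)
  expect_null(cls$species_pair)
})

test_that("purity is genetic; a mismatching label is flagged, not recoded", {
  s <- uniform_row(panel, c("Pcor", "Pcor"), mito = "Pcor", morph = "Pret")
  cls <- classify_individual(s, panel)
  expect_equal(cls$category, "PURE")
  expect_equal(cls$genetic_species, "Pcor")
  expect_equal(cls$label_concordant, "no")
})

test_that("the mitochondrial call never changes the category", {
  s_concord <- uniform_row(panel, c("Pcor", "Pcor"), mito = "Pcor")
  s_discord <- uniform_row(panel, c("Pcor", "Pcor"), mito = "Pret")
  a <- classify_individual(s_concord, panel)
  b <- classify_individual(s_discord, panel)
  expect_equal(a$category, b$category)
  expect_equal(a$genetic_species, b$genetic_species)
  expect_false("cytonuclear_discordance" %in% a$flags)
  expect_true("cytonuclear_discordance" %in% b$flags)
  # F1 whose maternal species is outside its pair
  f1_odd <- classify_individual(uniform_row(panel, het_PP, mito = "Lmar"),
                                panel)
  expect_equal(f1_odd$category, "F1_HYBRID")
  expect_true("cytonuclear_discordance" %in% f1_odd$flags)
})

test_that("missing loci are dropped and the typed-locus floor applies", {
  all_missing <- make_row(panel, list(), mito = NA)
  expect_equal(classify_individual(all_missing, panel)$category,
               "UNRESOLVED")
  one_typed <- make_row(panel, list(RAG2 = c("Pret", "Pret")))
  expect_equal(classify_individual(one_typed, panel)$category, "PURE")
  expect_equal(
    classify_individual(one_typed, panel,
                        classifier_policy(min_typed_nuclear_loci = 2))$
      category,
    "UNRESOLVED")
  # unknown morphology => concordance unknown
  expect_equal(classify_individual(one_typed, panel)$label_concordant,
               "unknown")
})

test_that("maternal lineage comes from the mitochondrial marker alone", {
  expect_equal(
    assign_maternal_lineage(uniform_row(panel, het_PP, mito = "Pret"),
                            panel),
    "Pret")
  expect_true(is.na(
    assign_maternal_lineage(uniform_row(panel, het_PP, mito = NA), panel)))
  s <- uniform_row(panel, het_PP, mito = "Pret")
  s$`16S` <- "Pxxx"
  expect_error(assign_maternal_lineage(s, panel), "Pxxx")
})

test_that("classifier matches the literal-rule oracle on the full
           3-locus genotype space and is total and exclusive", {
  rows <- enumerate_genotype_rows(panel)
  expect_equal(nrow(rows), 216L)  # 6 genotypes ^ 3 loci
  got <- classify_dataset(new_dataset(panel, rows))
  want <- vapply(seq_len(nrow(rows)), function(i) {
    oracle_classify(as.list(rows[i, ]), panel)
  }, character(1))
  expect_equal(got$category, want)
  expect_true(all(got$category %in%
                    c("PURE", "F1_HYBRID", "POST_F1_HYBRID", "UNRESOLVED")))
})

test_that("category is invariant to locus order and within-pair order", {
  set.seed(202)
  rows <- enumerate_genotype_rows(panel)
  nuc <- names(nuclear_loci(panel))
  for (i in sample.int(nrow(rows), 25)) {
    base <- as.list(rows[i, ])
    ref <- classify_individual(base, panel)
    perm <- sample(nuc)
    permuted <- base
    for (k in seq_along(nuc)) {
      # swap alleles too: (a2, a1) of a permuted locus
      permuted[[paste0(nuc[k], "_a1")]] <- base[[paste0(perm[k], "_a2")]]
      permuted[[paste0(nuc[k], "_a2")]] <- base[[paste0(perm[k], "_a1")]]
    }
    got <- classify_individual(permuted, panel)
    expect_equal(got$category, ref$category)
    expect_equal(got$genetic_species, ref$genetic_species)
  }
})

test_that("classify_dataset preserves order and handles the empty dataset", {
  fx <- make_table2_fixture(panel)
  cls <- classify_dataset(fx)
  expect_equal(cls$sample_id, fx$samples$sample_id)
  expect_equal(as.vector(table(factor(cls$category,
                                      c("PURE", "F1_HYBRID",
                                        "POST_F1_HYBRID")))),
               c(62L, 2L, 20L))
  empty <- fx
  empty$samples <- fx$samples[0, ]
  expect_equal(nrow(classify_dataset(empty)), 0L)
})

test_that("simulated pure and F1 individuals classify perfectly without
           error or missingness", {
  cfg <- simulation_config(
    panel,
    list(list(spec = leaf("Lmar"), count = 50),
         list(spec = cross(leaf("Pret"), leaf("Pcor")), count = 50)),
    seed = 5)
  cls <- classify_dataset(simulate_dataset(cfg))
  expect_true(all(cls$category[1:50] == "PURE"))
  expect_true(all(cls$genetic_species[1:50] == "Lmar"))
  expect_true(all(cls$category[51:100] == "F1_HYBRID"))
  expect_true(all(cls$maternal_species[51:100] == "Pret"))
})
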