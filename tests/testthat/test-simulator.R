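panel <- default_catfish_panel()
F1 <- cross(leaf("Pret"), leaf("Pcor"))
BC1 <- cross(F1, leaf("Pret"))

test_that("founders and F1s have forced genotypes", {
  set.seed(1)
  p <- simulate_individual(leaf("Pret"), panel)
  for (ln in names(nuclear_loci(panel))) {
    expect_equal(p[[paste0(ln, "_a1")]], "Pret")
    expect_equal(p[[paste0(ln, "_a2")]], "Pret")
  }
  expect_equal(p$`16S`, "Pret")

  for (i in 1:20) {
    f1 <- simulate_individual(F1, panel)
    for (ln in names(nuclear_loci(panel))) {
      expect_setequal(c(f1[[paste0(ln, "_a1")]], f1[[paste0(ln, "_a2")]]),
                      c("Pcor", "Pret"))
    }
    expect_equal(f1$`16S`, "Pret")  # dam was P. reticulatum
  }
})

test_that("gametes segregate 1:1 and loci assort independently", {
  set.seed(42)
  parent <- list(RAG2 = c("Pcor", "Pret"), EF1a = c("Pcor", "Pret"),
                 glob = c("Pret", "Pret"))
  n <- 10000
  gam <- replicate(n, simulate_gamete(parent, panel))
  # binomial(n, 1/2) oracle: 3 SE band around 0.5
  se3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(gam["RAG2", ] == "Pcor") - 0.5), se3)
  expect_true(all(gam["glob", ] == "Pret"))  # homozygote transmits surely
  # two-locus joint distribution uniform over the 4 combinations
  joint <- table(paste(gam["RAG2", ], gam["EF1a", ]))
  expect_equal(sort(names(joint)),
               sort(c("Pcor Pcor", "Pcor Pret", "Pret Pcor", "Pret Pret")))
  chi <- suppressWarnings(chisq.test(joint, p = rep(0.25, 4)))
  expect_gt(chi$p.value, 1e-4)
  # incomplete parental genotype is an error
  expect_error(simulate_gamete(list(RAG2 = c("Pcor", "Pret")), panel),
               "EF1a")
})

test_that("mitochondrial transmission is strictly maternal on deep
           pedigrees", {
  set.seed(99)
  specs <- list(
    BC1,
    cross(leaf("Lmar"), BC1),
    cross(cross(F1, F1), cross(leaf("Pcor"), leaf("Lmar"))),
    cross(cross(cross(leaf("Lmar"), leaf("Pcor")), F1), leaf("Pret"))
  )
  for (spec in specs) {
    want <- dam_line_species(spec)
    for (i in 1:10) {
      ind <- simulate_individual(spec, panel)
      expect_equal(ind$`16S`, want)
    }
  }
})

test_that("simulate_dataset is a deterministic function of its config", {
  cfg <- simulation_config(
    panel,
    list(list(spec = BC1, count = 30), list(spec = leaf("Pcor"), count = 10)),
    seed = 77, genotyping_error_rate = 0.1, missing_rate = 0.1,
    morph_label_policy = c(Pcor = "Pcor"))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_genotype_table(d1, f1)
  write_genotype_table(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 78L
  expect_false(identical(simulate_dataset(cfg2)$samples, d1$samples))
  # ids encode component and replicate; morph label policy applied
  expect_equal(d1$samples$sample_id[1], "c1_PretxPcorxPret_1")
  expect_true(all(d1$samples$morph_species[31:40] == "Pcor"))
  expect_true(all(is.na(d1$samples$morph_species[1:30])))
})

test_that("degenerate rates behave as documented", {
  cfg <- simulation_config(panel, list(list(spec = leaf("Pret"), count = 8)),
                           seed = 3, missing_rate = 1)
  cls <- classify_dataset(simulate_dataset(cfg))
  expect_true(all(cls$category == "UNRESOLVED"))
  expect_error(simulation_config(panel, list(), seed = 1), "composition")
  expect_error(
    simulation_config(panel, list(list(spec = leaf("Pret"), count = 1)),
                      seed = 1, missing_rate = 2))
  expect_error(
    simulation_config(panel, list(list(spec = leaf("Pret"), count = 1))),
    "seed")
})

test_that("genotyping error injects only valid allele codes", {
  cfg <- simulation_config(panel,
                           list(list(spec = leaf("Pret"), count = 200)),
                           seed = 8, genotyping_error_rate = 0.5)
  d <- simulate_dataset(cfg)
  cls <- classify_dataset(d)  # validates every code against the panel
  expect_true(any(cls$category != "PURE"))  # errors visibly corrupt calls
})

test_that("the cross notation parser matches hand-built specs", {
  expect_equal(format(parse_cross_spec("Pret")), "Pret")
  expect_equal(format(parse_cross_spec("Pret x Pcor")), "(Pret x Pcor)")
  expect_equal(format(parse_cross_spec("(Pret x Pcor) x Pret")),
               format(BC1))
  expect_equal(format(parse_cross_spec("(Pret x Pcor) x (Pret x Pcor)")),
               "((Pret x Pcor) x (Pret x Pcor))")
  expect_error(parse_cross_spec("A x B x C"), "ambiguous")
  expect_error(parse_cross_spec("(A x B"), "unbalanced")
  expect_error(parse_cross_spec(""), "empty")
  # simulator rejects species outside the panel
  expect_error(simulate_individual(parse_cross_spec("Xyz"), panel),
               "not in panel")
})

test_that("the 84-sample fixture reproduces the published per-source
           composition deterministically", {
  fx <- make_table2_fixture(panel)
  expect_equal(n_samples(fx), 84L)
  expect_identical(fx, make_table2_fixture(panel))  # no RNG anywhere
  cls <- classify_dataset(fx)
  by_src <- split(cls$category, cls$source)
  expect_true(all(by_src$A == "PURE"))
  expect_length(by_src$A, 49L)
  expect_true(all(by_src$C == "POST_F1_HYBRID"))
  expect_length(by_src$C, 6L)
  e <- cls[cls$source == "E", ]
  expect_true(all(e$category == "PURE" & e$genetic_species == "Lmar"))
  expect_equal(sum(by_src$D == "POST_F1_HYBRID"), 13L)
  # morphological labels are concordant exactly for the pure samples
  expect_equal(cls$label_concordant == "yes", cls$category == "PURE")
})

test_that("empirical category frequencies match the exact per-cross law", {
  n <- 4000
  cfg <- simulation_config(panel, list(list(spec = BC1, count = n)),
                           seed = 13)
  cls <- classify_dataset(simulate_dataset(cfg))
  ex <- category_distribution(BC1, panel)
  for (pair in list(c(sum(cls$category == "F1_HYBRID") / n, ex$p_f1),
                    c(sum(cls$category == "POST_F1_HYBRID") / n,
                      ex$p_postf1),
                    c(sum(cls$category == "PURE") / n, sum(ex$p_pure)))) {
    expect_lt(abs(pair[1] - pair[2]),
              3 * sqrt(pair[2] * (1 - pair[2]) / n))
  }
})
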