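#' Classifier policy
#'
#' Tunables for the genotype-pattern classifier. Only loci with non-missing
#' calls enter the rule; `min_typed_nuclear_loci` sets how many typed
#' nuclear loci are required before a category is assigned at all —
#' individuals with fewer are `UNRESOLVED` rather than guessed.
#'
#' @param min_typed_nuclear_loci Minimum number of typed nuclear loci
#'   (default 1).
#' @return A list of class `classifier_policy`.
#' @export
classifier_policy <- function(min_typed_nuclear_loci = 1L) {
  stopifnot(length(min_typed_nuclear_loci) == 1L,
            min_typed_nuclear_loci >= 1L)
  structure(list(min_typed_nuclear_loci = as.integer(min_typed_nuclear_loci)),
            class = "classifier_policy")
}

CATEGORIES <- c("PURE", "F1_HYBRID", "POST_F1_HYBRID", "UNRESOLVED")

# Vectorised classification over a sample table in dataset column layout.
# Returns one data.frame row per sample; the genotype-pattern rule over
# typed nuclear loci:
#   * all homozygous for one species s        -> PURE(s)
#   * all heterozygous, same species pair     -> F1_HYBRID(pair)
#   * any mix of homozygous and heterozygous  -> POST_F1_HYBRID
#   * all homozygous but discordant species   -> POST_F1_HYBRID
#                                                (flag all_hom_discordant)
#   * all heterozygous, mixed species pairs   -> POST_F1_HYBRID
#                                                (flag multispecies_ancestry)
#   * fewer typed loci than the policy floor  -> UNRESOLVED
# The mitochondrial call never influences the category; it only sets the
# maternal species and the cytonuclear_discordance advisory flag.
classify_core <- function(samples, panel, policy) {
  nuc <- nuclear_loci(panel)
  L <- length(nuc)
  n <- nrow(samples)
  sp_ids <- panel_species_ids(panel)

  s1 <- matrix(NA_character_, n, L)
  s2 <- matrix(NA_character_, n, L)
  for (j in seq_len(L)) {
    map <- allele_species_map(nuc[[j]])
    s1[, j] <- unname(map[as.character(samples[[paste0(names(nuc)[j], "_a1")]])])
    s2[, j] <- unname(map[as.character(samples[[paste0(names(nuc)[j], "_a2")]])])
  }
  typed <- !is.na(s1) & !is.na(s2)
  hom <- typed & (s1 == s2)
  hom[is.na(hom)] <- FALSE
  het <- typed & !hom
  n_typed <- rowSums(typed)
  n_hom <- rowSums(hom)
  n_het <- rowSums(het)

  hom_sp_count <- integer(n)
  hom_single <- rep(NA_character_, n)
  for (s in sp_ids) {
    ind <- hom & !is.na(s1) & (s1 == s)
    ind[is.na(ind)] <- FALSE
    any_s <- rowSums(ind) > 0L
    hom_sp_count <- hom_sp_count + as.integer(any_s)
    hom_single[any_s] <- ifelse(is.na(hom_single[any_s]), s, "*")
  }
  hom_single[hom_sp_count != 1L] <- NA_character_

  pairlab <- matrix(NA_character_, n, L)
  pairlab[het] <- paste(pmin(s1[het], s2[het]), pmax(s1[het], s2[het]),
                        sep = "/")
  pair_count <- integer(n)
  pair_single <- rep(NA_character_, n)
  if (length(sp_ids) >= 2L) {
    combs <- utils::combn(sort(sp_ids), 2L)
    for (k in seq_len(ncol(combs))) {
      plab <- paste(combs[1L, k], combs[2L, k], sep = "/")
      ind <- !is.na(pairlab) & (pairlab == plab)
      any_p <- rowSums(ind) > 0L
      pair_count <- pair_count + as.integer(any_p)
      pair_single[any_p] <- ifelse(is.na(pair_single[any_p]), plab, "*")
    }
  }
  pair_single[pair_count != 1L] <- NA_character_

  unres <- n_typed < policy$min_typed_nuclear_loci
  pure <- !unres & n_het == 0L & hom_sp_count == 1L
  all_hom_disc <- !unres & n_het == 0L & hom_sp_count > 1L
  f1 <- !unres & n_hom == 0L & n_het > 0L & pair_count == 1L
  all_het_multi <- !unres & n_hom == 0L & n_het > 0L & pair_count > 1L

  category <- rep("POST_F1_HYBRID", n)
  category[unres] <- "UNRESOLVED"
  category[pure] <- "PURE"
  category[f1] <- "F1_HYBRID"

  genetic_species <- ifelse(pure, hom_single, NA_character_)
  species_pair <- ifelse(f1, pair_single, NA_character_)

  m <- mito_locus(panel)
  maternal <- rep(NA_character_, n)
  if (!is.null(m)) {
    map <- allele_species_map(m)
    maternal <- unname(map[as.character(samples[[m$name]])])
  }

  morph <- samples$morph_species
  label_concordant <- rep("unknown", n)
  chk <- pure & !is.na(morph)
  label_concordant[chk] <- ifelse(morph[chk] == genetic_species[chk],
                                  "yes", "no")

  cyto <- (pure & !is.na(maternal) & maternal != genetic_species) |
    (f1 & !is.na(maternal) &
       maternal != sub("/.*", "", species_pair) &
       maternal != sub(".*/", "", species_pair))
  cyto[is.na(cyto)] <- FALSE

  flags <- character(n)
  add_flag <- function(flags, which, flag) {
    ifelse(which, ifelse(nzchar(flags), paste(flags, flag, sep = ";"), flag),
           flags)
  }
  flags <- add_flag(flags, all_hom_disc, "all_hom_discordant")
  flags <- add_flag(flags, all_het_multi, "multispecies_ancestry")
  flags <- add_flag(flags, cyto, "cytonuclear_discordance")

  data.frame(
    sample_id = samples$sample_id,
    source = samples$source,
    morph_species = morph,
    category = category,
    genetic_species = genetic_species,
    species_pair = species_pair,
    maternal_species = maternal,
    label_concordant = label_concordant,
    flags = flags,
    stringsAsFactors = FALSE
  )
}

#' Classify one individual
#'
#' Applies the genotype-pattern rule to a single sample: using only typed
#' (non-missing) nuclear loci, an individual homozygous for the same species
#' at every locus is a pure representative of that species; heterozygous at
#' every locus for the same species pair, an F1 hybrid; any combination of
#' homozygous and heterozygous diagnostic genotypes marks a post-F1
#' (advanced-generation) hybrid. Two corner patterns that the three clauses
#' do not literally cover are resolved by their genetics: all-homozygous but
#' for different species at different loci, and all-heterozygous spanning
#' different species pairs, are both impossible without hybrid ancestry at
#' fully diagnostic unlinked loci and are assigned `POST_F1_HYBRID` with
#' advisory flags `all_hom_discordant` / `multispecies_ancestry`. Purity is
#' decided genetically regardless of the morphological label; a mismatching
#' label is reported via `label_concordant = "no"`, not as a hybrid call.
#' The mitochondrial marker never affects the category: it sets
#' `maternal_species`, and a maternal species incompatible with the nuclear
#' call raises the `cytonuclear_discordance` flag.
#'
#' @param sample A one-row data.frame (or named list) in the dataset column
#'   layout of [genotype-tables].
#' @param panel A valid [marker_panel()].
#' @param policy A [classifier_policy()].
#' @return A list of class `hd_classification` with fields `category`,
#'   `genetic_species`, `species_pair` (character vector of 2 or `NULL`),
#'   `maternal_species`, `label_concordant` and `flags`.
#' @export
#' @examples
#' p <- default_catfish_panel()
#' s <- list(sample_id = "x", source = "A", morph_species = "Pret",
#'           RAG2_a1 = "Pcor", RAG2_a2 = "Pret",
#'           EF1a_a1 = "Pcor", EF1a_a2 = "Pret",
#'           glob_a1 = "Pcor", glob_a2 = "Pret", `16S` = "Pret")
#' classify_individual(s, p)$category  # "F1_HYBRID"
classify_individual <- function(sample, panel, policy = classifier_policy()) {
  stop_if_invalid_panel(panel)
  row <- as.data.frame(as.list(sample), check.names = FALSE,
                       stringsAsFactors = FALSE)
  validate_samples(row, panel)
  res <- classify_core(row, panel, policy)
  pair <- if (is.na(res$species_pair)) NULL else {
    strsplit(res$species_pair, "/", fixed = TRUE)[[1L]]
  }
  structure(list(
    category = res$category,
    genetic_species = if (is.na(res$genetic_species)) NULL else
      res$genetic_species,
    species_pair = pair,
    maternal_species = if (is.na(res$maternal_species)) NA_character_ else
      res$maternal_species,
    label_concordant = res$label_concordant,
    flags = if (nzchar(res$flags)) {
      strsplit(res$flags, ";", fixed = TRUE)[[1L]]
    } else {
      character()
    }
  ), class = "hd_classification")
}

#' @export
print.hd_classification <- function(x, ...) {
  cat(x$category)
  if (!is.null(x$genetic_species)) cat(" (", x$genetic_species, ")", sep = "")
  if (!is.null(x$species_pair)) {
    cat(" (", paste(x$species_pair, collapse = " x "), ")", sep = "")
  }
  cat("; maternal:",
      if (is.na(x$maternal_species)) "unknown" else x$maternal_species, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Assign the maternal lineage of one individual
#'
#' The mitochondrial marker is inherited strictly through the maternal line,
#' so its diagnostic allele identifies the dam-side species of the cross.
#'
#' @inheritParams classify_individual
#' @return A species id, or `NA` when the mitochondrial call is missing.
#' @export
assign_maternal_lineage <- function(sample, panel) {
  m <- mito_locus(panel)
  if (is.null(m)) stop("panel has no mitochondrial locus")
  call <- sample[[m$name]]
  if (is.null(call) || is.na(call)) return(NA_character_)
  map <- allele_species_map(m)
  if (!call %in% names(map)) {
    stop("mitochondrial allele code ", shQuote(call),
         " is not diagnostic for any panel species")
  }
  unname(map[call])
}

#' Classify every sample of a dataset
#'
#' Element-wise [classify_individual()] over the dataset, preserving sample
#' order; fully deterministic.
#'
#' @param dataset A `hybrid_dataset` from [read_genotype_table()],
#'   [simulate_dataset()] or [make_table2_fixture()].
#' @param policy A [classifier_policy()].
#' @return A data.frame with one row per sample: `sample_id`, `source`,
#'   `morph_species`, `category`, `genetic_species`, `species_pair`
#'   (as `"A/B"`), `maternal_species`, `label_concordant`, `flags`
#'   (`;`-separated advisories).
#' @export
classify_dataset <- function(dataset, policy = classifier_policy()) {
  stop_if_invalid_panel(dataset$panel)
  validate_samples(dataset$samples, dataset$panel)
  if (n_samples(dataset) == 0L) {
    return(data.frame(
      sample_id = character(), source = character(),
      morph_species = character(), category = character(),
      genetic_species = character(), species_pair = character(),
      maternal_species = character(), label_concordant = character(),
      flags = character(), stringsAsFactors = FALSE))
  }
  classify_core(dataset$samples, dataset$panel, policy)
}
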