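#' @title Mendelian cross simulation
#' @description
#' Genotypes are simulated forward through an explicit pedigree under
#' standard Mendelian transmission: founders (leaves) are homozygous for
#' their species' diagnostic allele at every nuclear locus and carry that
#' species' mitochondrial allele; at each cross, each offspring receives one
#' uniformly chosen allele per nuclear locus from each parent, loci
#' assorting independently (the panel's markers sit on distinct genes and
#' are treated as unlinked and mutation-free), and the mitochondrial allele
#' comes from the dam lineage only. Every cross node draws fresh,
#' independent parents per offspring — shared broodstock is deliberately not
#' modelled.
#' @name cross-simulation
NULL

# Vectorised recursive cohort simulation: n independent individuals of the
# same pedigree. Uses the global RNG stream.
sim_cohort <- function(spec, n, panel) {
  nuc <- nuclear_loci(panel)
  L <- length(nuc)
  if (spec$type == "leaf") {
    al <- vapply(nuc, function(l) unname(l$alleles[spec$species]),
                 character(1))
    if (anyNA(al)) stop("leaf species not in panel: ", spec$species)
    a <- matrix(rep(al, each = n), n, L, dimnames = list(NULL, names(nuc)))
    m <- mito_locus(panel)
    mito <- if (is.null(m)) rep(NA_character_, n) else {
      rep(unname(m$alleles[spec$species]), n)
    }
    return(list(a1 = a, a2 = a, mito = mito))
  }
  dam <- sim_cohort(spec$dam, n, panel)
  sire <- sim_cohort(spec$sire, n, panel)
  pick_d <- matrix(stats::runif(n * L) < 0.5, n, L)
  pick_s <- matrix(stats::runif(n * L) < 0.5, n, L)
  a1 <- ifelse(pick_d, dam$a1, dam$a2)
  a2 <- ifelse(pick_s, sire$a1, sire$a2)
  dimnames(a1) <- dimnames(a2) <- list(NULL, names(nuc))
  list(a1 = a1, a2 = a2, mito = dam$mito)
}

#' Simulate one gamete from a parental genotype
#'
#' At each nuclear locus independently, one of the parent's two alleles is
#' chosen with probability 1/2; loci assort independently. Uses the global
#' RNG stream (seed with [set.seed()]).
#'
#' @param parent_genotype Named list mapping nuclear locus name to a
#'   character vector of the parent's two allele codes.
#' @param panel A [marker_panel()].
#' @return Named character vector: one allele code per nuclear locus.
#' @export
simulate_gamete <- function(parent_genotype, panel) {
  nuc <- nuclear_loci(panel)
  vapply(names(nuc), function(ln) {
    g <- parent_genotype[[ln]]
    if (is.null(g) || length(g) != 2L || anyNA(g)) {
      stop("parent genotype missing or incomplete at locus ", ln)
    }
    g[[sample.int(2L, 1L)]]
  }, character(1))
}

#' Simulate one individual of a pedigree
#'
#' @param spec A `cross_spec` (see [leaf()] / [cross()]).
#' @param panel A valid [marker_panel()].
#' @param sample_id,source,morph_species Metadata stamped on the record.
#' @return A one-row data.frame in the dataset column layout of
#'   [genotype-tables].
#' @export
#' @examples
#' set.seed(1)
#' p <- default_catfish_panel()
#' f1 <- simulate_individual(cross(leaf("Pret"), leaf("Pcor")), p)
#' f1$RAG2_a1 != f1$RAG2_a2  # always heterozygous
simulate_individual <- function(spec, panel, sample_id = spec$label,
                                source = "sim",
                                morph_species = NA_character_) {
  stop_if_invalid_panel(panel)
  check_cross_spec(spec, panel)
  coh <- sim_cohort(spec, 1L, panel)
  cohort_to_samples(coh, panel, sample_id, source, morph_species)
}

# assemble sim_cohort output into the dataset column layout
cohort_to_samples <- function(coh, panel, sample_ids, source, morph) {
  n <- length(sample_ids)
  out <- data.frame(sample_id = sample_ids,
                    source = rep_len(source, n),
                    morph_species = rep_len(morph, n),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (ln in colnames(coh$a1)) {
    out[[paste0(ln, "_a1")]] <- pmin(coh$a1[, ln], coh$a2[, ln])
    out[[paste0(ln, "_a2")]] <- pmax(coh$a1[, ln], coh$a2[, ln])
  }
  m <- mito_locus(panel)
  if (!is.null(m)) out[[m$name]] <- coh$mito
  out
}

#' Simulation configuration
#'
#' @param panel A valid [marker_panel()].
#' @param composition List of components, each a list with `spec` (a
#'   `cross_spec`) and `count` (non-negative integer).
#' @param seed Mandatory integer seed; the dataset is a deterministic
#'   function of the config.
#' @param genotyping_error_rate Per-locus probability that a call is
#'   replaced by a uniformly random valid genotype at that locus (whole-call
#'   corruption, the way a miscalled multiplex lane corrupts a genotype, not
#'   a single-allele flip).
#' @param missing_rate Per-locus probability that a call is dropped
#'   (applied after genotyping error).
#' @param morph_label_policy Named character vector mapping a component
#'   spec's label to the species id stamped as its morphological label;
#'   unlisted components get an unknown (`NA`) label.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(panel, composition, seed,
                              genotyping_error_rate = 0,
                              missing_rate = 0,
                              morph_label_policy = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            length(composition) > 0L)
  for (comp in composition) {
    stopifnot(inherits(comp$spec, "cross_spec"), comp$count >= 0L)
  }
  structure(list(panel = panel, composition = composition,
                 seed = as.integer(seed),
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate,
                 morph_label_policy = morph_label_policy),
            class = "simulation_config")
}

# uniform random valid genotypes at a locus (unordered pairs incl. homs)
all_locus_genotypes <- function(loc) {
  codes <- sort(unname(loc$alleles))
  homs <- cbind(codes, codes)
  hets <- if (length(codes) >= 2L) t(utils::combn(codes, 2L)) else NULL
  unname(rbind(homs, hets))
}

#' Simulate a genotype dataset from a pedigree composition
#'
#' Concatenates independently simulated individuals per composition
#' component (in order), then applies genotyping error and missingness
#' independently per locus. Deterministic given the config's seed; sample
#' ids encode the component label and replicate index.
#'
#' @param config A [simulation_config()].
#' @return A `hybrid_dataset`.
#' @export
#' @examples
#' p <- default_catfish_panel()
#' cfg <- simulation_config(p, list(list(spec = leaf("Pret"), count = 5)),
#'                          seed = 42)
#' n_samples(simulate_dataset(cfg))  # 5
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- config$panel
  stop_if_invalid_panel(panel)
  set.seed(config$seed)
  parts <- vector("list", length(config$composition))
  for (i in seq_along(config$composition)) {
    comp <- config$composition[[i]]
    check_cross_spec(comp$spec, panel)
    n <- as.integer(comp$count)
    if (n == 0L) next
    lab <- comp$spec$label
    safe <- gsub("[^A-Za-z0-9]+", "", lab)
    if (!nzchar(safe)) safe <- "cross"
    ids <- sprintf("c%d_%s_%d", i, safe, seq_len(n))
    morph <- NA_character_
    if (!is.null(config$morph_label_policy) &&
        lab %in% names(config$morph_label_policy)) {
      morph <- unname(config$morph_label_policy[[lab]])
    }
    coh <- sim_cohort(comp$spec, n, panel)
    parts[[i]] <- cohort_to_samples(coh, panel, ids, lab, morph)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) stop("empty composition: no samples to simulate")
  samples <- do.call(rbind, parts)
  rownames(samples) <- NULL
  n <- nrow(samples)

  e <- config$genotyping_error_rate
  mr <- config$missing_rate
  for (loc in panel$loci) {
    is_nuc <- loc$kind == "nuclear"
    cn <- if (is_nuc) paste0(loc$name, c("_a1", "_a2")) else loc$name
    if (e > 0) {
      err <- which(stats::runif(n) < e)
      if (length(err) > 0L) {
        if (is_nuc) {
          g <- all_locus_genotypes(loc)
          pick <- sample.int(nrow(g), length(err), replace = TRUE)
          samples[err, cn[1L]] <- g[pick, 1L]
          samples[err, cn[2L]] <- g[pick, 2L]
        } else {
          codes <- sort(unname(loc$alleles))
          samples[err, cn] <- codes[sample.int(length(codes), length(err),
                                               replace = TRUE)]
        }
      }
    }
    if (mr > 0) {
      miss <- stats::runif(n) < mr
      samples[miss, cn] <- NA_character_
    }
  }
  new_dataset(panel, samples)
}

#' Deterministic 84-sample stock-screening fixture
#'
#' Reconstructs the multi-institution screening dataset from its published
#' per-source category counts: 49 pure *P. reticulatum* (source A); 3 pure
#' *P. reticulatum*, 1 F1 and 1 post-F1 (source B); 6 post-F1 (source C);
#' 1 pure *P. corruscans*, 1 F1 and 13 post-F1 (source D); and 9 pure
#' *L. marmoratus* (source E), with morphological labels as recorded at
#' sampling (A, B: cachara; C, D: pintado; E: jundia). Per-sample genotypes
#' were not published, so each category uses a canonical genotype vector:
#' pure individuals are homozygous throughout; F1 individuals heterozygous
#' *P. corruscans* x *P. reticulatum* throughout; post-F1 individuals
#' homozygous for the labelled species at the first nuclear locus and
#' heterozygous at the rest (one arbitrary representative of the many
#' advanced-generation patterns, which the panel cannot tell apart). The
#' mitochondrial allele is the labelled species' throughout. Construction is
#' fully deterministic — no RNG.
#'
#' @param panel A panel containing species `Pcor`, `Pret`, `Lmar`, at least
#'   two nuclear loci and a mitochondrial locus (default
#'   [default_catfish_panel()]).
#' @return A `hybrid_dataset` of 84 samples.
#' @export
make_table2_fixture <- function(panel = default_catfish_panel()) {
  stop_if_invalid_panel(panel)
  ids <- panel_species_ids(panel)
  if (!all(c("Pcor", "Pret", "Lmar") %in% ids)) {
    stop("fixture requires a panel with species Pcor, Pret and Lmar")
  }
  nuc <- names(nuclear_loci(panel))
  if (length(nuc) < 2L) {
    stop("fixture requires at least two nuclear loci")
  }
  m <- mito_locus(panel)
  if (is.null(m)) stop("fixture requires a mitochondrial locus")

  # one row in dataset layout from per-locus genotypes
  row_for <- function(id, src, morph, genotypes, mito_sp) {
    out <- list(sample_id = id, source = src, morph_species = morph)
    for (ln in nuc) {
      g <- sort(genotypes[[ln]])
      out[[paste0(ln, "_a1")]] <- g[1L]
      out[[paste0(ln, "_a2")]] <- g[2L]
    }
    out[[m$name]] <- unname(m$alleles[mito_sp])
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  }
  geno_pure <- function(sp) {
    stats::setNames(lapply(nuc, function(ln) {
      rep(unname(panel$loci[[ln]]$alleles[sp]), 2L)
    }), nuc)
  }
  geno_f1 <- function(sp1, sp2) {
    stats::setNames(lapply(nuc, function(ln) {
      al <- panel$loci[[ln]]$alleles
      c(unname(al[sp1]), unname(al[sp2]))
    }), nuc)
  }
  geno_postf1 <- function(hom_sp, other_sp) {
    g <- geno_f1(hom_sp, other_sp)
    g[[1L]] <- rep(unname(panel$loci[[nuc[1L]]]$alleles[hom_sp]), 2L)
    g
  }

  plan <- list(
    list(src = "A", morph = "Pret",
         counts = c(pure = 49L, f1 = 0L, postf1 = 0L)),
    list(src = "B", morph = "Pret",
         counts = c(pure = 3L, f1 = 1L, postf1 = 1L)),
    list(src = "C", morph = "Pcor",
         counts = c(pure = 0L, f1 = 0L, postf1 = 6L)),
    list(src = "D", morph = "Pcor",
         counts = c(pure = 1L, f1 = 1L, postf1 = 13L)),
    list(src = "E", morph = "Lmar",
         counts = c(pure = 9L, f1 = 0L, postf1 = 0L))
  )
  rows <- list()
  for (inst in plan) {
    sp <- inst$morph
    other <- if (sp == "Pret") "Pcor" else "Pret"
    k <- 0L
    emit <- function(genotypes) {
      k <<- k + 1L
      rows[[length(rows) + 1L]] <<- row_for(
        sprintf("%s%02d", inst$src, k), inst$src, sp, genotypes, sp)
    }
    for (i in seq_len(inst$counts[["pure"]])) emit(geno_pure(sp))
    for (i in seq_len(inst$counts[["f1"]])) emit(geno_f1(sp, other))
    for (i in seq_len(inst$counts[["postf1"]])) emit(geno_postf1(sp, other))
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  new_dataset(panel, samples)
}
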