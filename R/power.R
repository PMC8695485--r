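#' @title Panel power: category probabilities for a given cross
#' @description
#' Under fully diagnostic unlinked loci, every nuclear locus of a given
#' pedigree follows the same genotype law over species-ancestry genotypes,
#' and loci are independent. The probability that an individual of that
#' pedigree is classified pure, F1 or post-F1 by an L-locus panel is then a
#' product over loci: these functions compute it exactly (recursively on the
#' pedigree) and by Monte Carlo (through the simulator), quantifying the
#' misclassification risk a finite panel carries — e.g. a first backcross
#' looks like an F1 whenever every locus happens to be heterozygous.
#' @name panel-power
NULL

genotype_label <- function(x, y) {
  paste(pmin(x, y), pmax(x, y), sep = "/")
}

# marginal allele-output (gamete) law of a pedigree: named prob vector over
# species ids
allele_law <- function(spec) {
  q <- locus_law(spec)
  parts <- strsplit(names(q), "/", fixed = TRUE)
  sp <- unique(unlist(parts))
  a <- stats::setNames(numeric(length(sp)), sp)
  for (i in seq_along(q)) {
    p <- parts[[i]]
    if (p[1L] == p[2L]) {
      a[p[1L]] <- a[p[1L]] + q[[i]]
    } else {
      a[p[1L]] <- a[p[1L]] + q[[i]] / 2
      a[p[2L]] <- a[p[2L]] + q[[i]] / 2
    }
  }
  a
}

# exact single-locus genotype law of a pedigree over species-ancestry
# genotypes "x/y" (unordered)
locus_law <- function(spec) {
  if (spec$type == "leaf") {
    return(stats::setNames(1, genotype_label(spec$species, spec$species)))
  }
  ad <- allele_law(spec$dam)
  as_ <- allele_law(spec$sire)
  q <- list()
  for (x in names(ad)) {
    for (y in names(as_)) {
      lab <- genotype_label(x, y)
      q[[lab]] <- (if (is.null(q[[lab]])) 0 else q[[lab]]) + ad[[x]] * as_[[y]]
    }
  }
  unlist(q)
}

#' Exact per-locus genotype distribution of a cross
#'
#' Computed recursively: a pure founder is homozygous with probability 1; a
#' cross's genotype law is the product of its dam's and sire's gamete laws,
#' where a parent's gamete law puts half of each heterozygous genotype's
#' mass on each allele. The law is identical at every fully diagnostic
#' nuclear locus of the panel.
#'
#' @param spec A `cross_spec`.
#' @param panel A [marker_panel()] (leaf species must belong to it).
#' @return Named numeric vector: probability per unordered species-ancestry
#'   genotype `"x/y"`; sums to 1.
#' @export
#' @examples
#' p <- default_catfish_panel()
#' f1 <- cross(leaf("Pret"), leaf("Pcor"))
#' locus_distribution(cross(f1, leaf("Pret")), p)  # BC1: 1/2 hom, 1/2 het
locus_distribution <- function(spec, panel) {
  check_cross_spec(spec, panel)
  q <- locus_law(spec)
  stopifnot(abs(sum(q) - 1) < 1e-12)
  q[order(names(q))]
}

new_category_distribution <- function(p_pure, p_f1, p_postf1, ci = NULL,
                                      n_reps = NULL) {
  total <- sum(p_pure) + p_f1 + p_postf1
  stopifnot(abs(total - 1) < 1e-9)
  structure(list(p_pure = p_pure, p_f1 = p_f1, p_postf1 = p_postf1,
                 ci = ci, n_reps = n_reps),
            class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, digits = 4, ...) {
  for (s in names(x$p_pure)) {
    cat(sprintf("  P(PURE %s)     = %.*f\n", s, digits, x$p_pure[[s]]))
  }
  cat(sprintf("  P(F1_HYBRID)   = %.*f\n", digits, x$p_f1))
  cat(sprintf("  P(POST_F1)     = %.*f\n", digits, x$p_postf1))
  if (!is.null(x$n_reps)) cat("  (Monte Carlo, n =", x$n_reps, ")\n")
  invisible(x)
}

# category probabilities from per-locus genotype laws (one law per nuclear
# locus; the exchangeable case passes L copies of the same law)
category_from_locus_laws <- function(laws) {
  all_labs <- unique(unlist(lapply(laws, names)))
  parts <- strsplit(all_labs, "/", fixed = TRUE)
  sp <- sort(unique(unlist(parts)))
  is_het <- vapply(parts, function(p) p[1L] != p[2L], logical(1))
  mass <- function(law, lab) if (lab %in% names(law)) law[[lab]] else 0
  p_pure <- stats::setNames(vapply(sp, function(s) {
    prod(vapply(laws, mass, numeric(1), genotype_label(s, s)))
  }, numeric(1)), sp)
  p_f1 <- sum(vapply(all_labs[is_het], function(lab) {
    prod(vapply(laws, mass, numeric(1), lab))
  }, numeric(1)))
  p_postf1 <- 1 - sum(p_pure) - p_f1
  list(p_pure = p_pure, p_f1 = p_f1, p_postf1 = max(p_postf1, 0))
}

#' Exact category distribution of a cross under an L-locus panel
#'
#' Probability that an individual of the given pedigree is classified
#' `PURE` (per species), `F1_HYBRID` or `POST_F1_HYBRID` by the panel's
#' nuclear loci, to machine precision. All-homozygous-but-discordant and
#' mixed-pair all-heterozygous patterns count as post-F1, matching the
#' classifier. With per-locus law `q` and `L` exchangeable loci,
#' `P(F1) = sum over pairs of q(het pair)^L` and
#' `P(PURE s) = q(hom s)^L`; the remaining mass is post-F1.
#'
#' @param spec A `cross_spec`.
#' @param panel A valid [marker_panel()]; its number of nuclear loci sets L.
#' @param policy A [classifier_policy()] (no effect without missing data;
#'   accepted for interface symmetry with the classifier).
#' @return A `category_distribution` with fields `p_pure` (named per
#'   species), `p_f1`, `p_postf1`.
#' @export
#' @examples
#' p <- default_catfish_panel()
#' bc1 <- cross(cross(leaf("Pret"), leaf("Pcor")), leaf("Pret"))
#' category_distribution(bc1, p)  # 1/8 pure, 1/8 F1, 3/4 post-F1
category_distribution <- function(spec, panel,
                                  policy = classifier_policy()) {
  stop_if_invalid_panel(panel)
  L <- length(nuclear_loci(panel))
  q <- locus_distribution(spec, panel)
  res <- category_from_locus_laws(rep(list(as.list(q)), L))
  new_category_distribution(res$p_pure, res$p_f1, res$p_postf1)
}

# Wilson 95% score interval, sane at boundary proportions
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Monte Carlo category distribution of a cross
#'
#' Simulates `n_reps` independent individuals of the pedigree, classifies
#' them, and tabulates category frequencies with 95% Wilson score
#' intervals. Deterministic given `seed`.
#'
#' @inheritParams category_distribution
#' @param n_reps Number of simulated individuals (at least 1).
#' @param seed Integer seed.
#' @return A `category_distribution` whose `ci` field is a data.frame with
#'   columns `outcome`, `estimate`, `lower`, `upper`.
#' @export
mc_category_distribution <- function(spec, panel,
                                     policy = classifier_policy(),
                                     n_reps = 10000L, seed) {
  stopifnot(n_reps >= 1L)
  if (missing(seed)) stop("seed is mandatory")
  stop_if_invalid_panel(panel)
  check_cross_spec(spec, panel)
  set.seed(seed)
  coh <- sim_cohort(spec, n_reps, panel)
  samples <- cohort_to_samples(coh, panel,
                               sprintf("mc_%d", seq_len(n_reps)),
                               spec$label, NA_character_)
  cls <- classify_core(samples, panel, policy)
  sp <- sort(panel_species_ids(panel))
  k_pure <- vapply(sp, function(s) {
    sum(cls$category == "PURE" & cls$genetic_species == s, na.rm = TRUE)
  }, numeric(1))
  k_f1 <- sum(cls$category == "F1_HYBRID")
  k_post <- sum(cls$category == "POST_F1_HYBRID")
  ks <- c(stats::setNames(k_pure, paste0("pure_", sp)),
          f1 = k_f1, postf1 = k_post)
  ci <- do.call(rbind, lapply(names(ks), function(o) {
    w <- wilson_ci(ks[[o]], n_reps)
    data.frame(outcome = o, estimate = ks[[o]] / n_reps,
               lower = w[["lower"]], upper = w[["upper"]])
  }))
  new_category_distribution(stats::setNames(k_pure / n_reps, sp),
                            k_f1 / n_reps, k_post / n_reps,
                            ci = ci, n_reps = n_reps)
}

#' Post-F1 detection power as a function of panel size
#'
#' Evaluates the exact category distribution on hypothetical panels of L
#' identical fully diagnostic nuclear loci. A single locus can never show
#' the combined homozygous-plus-heterozygous pattern, so post-F1 detection
#' is 0 at L = 1 and nondecreasing in L for backcross and F2 pedigrees.
#'
#' @inheritParams category_distribution
#' @param L_values Positive integers: panel sizes to evaluate.
#' @return A data.frame with columns `L`, `p_pure_<species>` per species,
#'   `p_f1`, `p_postf1`.
#' @export
#' @examples
#' p <- default_catfish_panel()
#' bc1 <- cross(cross(leaf("Pret"), leaf("Pcor")), leaf("Pret"))
#' detection_curve(bc1, p, L_values = 1:3)$p_postf1  # 0, 0.5, 0.75
detection_curve <- function(spec, panel, policy = classifier_policy(),
                            L_values = 1:10) {
  stopifnot(all(L_values >= 1L), all(L_values == as.integer(L_values)))
  q <- locus_distribution(spec, panel)
  rows <- lapply(L_values, function(L) {
    res <- category_from_locus_laws(rep(list(as.list(q)), L))
    out <- data.frame(L = as.integer(L))
    for (s in names(res$p_pure)) {
      out[[paste0("p_pure_", s)]] <- res$p_pure[[s]]
    }
    out$p_f1 <- res$p_f1
    out$p_postf1 <- res$p_postf1
    out
  })
  do.call(rbind, rows)
}
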