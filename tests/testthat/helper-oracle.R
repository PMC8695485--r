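# Independent oracles, deliberately written as plain literal loops so they
# share no code path with the package internals they check.

# Literal reading of the three-category genotype-pattern rule, applied to a
# sample row in dataset layout. Typed nuclear loci only; the two patterns
# outside the literal clauses (all-homozygous discordant, all-heterozygous
# with mixed pairs) are post-F1, matching the package's documented
# convention. Returns just the category string.
oracle_classify <- function(row, panel, min_typed = 1) {
  states <- list()
  for (loc in nuclear_loci(panel)) {
    a1 <- row[[paste0(loc$name, "_a1")]]
    a2 <- row[[paste0(loc$name, "_a2")]]
    if (is.null(a1) || is.na(a1) || is.null(a2) || is.na(a2)) next
    sp1 <- names(loc$alleles)[loc$alleles == a1]
    sp2 <- names(loc$alleles)[loc$alleles == a2]
    states[[length(states) + 1L]] <- sort(c(sp1, sp2))
  }
  if (length(states) < min_typed) return("UNRESOLVED")
  is_hom <- sapply(states, function(s) s[1] == s[2])
  if (all(is_hom)) {
    sps <- unique(sapply(states, `[`, 1))
    if (length(sps) == 1) "PURE" else "POST_F1_HYBRID"
  } else if (all(!is_hom)) {
    pairs <- unique(sapply(states, paste, collapse = "+"))
    if (length(pairs) == 1) "F1_HYBRID" else "POST_F1_HYBRID"
  } else {
    "POST_F1_HYBRID"
  }
}

# Enumerate every L-locus genotype vector over the panel's allele codes
# (all unordered pairs per locus) as a data.frame of sample rows.
enumerate_genotype_rows <- function(panel) {
  nuc <- nuclear_loci(panel)
  per_locus <- lapply(nuc, function(loc) {
    codes <- sort(unname(loc$alleles))
    g <- list()
    for (i in seq_along(codes)) {
      for (j in i:length(codes)) {
        g[[length(g) + 1L]] <- c(codes[i], codes[j])
      }
    }
    g
  })
  idx <- expand.grid(lapply(per_locus, seq_along))
  rows <- data.frame(sample_id = sprintf("enum_%d", seq_len(nrow(idx))),
                     source = "enum", morph_species = NA_character_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(nuc)) {
    picks <- per_locus[[k]][idx[[k]]]
    rows[[paste0(names(nuc)[k], "_a1")]] <- sapply(picks, `[`, 1)
    rows[[paste0(names(nuc)[k], "_a2")]] <- sapply(picks, `[`, 2)
  }
  m <- mito_locus(panel)
  if (!is.null(m)) rows[[m$name]] <- NA_character_
  rows
}

# Exact category distribution of a pedigree by brute-force enumeration of
# the full multi-locus genotype space: the joint law of complete genotype
# vectors is propagated through the pedigree by enumerating every gamete
# index combination (2^L per parent), then each vector is classified with
# oracle_classify and masses are summed per category.
oracle_category_distribution <- function(spec, panel) {
  nuc <- names(nuclear_loci(panel))
  L <- length(nuc)
  joint <- function(sp) {
    if (sp$type == "leaf") {
      al <- sapply(nuc, function(ln) {
        unname(panel$loci[[ln]]$alleles[sp$species])
      })
      return(list(list(p = 1, a1 = al, a2 = al)))
    }
    dj <- joint(sp$dam)
    sj <- joint(sp$sire)
    combos <- as.matrix(expand.grid(rep(list(1:2), L)))
    gametes <- function(entry) {
      out <- list()
      for (i in seq_len(nrow(combos))) {
        al <- ifelse(combos[i, ] == 1, entry$a1, entry$a2)
        out[[i]] <- list(p = entry$p * 0.5^L, al = al)
      }
      out
    }
    acc <- list()
    for (d in dj) {
      for (gd in gametes(d)) {
        for (s in sj) {
          for (gs in gametes(s)) {
            a1 <- pmin(gd$al, gs$al)
            a2 <- pmax(gd$al, gs$al)
            key <- paste(a1, a2, sep = "/", collapse = ";")
            w <- gd$p * gs$p
            acc[[key]] <- if (is.null(acc[[key]])) w else acc[[key]] + w
          }
        }
      }
    }
    lapply(names(acc), function(key) {
      pairs <- strsplit(strsplit(key, ";", fixed = TRUE)[[1]], "/",
                        fixed = TRUE)
      list(p = acc[[key]],
           a1 = sapply(pairs, `[`, 1), a2 = sapply(pairs, `[`, 2))
    })
  }
  dist <- joint(spec)
  out <- c(PURE = 0, F1_HYBRID = 0, POST_F1_HYBRID = 0)
  pure_by_species <- list()
  for (entry in dist) {
    row <- list(sample_id = "o", source = "o",
                morph_species = NA_character_)
    for (k in seq_len(L)) {
      row[[paste0(nuc[k], "_a1")]] <- entry$a1[[k]]
      row[[paste0(nuc[k], "_a2")]] <- entry$a2[[k]]
    }
    cat_ <- oracle_classify(row, panel)
    out[[cat_]] <- out[[cat_]] + entry$p
    if (cat_ == "PURE") {
      sp <- names(panel$loci[[nuc[1]]]$alleles)[
        panel$loci[[nuc[1]]]$alleles == entry$a1[[1]]]
      pure_by_species[[sp]] <- if (is.null(pure_by_species[[sp]])) entry$p
        else pure_by_species[[sp]] + entry$p
    }
  }
  list(p_pure = unlist(pure_by_species), p_f1 = out[["F1_HYBRID"]],
       p_postf1 = out[["POST_F1_HYBRID"]], p_pure_total = out[["PURE"]])
}

# random pedigree of bounded depth over given species ids, for properties
random_cross_spec <- function(species_ids, max_depth = 3) {
  if (max_depth == 0 || stats::runif(1) < 0.4) {
    return(leaf(sample(species_ids, 1)))
  }
  cross(random_cross_spec(species_ids, max_depth - 1),
        random_cross_spec(species_ids, max_depth - 1))
}

# dam-lineage founder species of a pedigree (strict maternal line)
dam_line_species <- function(spec) {
  while (spec$type == "cross") spec <- spec$dam
  spec$species
}
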