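# build a one-row sample in dataset layout from per-locus genotypes;
# genotypes: named list nuclear locus -> character(2), mito: allele or NA
make_row <- function(panel, genotypes, mito = NA_character_,
                     id = "s1", source = "test",
                     morph = NA_character_) {
  out <- list(sample_id = id, source = source, morph_species = morph)
  for (loc in nuclear_loci(panel)) {
    g <- genotypes[[loc$name]]
    if (is.null(g)) g <- c(NA_character_, NA_character_)
    out[[paste0(loc$name, "_a1")]] <- g[1]
    out[[paste0(loc$name, "_a2")]] <- g[2]
  }
  m <- mito_locus(panel)
  if (!is.null(m)) out[[m$name]] <- mito
  as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
}

# same-genotype-at-every-locus shorthand
uniform_row <- function(panel, pair, mito = NA_character_, ...) {
  nuc <- names(nuclear_loci(panel))
  make_row(panel, setNames(rep(list(pair), length(nuc)), nuc), mito, ...)
}
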