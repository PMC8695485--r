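#' Define a species for a marker panel
#'
#' A species is identified by a short unique code (its id) used as the
#' default allele code at diagnostic loci, plus a free-text display name.
#'
#' @param id Short unique code, e.g. `"Pcor"`. Must be non-empty and contain
#'   no whitespace.
#' @param display_name Human-readable name; defaults to `id`.
#' @return A list of class `hd_species`.
#' @export
#' @examples
#' species("Pcor", "Pseudoplatystoma corruscans (pintado)")
species <- function(id, display_name = id) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(id = id, display_name = display_name), class = "hd_species")
}

#' Define a diagnostic marker locus
#'
#' A locus is fully diagnostic: each species in the panel carries a distinct
#' fixed allele, so a heterozygote directly reveals mixed ancestry. Nuclear
#' loci are codominant (both alleles of a genotype observable); the
#' mitochondrial locus is haploid and maternally inherited.
#'
#' @param name Short unique locus code, e.g. `"RAG2"`.
#' @param kind `"nuclear"` or `"mitochondrial"`.
#' @param alleles Named character vector mapping species id to the
#'   diagnostic allele code at this locus.
#' @param band_sizes Optional named numeric vector mapping species id to the
#'   expected amplicon length in base pairs. Only required when decoding gel
#'   band observations.
#' @return A list of class `hd_locus`.
#' @export
locus <- function(name, kind = c("nuclear", "mitochondrial"), alleles,
                  band_sizes = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, is.character(alleles),
            !is.null(names(alleles)))
  if (!is.null(band_sizes)) {
    stopifnot(is.numeric(band_sizes), !is.null(names(band_sizes)))
  }
  structure(list(name = name, kind = kind, alleles = alleles,
                 band_sizes = band_sizes),
            class = "hd_locus")
}

#' Assemble a marker panel
#'
#' A panel bundles the species under study with the diagnostic loci typed on
#' them: at least one nuclear locus and at most one mitochondrial locus.
#' Construction performs only structural checks; use [validate_panel()] for
#' the full invariant report. Panels are treated as immutable: classify
#' against a frozen panel and build a new one to change it.
#'
#' @param species List of [species()] objects (at least 2).
#' @param loci List of [locus()] objects.
#' @param name Free-text panel name.
#' @return A list of class `marker_panel`.
#' @seealso [default_catfish_panel()], [validate_panel()]
#' @export
marker_panel <- function(species, loci, name = "panel") {
  stopifnot(is.list(species), is.list(loci))
  stopifnot(all(vapply(species, inherits, logical(1), "hd_species")),
            all(vapply(loci, inherits, logical(1), "hd_locus")))
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  structure(list(name = name, species = species, loci = loci),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel:", x$name, "\n")
  cat("  species:", paste(panel_species_ids(x), collapse = ", "), "\n")
  kinds <- vapply(x$loci, `[[`, character(1), "kind")
  cat("  loci:   ",
      paste(sprintf("%s (%s)", names(x$loci), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Species ids of a panel
#' @param panel A [marker_panel()].
#' @return Character vector of species ids, in panel order.
#' @export
panel_species_ids <- function(panel) {
  vapply(panel$species, `[[`, character(1), "id")
}

#' Nuclear loci of a panel
#' @param panel A [marker_panel()].
#' @return Named list of nuclear `hd_locus` objects, in panel order.
#' @export
nuclear_loci <- function(panel) {
  panel$loci[vapply(panel$loci, function(l) l$kind == "nuclear", logical(1))]
}

#' Mitochondrial locus of a panel
#' @param panel A [marker_panel()].
#' @return The mitochondrial `hd_locus`, or `NULL` if the panel has none.
#' @export
mito_locus <- function(panel) {
  m <- panel$loci[vapply(panel$loci,
                         function(l) l$kind == "mitochondrial", logical(1))]
  if (length(m) == 0L) NULL else m[[1L]]
}

# allele code -> species id map for one locus
allele_species_map <- function(loc) {
  stats::setNames(names(loc$alleles), unname(loc$alleles))
}

#' Validate a marker panel
#'
#' Checks every panel invariant and returns the violations as data rather
#' than raising: species ids unique, non-empty and whitespace-free; at least
#' two species; locus names unique; at least one nuclear locus; at most one
#' mitochondrial locus; every locus carries a diagnostic allele for every
#' species, pairwise distinct within the locus; band sizes (when present)
#' positive and pairwise distinct. The check is idempotent and insensitive
#' to the order in which loci are listed.
#'
#' @param panel A [marker_panel()].
#' @return A data.frame with columns `locus`, `species`, `message`; zero
#'   rows means the panel is valid.
#' @export
#' @examples
#' nrow(validate_panel(default_catfish_panel()))  # 0
validate_panel <- function(panel) {
  v <- list()
  add <- function(locus = NA_character_, species = NA_character_, message) {
    v[[length(v) + 1L]] <<- data.frame(locus = locus, species = species,
                                       message = message)
  }
  ids <- panel_species_ids(panel)
  if (length(ids) < 2L) add(message = "panel must declare at least 2 species")
  bad <- ids[!nzchar(ids) | grepl("\\s", ids)]
  for (s in bad) add(species = s,
                     message = "species id empty or contains whitespace")
  for (s in unique(ids[duplicated(ids)])) {
    add(species = s, message = "duplicate species id")
  }
  lnames <- vapply(panel$loci, `[[`, character(1), "name")
  for (l in unique(lnames[duplicated(lnames)])) {
    add(locus = l, message = "duplicate locus name")
  }
  kinds <- vapply(panel$loci, `[[`, character(1), "kind")
  if (sum(kinds == "nuclear") < 1L) {
    add(message = "panel must have at least one nuclear locus")
  }
  if (sum(kinds == "mitochondrial") > 1L) {
    add(message = "multiple mitochondrial loci")
  }
  for (loc in panel$loci) {
    miss <- setdiff(ids, names(loc$alleles))
    for (s in miss) {
      add(locus = loc$name, species = s,
          message = "no diagnostic allele for species")
    }
    have <- loc$alleles[intersect(names(loc$alleles), ids)]
    if (anyDuplicated(unname(have))) {
      add(locus = loc$name,
          message = "non-diagnostic locus: shared allele code between species")
    }
    if (!is.null(loc$band_sizes)) {
      if (any(loc$band_sizes <= 0)) {
        add(locus = loc$name, message = "non-positive band size")
      }
      if (anyDuplicated(unname(loc$band_sizes))) {
        add(locus = loc$name, message = "duplicate band sizes at locus")
      }
    }
  }
  if (length(v) == 0L) {
    data.frame(locus = character(), species = character(),
               message = character())
  } else {
    do.call(rbind, v)
  }
}

stop_if_invalid_panel <- function(panel) {
  rep <- validate_panel(panel)
  if (nrow(rep) > 0L) {
    stop("invalid marker panel: ", paste(rep$message, collapse = "; "),
         call. = FALSE)
  }
  invisible(panel)
}

#' The default catfish diagnosis panel
#'
#' The three-species panel used for Neotropical catfish stock monitoring:
#' *Pseudoplatystoma corruscans* (pintado, `Pcor`), *P. reticulatum*
#' (cachara, `Pret`) and *Leiarius marmoratus* (jundia, `Lmar`), typed at
#' three diagnostic nuclear genes (RAG2, EF1a, glob) and one mitochondrial
#' marker (16S rRNA) that identifies the maternal species. Allele codes
#' equal species ids; expected band sizes are left unset and must be
#' supplied explicitly for gel decoding. The panel assumes all three loci
#' are diagnostic for every pairwise species contrast.
#'
#' @return A validated [marker_panel()].
#' @export
#' @examples
#' p <- default_catfish_panel()
#' length(nuclear_loci(p))  # 3
default_catfish_panel <- function() {
  sp <- list(
    species("Pcor", "Pseudoplatystoma corruscans (pintado)"),
    species("Pret", "Pseudoplatystoma reticulatum (cachara)"),
    species("Lmar", "Leiarius marmoratus (jundia)")
  )
  ids <- vapply(sp, `[[`, character(1), "id")
  alleles <- stats::setNames(ids, ids)
  loci <- list(
    locus("RAG2", "nuclear", alleles),
    locus("EF1a", "nuclear", alleles),
    locus("glob", "nuclear", alleles),
    locus("16S", "mitochondrial", alleles)
  )
  marker_panel(sp, loci, name = "catfish-3sp")
}
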