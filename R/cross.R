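#' Pedigree cross specifications
#'
#' A `cross_spec` describes an explicit pedigree: either a pure-species leaf
#' or a cross of a dam lineage and a sire lineage, each itself a
#' `cross_spec`. The dam side matters because the mitochondrial marker is
#' transmitted strictly maternally.
#'
#' @param species_id Species id of a pure founder.
#' @param label Free-text label used in simulated sample ids; defaults to a
#'   canonical rendering of the pedigree.
#' @return A list of class `cross_spec`.
#' @export
#' @examples
#' bc1 <- cross(cross(leaf("Pret"), leaf("Pcor")), leaf("Pret"))
#' format(bc1)  # "((Pret x Pcor) x Pret)"
leaf <- function(species_id, label = species_id) {
  stopifnot(is.character(species_id), length(species_id) == 1L)
  structure(list(type = "leaf", species = species_id, label = label),
            class = "cross_spec")
}

#' @param dam `cross_spec` of the maternal lineage (listed first).
#' @param sire `cross_spec` of the paternal lineage.
#' @rdname leaf
#' @export
cross <- function(dam, sire, label = NULL) {
  stopifnot(inherits(dam, "cross_spec"), inherits(sire, "cross_spec"))
  if (is.null(label)) {
    label <- paste0("(", dam$label, " x ", sire$label, ")")
  }
  structure(list(type = "cross", dam = dam, sire = sire, label = label),
            class = "cross_spec")
}

#' @export
format.cross_spec <- function(x, ...) {
  if (x$type == "leaf") x$species else {
    paste0("(", format(x$dam), " x ", format(x$sire), ")")
  }
}

#' @export
print.cross_spec <- function(x, ...) {
  cat("Cross spec:", format(x), "\n")
  invisible(x)
}

# species ids appearing at the leaves of a spec
cross_leaf_species <- function(spec) {
  if (spec$type == "leaf") spec$species else {
    unique(c(cross_leaf_species(spec$dam), cross_leaf_species(spec$sire)))
  }
}

check_cross_spec <- function(spec, panel) {
  bad <- setdiff(cross_leaf_species(spec), panel_species_ids(panel))
  if (length(bad) > 0L) {
    stop("cross spec references species not in panel: ",
         paste(bad, collapse = ", "))
  }
  invisible(spec)
}

#' Parse a cross specification from text
#'
#' Small recursive notation with the dam listed first: `Pret` is a pure
#' leaf, `Pret x Pcor` an F1, `(Pret x Pcor) x Pret` a first backcross to
#' *P. reticulatum*. `x` binds left-to-right only through explicit
#' parentheses; an unparenthesised expression may contain at most one `x`.
#'
#' @param text The specification string.
#' @return A `cross_spec`.
#' @export
#' @examples
#' parse_cross_spec("(Pret x Pcor) x Pret")
parse_cross_spec <- function(text) {
  s <- trimws(text)
  if (!nzchar(s)) stop("empty cross specification")
  # split on the top-level " x " (depth 0)
  depth <- 0L
  chars <- strsplit(s, "")[[1L]]
  split_at <- integer()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses in ", shQuote(text))
    }
    if (depth == 0L && ch == "x" &&
        (i > 1L && chars[i - 1L] == " ") &&
        (i < length(chars) && chars[i + 1L] == " ")) {
      split_at <- c(split_at, i)
    }
    i <- i + 1L
  }
  if (depth != 0L) stop("unbalanced parentheses in ", shQuote(text))
  if (length(split_at) > 1L) {
    stop("ambiguous cross ", shQuote(text),
         ": parenthesise to a single top-level 'x'")
  }
  if (length(split_at) == 1L) {
    dam <- parse_cross_spec(substr(s, 1L, split_at - 1L))
    sire <- parse_cross_spec(substr(s, split_at + 1L, nchar(s)))
    return(cross(dam, sire))
  }
  if (startsWith(s, "(") && endsWith(s, ")")) {
    return(parse_cross_spec(substr(s, 2L, nchar(s) - 1L)))
  }
  if (grepl("[()\\s]", s)) stop("cannot parse cross leaf ", shQuote(s))
  leaf(s)
}
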