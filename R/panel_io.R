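#' Read a marker panel from a YAML config file
#'
#' The config declares `name`, a `species` list (each with `id` and
#' `display_name`) and a `loci` list (each with `name`, `kind`, an `alleles`
#' map from species id to allele code and an optional `band_sizes` map).
#' [write_panel()] emits exactly this dialect, so write-then-read is the
#' identity on panels.
#'
#' @param path Path to the YAML file.
#' @return A [marker_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (field in c("name", "species", "loci")) {
    if (is.null(cfg[[field]])) {
      stop("panel config missing field: ", field)
    }
  }
  sp <- lapply(cfg$species, function(s) {
    if (is.null(s$id)) stop("species entry missing id")
    species(s$id, if (is.null(s$display_name)) s$id else s$display_name)
  })
  loci <- lapply(cfg$loci, function(l) {
    if (is.null(l$name) || is.null(l$kind) || is.null(l$alleles)) {
      stop("locus entry missing name, kind or alleles")
    }
    bands <- if (is.null(l$band_sizes)) NULL else {
      unlist(l$band_sizes)
    }
    locus(l$name, l$kind, unlist(l$alleles), band_sizes = bands)
  })
  marker_panel(sp, loci, name = cfg$name)
}

#' Write a marker panel to a YAML config file
#'
#' @param panel A [marker_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  cfg <- list(
    name = panel$name,
    species = lapply(panel$species, function(s) {
      list(id = s$id, display_name = s$display_name)
    }),
    loci = lapply(unname(panel$loci), function(l) {
      out <- list(name = l$name, kind = l$kind, alleles = as.list(l$alleles))
      if (!is.null(l$band_sizes)) out$band_sizes <- as.list(l$band_sizes)
      out
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
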