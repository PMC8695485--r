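#' @title Genotype tables
#' @description
#' A dataset couples a frozen [marker_panel()] with a table of per-individual
#' genotype calls. On disk the table is UTF-8 CSV with header
#' `sample_id,source,morph_species`, two columns `<locus>_a1,<locus>_a2` per
#' nuclear locus and one column `<locus>` for the mitochondrial locus.
#' Missing calls and unknown morphological labels use the token `?`.
#' In memory missing values are `NA`; nuclear allele order is not meaningful
#' and the writer emits the pair sorted lexicographically so that output is
#' byte-stable.
#' @name genotype-tables
NULL

MISSING_TOKEN <- "?"

dataset_columns <- function(panel) {
  nuc <- names(nuclear_loci(panel))
  cols <- c("sample_id", "source", "morph_species",
            as.vector(rbind(paste0(nuc, "_a1"), paste0(nuc, "_a2"))))
  m <- mito_locus(panel)
  if (!is.null(m)) cols <- c(cols, m$name)
  cols
}

new_dataset <- function(panel, samples) {
  structure(list(panel = panel, samples = samples),
            class = "hybrid_dataset")
}

#' Number of samples in a dataset
#' @param dataset A `hybrid_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$samples)

#' @export
print.hybrid_dataset <- function(x, ...) {
  cat("Genotype dataset:", n_samples(x), "samples over panel",
      shQuote(x$panel$name), "\n")
  invisible(x)
}

# validate a sample table against a panel; stops with a named error
validate_samples <- function(samples, panel) {
  cols <- dataset_columns(panel)
  unknown <- setdiff(names(samples), cols)
  if (length(unknown) > 0L) {
    stop("unknown column(s) in genotype table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(samples))
  if (length(missing_cols) > 0L) {
    stop("genotype table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  ids <- panel_species_ids(panel)
  bad_morph <- setdiff(stats::na.omit(samples$morph_species), ids)
  if (length(bad_morph) > 0L) {
    stop("morph_species not a panel species id: ",
         paste(unique(bad_morph), collapse = ", "), call. = FALSE)
  }
  for (loc in panel$loci) {
    codes <- unname(loc$alleles)
    cn <- if (loc$kind == "nuclear") {
      paste0(loc$name, c("_a1", "_a2"))
    } else {
      loc$name
    }
    for (cc in cn) {
      vals <- samples[[cc]]
      bad <- which(!is.na(vals) & !(vals %in% codes))
      if (length(bad) > 0L) {
        stop(sprintf(
          "sample %s, locus %s: allele code %s not in panel",
          samples$sample_id[bad[1L]], loc$name, shQuote(vals[bad[1L]])),
          call. = FALSE)
      }
    }
    if (loc$kind == "nuclear") {
      a1 <- samples[[cn[1L]]]; a2 <- samples[[cn[2L]]]
      half <- which(is.na(a1) != is.na(a2))
      if (length(half) > 0L) {
        stop(sprintf(
          "sample %s, locus %s: half-missing nuclear call",
          samples$sample_id[half[1L]], loc$name), call. = FALSE)
      }
    }
  }
  invisible(samples)
}

#' Read a genotype table
#'
#' Reads the CSV dialect described in [genotype-tables] and validates every
#' row against the panel: unknown columns, duplicate sample ids and allele
#' codes outside the panel's code set are rejected with named errors. Row
#' order is preserved; `?` cells become missing calls.
#'
#' @param path Path to the CSV file.
#' @param panel The [marker_panel()] the table was typed on.
#' @return A `hybrid_dataset`.
#' @export
read_genotype_table <- function(path, panel) {
  if (!file.exists(path)) stop("genotype table not found: ", path)
  stop_if_invalid_panel(panel)
  samples <- tryCatch(
    utils::read.csv(path, check.names = FALSE, colClasses = "character",
                    na.strings = character()),
    error = function(e) stop("malformed CSV at ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  samples[samples == MISSING_TOKEN] <- NA_character_
  validate_samples(samples, panel)
  samples <- samples[, dataset_columns(panel), drop = FALSE]
  rownames(samples) <- NULL
  new_dataset(panel, samples)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: emits the same CSV dialect with
#' nuclear allele pairs sorted lexicographically and missing values as `?`,
#' so write-then-read is the identity and repeated writes are byte-stable.
#'
#' @param dataset A `hybrid_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(dataset, path) {
  samples <- dataset$samples
  validate_samples(samples, dataset$panel)
  for (loc in nuclear_loci(dataset$panel)) {
    c1 <- paste0(loc$name, "_a1"); c2 <- paste0(loc$name, "_a2")
    lo <- pmin(samples[[c1]], samples[[c2]])
    hi <- pmax(samples[[c1]], samples[[c2]])
    samples[[c1]] <- lo; samples[[c2]] <- hi
  }
  samples[is.na(samples)] <- MISSING_TOKEN
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Decode gel band observations into genotype calls
#'
#' Species-diagnostic multiplex PCR markers are read out as band sizes on an
#' agarose gel; each species produces a distinct amplicon length per locus.
#' Each observed band is matched to the unique expected species band within
#' `tolerance_bp`; at a nuclear locus one matched band means a homozygote
#' and two matched bands a heterozygote, while the mitochondrial locus must
#' show exactly one band. A band matching zero or several expected sizes is
#' an ambiguity error, as are more bands than the locus ploidy allows.
#'
#' @param obs List of observations, each a list with `locus` (name) and
#'   `sizes` (numeric vector of observed band lengths in bp).
#' @param panel A [marker_panel()] whose referenced loci carry `band_sizes`.
#' @param tolerance_bp Non-negative matching tolerance in bp (default 0:
#'   exact match, since defensible slack is gel-dependent).
#' @return Named list mapping locus name to a character vector of allele
#'   codes (length 2 for nuclear, 1 for mitochondrial). Order of observed
#'   sizes does not affect the result.
#' @export
#' @examples
#' p <- default_catfish_panel()
#' p$loci[["RAG2"]]$band_sizes <- c(Pcor = 300, Pret = 450, Lmar = 600)
#' decode_band_pattern(list(list(locus = "RAG2", sizes = c(450, 300))), p,
#'                     tolerance_bp = 10)
decode_band_pattern <- function(obs, panel, tolerance_bp = 0) {
  stopifnot(tolerance_bp >= 0)
  out <- list()
  for (ob in obs) {
    loc <- panel$loci[[ob$locus]]
    if (is.null(loc)) stop("unknown locus: ", ob$locus)
    if (is.null(loc$band_sizes)) {
      stop("locus ", loc$name, " has no expected band sizes in the panel")
    }
    sizes <- ob$sizes
    if (any(sizes <= 0)) stop("non-positive band size at locus ", loc$name)
    max_bands <- if (loc$kind == "nuclear") 2L else 1L
    if (length(sizes) > max_bands) {
      stop(sprintf("%d bands at %s locus %s (at most %d expected)",
                   length(sizes), loc$kind, loc$name, max_bands))
    }
    if (length(sizes) == 0L) {
      stop("no bands observed at locus ", loc$name)
    }
    hit_species <- vapply(sizes, function(s) {
      hits <- names(loc$band_sizes)[abs(loc$band_sizes - s) <= tolerance_bp]
      if (length(hits) != 1L) {
        stop(sprintf(
          "ambiguous band of %g bp at locus %s: matches %d expected band(s) within %g bp",
          s, loc$name, length(hits), tolerance_bp), call. = FALSE)
      }
      hits
    }, character(1))
    if (anyDuplicated(hit_species)) {
      stop("two bands at locus ", loc$name,
           " match the same species band: ", hit_species[1L])
    }
    codes <- sort(unname(loc$alleles[hit_species]))
    if (loc$kind == "nuclear" && length(codes) == 1L) codes <- rep(codes, 2L)
    out[[loc$name]] <- codes
  }
  out
}
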