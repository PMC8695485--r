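#' Half-up rounding of percentages
#'
#' Base `round()` rounds half to even; summary percentages are instead
#' rounded half-up to `digits` decimals so that rendered tables match the
#' common manual convention.
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# percentage formatting: half-up to 2 decimals, integers without decimals
fmt_pct <- function(x) {
  r <- round_half_up(x, 2)
  ifelse(r == floor(r), sprintf("%d", as.integer(r)), sprintf("%.2f", r))
}

#' Summarise classifications into per-group category counts
#'
#' Aggregates a classified table into the per-source summary shape of a
#' stock-screening report: per group, sample count, count per category and
#' percent hybrids (F1 plus post-F1 over group n); globally, the category
#' percentages over total n and the share of post-F1 among hybrids.
#' `UNRESOLVED` samples stay visible as their own column — they count in n
#' but never as hybrids, so unclassifiable individuals can't silently
#' inflate or deflate purity.
#'
#' @param classified Data.frame from [classify_dataset()].
#' @param group_by Name of the grouping column (default `"source"`; any
#'   column of `classified` may be used).
#' @return A list of class `summary_table` with `groups` (data.frame:
#'   `group`, `n`, `pure`, `f1`, `post_f1`, `unresolved`, `pct_hybrids`)
#'   and `overall` (data.frame: `n`, counts, `pct_pure`, `pct_f1`,
#'   `pct_postf1`, `pct_hybrids`, `pct_postf1_among_hybrids`). Percentages
#'   are kept at full precision; rounding happens at render time.
#' @export
#' @examples
#' cls <- classify_dataset(make_table2_fixture())
#' summarize_classifications(cls)$overall$pct_hybrids  # 26.190...
summarize_classifications <- function(classified, group_by = "source") {
  if (!group_by %in% names(classified)) {
    stop("grouping column not present: ", group_by)
  }
  if (nrow(classified) == 0L) {
    groups <- data.frame(group = character(), n = integer(),
                         pure = integer(), f1 = integer(),
                         post_f1 = integer(), unresolved = integer(),
                         pct_hybrids = numeric())
    return(structure(list(groups = groups, overall = NULL),
                     class = "summary_table"))
  }
  tab_group <- function(sub) {
    n <- nrow(sub)
    k <- function(cat) sum(sub$category == cat)
    data.frame(n = n, pure = k("PURE"), f1 = k("F1_HYBRID"),
               post_f1 = k("POST_F1_HYBRID"), unresolved = k("UNRESOLVED"),
               pct_hybrids = 100 * (k("F1_HYBRID") + k("POST_F1_HYBRID")) / n)
  }
  keys <- as.character(classified[[group_by]])
  levs <- unique(keys)  # first-appearance order
  groups <- do.call(rbind, lapply(levs, function(g) {
    cbind(data.frame(group = g), tab_group(classified[keys == g, ]))
  }))
  rownames(groups) <- NULL
  ov <- tab_group(classified)
  n_hyb <- ov$f1 + ov$post_f1
  overall <- data.frame(
    n = ov$n, pure = ov$pure, f1 = ov$f1, post_f1 = ov$post_f1,
    unresolved = ov$unresolved,
    pct_pure = 100 * ov$pure / ov$n,
    pct_f1 = 100 * ov$f1 / ov$n,
    pct_postf1 = 100 * ov$post_f1 / ov$n,
    pct_hybrids = ov$pct_hybrids,
    pct_postf1_among_hybrids = if (n_hyb > 0) 100 * ov$post_f1 / n_hyb else
      NA_real_
  )
  structure(list(groups = groups, overall = overall),
            class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat(render_summary(x, format = "markdown"))
  invisible(x)
}

#' Render a summary table as CSV or markdown text
#'
#' Column order is fixed; percentages are rendered half-up to 2 decimals
#' (integer percentages without decimals), identically in both formats, so
#' output is byte-stable across runs.
#'
#' @param table A `summary_table` from [summarize_classifications()].
#' @param format `"csv"` or `"markdown"`.
#' @return A single string.
#' @export
render_summary <- function(table, format = c("csv", "markdown")) {
  format <- match.arg(format)
  g <- table$groups
  header <- c("group", "n", "pure", "f1", "post_f1", "unresolved",
              "pct_hybrids")
  rows <- lapply(seq_len(nrow(g)), function(i) {
    c(g$group[i], g$n[i], g$pure[i], g$f1[i], g$post_f1[i],
      g$unresolved[i], fmt_pct(g$pct_hybrids[i]))
  })
  ov <- table$overall
  metrics <- NULL
  if (!is.null(ov)) {
    rows[[length(rows) + 1L]] <- c("TOTAL", ov$n, ov$pure, ov$f1,
                                   ov$post_f1, ov$unresolved,
                                   fmt_pct(ov$pct_hybrids))
    metrics <- rbind(
      c("pct_pure", fmt_pct(ov$pct_pure)),
      c("pct_f1", fmt_pct(ov$pct_f1)),
      c("pct_postf1", fmt_pct(ov$pct_postf1)),
      c("pct_hybrids", fmt_pct(ov$pct_hybrids)),
      c("pct_postf1_among_hybrids",
        if (is.na(ov$pct_postf1_among_hybrids)) "NA" else
          fmt_pct(ov$pct_postf1_among_hybrids)))
  }
  if (format == "csv") {
    lines <- c(paste(header, collapse = ","),
               vapply(rows, paste, character(1), collapse = ","))
    if (!is.null(metrics)) {
      lines <- c(lines, "", "metric,value",
                 apply(metrics, 1L, paste, collapse = ","))
    }
  } else {
    md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "),
                                     " |")
    lines <- c(md_row(header),
               md_row(rep("---", length(header))),
               vapply(rows, md_row, character(1)))
    if (!is.null(metrics)) {
      lines <- c(lines, "",
                 apply(metrics, 1L, function(r) {
                   paste0("- ", r[1L], ": ", r[2L])
                 }))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
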