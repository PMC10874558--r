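#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a proportion table
#'
#' One row per called orientation pattern with its report group.
#'
#' @param x A `proportion_table` from [compute_proportions()].
#' @param ... Unused.
#' @return A tibble: `category`, `pattern`, `group`, `n_reads`,
#'   `proportion`.
#' @export
tidy.proportion_table <- function(x, ...) {
  grp <- x$groups
  pat <- x$patterns
  grp_of <- function(category) {
    dplyr::case_when(
      category == "F" ~ "single_F",
      category == "B" ~ "single_B",
      category == "BF" ~ "complete_donor",
      TRUE ~ "compound"
    )
  }
  mutate(pat, group = grp_of(.data$category), .after = "pattern")
}

#' Glance at a proportion table
#'
#' @param x A `proportion_table`.
#' @param ... Unused.
#' @return One-row tibble: denominator, called/background/ambiguous read
#'   counts and the four report-group shares.
#' @export
glance.proportion_table <- function(x, ...) {
  g <- function(name) {
    v <- x$groups$proportion[x$groups$group == name]
    if (length(v) == 0) 0 else v
  }
  cat_n <- function(name) {
    v <- x$categories$n_reads[x$categories$category == name]
    if (length(v) == 0) 0L else v
  }
  tibble(
    denominator = x$denominator,
    n_called = sum(x$patterns$n_reads),
    n_background = cat_n("background"),
    n_ambiguous = cat_n("ambiguous"),
    n_unclassified = cat_n("unclassified"),
    single_F = g("single_F"),
    single_B = g("single_B"),
    complete_donor = g("complete_donor"),
    compound = g("compound")
  )
}

#' Tidy a deletion report
#'
#' @param x A `deletion_report`.
#' @param ... Unused.
#' @return The per-read largest-gap tibble.
#' @export
tidy.deletion_report <- function(x, ...) x$max_gap

#' Glance at a deletion report
#'
#' @param x A `deletion_report`.
#' @param ... Unused.
#' @return One-row tibble with `deletion_index`, `d100`, `n_reads`.
#' @export
glance.deletion_report <- function(x, ...) {
  tibble(deletion_index = x$deletion_index, d100 = x$d100, n_reads = x$n_reads)
}

#' Tidy a pipeline report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return Per-sample, per-pattern tibble.
#' @export
tidy.pipeline_report <- function(x, ...) {
  purrr::map_dfr(x$samples, function(s) {
    mutate(tidy(s$proportions), barcode = s$barcode, .before = 1)
  })
}

#' Glance at a pipeline report
#'
#' @param x A `pipeline_report`.
#' @param ... Unused.
#' @return One row per sample with group shares, HDR fraction and deletion
#'   metrics.
#' @export
glance.pipeline_report <- function(x, ...) {
  purrr::map_dfr(x$samples, function(s) {
    out <- glance(s$proportions)
    rep_s <- attr(s$repair, "summary")
    out$hdr_fraction <- rep_s$hdr_fraction
    out$deletion_index <- if (!is.null(s$deletion)) s$deletion$deletion_index else NA_real_
    out$d100 <- if (!is.null(s$deletion)) s$deletion$d100 else NA_real_
    mutate(out, barcode = s$barcode, .before = 1)
  })
}
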