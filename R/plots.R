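#' @importFrom ggplot2 ggplot aes geom_col geom_histogram geom_line geom_vline
#'   labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot insertion-pattern proportions
#'
#' Bar chart of per-pattern proportions, filled by report group.
#'
#' @param object A `proportion_table` from [compute_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.proportion_table <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(
    x = stats::reorder(.data$pattern, -.data$proportion),
    y = .data$proportion, fill = .data$group
  )) +
    geom_col() +
    labs(
      x = "orientation pattern", y = "proportion of flank-anchored reads",
      fill = "group", title = "Insertion-pattern proportions"
    ) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.proportion_table
#' @param x A `proportion_table`.
#' @export
plot_proportions <- function(x, ...) autoplot(x, ...)

#' Plot a read-length distribution
#'
#' @param lengths Numeric vector of read lengths or a read tibble.
#' @param binwidth Histogram bin width in bp (default 50).
#' @param expected Optional numeric vector of expected category lengths to
#'   mark.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(lengths, binwidth = 50, expected = NULL) {
  if (is.data.frame(lengths)) lengths <- nchar(lengths$seq)
  p <- ggplot(tibble(length = lengths), aes(x = .data$length)) +
    geom_histogram(binwidth = binwidth, fill = "grey35") +
    labs(x = "read length (bp)", y = "reads", title = "Read-length distribution") +
    theme_minimal()
  if (!is.null(expected)) {
    p <- p + geom_vline(xintercept = expected, linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot an amplicon coverage profile
#'
#' Depth across the wild-type amplicon; dips at the cut site reveal
#' deletions.
#'
#' @param object A `coverage_profile` from [coverage_from_alignments()].
#' @param cut_position Optional cut position to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, cut_position = NULL, ...) {
  df <- tibble(position = seq_along(object$depth), depth = object$depth)
  p <- ggplot(df, aes(x = .data$position, y = .data$depth)) +
    geom_line() +
    labs(x = "amplicon position (bp)", y = "depth", title = "Amplicon coverage") +
    theme_minimal()
  if (!is.null(cut_position)) {
    p <- p + geom_vline(xintercept = cut_position, linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname autoplot.coverage_profile
#' @param x A `coverage_profile`.
#' @export
plot_coverage <- function(x, ...) autoplot(x, ...)
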