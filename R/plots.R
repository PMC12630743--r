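#' Plot a PCA projection
#'
#' Scatter of the first two principal components coloured by group (joined
#' from a label table when supplied) with reference and query samples
#' distinguished by shape — the standard look of a species-identification
#' ordination.
#'
#' @param coords Output of [pca_project()].
#' @param labels Optional tibble `sample_id`, `group` for colouring.
#' @return A ggplot object.
#' @export
plot_pca <- function(coords, labels = NULL) {
  df <- coords
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels, by = "sample_id")
  } else {
    df$group <- df$set
  }
  expl <- attr(coords, "explained")
  lab <- function(i) {
    if (is.null(expl) || length(expl) < i) paste0("PC", i)
    else sprintf("PC%d (%.1f%%)", i, 100 * expl[i])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$group,
                                   shape = .data$set)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot the pairwise mismatch distribution
#'
#' Histogram of pairwise mismatch counts for pairs with sufficient overlap,
#' with the identity threshold drawn as a vertical line. Same-individual
#' pairs form the mode near zero; distinct individuals the mass to the
#' right — the gap between them is what the automatic threshold rule finds.
#'
#' @param pairs Output of [pairwise_mismatch_table()].
#' @param threshold Mismatch threshold to annotate.
#' @param min_overlap Only pairs with at least this overlap are shown.
#' @return A ggplot object.
#' @export
plot_mismatch_distribution <- function(pairs, threshold = NULL,
                                       min_overlap = 79) {
  df <- pairs[pairs$n_overlap >= min_overlap, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$n_mismatch)) +
    ggplot2::geom_histogram(binwidth = 1, boundary = -0.5,
                            fill = "grey40") +
    ggplot2::labs(x = "pairwise mismatching loci", y = "sample pairs") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold + 0.5,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot cumulative identity power
#'
#' Cumulative PID and PIDsib products against the number of loci (most
#' informative first), with the panel-sizing threshold marked.
#'
#' @param x A `pid_result` from [pid_summary()].
#' @return A ggplot object.
#' @export
plot_pid_curve <- function(x) {
  df <- dplyr::bind_rows(
    tibble::tibble(n = seq_along(x$cum_pid), value = x$cum_pid,
                   statistic = "PID"),
    tibble::tibble(n = seq_along(x$cum_pidsib), value = x$cum_pidsib,
                   statistic = "PIDsib"))
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$value,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = x$threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of loci (most informative first)",
                  y = "multi-locus probability of identity") +
    ggplot2::theme_minimal()
}

#' @method autoplot pid_result
#' @export
autoplot.pid_result <- function(object, ...) plot_pid_curve(object)

#' @method autoplot individual_clusters
#' @export
autoplot.individual_clusters <- function(object, ...) {
  plot_mismatch_distribution(object$pairs, object$threshold)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
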