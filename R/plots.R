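#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_histogram
#'   geom_vline geom_boxplot facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a representation space
#'
#' Scatter plot of the subjects on the first two coordinates of the space
#' (one measure under two algorithm variants, or the first two combined
#' coordinates), colored by group when known.
#'
#' @param object A `rep_space`.
#' @param dims Which two coordinates to draw (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rep_space <- function(object, dims = 1:2, ...) {
  stopifnot(length(dims) == 2, max(dims) <= ncol(object$X))
  df <- tibble(
    x = object$X[, dims[1L]], y = object$X[, dims[2L]],
    subject = object$subjects
  )
  if (!is.null(object$labels)) df$group <- object$labels
  p <- ggplot(df, if (is.null(object$labels)) aes(x = .data$x, y = .data$y)
              else aes(x = .data$x, y = .data$y, color = .data$group)) +
    geom_point(size = 2.5) +
    labs(x = colnames(object$X)[dims[1L]], y = colnames(object$X)[dims[2L]],
         title = paste("Representation space:",
                       paste(object$measures, collapse = ", "))) +
    theme_minimal()
  p
}

#' Plot the permutation null of a max-t test
#'
#' Histogram of the permutation distribution of max |t| with the observed
#' statistic marked.
#'
#' @param object A `maxt_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.maxt_test <- function(object, ...) {
  df <- tibble(max_t = object$perm_max_t)
  ggplot(df, aes(x = .data$max_t)) +
    geom_histogram(bins = 40, fill = "grey70", color = "grey40") +
    geom_vline(xintercept = object$max_t, color = "red", linetype = 2) +
    labs(x = "permutation max |t|", y = "count",
         title = sprintf("max-t permutation null (p = %.4g, %s)",
                         object$p, object$mode)) +
    theme_minimal()
}

#' Group distributions of the network measures
#'
#' Boxplots of each measure's values by group and algorithm variant, from a
#' long metric table.
#'
#' @param metrics Tibble from [metrics_table()] with a `group` column.
#' @param measures Measures to show (default: canonical six present).
#' @return A ggplot faceted by measure.
#' @export
plot_metric_distributions <- function(metrics, measures = NULL) {
  stopifnot("group" %in% names(metrics))
  if (is.null(measures)) {
    measures <- intersect(MEASURE_ORDER, unique(metrics$measure))
  }
  df <- metrics[metrics$measure %in% measures, ]
  df$measure <- factor(df$measure, levels = measures)
  ggplot(df, aes(x = .data$algorithm, y = .data$value, fill = .data$group)) +
    geom_boxplot(outlier.size = 0.8) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = "value") +
    theme_minimal()
}
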