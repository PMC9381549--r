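#' Ordination scatter plot
#'
#' @param object an `eco_pcoa` or `eco_dbrda` fit.
#' @param metadata optional data frame with `sample_id` plus aesthetics
#'   columns.
#' @param colour,shape metadata column names mapped to aesthetics.
#' @param axes which two axes to draw.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.eco_pcoa <- function(object, metadata = NULL, colour = NULL,
                              shape = NULL, axes = c(1, 2), ...) {
  df <- object$coordinates
  lab <- sprintf("Axis %d (%.1f%%)", axes, 100 * object$proportion[axes])
  plot_ordination_df(df, metadata, colour, shape, axes, lab)
}

#' @rdname autoplot.eco_pcoa
#' @exportS3Method ggplot2::autoplot
autoplot.eco_dbrda <- function(object, metadata = NULL, colour = NULL,
                               shape = NULL, axes = c(1, 2), ...) {
  df <- object$site_scores
  axes <- axes[axes <= ncol(df) - 1]
  if (length(axes) < 2) stop("fit has fewer than two constrained axes")
  lab <- sprintf("%s (%.1f%%)", names(df)[axes + 1],
                 100 * object$eigenvalues$proportion[axes])
  plot_ordination_df(df, metadata, colour, shape, axes, lab)
}

plot_ordination_df <- function(df, metadata, colour, shape, axes, lab) {
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, as_tibble(metadata), by = "sample_id")
  }
  xn <- names(df)[axes[1] + 1]
  yn <- names(df)[axes[2] + 1]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[xn]], y = .data[[yn]],
    colour = if (is.null(colour)) NULL else .data[[colour]],
    shape = if (is.null(shape)) NULL else .data[[shape]]
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = colour, shape = shape) +
    ggplot2::theme_minimal()
}

#' Stacked bars of assembly-process fractions per group
#'
#' @param summary tibble from [summarize_processes()].
#' @return a ggplot.
#' @export
plot_process_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$group, y = .data$fraction,
                                        fill = .data$process)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fraction of sample pairs", fill = "process") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cohesion along an environmental gradient
#'
#' @param cohesion_table tibble from [compute_cohesion()].
#' @param metadata data frame with `sample_id` and the `x` column.
#' @param x metadata column for the horizontal axis (e.g. `"salinity"`).
#' @return a ggplot.
#' @export
plot_cohesion <- function(cohesion_table, metadata, x = "salinity") {
  df <- dplyr::left_join(as_tibble(cohesion_table), as_tibble(metadata),
                         by = "sample_id") |>
    tidyr::pivot_longer(c("pos_cohesion", "abs_neg_cohesion"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[x]], y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::labs(y = "cohesion", colour = NULL) +
    ggplot2::theme_minimal()
}
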