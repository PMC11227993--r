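#' Plot an axial slice of a timescale map
#'
#' @param object An `int_map`.
#' @param slice Axial (z) slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.int_map <- function(object, slice = NULL, ...) {
  d <- dim(object$values)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$int_s <- object$values[cbind(df$i, df$j, slice)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$int_s)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "INT (s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Intrinsic timescale, axial slice z = %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the bootstrap distribution of a mediation indirect effect
#'
#' Histogram of the bootstrap `ab` draws with the point estimate and the
#' percentile confidence limits marked.
#'
#' @param object A `mediation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- tibble::tibble(ab = object$boot_ab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ab)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$ab, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(
      title = sprintf("Indirect effect %s -> %s -> %s", object$x, object$m, object$y),
      subtitle = sprintf("ab = %.3f, 95%% CI [%.3f, %.3f], p = %.3g",
                         object$ab, object$ci_low, object$ci_high, object$p),
      x = "bootstrap ab", y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Group comparison plot for a network or ROI timescale
#'
#' Jittered points with group means for a per-subject summary column.
#'
#' @param data Subject-level tibble with a `group` column.
#' @param column Name of the timescale column to plot.
#' @return A ggplot.
#' @export
plot_group_int <- function(data, column = "dmn_int") {
  stopifnot(column %in% names(data), "group" %in% names(data))
  ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data[[column]],
                                     colour = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "black", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = paste(column, "(s)")) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}
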