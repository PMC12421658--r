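#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a replica summary trace as mean line with SD band
#'
#' @param object A `summary_trace` or a list of them (one per group).
#' @param alpha Band transparency.
#' @param colors Optional colour vector, cycled over groups.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.summary_trace <- function(object, alpha = 0.25, colors = NULL, ...) {
  plot_summary_traces(list(object), alpha = alpha, colors = colors)
}

#' @rdname autoplot.summary_trace
#' @param traces A list of `summary_trace` objects.
#' @export
plot_summary_traces <- function(traces, alpha = 0.25, colors = NULL) {
  if (inherits(traces, "summary_trace")) traces <- list(traces)
  df <- dplyr::bind_rows(lapply(traces, tidy))
  unit <- attr(traces[[1]], "time_unit") %||% "ns"
  prop <- attr(traces[[1]], "property") %||% "value"
  xl <- switch(unit, ns = "Time (ns)", ps = "Time (ps)", "Index")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean,
                                        colour = .data$group,
                                        fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = alpha, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xl, y = prop, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(colors)) {
    colors <- rep_len(colors, length(unique(df$group)))
    p <- p + ggplot2::scale_colour_manual(values = colors) +
      ggplot2::scale_fill_manual(values = colors)
  }
  p
}

#' Plot a 1D kernel density estimate
#'
#' @param object A `density_estimate`.
#' @param fill Fill colour under the curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_estimate <- function(object, fill = "steelblue", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_area(alpha = 0.4, fill = fill) +
    ggplot2::geom_line(colour = fill) +
    ggplot2::labs(x = "Value", y = "Density") +
    ggplot2::theme_minimal()
}

#' Plot a 2D kernel density estimate as a filled heatmap
#'
#' @param object A `density_2d`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_2d <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = "Density") +
    ggplot2::theme_minimal()
}

#' Plot an occupancy map over the box XY plane
#'
#' @param object An `occupancy_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occupancy_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "X (nm)", y = "Y (nm)", fill = "Relative density") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot an inter-residue distance matrix heatmap
#'
#' @param object A `distance_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$res_j, y = .data$res_i,
                               fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "Residue", y = "Residue", fill = "Distance (nm)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a PCA projection coloured by temporal progression
#'
#' @param object A `pca_projection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_projection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                       colour = .data$frame_order)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "Frame") +
    ggplot2::theme_minimal()
}

#' Boxplot of secondary-structure probabilities per class
#'
#' @param prob_tables Named list of [ss_probability()] tibbles (names are
#'   group labels), or one tibble.
#' @return A ggplot.
#' @export
plot_ss_boxplot <- function(prob_tables) {
  if (is.data.frame(prob_tables)) prob_tables <- list(group = prob_tables)
  df <- dplyr::bind_rows(prob_tables, .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$probability,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Occurrence probability (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Secondary-structure fractions over time, one line per class
#'
#' @param frac_table An [ss_fraction()] tibble.
#' @return A ggplot.
#' @export
plot_ss_fractions <- function(frac_table) {
  xvar <- if (all(is.na(frac_table$time))) "frame" else "time"
  ggplot2::ggplot(frac_table,
                  ggplot2::aes(x = .data[[xvar]], y = .data$fraction,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (xvar == "time") "Time" else "Frame",
                  y = "Fraction of residues", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram plot of dihedral angles
#'
#' @param hist_table An [angle_histogram()] tibble.
#' @param fill Bar colour.
#' @return A ggplot.
#' @export
plot_angle_histogram <- function(hist_table, fill = "steelblue") {
  ggplot2::ggplot(hist_table, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = hist_table$bin_hi[1] - hist_table$bin_lo[1],
                      fill = fill, alpha = 0.8) +
    ggplot2::labs(x = "Angle (degrees)", y = "Count") +
    ggplot2::theme_minimal()
}
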