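#' Plot a region report
#'
#' Horizontal bars of microsphere density (or count / proportion) per
#' terminal branch, ordered by value -- the usual way the regional burden of
#' microemboli is displayed.
#'
#' @param object A `region_report` from [compile_report()].
#' @param metric `"density"`, `"count"` or `"proportion"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.region_report <- function(object,
                                   metric = c("density", "count",
                                              "proportion"),
                                   ...) {
  metric <- match.arg(metric)
  col <- switch(metric, density = "density_per_mm3", count = "count",
                proportion = "proportion_pct")
  lab <- switch(metric, density = "microspheres / mm^3",
                count = "microspheres", proportion = "% of detections")
  df <- object$regions
  df$name <- stats::reorder(df$name, df[[col]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]], y = .data$name)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = lab, y = NULL,
                  title = sprintf("Terminal branches (>= %d spheres)",
                                  object$min_count)) +
    ggplot2::theme_minimal()
}

#' Plot a level-wise agreement table
#'
#' @param object An `agreement_table`.
#' @param ... Ignored.
#' @return A ggplot object showing agreement, sum-of-agreement and
#'   disagreement percentages against ontology level.
#' @export
autoplot.agreement_table <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("level", "agreement_pct",
                                  "sum_of_agreement_pct",
                                  "disagreement_pct")],
    -"level", names_to = "measure", values_to = "pct")
  df$measure <- sub("_pct$", "", df$measure)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$pct,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ontology level", y = "% of spheres",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay detections on a section image
#'
#' @param stack A [blockface_stack].
#' @param detections Detection tibble (needs `section_index`, `x_px`,
#'   `y_px`).
#' @param section 0-based section index to show.
#' @return A ggplot object: the section's green channel with detection
#'   centroids circled.
#' @export
plot_section_detections <- function(stack, detections, section) {
  img <- section_channel(stack$sections[[section + 1L]], "green")
  d <- dim(img)
  df <- expand.grid(y = seq_len(d[1]) - 0.5, x = seq_len(d[2]) - 0.5)
  df$intensity <- as.vector(img)
  pts <- detections[detections$section_index == section, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "green",
                                 limits = c(0, 255)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$x_px, y = .data$y_px),
                        shape = 1, colour = "red", size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("section %d", section),
                  x = "x (px)", y = "y (px)", fill = "green") +
    ggplot2::theme_minimal()
}
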