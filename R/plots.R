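#' Plot a grayscale visual-field map
#'
#' Tile plot of per-point thresholds on field-angle axes with the perimetric
#' grayscale convention (14 dB black to 40 dB white).
#'
#' @param object An `exam_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.exam_result <- function(object, ...) {
  df <- object$thresholds |>
    dplyr::mutate(gray = db_to_gray(pmin(pmax(.data$threshold, 14), 40)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$gray)) +
    ggplot2::geom_tile(width = 6, height = 6, colour = "grey70",
                       linewidth = 0.2) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "gray") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "field azimuth (deg)", y = "field elevation (deg)",
                  title = sprintf("Grayscale map (%s)",
                                  object$thresholds$eye[1])) +
    ggplot2::theme_minimal()
}

#' Plot a true sensitivity field
#'
#' @param field Tibble with `x`, `y`, `sens`.
#' @return A ggplot.
#' @export
plot_field <- function(field) {
  ggplot2::ggplot(field, ggplot2::aes(.data$x, .data$y, fill = .data$sens)) +
    ggplot2::geom_tile(width = 6, height = 6) +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "field azimuth (deg)", y = "field elevation (deg)") +
    ggplot2::theme_minimal()
}

#' Plot the point-wise correlation classification grid
#'
#' Mirror of the point-by-point agreement figure: one cell per test location
#' coloured by correlation strength class.
#'
#' @param object A `comparison_report` (or `correlation_report`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) {
  df <- object$points |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("strong", "moderate", "weak")))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_tile(width = 6, height = 6, colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(strong = "#f5d648", moderate = "#66c26b", weak = "#4976d1"),
      na.value = "grey80", name = "correlation") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "field azimuth (deg)", y = "field elevation (deg)",
                  title = "Point-wise device agreement") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.comparison_report
#' @exportS3Method ggplot2::autoplot
autoplot.correlation_report <- autoplot.comparison_report
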