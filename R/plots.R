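#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep result
#'
#' Mean CNR per material against the swept parameter, with one-SD ribbons
#' over noise realizations -- the trend-curve view of the study figures.
#'
#' @param object A `fid_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fid_sweep <- function(object, ...) {
  s <- object$summary
  if (!is.numeric(s$value)) {
    return(
      ggplot2::ggplot(s, ggplot2::aes(x = .data$value, y = .data$mean_cnr,
                                      fill = .data$material)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::labs(x = object$axis, y = "CNR",
                      title = sprintf("%s: CNR by %s", object$modality,
                                      object$axis)) +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$value, y = .data$mean_cnr,
                                  colour = .data$material)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_cnr - .data$sd_cnr,
                                      ymax = .data$mean_cnr + .data$sd_cnr,
                                      fill = .data$material),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$axis, y = "CNR",
                  title = sprintf("%s: CNR vs %s", object$modality,
                                  object$axis)) +
    ggplot2::theme_minimal()
}

#' Plot a ring artifact profile
#'
#' Per-ring SD of pixel values against ring radius.
#'
#' @param object A `ring_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ring_profile <- function(object, ...) {
  ggplot2::ggplot(tidy.ring_profile(object),
                  ggplot2::aes(x = .data$radius_mm, y = .data$sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ring radius (mm)",
                  y = sprintf("SD of ring samples (%s)",
                              attr(object, "units") %||% "intensity")) +
    ggplot2::theme_minimal()
}

#' Display an image
#'
#' Raster display of a `fid_image` in physical coordinates.
#'
#' @param object A `fid_image`.
#' @param limits Optional length-2 intensity window.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fid_image <- function(object, limits = NULL, ...) {
  df <- tidy.fid_image(object)
  if (!is.null(limits)) {
    df$value <- pmin(pmax(df$value, limits[1]), limits[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = object$units) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
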