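# ggplot2 autoplot methods for the result types.

#' Plot a pair correlation curve
#'
#' g(r) against band start radius with the CSR reference line at 1.
#'
#' @param object a `pcf_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pcf_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$r_mid, y = .data$g)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = sprintf("r (%s)", attr(object, "unit")),
                  y = "g(r)",
                  title = "Pair correlation",
                  subtitle = sprintf("n = %d origins, guard %g",
                                     attr(object, "n"),
                                     attr(object, "guard"))) +
    ggplot2::theme_minimal()
}

#' Plot a PC-PALM fit over its curve
#'
#' @param object a `pcpalm_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pcpalm_fit <- function(object, ...) {
  if (is.null(object$fitted)) abort("fit did not produce a curve")
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$r_mid)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$g_fit), colour = "red") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "r", y = "g(r)", title = "PC-PALM fit",
                  subtitle = sprintf("A = %.3g, xi = %.3g, clustering: %s",
                                     object$coef["A"], object$coef["xi"],
                                     object$clustering_detected)) +
    ggplot2::theme_minimal()
}

#' Plot a nearest-neighbour distance distribution
#'
#' Normalized histogram of nearest-neighbour distances.
#'
#' @param object an `nn_dist`.
#' @param binwidth distance bin width.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nn_dist <- function(object, binwidth = 1, ...) {
  h <- nn_histogram(object, binwidth = binwidth)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$distance, y = .data$freq)) +
    ggplot2::geom_col(width = binwidth, fill = "steelblue") +
    ggplot2::labs(x = sprintf("nearest-neighbour distance (%s)",
                              attr(object, "unit")),
                  y = "relative frequency",
                  title = "Nearest-neighbour distances") +
    ggplot2::theme_minimal()
}

#' Plot a pixel image as a raster
#'
#' @param object a [pixel_image()] or `difference_image` (diverging scale,
#'   centred at zero).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pixel_image <- function(object, ...) {
  df <- tidy.pixel_image(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  if (inherits(object, "difference_image")) {
    lim <- max(abs(df$value))
    p <- p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                           high = "red",
                                           limits = c(-lim, lim))
  } else {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Plot a localization table
#'
#' @param object a [loc_table()].
#' @param size point size.
#' @param ... unused.
#' @return A ggplot (y reversed to match image orientation).
#' @export
autoplot.loc_table <- function(object, size = 0.3, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = size, alpha = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("x (%s)", loc_unit(object)),
                  y = sprintf("y (%s)", loc_unit(object))) +
    ggplot2::theme_minimal()
}
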