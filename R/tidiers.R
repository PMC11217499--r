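# broom-style tidiers for fitted objects.

#' Tidy a PC-PALM fit
#'
#' @param x a [pcpalm_fit()] result.
#' @param ... unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error` (plus the fixed `sigma_psf` as a term with no standard
#'   error).
#' @export
tidy.pcpalm_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$coef), "sigma_psf"),
    estimate = c(unname(x$coef), x$sigma_psf),
    std.error = c(unname(x$se), NA_real_)
  )
}

#' Glance at a PC-PALM fit
#'
#' @param x a [pcpalm_fit()] result.
#' @param ... unused.
#' @return One-row tibble: `rss`, `converged`, `clustering_detected`,
#'   `sigma_psf`, `n_bands`.
#' @export
glance.pcpalm_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, converged = x$converged,
    clustering_detected = x$clustering_detected,
    sigma_psf = x$sigma_psf,
    n_bands = if (is.null(x$fitted)) NA_integer_ else nrow(x$fitted)
  )
}

#' Tidy a pixel image into long pixel records
#'
#' @param x a [pixel_image()].
#' @param ... unused.
#' @return Tibble with `row`, `col`, `x`, `y` (pixel-center coordinates in
#'   table units) and `value`.
#' @export
tidy.pixel_image <- function(x, ...) {
  p <- attr(x, "pixel_size")
  tibble::tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    value = as.vector(unclass(x))
  ) |>
    dplyr::mutate(x = (.data$col - 0.5) * p, y = (.data$row - 0.5) * p)
}
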