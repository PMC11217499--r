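# Dimer / detection-efficiency simulation: pairs of molecules on a pixel
# grid, used to show how partial detection inflates nearest-neighbour
# distances (the mean rises while the median stays at the pair scale).

#' Simulate a field of molecular dimers on a pixel grid
#'
#' Places `n_pairs` "black" molecules at distinct random pixels of a
#' `width` x `height` image (each molecule occupies one pixel) and adds for
#' each a "red" partner uniformly at random in one of its eight adjacent
#' pixels. The reference configuration is 4048 pairs in a 600 x 600 image.
#' Red molecules of different pairs may share a pixel; a black molecule on
#' the image border draws its partner among its valid in-image neighbours.
#'
#' @param n_pairs number of dimers (>= 1; must fit in the grid).
#' @param width,height image size in pixels.
#' @param seed RNG seed.
#' @return A `dimer_field`: tibble with one row per pair — black pixel
#'   coordinates `bx`, `by` (1-based), red partner `rx`, `ry`, and
#'   `red_detected` (all `TRUE` initially) — with attributes `width`,
#'   `height`, `detect_fraction` (1) and `seed`.
#' @export
simulate_dimers <- function(n_pairs, width, height, seed) {
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  if (n_pairs > width * height) abort("more pairs than pixels")
  offs <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  df <- with_seed(child_seed(seed, "dimers"), {
    idx <- sample.int(width * height, n_pairs)  # distinct black pixels
    bx <- (idx - 1L) %% width + 1L
    by <- (idx - 1L) %/% width + 1L
    rx <- integer(n_pairs); ry <- integer(n_pairs)
    for (i in seq_len(n_pairs)) {
      nx <- bx[i] + offs[, "dx"]
      ny <- by[i] + offs[, "dy"]
      ok <- which(nx >= 1 & nx <= width & ny >= 1 & ny <= height)
      pick <- ok[sample.int(length(ok), 1L)]
      rx[i] <- nx[pick]; ry[i] <- ny[pick]
    }
    tibble::tibble(bx = bx, by = by, rx = rx, ry = ry,
                   red_detected = TRUE)
  })
  tibble::new_tibble(df, width = width, height = height,
                     detect_fraction = 1, seed = seed,
                     class = "dimer_field")
}

#' Thin the detected red molecules of a dimer field
#'
#' Retains a uniformly random subset of `round(fraction * n_red)` red
#' molecules (black molecules are untouched), modelling the unknown and
#' incomplete detection efficiency of SMLM. The pairing map is updated:
#' pairs whose red partner was removed have `red_detected = FALSE`.
#'
#' @param field a [simulate_dimers()] result (thinning is applied to the
#'   currently detected red set).
#' @param fraction detection fraction d, 0 < d <= 1.
#' @param seed RNG seed.
#' @return The thinned `dimer_field`.
#' @export
thin_detections <- function(field, fraction, seed) {
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  det <- which(field$red_detected)
  keep_n <- round(fraction * length(det))
  keep <- with_seed(child_seed(seed, "thin"),
                    det[sample.int(length(det), keep_n)])
  out <- field
  out$red_detected <- seq_len(nrow(field)) %in% keep
  attr(out, "detect_fraction") <- attr(field, "detect_fraction") * fraction
  out
}

#' Extract black or detected-red molecules of a dimer field as pixel points
#'
#' @param field a `dimer_field`.
#' @param which `"black"` or `"red"` (detected reds only).
#' @return Tibble with integer pixel columns `px`, `py`.
#' @export
dimer_points <- function(field, which = c("black", "red")) {
  which <- match.arg(which)
  if (which == "black") {
    tibble::tibble(px = field$bx, py = field$by)
  } else {
    tibble::tibble(px = field$rx[field$red_detected],
                   py = field$ry[field$red_detected])
  }
}

#' Count black molecules inside a centered square window
#'
#' Edge effects in the dimer nearest-neighbour analysis are avoided by
#' measuring only black molecules in a central window (512 x 512 of the
#' 600 x 600 reference field, around 2900 molecules).
#'
#' @param field a `dimer_field`.
#' @param size window side length in pixels.
#' @return Integer count of black molecules inside the window.
#' @export
count_central_black <- function(field, size = 512) {
  w <- attr(field, "width"); h <- attr(field, "height")
  if (size > w || size > h) abort("window larger than the field")
  x0 <- floor((w - size) / 2)
  y0 <- floor((h - size) / 2)
  sum(field$bx > x0 & field$bx <= x0 + size &
      field$by > y0 & field$by <= y0 + size)
}
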