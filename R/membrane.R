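# Membrane topography model: per-pixel relative membrane amount
# M = L * S, with L an integer count of stacked membrane sheets (folds,
# collapsed filopodia) and S = sqrt(1 + |grad h|^2) the surface-slope factor
# of a height field h (ruffles, bumps). Molecules distributed uniformly *in
# the membrane* are then sampled with per-pixel weight proportional to M,
# which is what makes them look clustered in the 2D projection.

#' Build a per-pixel membrane-area map from topographic features
#'
#' Constructs a `membrane_map` holding, per pixel, the layer count `L`
#' (membrane sheets stacked in the pixel, >= 1), the slope factor
#' `S = sqrt(1 + |grad h|^2)` of a Gaussian height field, the membrane-area
#' factor `M = L * S`, and an optional genuine-cluster enrichment field `E`
#' (>= 1) used to model a protein that really does concentrate somewhere.
#'
#' Feature primitives (each a named list with a `type`):
#' \describe{
#'   \item{`fold`}{`list(type = "fold", x0, x1, y0, y1, layers)` — an
#'     elongated membrane fold (e.g. a collapsed filopodium) covering the
#'     axis-aligned stripe `[x0, x1) x [y0, y1)`; sets the local layer count
#'     to `layers` (stacking with other folds additively).}
#'   \item{`bump`}{`list(type = "bump", cx, cy, height, sd)` — a Gaussian
#'     height bump `h = height * exp(-((x-cx)^2 + (y-cy)^2) / (2 sd^2))`
#'     (membrane ruffling); raises `S` through its analytic gradient. Its
#'     maximum slope is `height * exp(-1/2) / sd`.}
#'   \item{`patch`}{`list(type = "patch", cx, cy, radius, enrichment)` — a
#'     disk where the protein (not the membrane) is genuinely enriched
#'     `enrichment`-fold; affects only `E`.}
#' }
#'
#' @param width,height map size in pixels.
#' @param features list of feature primitives (may be empty: flat membrane,
#'   `M` identically 1).
#' @return A `membrane_map`: list with matrices `L`, `S`, `M`, `E`
#'   (height x width, row = y pixel), logical `footprints` per feature
#'   (ground-truth masks), and the feature list.
#' @export
build_membrane_map <- function(width, height, features = list()) {
  xs <- matrix(rep(seq_len(width) - 0.5, each = height), nrow = height)
  ys <- matrix(rep(seq_len(height) - 0.5, times = width), nrow = height)
  L <- matrix(1, height, width)
  E <- matrix(1, height, width)
  gx <- matrix(0, height, width)  # accumulated analytic height gradient
  gy <- matrix(0, height, width)
  footprints <- vector("list", length(features))
  for (i in seq_along(features)) {
    f <- features[[i]]
    fp <- switch(f$type,
      fold = {
        if (f$x0 < 0 || f$x1 > width || f$y0 < 0 || f$y1 > height) {
          abort("fold feature extends outside the image")
        }
        m <- xs >= f$x0 & xs < f$x1 & ys >= f$y0 & ys < f$y1
        L[m] <- L[m] + (f$layers - 1)
        m
      },
      bump = {
        if (f$cx < 0 || f$cx > width || f$cy < 0 || f$cy > height) {
          abort("bump feature center outside the image")
        }
        h <- f$height * exp(-((xs - f$cx)^2 + (ys - f$cy)^2) / (2 * f$sd^2))
        gx <- gx - (xs - f$cx) / f$sd^2 * h
        gy <- gy - (ys - f$cy) / f$sd^2 * h
        # footprint: where the bump has any appreciable slope (within 3 sd)
        (xs - f$cx)^2 + (ys - f$cy)^2 <= (3 * f$sd)^2
      },
      patch = {
        if (f$cx < 0 || f$cx > width || f$cy < 0 || f$cy > height) {
          abort("patch feature center outside the image")
        }
        m <- (xs - f$cx)^2 + (ys - f$cy)^2 <= f$radius^2
        E[m] <- E[m] * f$enrichment
        m
      },
      abort(sprintf("unknown feature type '%s'", f$type))
    )
    footprints[[i]] <- fp
  }
  S <- sqrt(1 + gx^2 + gy^2)
  structure(list(L = L, S = S, M = L * S, E = E,
                 footprints = footprints, features = features,
                 width = width, height = height),
            class = "membrane_map")
}

#' @export
print.membrane_map <- function(x, ...) {
  cat(sprintf("<membrane_map %d x %d: %d feature(s), M in [%.3g, %.3g]>\n",
              x$width, x$height, length(x$features), min(x$M), max(x$M)))
  invisible(x)
}

#' Sample localizations weighted by local membrane amount
#'
#' Draws `n` localizations with per-pixel probability proportional to the
#' membrane-area factor `M` (marker mode: a probe like DiI that distributes
#' uniformly in the membrane) or to `M * E` (protein mode: additionally
#' enriched in genuine-cluster patches), uniform within the pixel. A flat map
#' (`M` identically 1, marker mode) reduces to complete spatial randomness.
#'
#' @param map a [build_membrane_map()] result.
#' @param n number of localizations.
#' @param mode `"marker"` (weight `M`) or `"protein"` (weight `M * E`).
#' @param seed RNG seed.
#' @param channel channel label.
#' @return A [loc_table()] (unit `"pixel"`).
#' @export
sample_topography <- function(map, n, mode = c("marker", "protein"), seed,
                              channel = mode) {
  mode <- match.arg(mode)
  w <- if (mode == "marker") map$M else map$M * map$E
  if (all(w <= 0)) abort("all sampling weights are zero")
  channel <- channel[1]
  df <- with_seed(child_seed(seed, paste0("topo-", mode)), {
    idx <- sample.int(length(w), n, replace = TRUE, prob = as.vector(w))
    row <- (idx - 1L) %% map$height + 1L
    col <- (idx - 1L) %/% map$height + 1L
    tibble::tibble(
      frame = seq_len(n),
      x = (col - 1L) + runif(n),
      y = (row - 1L) + runif(n),
      channel = channel
    )
  })
  loc_table(df, unit = "pixel", extent = c(0, map$width, 0, map$height),
            source = sprintf("sample_topography(%s, n=%d)", mode, n),
            seed = seed)
}
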