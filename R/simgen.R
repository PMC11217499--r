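# Seeded generators for the simulation families: partition-ratio cluster
# datasets over randomly placed non-touching disks.

# Deterministic child-seed derivation so that every generator stage draws
# from its own stream of the root seed (keeps nested-ratio datasets and
# marker/protein channels independent but reproducible).
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 362437) %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Generate a random layout of non-touching cluster disks
#'
#' Places `n_clusters` disks of radius `radius` uniformly at random in a
#' `width` x `height` pixel image under two restrictions: disks lie fully
#' inside the image, and no two disks overlap or touch (strict center
#' distance > 2*radius). The reference layout is 52 disks of radius 32 in a
#' 2048 x 2048 image, covering ~4% of the area.
#'
#' @param n_clusters number of disks (>= 0).
#' @param radius disk radius in pixels (> 0).
#' @param width,height image size in pixels.
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling budget (default 1e6).
#' @return A `cluster_layout`: tibble of disk centers (`cx`, `cy`) with
#'   attributes `radius`, `width`, `height` and the analytic area fraction
#'   `area_fraction` = n * pi * r^2 / (W * H).
#' @export
generate_cluster_layout <- function(n_clusters, radius, width, height, seed,
                                    max_attempts = 1e6) {
  if (n_clusters < 0) abort("n_clusters must be >= 0")
  if (radius <= 0) abort("radius must be > 0")
  if (n_clusters > 0 && (2 * radius > width || 2 * radius > height)) {
    abort("a disk of this radius cannot fit inside the image")
  }
  cx <- numeric(n_clusters)
  cy <- numeric(n_clusters)
  if (n_clusters > 0) {
    with_seed(seed, {
      placed <- 0L
      attempts <- 0L
      while (placed < n_clusters) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          abort(sprintf(
            "could not place %d non-touching disks of radius %g in %g x %g after %g attempts",
            n_clusters, radius, width, height, max_attempts))
        }
        px <- runif(1, radius, width - radius)
        py <- runif(1, radius, height - radius)
        if (placed == 0L ||
            all((cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2 >
                (2 * radius)^2)) {
          placed <- placed + 1L
          cx[placed] <- px
          cy[placed] <- py
        }
      }
    })
  }
  tibble::new_tibble(tibble::tibble(cx = cx, cy = cy),
                     radius = radius, width = width, height = height,
                     area_fraction = n_clusters * pi * radius^2 / (width * height),
                     seed = seed, class = "cluster_layout")
}

layout_fraction <- function(layout) attr(layout, "area_fraction")

#' Split a fixed localization budget between cluster and background areas
#'
#' For a total of `n_total` localizations, a designated-cluster area fraction
#' `f` and a partition ratio `ratio` (in-cluster density divided by
#' out-of-cluster density, >= 1), the in-cluster count is
#' \deqn{n_{in} = \mathrm{round}\left(\frac{N R f}{R f + 1 - f}\right)}
#' so that the realized density ratio equals `ratio` while the total count
#' stays constant. `ratio = 1` reduces to uniform density (n_in = f * N).
#'
#' @param n_total total localization count N (>= 0).
#' @param f designated cluster-area fraction, 0 < f < 1.
#' @param ratio partition ratio R >= 1.
#' @return Named list `n_in`, `n_out`.
#' @export
partition_counts <- function(n_total, f, ratio) {
  if (n_total < 0) abort("n_total must be >= 0")
  if (f <= 0 || f >= 1) abort("f must lie in (0, 1)")
  if (ratio < 1) abort("partition ratios below 1 are not modelled")
  n_in <- round(n_total * ratio * f / (ratio * f + 1 - f))
  list(n_in = as.integer(n_in), n_out = as.integer(n_total - n_in))
}

# Draw k uniform points in the union of the layout's disks: pick a disk
# uniformly (equal radii => equal areas), then the exact polar transform
# inside it. Each point consumes exactly three uniforms in stream order, so
# a shorter run is always a prefix of a longer run under the same seed.
sample_in_disks <- function(layout, k) {
  if (k == 0) return(list(x = numeric(0), y = numeric(0)))
  r <- attr(layout, "radius")
  n_disk <- nrow(layout)
  u <- matrix(runif(3L * k), nrow = 3L)
  d <- pmin(floor(u[1L, ] * n_disk) + 1L, n_disk)
  rr <- r * sqrt(u[2L, ])
  th <- 2 * pi * u[3L, ]
  list(x = layout$cx[d] + rr * cos(th), y = layout$cy[d] + rr * sin(th))
}

# Uniform points in the rectangle, rejecting draws that land in any disk.
# Candidates are consumed from the RNG stream in fixed-size batches, so the
# sequence of accepted points is independent of how many are requested: the
# first k accepted are a prefix of any longer run (nested-ratio property).
sample_out_disks <- function(layout, k, batch = 10000L) {
  if (k == 0) return(list(x = numeric(0), y = numeric(0)))
  r2 <- attr(layout, "radius")^2
  w <- attr(layout, "width"); h <- attr(layout, "height")
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < k) {
    u <- matrix(runif(2L * batch), nrow = 2L)
    px <- u[1L, ] * w
    py <- u[2L, ] * h
    ok <- rep(TRUE, batch)
    for (j in seq_len(nrow(layout))) {
      ok <- ok & ((px - layout$cx[j])^2 + (py - layout$cy[j])^2 > r2)
    }
    xs <- c(xs, px[ok]); ys <- c(ys, py[ok])
  }
  list(x = xs[seq_len(k)], y = ys[seq_len(k)])
}

#' Sample a partitioned localization dataset over a cluster layout
#'
#' Draws `n_in` localizations uniformly over the union of the layout's disks
#' and `n_out` uniformly over the complement, with counts from
#' [partition_counts()]. Each localization carries its sequence index within
#' its pool (`pool` = "in"/"out", `seq`), mimicking sequential addition of
#' single localizations: for the same seed, the dataset at a lower ratio is a
#' prefix subset of the dataset at a higher ratio (nested datasets share
#' localizations).
#'
#' @param layout a [generate_cluster_layout()] result.
#' @param n_total total localization count.
#' @param ratio partition ratio R >= 1.
#' @param seed root RNG seed; in- and out-pool points are drawn from child
#'   streams derived from it.
#' @param channel channel label stored on the records.
#' @return A [loc_table()] (unit `"pixel"`) with columns `frame`, `x`, `y`,
#'   `pool`, `seq`, `channel`.
#' @export
sample_partitioned <- function(layout, n_total, ratio, seed,
                               channel = "simulated") {
  cnt <- partition_counts(n_total, layout_fraction(layout), ratio)
  pin <- with_seed(child_seed(seed, "partition-in"),
                   sample_in_disks(layout, cnt$n_in))
  pout <- with_seed(child_seed(seed, "partition-out"),
                    sample_out_disks(layout, cnt$n_out))
  df <- tibble::tibble(
    frame = seq_len(n_total),
    x = c(pin$x, pout$x),
    y = c(pin$y, pout$y),
    pool = rep(c("in", "out"), c(cnt$n_in, cnt$n_out)),
    seq = c(seq_len(cnt$n_in), seq_len(cnt$n_out)),
    channel = channel
  )
  loc_table(df, unit = "pixel",
            extent = c(0, attr(layout, "width"), 0, attr(layout, "height")),
            source = sprintf("sample_partitioned(N=%d, R=%g)", n_total, ratio),
            seed = seed)
}

#' Test disk membership of points against a cluster layout
#'
#' @param layout a `cluster_layout`.
#' @param x,y point coordinates.
#' @return Logical vector: `TRUE` where the point lies inside some disk.
#' @export
in_cluster <- function(layout, x, y) {
  r2 <- attr(layout, "radius")^2
  if (nrow(layout) == 0) return(rep(FALSE, length(x)))
  vapply(seq_along(x), function(i) {
    any((layout$cx - x[i])^2 + (layout$cy - y[i])^2 <= r2)
  }, logical(1))
}

#' Rasterize a cluster layout to a logical mask
#'
#' @param layout a `cluster_layout`.
#' @return Logical matrix (height x width); `TRUE` inside disks (tested at
#'   pixel centers).
#' @export
layout_mask <- function(layout) {
  w <- attr(layout, "width"); h <- attr(layout, "height")
  r2 <- attr(layout, "radius")^2
  mask <- matrix(FALSE, nrow = h, ncol = w)
  xs <- seq_len(w) - 0.5
  for (k in seq_len(nrow(layout))) {
    dy2 <- (seq_len(h) - 0.5 - layout$cy[k])^2
    rows <- which(dy2 <= r2)
    for (i in rows) {
      mask[i, (xs - layout$cx[k])^2 <= r2 - dy2[i]] <- TRUE
    }
  }
  mask
}
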