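# Nearest-neighbour analysis: continuous (exact Euclidean) and
# distance-map (Euclidean distance transform of the target raster) variants.

#' Nearest-neighbour distances between localization sets
#'
#' For every origin localization inside the guard area, the shortest 2D
#' Euclidean distance to a target localization (the origin's own record is
#' excluded when origins and targets are the same table). Two methods:
#' \describe{
#'   \item{`continuous`}{exact point-to-point distances.}
#'   \item{`distance_map`}{targets are rasterized to a pixel occupancy
#'     image, the exact Euclidean distance transform is computed, and
#'     distances are read off at the origin pixels — the variant used for
#'     pixel-grid dimer simulations.}
#' }
#'
#' @param origins [loc_table()] of origin points.
#' @param targets [loc_table()] of neighbours; defaults to `origins`.
#' @param guard border strip (table units) excluded for origins; 100 pixels
#'   for simulated data.
#' @param method `"continuous"` or `"distance_map"`.
#' @param pixel_size raster pixel size for the distance-map method.
#' @return An `nn_dist`: tibble with column `distance` (one row per origin
#'   used) and attributes `n`, `method`, `guard`, `unit`.
#' @export
nearest_neighbour <- function(origins, targets = NULL, guard = 0,
                              method = c("continuous", "distance_map"),
                              pixel_size = 1) {
  method <- match.arg(method)
  same_set <- is.null(targets)
  if (same_set) targets <- origins
  if (nrow(targets) == 0) abort("target table is empty")
  keep <- guard_origins(origins, guard)
  if (!any(keep)) abort("no origins survive the guard area")
  if (method == "continuous") {
    origin_idx <- if (same_set) which(keep) - 1L else rep(-1L, sum(keep))
    d <- nn_dist_cpp(origins$x[keep], origins$y[keep],
                     targets$x, targets$y, origin_idx)
  } else {
    ext <- loc_extent(targets)
    occ <- render_histogram(targets, pixel_size = pixel_size, extent = ext)
    dmap <- distance_map(unclass(occ) > 0)
    col <- floor((origins$x[keep] - ext["xmin"]) / pixel_size) + 1L
    row <- floor((origins$y[keep] - ext["ymin"]) / pixel_size) + 1L
    d <- dmap[cbind(row, col)] * pixel_size
  }
  tibble::new_tibble(tibble::tibble(distance = as.numeric(d)),
                     n = sum(keep), method = method, guard = guard,
                     unit = loc_unit(origins), class = "nn_dist")
}

# Exact Euclidean distance transform: per pixel, the distance to the
# nearest TRUE pixel of `mask` (0 on the mask itself).
distance_map <- function(mask) {
  EBImage::distmap(1 - mask, metric = "euclidean")
}

#' Black-to-red nearest-neighbour distances of a dimer field
#'
#' The dimer analysis measures, from a Euclidean distance map of the
#' detected red molecules, the distance from each black molecule in the
#' central `central` x `central` window (edge-effect avoidance) to its
#' nearest red molecule. At full detection every black molecule has its
#' partner in an adjacent pixel, so every distance is 1 or sqrt(2); as reds
#' are thinned the mean distance grows while the median stays at the pair
#' scale as long as at least half the partners are detected.
#'
#' @param field a [simulate_dimers()] (possibly [thin_detections()]-ed)
#'   field.
#' @param central central window side in pixels (default 512).
#' @return An `nn_dist` tibble of distances in pixels.
#' @export
nn_dimers <- function(field, central = 512) {
  w <- attr(field, "width"); h <- attr(field, "height")
  red <- dimer_points(field, "red")
  if (nrow(red) == 0) abort("no detected red molecules")
  mask <- matrix(FALSE, h, w)
  mask[cbind(red$py, red$px)] <- TRUE
  dmap <- distance_map(mask)
  x0 <- floor((w - central) / 2); y0 <- floor((h - central) / 2)
  black <- dimer_points(field, "black")
  keep <- black$px > x0 & black$px <= x0 + central &
          black$py > y0 & black$py <= y0 + central
  d <- dmap[cbind(black$py[keep], black$px[keep])]
  tibble::new_tibble(tibble::tibble(distance = as.numeric(d)),
                     n = sum(keep), method = "distance_map",
                     guard = (w - central) / 2, unit = "pixel",
                     class = "nn_dist")
}

#' Summarize a nearest-neighbour distance distribution
#'
#' Mean, median, quartiles and the 5th/95th percentiles (linear-interpolation
#' quantiles, type 7) of the distances — the summaries drawn as whiskers,
#' bars and circles in detection-sweep plots.
#'
#' @param nn an `nn_dist` (or any data frame with a `distance` column).
#' @return One-row tibble: `n`, `mean`, `median`, `q1`, `q3`, `p5`, `p95`.
#' @export
nn_summary <- function(nn) {
  d <- nn$distance
  if (length(d) < 1) abort("empty distance distribution")
  q <- quantile(d, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  tibble::tibble(n = length(d), mean = mean(d), median = q[3],
                 q1 = q[2], q3 = q[4], p5 = q[1], p95 = q[5])
}

#' Normalized nearest-neighbour histogram
#'
#' Relative frequency of distances per bin (frequencies sum to 1, i.e.
#' normalized to the total number of events).
#'
#' @param nn an `nn_dist`.
#' @param binwidth distance bin width.
#' @return Tibble with `distance` (bin start) and `freq`.
#' @export
nn_histogram <- function(nn, binwidth = 1) {
  d <- nn$distance
  if (length(d) < 1) abort("empty distance distribution")
  bin <- floor(d / binwidth)
  tab <- table(bin)
  tibble::tibble(distance = as.numeric(names(tab)) * binwidth,
                 freq = as.numeric(tab) / length(d))
}
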