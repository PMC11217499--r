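# Image pipeline: localization-histogram rendering, Gaussian smoothing,
# common-mean normalization, membrane-marker subtraction, background
# handling and guarded intensity extraction.

#' Construct a pixel image
#'
#' A `pixel_image` is a numeric matrix (rows = y, cols = x, row 1 at the
#' image top) with a pixel size in table units and a provenance record
#' (source, smoothing sigma, normalization constant) that downstream steps
#' update.
#'
#' @param mat numeric matrix of finite values.
#' @param pixel_size table units per pixel (> 0).
#' @param provenance named list; merged into the default fields.
#' @return A `pixel_image`.
#' @export
pixel_image <- function(mat, pixel_size = 1, provenance = list()) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat))) abort("pixel image values must be finite")
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  prov <- modifyList(list(source = "unknown", sigma = NULL,
                          norm_factor = NULL), provenance)
  structure(mat, pixel_size = pixel_size, provenance = prov,
            class = c("pixel_image", "matrix", "array"))
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image %d x %d, pixel size %g, mean %.4g>\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), mean(x)))
  invisible(x)
}

img_prov <- function(img) attr(img, "provenance")

update_image <- function(img, mat, ...) {
  pixel_image(mat, pixel_size = attr(img, "pixel_size"),
              provenance = modifyList(img_prov(img), list(...)))
}

#' Render a localization table as a count-histogram image
#'
#' Converts localizations into an image by counting, per pixel, the
#' localizations whose coordinates fall in that pixel's half-open square
#' (a coordinate exactly on a pixel boundary belongs to the higher pixel).
#' The grid sum therefore equals the number of in-extent localizations. An
#' extent not divisible into whole pixels is padded by a partial last
#' row/column.
#'
#' @param tbl a [loc_table()].
#' @param pixel_size rendering pixel size in table units.
#' @param extent rendering extent; defaults to the table extent.
#' @return A [pixel_image()] of localization counts.
#' @export
render_histogram <- function(tbl, pixel_size = 1, extent = loc_extent(tbl)) {
  if (pixel_size <= 0) abort("pixel_size must be > 0")
  extent <- as.numeric(extent)
  if (extent[2] <= extent[1] || extent[4] <= extent[3]) {
    abort("empty extent")
  }
  ncols <- ceiling((extent[2] - extent[1]) / pixel_size)
  nrows <- ceiling((extent[4] - extent[3]) / pixel_size)
  keep <- tbl$x >= extent[1] & tbl$x < extent[2] &
          tbl$y >= extent[3] & tbl$y < extent[4]
  col <- floor((tbl$x[keep] - extent[1]) / pixel_size) + 1L
  row <- floor((tbl$y[keep] - extent[3]) / pixel_size) + 1L
  counts <- tabulate((col - 1L) * nrows + row, nbins = nrows * ncols)
  pixel_image(matrix(counts, nrow = nrows, ncol = ncols),
              pixel_size = pixel_size,
              provenance = list(source = attr(tbl, "source")))
}

#' Gaussian-smooth a pixel image
#'
#' Smooths with an isotropic Gaussian of the given sigma (in pixels). To
#' avoid artefacts at edge positions a one-pixel-wide zero frame is added
#' before filtering and removed afterwards; outside that frame the filter
#' boundary replicates, so the frame value effectively zero-pads the edge.
#' All published statistics additionally apply guard areas, so the boundary
#' treatment does not influence results.
#'
#' @param img a [pixel_image()].
#' @param sigma Gaussian sigma in pixels (>= 0; 0 is the identity).
#' @return The smoothed [pixel_image()]; provenance records `sigma`.
#' @export
gaussian_smooth <- function(img, sigma) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (sigma == 0) return(update_image(img, img, sigma = 0))
  framed <- matrix(0, nrow(img) + 2L, ncol(img) + 2L)
  framed[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  sm <- EBImage::gblur(framed, sigma = sigma, boundary = "replicate")
  update_image(img, sm[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)],
               sigma = sigma)
}

#' Normalize an image pair to a common intensity mean
#'
#' Scales each image by the reciprocal of its mean so that both have mean
#' exactly 1. The subtraction of images normalized this way has zero mean by
#' construction, which anchors the intensity-histogram skewness analysis.
#'
#' @param a,b [pixel_image()]s of the same shape with positive mean.
#' @return List of the two normalized images (`a`, `b`); provenance records
#'   each original mean as `norm_factor`.
#' @export
normalize_common_mean <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("images must have the same shape")
  ma <- mean(a); mb <- mean(b)
  if (ma <= 0 || mb <= 0) abort("cannot normalize an image with mean <= 0")
  list(a = update_image(a, a / ma, norm_factor = ma),
       b = update_image(b, b / mb, norm_factor = mb))
}

#' Subtract a membrane-marker image from a protein image
#'
#' Pixelwise `protein - membrane`. When both parents were normalized to a
#' common mean ([normalize_common_mean()]) the difference has zero mean;
#' genuine protein clusters then show up as a positively skewed tail of the
#' difference-intensity distribution, whereas membrane-topography-instigated
#' clusters cancel. A warning is issued if the parents do not appear
#' normalized.
#'
#' @param protein,membrane [pixel_image()]s of the same shape.
#' @return A `difference_image` (a signed [pixel_image()]) recording its
#'   parents' provenance.
#' @export
subtract_images <- function(protein, membrane) {
  if (!all(dim(protein) == dim(membrane))) {
    abort("images must have the same shape")
  }
  if (is.null(img_prov(protein)$norm_factor) ||
      is.null(img_prov(membrane)$norm_factor)) {
    warn("subtracting images that were not normalized to a common mean")
  }
  out <- pixel_image(unclass(protein) - unclass(membrane),
                     pixel_size = attr(protein, "pixel_size"),
                     provenance = list(source = "difference",
                                       parents = list(img_prov(protein),
                                                      img_prov(membrane)),
                                       sigma = img_prov(protein)$sigma))
  class(out) <- c("difference_image", class(out))
  out
}

#' Subtract the off-cell background from a membrane-marker image
#'
#' The background is defined as the area without protein: pixels with zero
#' protein localizations after morphological closing of the protein
#' occupancy image (structuring disk radius = the smoothing sigma, so that
#' sparse empty pixels inside the cell are not classified as background).
#' The mean membrane intensity over the background is subtracted from the
#' whole membrane image, and the few foreground pixels that become negative
#' are excluded from the foreground mask.
#'
#' @param membrane a [pixel_image()] of the membrane marker.
#' @param protein_table the protein channel [loc_table()].
#' @param pixel_size rendering pixel size for the occupancy image.
#' @param closing_radius structuring-element radius in pixels (use the
#'   smoothing sigma).
#' @return List: `image` (background-subtracted membrane) and `mask`
#'   (logical foreground matrix). If there is no background area the image
#'   is returned unchanged with a warning.
#' @export
background_correct <- function(membrane, protein_table, pixel_size = 1,
                               closing_radius = 8) {
  occ <- render_histogram(protein_table, pixel_size = pixel_size,
                          extent = loc_extent(protein_table))
  if (!all(dim(occ) == dim(membrane))) {
    abort("protein occupancy and membrane image shapes differ")
  }
  occ_bin <- (unclass(occ) > 0) * 1
  if (sum(occ_bin) == 0) {
    warn("no protein localizations: empty foreground, no correction applied")
    return(list(image = membrane, mask = matrix(FALSE, nrow(membrane),
                                                ncol(membrane))))
  }
  brush_size <- 2L * as.integer(ceiling(closing_radius)) + 1L
  closed <- EBImage::closing(occ_bin, EBImage::makeBrush(brush_size, "disc"))
  fg <- closed > 0
  if (all(fg)) {
    warn("protein occupies the whole image: no background to subtract")
    return(list(image = membrane, mask = fg))
  }
  bg_mean <- mean(unclass(membrane)[!fg])
  corrected <- unclass(membrane) - bg_mean
  fg[corrected < 0] <- FALSE
  list(image = update_image(membrane, corrected, background = bg_mean),
       mask = fg)
}

#' Extract guarded interior intensity values
#'
#' Returns the pixel values strictly inside a guard frame (a border strip of
#' `guard` pixels excluded to minimize edge effects; 40 pixels for the
#' skewness analysis), optionally intersected with a foreground mask.
#'
#' @param img a [pixel_image()] or `difference_image`.
#' @param guard guard width in pixels (>= 0; `2 * guard` must be smaller
#'   than both image dimensions).
#' @param mask optional logical matrix of pixels to keep.
#' @return Numeric vector of interior intensity values.
#' @export
intensity_values <- function(img, guard = 40, mask = NULL) {
  if (guard < 0) abort("guard must be >= 0")
  if (2 * guard >= min(dim(img))) abort("guard too large for this image")
  rows <- (guard + 1L):(nrow(img) - guard)
  cols <- (guard + 1L):(ncol(img) - guard)
  vals <- unclass(img)[rows, cols]
  if (!is.null(mask)) vals <- vals[mask[rows, cols]]
  as.numeric(vals)
}
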