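# Localization-table data model: tibble of per-molecule records plus
# metadata attributes (unit, extent, source, seed).

#' Construct a localization table
#'
#' A `loc_table` is a tibble with one row per localization (columns `frame`,
#' `x`, `y` and optionally `uncertainty` and `channel`) carrying metadata as
#' attributes: the coordinate `unit` (`"nm"` for cell data, `"pixel"` for
#' simulated data), the rectangular `extent` the coordinates live in, a
#' free-text `source`, and the RNG `seed` for generated tables.
#'
#' Coordinates are continuous with the origin at the image top-left; pixel
#' (row i, col j) covers the half-open square
#' \eqn{[jp, (j+1)p) \times [ip, (i+1)p)} for pixel size p, so extents are
#' half-open: `xmin <= x < xmax`, `ymin <= y < ymax`.
#'
#' @param df data frame with numeric columns `x`, `y`; `frame` (positive
#'   integers, default 1), `uncertainty` (> 0) and `channel` are optional.
#' @param unit `"nm"` or `"pixel"`.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`; defaults to the tight
#'   bounds of the data (with a half-open-safe nudge at the max edge).
#' @param source free-text provenance string.
#' @param seed integer seed used to generate the table, or `NULL`.
#'
#' @return A tibble of class `loc_table`.
#' @export
loc_table <- function(df, unit = c("nm", "pixel"), extent = NULL,
                      source = "unknown", seed = NULL) {
  unit <- match.arg(unit)
  df <- tibble::as_tibble(df)
  if (!all(c("x", "y") %in% names(df))) {
    abort("loc_table requires columns `x` and `y`")
  }
  if (!"frame" %in% names(df)) df$frame <- rep(1L, nrow(df))
  df$frame <- as.integer(df$frame)
  if (is.null(extent)) {
    extent <- if (nrow(df) == 0) c(0, 1, 0, 1) else {
      eps <- 1e-9
      c(min(df$x), max(df$x) + eps, min(df$y), max(df$y) + eps)
    }
  }
  extent <- as.numeric(extent)
  names(extent) <- c("xmin", "xmax", "ymin", "ymax")
  out <- tibble::new_tibble(df, unit = unit, extent = extent,
                            source = source, seed = seed,
                            class = "loc_table")
  validate_loc_table(out)
}

validate_loc_table <- function(tbl) {
  ext <- attr(tbl, "extent")
  if (nrow(tbl) > 0) {
    if (any(tbl$frame < 1L)) abort("frames must be strictly positive")
    inx <- tbl$x >= ext["xmin"] & tbl$x < ext["xmax"]
    iny <- tbl$y >= ext["ymin"] & tbl$y < ext["ymax"]
    if (!all(inx & iny)) {
      abort(sprintf("%d localization(s) fall outside the stated extent",
                    sum(!(inx & iny))))
    }
    if ("uncertainty" %in% names(tbl)) {
      u <- tbl$uncertainty
      if (any(!is.na(u) & u <= 0)) abort("uncertainty must be > 0")
    }
  }
  tbl
}

loc_unit <- function(tbl) attr(tbl, "unit")
loc_extent <- function(tbl) attr(tbl, "extent")

#' @export
print.loc_table <- function(x, ...) {
  ext <- loc_extent(x)
  cat(sprintf("<loc_table: %d localizations, unit %s, extent [%g,%g) x [%g,%g)>\n",
              nrow(x), loc_unit(x), ext[1], ext[2], ext[3], ext[4]))
  NextMethod()
}

# ---- CSV dialects ------------------------------------------------------

# Registry mapping header names of localization-software exports onto the
# canonical columns. The default dialect is this package's own convention.
.dialects <- list(
  default = list(frame = "frame", x = "x_nm", y = "y_nm",
                 uncertainty = "uncertainty_nm", channel = "channel",
                 unit = "nm"),
  pixel   = list(frame = "frame", x = "x_px", y = "y_px",
                 uncertainty = "uncertainty_px", channel = "channel",
                 unit = "pixel")
)

#' List registered localization CSV dialects
#' @return Named list of dialect definitions (column mappings + unit tag).
#' @export
loc_dialects <- function() .dialects

#' Read a localization table from CSV
#'
#' Parses a localization CSV under a named dialect (see [loc_dialects()]).
#' Mandatory columns are `frame`, `x` and `y` under the dialect's header
#' names; `uncertainty` and `channel` are optional, and unknown extra columns
#' are preserved as-is. Rows with non-numeric coordinates are rejected with
#' an error naming the offending data line.
#'
#' @param path CSV file path.
#' @param dialect dialect name, default `"default"` (headers
#'   `frame,x_nm,y_nm,uncertainty_nm,channel`, unit nm).
#' @param extent optional extent override (`c(xmin, xmax, ymin, ymax)`).
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, dialect = "default", extent = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  dia <- .dialects[[dialect]]
  if (is.null(dia)) abort(sprintf("unknown dialect '%s'", dialect))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  for (col in c("frame", "x", "y")) {
    if (!dia[[col]] %in% names(raw)) {
      abort(sprintf("format error: mandatory column '%s' missing from %s",
                    dia[[col]], path))
    }
  }
  parse_num <- function(header, what) {
    v <- suppressWarnings(as.numeric(raw[[header]]))
    bad <- which(is.na(v) & !is.na(raw[[header]]))
    if (length(bad) > 0) {
      abort(sprintf("parse error: non-numeric %s '%s' at data line %d",
                    what, raw[[header]][bad[1]], bad[1]))
    }
    v
  }
  df <- tibble::tibble(
    frame = parse_num(dia$frame, "frame"),
    x = parse_num(dia$x, "x coordinate"),
    y = parse_num(dia$y, "y coordinate")
  )
  if (dia$uncertainty %in% names(raw)) {
    df$uncertainty <- parse_num(dia$uncertainty, "uncertainty")
  }
  if (dia$channel %in% names(raw)) df$channel <- raw[[dia$channel]]
  known <- unlist(dia[c("frame", "x", "y", "uncertainty", "channel")])
  extra <- setdiff(names(raw), known)
  for (nm in extra) df[[nm]] <- raw[[nm]]
  loc_table(df, unit = dia$unit, extent = extent, source = path)
}

#' Write a localization table to CSV
#'
#' Serializes under the dialect matching the table's unit; coordinates are
#' written at full double precision so that a write/read round-trip is
#' bit-identical. If the table came from [split_snapshots()], the snapshot
#' index is appended as a column.
#'
#' @param tbl a [loc_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(tbl, path) {
  dia <- if (loc_unit(tbl) == "nm") .dialects$default else .dialects$pixel
  out <- tibble::as_tibble(tbl)
  nm_map <- c(frame = dia$frame, x = dia$x, y = dia$y,
              uncertainty = dia$uncertainty, channel = dia$channel)
  keep <- intersect(names(nm_map), names(out))
  names(out)[match(keep, names(out))] <- nm_map[keep]
  if (!is.null(attr(tbl, "snapshot"))) {
    out$snapshot <- attr(tbl, "snapshot")$index
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# ---- snapshot splitting and ROI cropping ------------------------------

#' Split an acquisition into fixed-length frame snapshots
#'
#' Divides a localization table into consecutive windows of `window` frames
#' (frames 1..window, window+1..2*window, ...), the convention used when a
#' 25,000-frame STORM acquisition is analysed as 25 snapshots of 1000 frames.
#' A final partial window is kept and flagged `partial`.
#'
#' @param tbl a [loc_table()].
#' @param window window length in frames (>= 1).
#' @return List of `loc_table` snapshots; each carries a `snapshot` attribute
#'   `list(index, first, last, partial)`.
#' @export
split_snapshots <- function(tbl, window) {
  if (window < 1) abort("window must be >= 1")
  window <- as.integer(window)
  if (nrow(tbl) == 0) return(list())
  max_frame <- max(tbl$frame)
  n_snap <- ceiling(max_frame / window)
  lapply(seq_len(n_snap), function(k) {
    first <- (k - 1L) * window + 1L
    last <- min(k * window, max_frame)
    snap <- tbl[tbl$frame >= first & tbl$frame <= last, , drop = FALSE]
    snap <- tibble::new_tibble(snap, unit = loc_unit(tbl),
                               extent = loc_extent(tbl),
                               source = attr(tbl, "source"),
                               seed = attr(tbl, "seed"),
                               snapshot = list(index = k, first = first,
                                               last = last,
                                               partial = (last - first + 1L) < window),
                               class = "loc_table")
    snap
  })
}

#' Crop a localization table to a rectangular region of interest
#'
#' Retains exactly the localizations with `xmin <= x < xmax` and
#' `ymin <= y < ymax` (half-open bounds, so a record on the max edge is
#' excluded) and updates the table extent to the ROI, e.g. the 2.5 x 2.5 um
#' regions used for per-snapshot statistics.
#'
#' @param tbl a [loc_table()].
#' @param roi numeric `c(xmin, xmax, ymin, ymax)` in table units.
#' @return Cropped `loc_table` with extent equal to `roi`.
#' @export
crop_roi <- function(tbl, roi) {
  roi <- as.numeric(roi)
  if (length(roi) != 4 || roi[1] >= roi[2] || roi[3] >= roi[4]) {
    abort("roi must be c(xmin, xmax, ymin, ymax) with min < max")
  }
  ext <- loc_extent(tbl)
  if (roi[1] < ext["xmin"] || roi[2] > ext["xmax"] ||
      roi[3] < ext["ymin"] || roi[4] > ext["ymax"]) {
    abort("roi extends outside the table extent")
  }
  keep <- tbl$x >= roi[1] & tbl$x < roi[2] & tbl$y >= roi[3] & tbl$y < roi[4]
  out <- tbl[keep, , drop = FALSE]
  tibble::new_tibble(out, unit = loc_unit(tbl), extent = setNames(
    roi, c("xmin", "xmax", "ymin", "ymax")),
    source = attr(tbl, "source"), seed = attr(tbl, "seed"),
    class = "loc_table")
}
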