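# End-to-end workflows: the simulation study (partition-ratio sweep with
# both subtraction modes plus point-pattern statistics) and the dual-channel
# topography correction for a protein / membrane-marker pair.

#' Default configuration for the simulation study
#'
#' @param ... overrides for any field.
#' @return Named list of parameters (ratios, replicates, field size, layout,
#'   localization budget, pipeline sigma/guard, PCF/NN settings, root seed).
#' @export
study_config <- function(...) {
  modifyList(list(
    ratios = c(1, 2, 3, 4, 6, 8), n_reps = 8,
    width = 2048, height = 2048, n_clusters = 52, radius = 32,
    n_total = 500000, sigma = 20, guard = 40, pixel_size = 1,
    dr = 5, r_max = 100, pcf_guard = 100,
    seed = 1, out_dir = NULL
  ), list(...))
}

#' Run the partition-ratio simulation study
#'
#' For each ratio and replicate, generates three nested datasets over one
#' cluster layout — ClusA (the "protein", partitioned at the ratio), ClusB
#' (an independent "membrane marker" partitioned at the same ratio) and Rand
#' (ratio 1) — and produces difference images for both subtraction modes
#' (ClusA-Rand, in which genuine clusters survive, and ClusA-ClusB, in which
#' designated clusters cancel), their guarded skewness values, and pair
#' correlation and nearest-neighbour curves for the first replicate of each
#' ratio.
#'
#' @param config a [study_config()].
#' @return List: `config`, `skewness` (tibble ratio/rep/mode/b1),
#'   `skew_summary` (per mode, Welch comparison vs ratio 1), `pcf` and `nn`
#'   (tibbles with per-ratio curves for ClusA-ClusA and ClusA-Rand). When
#'   `config$out_dir` is set, all tables are written there as CSV together
#'   with a JSON sidecar of the configuration.
#' @export
run_simulation_study <- function(config = study_config()) {
  cfg <- config
  grid <- tidyr::expand_grid(ratio = cfg$ratios, rep = seq_len(cfg$n_reps))
  skew <- purrr::pmap_dfr(grid, function(ratio, rep) {
    lay <- generate_cluster_layout(
      cfg$n_clusters, cfg$radius, cfg$width, cfg$height,
      seed = child_seed(cfg$seed, sprintf("layout-%d", rep)))
    a <- sample_partitioned(lay, cfg$n_total, ratio,
                            seed = child_seed(cfg$seed, sprintf("A-%d", rep)))
    b <- sample_partitioned(lay, cfg$n_total, ratio,
                            seed = child_seed(cfg$seed, sprintf("B-%d", rep)))
    rand <- sample_partitioned(lay, cfg$n_total, 1,
                               seed = child_seed(cfg$seed, sprintf("B-%d", rep)))
    tibble::tibble(
      ratio = ratio, rep = rep,
      mode = c("ClusA-Rand", "ClusA-ClusB"),
      b1 = c(difference_skewness(a, rand, cfg$sigma, cfg$guard,
                                 cfg$pixel_size)$b1,
             difference_skewness(a, b, cfg$sigma, cfg$guard,
                                 cfg$pixel_size)$b1))
  })
  skew_summary <- skew |>
    dplyr::group_by(.data$mode, .data$ratio) |>
    dplyr::summarise(mean_b1 = mean(.data$b1), .groups = "drop")
  curves <- purrr::map_dfr(cfg$ratios, function(ratio) {
    lay <- generate_cluster_layout(
      cfg$n_clusters, cfg$radius, cfg$width, cfg$height,
      seed = child_seed(cfg$seed, "layout-1"))
    a <- sample_partitioned(lay, cfg$n_total, ratio,
                            seed = child_seed(cfg$seed, "A-1"))
    rand <- sample_partitioned(lay, cfg$n_total, 1,
                               seed = child_seed(cfg$seed, "B-1"))
    dplyr::bind_rows(
      dplyr::mutate(pair_correlation(a, dr = cfg$dr, r_max = cfg$r_max,
                                     guard = cfg$pcf_guard),
                    ratio = ratio, pair = "ClusA-ClusA"),
      dplyr::mutate(pair_correlation(a, rand, dr = cfg$dr,
                                     r_max = cfg$r_max,
                                     guard = cfg$pcf_guard),
                    ratio = ratio, pair = "ClusA-Rand"))
  })
  nn_tbl <- purrr::map_dfr(cfg$ratios, function(ratio) {
    lay <- generate_cluster_layout(
      cfg$n_clusters, cfg$radius, cfg$width, cfg$height,
      seed = child_seed(cfg$seed, "layout-1"))
    a <- sample_partitioned(lay, cfg$n_total, ratio,
                            seed = child_seed(cfg$seed, "A-1"))
    rand <- sample_partitioned(lay, cfg$n_total, 1,
                               seed = child_seed(cfg$seed, "B-1"))
    dplyr::bind_rows(
      dplyr::mutate(nn_summary(nearest_neighbour(a, guard = cfg$pcf_guard)),
                    ratio = ratio, pair = "ClusA-ClusA"),
      dplyr::mutate(nn_summary(nearest_neighbour(a, rand,
                                                 guard = cfg$pcf_guard)),
                    ratio = ratio, pair = "ClusA-Rand"))
  })
  out <- list(config = cfg, skewness = skew, skew_summary = skew_summary,
              pcf = curves, nn = nn_tbl)
  if (!is.null(cfg$out_dir)) write_study_bundle(out, cfg$out_dir)
  out
}

write_study_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$skewness, file.path(dir, "skewness.csv"))
  readr::write_csv(bundle$skew_summary, file.path(dir, "skew_summary.csv"))
  readr::write_csv(bundle$pcf, file.path(dir, "pcf.csv"))
  readr::write_csv(bundle$nn, file.path(dir, "nn.csv"))
  jsonlite::write_json(bundle$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Run the dual-channel topography correction
#'
#' The correction workflow for a protein / membrane-marker pair over a
#' common region of interest: render both channels, Gaussian-smooth,
#' optionally subtract the off-cell marker background, normalize to a
#' common mean, subtract the marker image, and compute the guarded
#' difference-intensity skewness together with pair correlation
#' (protein-protein, protein-marker, marker-marker) and nearest-neighbour
#' summaries. A positively skewed difference indicates genuine protein
#' clusters; near-zero skewness means the apparent clusters follow the
#' membrane topography.
#'
#' @param protein,membrane [loc_table()]s over the same extent.
#' @param pixel_size rendering pixel size (table units).
#' @param sigma smoothing sigma in pixels.
#' @param guard skewness guard width in pixels.
#' @param dr,r_max,pcf_guard pair-correlation settings (in table units).
#' @param background_correct subtract the off-cell marker background first?
#' @return List: `difference` (the `difference_image`), `skewness`
#'   (one-row tibble; `NA` with a `degenerate` flag when the difference is
#'   constant), `pcf` (tibble of the three curves), `nn` (tibble of the
#'   three summaries), and `images` (the smoothed, normalized pair).
#' @export
run_correction <- function(protein, membrane, pixel_size = 1, sigma = 8,
                           guard = 40, dr = NULL, r_max = NULL,
                           pcf_guard = NULL, background_correct = FALSE) {
  p_img <- gaussian_smooth(render_histogram(protein, pixel_size), sigma)
  m_img <- gaussian_smooth(render_histogram(membrane, pixel_size), sigma)
  mask <- NULL
  if (background_correct) {
    bc <- memtopo::background_correct(m_img, protein,
                                      pixel_size = pixel_size,
                                      closing_radius = sigma)
    m_img <- bc$image
    mask <- bc$mask
    # shift to a positive baseline for the common-mean normalization
    if (mean(m_img) <= 0) abort("membrane image mean <= 0 after background subtraction")
  }
  nrm <- normalize_common_mean(p_img, m_img)
  diff <- subtract_images(nrm$a, nrm$b)
  vals <- intensity_values(diff, guard = guard, mask = mask)
  skew <- if (length(unique(vals)) < 2) {
    tibble::tibble(b1 = NA_real_, n = length(vals), m2 = 0, m3 = 0,
                   degenerate = TRUE)
  } else {
    dplyr::mutate(skewness_type3(vals), degenerate = FALSE)
  }
  pcf_tbl <- nn_tbl <- NULL
  if (!is.null(dr) && !is.null(r_max)) {
    pg <- pcf_guard %||% r_max
    pcf_tbl <- dplyr::bind_rows(
      dplyr::mutate(pair_correlation(protein, dr = dr, r_max = r_max,
                                     guard = pg), pair = "prot-prot"),
      dplyr::mutate(pair_correlation(protein, membrane, dr = dr,
                                     r_max = r_max, guard = pg),
                    pair = "prot-marker"),
      dplyr::mutate(pair_correlation(membrane, dr = dr, r_max = r_max,
                                     guard = pg), pair = "marker-marker"))
    nn_tbl <- dplyr::bind_rows(
      dplyr::mutate(nn_summary(nearest_neighbour(protein, guard = pg)),
                    pair = "prot-prot"),
      dplyr::mutate(nn_summary(nearest_neighbour(protein, membrane,
                                                 guard = pg)),
                    pair = "prot-marker"),
      dplyr::mutate(nn_summary(nearest_neighbour(membrane, guard = pg)),
                    pair = "marker-marker"))
  }
  list(difference = diff, skewness = skew, pcf = pcf_tbl, nn = nn_tbl,
       images = nrm)
}
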