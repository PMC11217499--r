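make_small_config <- function(seed = 3) {
  study_config(ratios = c(1, 4), n_reps = 2, width = 512, height = 512,
               n_clusters = 13, radius = 16, n_total = 30000,
               sigma = 20, guard = 40, dr = 5, r_max = 50, pcf_guard = 50,
               seed = seed)
}

test_that("the simulation study produces the full bookkeeping bundle", {
  res <- run_simulation_study(make_small_config())
  expect_equal(nrow(res$skewness), 2 * 2 * 2)  # ratios x reps x modes
  expect_setequal(unique(res$skewness$mode), c("ClusA-Rand", "ClusA-ClusB"))
  expect_equal(nrow(res$skew_summary), 4)
  expect_true(all(c("g", "ratio", "pair") %in% names(res$pcf)))
  expect_equal(nrow(res$nn), 4)
  # clustering raises ClusA-Rand skewness well above the ClusA-ClusB control
  s <- res$skew_summary
  expect_gt(s$mean_b1[s$mode == "ClusA-Rand" & s$ratio == 4],
            s$mean_b1[s$mode == "ClusA-ClusB" & s$ratio == 4] + 0.2)
})

test_that("re-running a study with the same config is reproducible", {
  r1 <- run_simulation_study(make_small_config())
  r2 <- run_simulation_study(make_small_config())
  expect_identical(r1$skewness, r2$skewness)
  expect_identical(r1$pcf$g, r2$pcf$g)
})

test_that("marker-image subtraction removes designated clusters", {
  lay <- generate_cluster_layout(13, 16, 512, 512, seed = 21)
  a <- sample_partitioned(lay, 60000, 4, seed = 22)
  b <- sample_partitioned(lay, 60000, 4, seed = 23)
  rand <- sample_partitioned(lay, 60000, 1, seed = 24)
  img <- function(tb) gaussian_smooth(render_histogram(tb, 1), 20)
  mask <- layout_mask(lay)
  inside_excess <- function(x, y) {
    nrm <- normalize_common_mean(img(x), img(y))
    d <- unclass(subtract_images(nrm$a, nrm$b))
    mean(d[mask]) - mean(d[!mask])
  }
  ab <- inside_excess(a, b)       # marker partitions like the protein
  ar <- inside_excess(a, rand)    # marker is random
  expect_gt(ar, 5 * abs(ab))      # designated clusters cancel in ClusA-ClusB
  expect_lt(abs(ab), 0.05)
})

test_that("the correction workflow separates genuine from topographic clustering", {
  # protein == marker: difference identically zero, skewness degenerate
  map <- build_membrane_map(256, 256, list(
    list(type = "fold", x0 = 40, x1 = 70, y0 = 30, y1 = 220, layers = 3)))
  mk <- sample_topography(map, 60000, "marker", seed = 41)
  self <- run_correction(mk, mk, sigma = 8, guard = 20)
  expect_true(all(unclass(self$difference) == 0))
  expect_true(self$skewness$degenerate)

  # CD59-like: protein follows the same topography, no enrichment
  pr <- sample_topography(map, 60000, "protein", seed = 42)
  cd59 <- run_correction(pr, mk, sigma = 8, guard = 20)
  expect_false(cd59$skewness$degenerate)
  expect_lt(abs(cd59$skewness$b1), 0.25)

  # TfR-like: protein enriched 6x in patches on the same membrane
  map_tfr <- build_membrane_map(256, 256, list(
    list(type = "fold", x0 = 40, x1 = 70, y0 = 30, y1 = 220, layers = 3),
    list(type = "patch", cx = 180, cy = 80, radius = 12, enrichment = 6),
    list(type = "patch", cx = 140, cy = 180, radius = 12, enrichment = 6)))
  mk2 <- sample_topography(map_tfr, 60000, "marker", seed = 43)
  pr2 <- sample_topography(map_tfr, 60000, "protein", seed = 44)
  tfr <- run_correction(pr2, mk2, sigma = 8, guard = 20)
  expect_gt(tfr$skewness$b1, cd59$skewness$b1 + 0.3)
})

test_that("the correction workflow emits the three-way statistics on request", {
  set.seed(51)
  pr <- csr_table(5000, 512, seed = 51)
  mk <- csr_table(5000, 512, seed = 52)
  res <- run_correction(pr, mk, sigma = 8, guard = 20, dr = 10, r_max = 50,
                        pcf_guard = 50)
  expect_setequal(unique(res$pcf$pair),
                  c("prot-prot", "prot-marker", "marker-marker"))
  expect_equal(nrow(res$nn), 3)
  expect_s3_class(autoplot(res$difference), "ggplot")
})
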