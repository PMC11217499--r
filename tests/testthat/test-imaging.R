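test_that("histogram rendering bins half-open pixels and conserves counts", {
  tb <- loc_table(data.frame(x = c(55, 20), y = c(12, 0)), unit = "nm",
                  extent = c(0, 100, 0, 100))
  img <- render_histogram(tb, pixel_size = 10)
  expect_equal(dim(img), c(10, 10))
  expect_equal(unclass(img)[2, 6], 1)   # x=55 -> col 6, y=12 -> row 2
  expect_equal(unclass(img)[1, 3], 1)   # boundary y=0 -> row 1
  expect_equal(sum(img), 2)
  # a coordinate exactly on a pixel boundary belongs to the higher pixel
  tb2 <- loc_table(data.frame(x = 30, y = 30), unit = "nm",
                   extent = c(0, 100, 0, 100))
  expect_equal(unclass(render_histogram(tb2, 10))[4, 4], 1)
  set.seed(1)
  tb3 <- csr_table(5000, 100)
  expect_equal(sum(render_histogram(tb3, 7)), 5000)  # padded last row/col
  expect_error(render_histogram(tb, 10, extent = c(5, 5, 0, 10)), "extent")
})

test_that("Gaussian smoothing conserves interior mass and peak height", {
  img <- pixel_image(matrix(0, 513, 513))
  m <- unclass(img); m[257, 257] <- 1
  img <- pixel_image(m)
  sm <- gaussian_smooth(img, 20)
  expect_lt(abs(unclass(sm)[257, 257] - 1 / (2 * pi * 20^2)) /
              (1 / (2 * pi * 20^2)), 0.01)
  expect_lt(abs(sum(sm) - 1), 1e-6)
  expect_equal(unclass(gaussian_smooth(img, 0)), unclass(img),
               ignore_attr = TRUE)
  expect_error(gaussian_smooth(img, -1), "sigma")
})

test_that("common-mean normalization fixes both means at one", {
  a <- pixel_image(matrix(c(1, 1, 3, 3), 2))
  b <- pixel_image(matrix(c(2, 6, 2, 6), 2))
  nrm <- normalize_common_mean(a, b)
  expect_equal(unclass(nrm$a), matrix(c(0.5, 0.5, 1.5, 1.5), 2),
               ignore_attr = TRUE)
  expect_equal(unclass(nrm$b), matrix(c(0.5, 1.5, 0.5, 1.5), 2),
               ignore_attr = TRUE)
  expect_equal(mean(nrm$a), 1)
  expect_equal(mean(nrm$b), 1)
  same <- normalize_common_mean(a, a)
  expect_identical(unclass(same$a), unclass(same$b))
  expect_error(normalize_common_mean(pixel_image(matrix(0, 2, 2)), b),
               "mean")
})

test_that("subtraction of a normalized pair has zero mean and is antisymmetric", {
  a <- pixel_image(matrix(c(1, 1, 3, 3), 2))
  b <- pixel_image(matrix(c(2, 6, 2, 6), 2))
  nrm <- normalize_common_mean(a, b)
  d <- subtract_images(nrm$a, nrm$b)
  expect_equal(unclass(d), matrix(c(0, -1, 1, 0), 2), ignore_attr = TRUE)
  expect_lt(abs(mean(d)), 1e-9)
  d2 <- subtract_images(nrm$b, nrm$a)
  expect_equal(unclass(d2), -unclass(d), ignore_attr = TRUE)
  expect_equal(unclass(subtract_images(nrm$a, nrm$a)),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(subtract_images(nrm$a, pixel_image(matrix(0, 3, 3))),
               "shape")
  expect_warning(subtract_images(a, b), "normalized")
})

test_that("guarded intensity extraction counts interior pixels", {
  img <- pixel_image(matrix(runif(200 * 200), 200))
  expect_length(intensity_values(img, guard = 40), 120^2)
  expect_length(intensity_values(img, guard = 0), 200^2)
  mask <- matrix(FALSE, 200, 200); mask[, 1:100] <- TRUE
  expect_length(intensity_values(img, guard = 40, mask = mask), 120 * 60)
  expect_error(intensity_values(img, guard = 100), "guard")
})

test_that("background correction recovers the on-cell offset", {
  # membrane with background b off-cell and b + s on-cell
  set.seed(6)
  b <- 2; s <- 5
  mem <- matrix(b, 100, 100); mem[, 1:50] <- b + s
  mem <- pixel_image(mem)
  prot <- loc_table(data.frame(x = runif(4000, 0, 50),
                               y = runif(4000, 0, 100)),
                    unit = "pixel", extent = c(0, 100, 0, 100))
  bc <- background_correct(mem, prot, pixel_size = 1, closing_radius = 4)
  expect_true(mean(bc$mask[, 1:45]) > 0.95)      # cell interior kept
  expect_true(mean(bc$mask[, 60:100]) < 0.05)    # off-cell excluded
  expect_lt(abs(mean(unclass(bc$image)[bc$mask]) - s), 0.1)
  expect_lt(abs(mean(unclass(bc$image)[, 60:100])), 0.1)
})

test_that("degenerate background cases warn instead of failing", {
  mem <- pixel_image(matrix(1, 50, 50))
  empty <- loc_table(data.frame(x = numeric(0), y = numeric(0)),
                     unit = "pixel", extent = c(0, 50, 0, 50))
  expect_warning(background_correct(mem, empty, 1, 2), "foreground")
  set.seed(2)
  everywhere <- csr_table(20000, 50)
  expect_warning(background_correct(mem, everywhere, 1, 2),
                 "whole image")
})

test_that("difference of two CSR renders has symmetric intensities", {
  b1s <- vapply(1:4, function(s) {
    a <- csr_table(1e5, 2048, seed = 40 + s)
    b <- csr_table(1e5, 2048, seed = 80 + s)
    difference_skewness(a, b, sigma = 20, guard = 40)$b1
  }, 0)
  expect_lt(abs(mean(b1s)), 0.05)
})

test_that("topography-matched subtraction cancels feature excess", {
  map <- build_membrane_map(512, 512, list(
    list(type = "fold", x0 = 80, x1 = 130, y0 = 60, y1 = 400, layers = 3),
    list(type = "bump", cx = 360, cy = 300, height = 120, sd = 40)))
  marker <- sample_topography(map, 150000, "marker", seed = 11)
  protein <- sample_topography(map, 150000, "protein", seed = 22)
  pa <- gaussian_smooth(render_histogram(protein, 1), 20)
  pb <- gaussian_smooth(render_histogram(marker, 1), 20)
  nrm <- normalize_common_mean(pa, pb)
  d <- subtract_images(nrm$a, nrm$b)
  fp <- map$footprints[[1]] | map$footprints[[2]]
  protein_excess <- max(unclass(nrm$a)[fp] - mean(nrm$a))
  expect_gte(1 - max(abs(unclass(d)[fp])) / protein_excess, 0.7)
})

test_that("genuine enrichment survives the subtraction in the right place", {
  centers <- seq(60, 460, by = 100)
  map <- build_membrane_map(512, 512, lapply(centers, function(cx)
    list(type = "patch", cx = cx, cy = cx, radius = 16, enrichment = 6)))
  marker <- sample_topography(map, 150000, "marker", seed = 31)
  protein <- sample_topography(map, 150000, "protein", seed = 32)
  pa <- gaussian_smooth(render_histogram(protein, 1), 8)
  pb <- gaussian_smooth(render_histogram(marker, 1), 8)
  nrm <- normalize_common_mean(pa, pb)
  d <- unclass(subtract_images(nrm$a, nrm$b))
  mask <- Reduce(`|`, map$footprints)
  thr <- quantile(d, 0.99)
  expect_gte(mean(mask[d >= thr]), 0.9)
})
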