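test_that("band membership follows the (r, r+dr] convention", {
  ext <- c(0, 400, 0, 400)
  origins <- loc_table(data.frame(x = 200, y = 200), unit = "pixel",
                       extent = ext)
  targets <- loc_table(data.frame(x = 207, y = 200), unit = "pixel",
                       extent = ext)
  pc <- pair_correlation(origins, targets, dr = 5, r_max = 100)
  expect_equal(which(pc$count > 0), 2L)   # distance 7 in band (5, 10]
  # a distance exactly on a band edge stays in the band it closes
  targets2 <- loc_table(data.frame(x = 210, y = 200), unit = "pixel",
                        extent = ext)
  pc2 <- pair_correlation(origins, targets2, dr = 5, r_max = 100)
  expect_equal(which(pc2$count > 0), 2L)  # d = 10 in (5, 10]
})

test_that("pair correlation equals the brute-force double loop bit-for-bit", {
  for (n in c(50, 300, 500)) {
    tb <- csr_table(n, 512, seed = n)
    pc <- pair_correlation(tb, dr = 5, r_max = 100, guard = 100)
    g0 <- pcf_oracle(tb, tb, dr = 5, r_max = 100, guard = 100,
                     same_set = TRUE)
    expect_identical(pc$g, unname(g0))
  }
  # cross-correlation of two different sets
  a <- csr_table(300, 512, seed = 1); b <- csr_table(200, 512, seed = 2)
  pc <- pair_correlation(a, b, dr = 10, r_max = 80, guard = 80)
  expect_identical(pc$g, unname(pcf_oracle(a, b, 10, 80, 80)))
})

test_that("CSR patterns give g near one in every band", {
  tb <- csr_table(20000, 2048, seed = 3)
  pc <- pair_correlation(tb, dr = 5, r_max = 100, guard = 100)
  count_se <- 1 / sqrt(pmax(pc$count, 1))
  expect_true(all(abs(pc$g - 1) < 5 * pmax(count_se, 0.005)))
  expect_lt(abs(mean(pc$g) - 1), 0.02)
})

test_that("pair correlation rejects degenerate inputs", {
  tb <- csr_table(100, 200, seed = 4)
  empty <- tb[0, ]
  expect_error(pair_correlation(tb, empty, dr = 5, r_max = 50), "empty")
  expect_error(pair_correlation(tb, dr = 5, r_max = 99), "multiple")
  expect_error(pair_correlation(tb, dr = 5, r_max = 50, guard = 100),
               "guard")
})

test_that("PC-PALM recovers forward-model parameters", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    r_mid <- seq(2.5, 197.5, by = 5)
    g <- pcpalm_model(r_mid, rho = 1e-3, sigma_psf = 10, A = 3, xi = 50)
    g <- g * (1 + rnorm(length(g), 0, 0.01))
    f <- pcpalm_fit(make_curve(g[seq_along(g)], dr = 5), sigma_psf = 10)
    c(abs(f$coef[["A"]] - 3) / 3, abs(f$coef[["xi"]] - 50) / 50,
      f$clustering_detected)
  }, numeric(3))
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.15)
  expect_true(all(errs[3, ] == 1))
})

test_that("a structureless curve yields no protein term", {
  f <- pcpalm_fit(make_curve(rep(1, 30)), sigma_psf = 10)
  expect_lt(f$coef[["A"]], 1e-6)
  expect_false(f$clustering_detected)
})

test_that("blinking-only CSR data are not called clustered", {
  for (s in 1:3) {
    tb <- blinking_table(800, 2048, sigma = 10, seed = s)
    pc <- pair_correlation(tb, dr = 5, r_max = 150, guard = 100)
    expect_gt(pc$g[1], 3)  # raw curve looks strongly clustered
    f <- pcpalm_fit(pc, sigma_psf = 10)
    expect_lt(f$coef[["A"]], 0.5)         # protein term near zero
    expect_false(f$clustering_detected)   # PC-PALM sees only blinking
  }
})

test_that("PC-PALM fits are tidy-able and plottable", {
  f <- pcpalm_fit(make_curve(pcpalm_model(seq(2.5, 147.5, 5), 1e-3, 10, 3, 50)),
                  sigma_psf = 10)
  td <- tidy(f)
  expect_setequal(td$term, c("rho", "A", "xi", "sigma_psf"))
  gl <- glance(f)
  expect_true(gl$clustering_detected)
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(f$curve), "ggplot")
  expect_error(pcpalm_fit(make_curve(rep(1, 5)), sigma_psf = 10), "bands")
  expect_error(pcpalm_fit(make_curve(rep(1, 30)), sigma_psf = 0), "sigma")
})
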