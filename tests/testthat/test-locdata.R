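test_that("CSV localization tables parse under the default dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x_nm,y_nm", "1,100,200", "1,150,210", "2,90,400"), f)
  tb <- read_localizations(f)
  expect_s3_class(tb, "loc_table")
  expect_equal(nrow(tb), 3)
  expect_equal(attr(tb, "unit"), "nm")
  expect_equal(tb$x, c(100, 150, 90))
  expect_equal(tb$frame, c(1L, 1L, 2L))

  writeLines("frame,x_nm,y_nm", f)
  expect_equal(nrow(read_localizations(f)), 0)
})

test_that("malformed localization CSVs are rejected informatively", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x_nm", "1,100"), f)
  expect_error(read_localizations(f), "mandatory column 'y_nm'")

  writeLines(c("frame,x_nm,y_nm", "1,100,200", "2,oops,300"), f)
  expect_error(read_localizations(f), "line 2")

  expect_error(read_localizations(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("write/read round-trip reproduces coordinates bit-identically", {
  set.seed(4)
  tb <- loc_table(data.frame(frame = sample(1:50, 200, TRUE),
                             x = runif(200, 0, 1000) + pi * 1e-8,
                             y = runif(200, 0, 1000)),
                  unit = "nm", extent = c(0, 1000, 0, 1000))
  f <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tb, f)
  back <- read_localizations(f, extent = c(0, 1000, 0, 1000))
  expect_identical(back$x, tb$x)
  expect_identical(back$y, tb$y)
  expect_identical(back$frame, tb$frame)
})

test_that("snapshot splitting covers consecutive windows and conserves records", {
  set.seed(9)
  n <- 5000
  frames <- sample(1:25000, n, TRUE)
  frames[1] <- 25000L  # acquisition runs to the final frame
  tb <- loc_table(data.frame(frame = frames,
                             x = runif(n, 0, 100), y = runif(n, 0, 100)),
                  unit = "nm", extent = c(0, 100, 0, 100))
  snaps <- split_snapshots(tb, 1000)
  expect_length(snaps, 25)
  expect_equal(sum(vapply(snaps, nrow, 0L)), n)
  info <- lapply(snaps, attr, "snapshot")
  expect_equal(vapply(info, `[[`, 0L, "first"), seq(1L, 24001L, by = 1000L))
  expect_false(any(vapply(info, `[[`, TRUE, "partial")))
  for (s in snaps) {
    i <- attr(s, "snapshot")
    expect_true(all(s$frame >= i$first & s$frame <= i$last))
  }
})

test_that("a final partial snapshot is kept and flagged", {
  tb <- loc_table(data.frame(frame = c(1L, 999L, 1200L, 1500L),
                             x = 1:4, y = 1:4),
                  unit = "pixel", extent = c(0, 10, 0, 10))
  snaps <- split_snapshots(tb, 1000)
  expect_length(snaps, 2)
  i2 <- attr(snaps[[2]], "snapshot")
  expect_true(i2$partial)
  expect_equal(i2$last - i2$first + 1L, 500L)
  expect_length(split_snapshots(tb[0, ], 1000), 0)
  expect_error(split_snapshots(tb, 0), ">= 1")
})

test_that("ROI cropping is half-open, idempotent and extent-checked", {
  tb <- loc_table(data.frame(x = c(100, 2499.9, 2500, 5000, 9000),
                             y = c(100, 2499.9, 2500, 200, 9000)),
                  unit = "nm", extent = c(0, 10000, 0, 10000))
  roi <- c(0, 2500, 0, 2500)
  cr <- crop_roi(tb, roi)
  expect_equal(nrow(cr), 2)  # the 2500-edge record is excluded (half-open)
  expect_equal(unname(attr(cr, "extent")), roi)
  expect_identical(tibble::as_tibble(crop_roi(cr, roi)),
                   tibble::as_tibble(cr))
  full <- crop_roi(tb, c(0, 10000, 0, 10000))
  expect_equal(nrow(full), nrow(tb))
  expect_error(crop_roi(tb, c(-1, 2500, 0, 2500)), "outside")
})

test_that("loc_table enforces its invariants", {
  expect_error(loc_table(data.frame(x = 5, y = 5), unit = "pixel",
                         extent = c(0, 4, 0, 4)), "outside")
  expect_error(loc_table(data.frame(frame = 0L, x = 1, y = 1),
                         unit = "pixel", extent = c(0, 4, 0, 4)),
               "positive")
  expect_error(loc_table(data.frame(x = 1, y = 1, uncertainty = -2),
                         unit = "pixel", extent = c(0, 4, 0, 4)),
               "uncertainty")
})
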