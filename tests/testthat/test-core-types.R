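test_that("rf_frame validates its invariants", {
  expect_s3_class(rf_frame(matrix(0, 2, 1), fs = 1), "rf_frame")
  expect_error(rf_frame(matrix(1, 1, 1), fs = 1), "2 samples")
  expect_error(rf_frame(matrix(NA_real_, 3, 2), fs = 1), "finite")
  expect_error(rf_frame(matrix(0, 3, 2), fs = 0), "positive")
  expect_error(rf_frame(matrix(0, 3, 2), fs = 1, t0 = NaN), "t0")
})

test_that("frame stacks require homogeneous shape and fs", {
  f1 <- rf_frame(matrix(rnorm(20), 10, 2), fs = 1e6)
  f2 <- rf_frame(matrix(rnorm(20), 10, 2), fs = 1e6)
  expect_equal(length(frame_stack(list(f1, f2))), 2L)
  expect_error(frame_stack(list()), "non-empty")
  f3 <- rf_frame(matrix(rnorm(10), 5, 2), fs = 1e6)
  expect_error(frame_stack(list(f1, f3)), "shape")
  f4 <- rf_frame(matrix(rnorm(20), 10, 2), fs = 2e6)
  expect_error(frame_stack(list(f1, f4)), "sampling frequency")
})

test_that("RF I/O round-trips bit-exactly and writes deterministic bytes", {
  set.seed(1)
  f <- rf_frame(matrix(rnorm(1019 * 60), 1019, 60), fs = 1 / 9.259e-9,
                t0 = 1.5e-6)
  p1 <- file.path(tempdir(), "a.rf")
  p2 <- file.path(tempdir(), "b.rf")
  write_rf(f, p1)
  write_rf(f, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  g <- read_rf(p1)
  expect_identical(g$data, f$data)
  expect_identical(g$fs, f$fs)
  expect_identical(g$t0, f$t0)
})

test_that("RF reader rejects missing files and malformed metadata", {
  expect_error(read_rf(file.path(tempdir(), "nope.rf")), "no such file")
  p <- file.path(tempdir(), "c.rf")
  write_rf(rf_frame(matrix(0, 4, 2), fs = 1e6), p)
  meta <- jsonlite::fromJSON(paste0(p, ".json"))
  meta$fs <- NULL
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE), paste0(p, ".json"))
  expect_error(read_rf(p), "malformed")
  file.remove(paste0(p, ".json"))
  expect_error(read_rf(p), "sidecar")
})

test_that("a zero frame writes a payload summing to zero", {
  p <- file.path(tempdir(), "z.rf")
  write_rf(rf_frame(matrix(0, 1019, 60), fs = 108e6), p)
  expect_identical(sum(readBin(p, "double", 1019 * 60, size = 8,
                               endian = "little")), 0)
})

test_that("circular preset has exact ring geometry", {
  g <- circular_array()
  expect_equal(g$n_elements, 60L)
  radii <- sqrt(rowSums(g$positions^2))
  expect_lt(max(abs(radii - 4.5e-3)), 1e-12)
  ang <- atan2(g$positions[, 2], g$positions[, 1])
  gaps <- diff(sort(ang))
  expect_lt(max(abs(gaps - 2 * pi / 60)), 1e-12)
})

test_that("phantom and image containers validate their contracts", {
  expect_error(pa_phantom(matrix(-1, 4, 4), 1e-4), ">= 0")
  expect_error(pa_phantom(matrix(1, 4, 4), 1e-4, c = -1), "sound speed")
  ph <- pa_phantom(matrix(1, 4, 4), 1e-4)
  expect_equal(ph$c, 1500)
  expect_equal(ph$origin, c(-1.5e-4, -1.5e-4))
  expect_error(pa_image(matrix(Inf, 4, 4), 1e-4), "finite")
})
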