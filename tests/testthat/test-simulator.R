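test_that("vessel phantom is deterministic, bounded and suitably sparse", {
  p1 <- make_vessel_phantom(256, 1)
  p2 <- make_vessel_phantom(256, 1)
  expect_identical(p1$p0, p2$p0)
  expect_gte(min(p1$p0), 0)
  expect_lte(max(p1$p0), 1)
  expect_false(identical(p1$p0, make_vessel_phantom(256, 2)$p0))
  expect_error(make_vessel_phantom(32, 1), ">= 64")
  # regression bound on occupancy, frozen for the default generator
  p <- make_vessel_phantom(512, 1)
  expect_gt(mean(p$p0 > 0), 0.005)
  expect_lt(mean(p$p0 > 0), 0.08)
  # 10 mm square grid
  expect_equal(p$pixel_size * 512, 10e-3)
  # confined to the circular-array aperture
  co <- lpfsc:::grid_coords(p)
  nz <- which(p$p0 > 0, arr.ind = TRUE)
  expect_lt(max(sqrt(co$x[nz[, 2]]^2 + co$y[nz[, 1]]^2)), 4.5e-3)
})

test_that("filament and tube presets have the stated geometry", {
  fil <- make_filament_phantom(256)
  lab <- label_components(fil$p0 > 0)
  expect_equal(lab$n, 2L)
  # centers 1 mm apart
  sep <- abs(diff(lab$centroids[, 2])) * fil$pixel_size
  expect_lt(abs(sep - 1e-3), 2 * fil$pixel_size)
  expect_gte(min(fil$p0), 0)

  tube <- make_tube_phantom()
  lab <- label_components(tube$p0 > 0)
  expect_equal(lab$n, 3L)
  depths <- sort(lab$centroids[, 1]) * tube$pixel_size + tube$origin[2]
  expect_lt(max(abs(diff(depths) - 5e-3)), tube$pixel_size)
  expect_gte(min(tube$p0), 0)
  # fluence decay option attenuates deep targets
  td <- make_tube_phantom(mu_eff = 100)
  expect_lt(max(td$p0), 1)
})

test_that("forward model is linear and handles the empty phantom", {
  acq <- acquisition_spec(n_samples = 400L)
  geom <- circular_array()
  z <- forward_simulate(pa_phantom(matrix(0, 64, 64), 10e-3 / 64), geom, acq)
  expect_identical(z$data, matrix(0, 400, 60))
  set.seed(90)
  pa <- matrix(0, 65, 65); pa[cbind(sample(20:45, 5), sample(20:45, 5))] <- runif(5)
  pb <- matrix(0, 65, 65); pb[cbind(sample(20:45, 5), sample(20:45, 5))] <- runif(5)
  ps <- 10e-3 / 65
  fa <- forward_simulate(pa_phantom(pa, ps), geom, acq)
  fb <- forward_simulate(pa_phantom(pb, ps), geom, acq)
  fab <- forward_simulate(pa_phantom(pa + pb, ps), geom, acq)
  expect_lt(max(abs(fab$data - fa$data - fb$data)), 1e-9 * max(abs(fab$data)))
  expect_error(forward_simulate(pa_phantom(matrix(1, 64, 64), 10e-3 / 64),
                                geom, acq), "aperture")
})

test_that("a central point source arrives at the ring travel time", {
  # odd grid so that a pixel sits exactly at the array center; the
  # 4.5 mm radius at 1500 m/s and 9.259 ns sampling is sample 324 (0-based)
  p0 <- matrix(0, 129, 129); p0[65, 65] <- 1
  fr <- forward_simulate(pa_phantom(p0, 10e-3 / 129), circular_array(),
                         acquisition_spec())
  env <- apply(fr$data, 2, envelope)
  peaks <- apply(env, 2, which.max)
  expect_true(all(peaks == round((4.5e-3 / 1500) / 9.259e-9) + 1L))
  # all channels identical by symmetry
  expect_lt(max(abs(fr$data - fr$data[, 1])), 1e-9 * max(abs(fr$data)))
})

test_that("quarter-turn rotation of a symmetric phantom shifts channels", {
  # 4-fold symmetric phantom is invariant under 90 deg rotation, so the
  # frame must equal itself cyclically shifted by 15 of the 60 channels
  p0 <- matrix(0, 65, 65)
  for (off in list(c(12, 0), c(-12, 0), c(0, 12), c(0, -12)))
    p0[33 + off[1], 33 + off[2]] <- 1
  fr <- forward_simulate(pa_phantom(p0, 10e-3 / 65), circular_array(),
                         acquisition_spec(n_samples = 500L))
  shifted <- fr$data[, c(16:60, 1:15)]
  expect_lt(max(abs(fr$data - shifted)), 1e-3 * max(abs(fr$data)))
})

test_that("noise injection hits the requested SNR and is seeded", {
  clean <- rf_frame(matrix(rnorm(1019 * 60), 1019, 60), fs = 108e6)
  n1 <- add_noise(clean, 10, seed = 5)
  n2 <- add_noise(clean, 10, seed = 5)
  expect_identical(n1$data, n2$data)
  w <- n1$data - clean$data
  snr_emp <- 10 * log10(mean(clean$data^2) / mean(w^2))
  expect_lt(abs(snr_emp - 10), 0.1)
  n3 <- add_noise(clean, 300, seed = 5)
  expect_lt(max(abs(n3$data - clean$data)), 1e-9 * max(abs(clean$data)))
  expect_error(add_noise(rf_frame(matrix(0, 4, 2), fs = 1), 10), "zero power")
})

test_that("noise injection does not disturb the caller's RNG stream", {
  clean <- rf_frame(matrix(rnorm(100), 50, 2), fs = 1e6)
  set.seed(123); a <- rnorm(3)
  set.seed(123); invisible(add_noise(clean, 5, seed = 9)); b <- rnorm(3)
  expect_identical(a, b)
})
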