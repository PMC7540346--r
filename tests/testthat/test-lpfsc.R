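test_that("configuration invariants are enforced", {
  expect_error(lpfsc_config(lam0 = -1), "nonnegative")
  expect_error(lpfsc_config(lam0 = 0, lam1 = 0), "both")
  expect_error(lpfsc_config(rho = 0), "rho")
  expect_error(lpfsc_config(tol = 0), "tol")
  expect_error(lpfsc_config(max_iter = 0), "max_iter")
  expect_error(lpfsc_config(over_relax = 2), "over_relax")
  expect_error(lpfsc_config(fc = 0.7), "inside")
  cfg <- lpfsc_config()
  p <- file.path(tempdir(), "cfg.json")
  write_lpfsc_config(cfg, p)
  expect_equal(read_lpfsc_config(p), cfg)
})

test_that("lpfsc_cost equals an independent term-by-term recomputation", {
  cfg <- lpfsc_config(lam0 = 0.7, lam1 = 1.3, lambda_scale = "absolute")
  expect_identical(lpfsc_cost(numeric(16), numeric(16), cfg), 0)
  set.seed(8)
  H <- dense_highpass_matrix(16, cfg$fc, cfg$d)
  for (i in 1:10) {
    x <- rnorm(16); u <- rnorm(16)
    ref <- 0.5 * sum((H %*% (x - u))^2) + 0.7 * sum(abs(u)) +
      1.3 * sum(abs(diff(u)))
    expect_lt(abs(lpfsc_cost(x, u, cfg) - ref), 1e-10)
  }
  x <- rnorm(16)
  expect_equal(lpfsc_cost(x, numeric(16), cfg),
               0.5 * sum(apply_highpass(design_highpass(cfg$fc, cfg$d), x)^2))
  expect_error(lpfsc_cost(rnorm(10), rnorm(9), cfg), "length")
})

test_that("zero input is a fixed point and output identity holds", {
  r <- lpfsc_denoise(numeric(128), lpfsc_config())
  expect_identical(r$s_sparse, numeric(128))
  expect_identical(r$denoised, numeric(128))
  expect_true(r$converged)
  g <- gen_channel(11, snr_db = 5)
  r <- lpfsc_denoise(g$noisy, lpfsc_config())
  expect_identical(r$denoised, r$s_sparse + r$s_low)
})

test_that("incumbent cost trace is nonincreasing", {
  for (s in 1:5) {
    g <- gen_channel(20 + s, snr_db = sample(c(-5, 0, 10), 1))
    r <- lpfsc_denoise(g$noisy, lpfsc_config())
    ct <- r$cost_trace
    expect_true(all(diff(ct) <= 1e-8 * pmax(abs(ct[-length(ct)]), 1e-12)))
  }
})

test_that("solver beats random candidates with coordinate-descent polish", {
  cfg <- lpfsc_config(lam0 = 0.05, lam1 = 0.1, lambda_scale = "absolute",
                      normalize = FALSE, tol = 1e-9, max_iter = 3000)
  for (s in 1:10) {
    g <- gen_channel(40 + s, n = 64, n_spikes = 3, snr_db = 5)
    x <- g$noisy / max(abs(g$noisy))
    r <- lpfsc_denoise(x, cfg)
    c_solver <- lpfsc_cost(x, r$s_sparse, cfg)
    set.seed(1000 + s)
    cands <- c(list(numeric(64), x),
               lapply(1:200, function(i) rnorm(64, sd = runif(1, 0.05, 0.5))))
    costs <- vapply(cands, function(u) lpfsc_cost(x, u, cfg), numeric(1))
    best <- cd_polish(x, cands[[which.min(costs)]], cfg)
    expect_lte(c_solver, best$cost + 1e-8)
  }
})

test_that("solution satisfies first-order optimality and warm-start fixed point", {
  cfg <- lpfsc_config(tol = 1e-9, max_iter = 5000)
  g <- gen_channel(33, n = 64, n_spikes = 3, snr_db = 0)
  r <- lpfsc_denoise(g$noisy, cfg)
  sc <- max(abs(g$noisy))
  expect_lt(lpfsc_optimality(g$noisy / sc, r$s_sparse / sc, cfg), 1e-6)
  r2 <- lpfsc_denoise(g$noisy, cfg, warm_start = r$s_sparse)
  expect_lt(max(abs(r2$s_sparse - r$s_sparse)) / sc, cfg$tol * 10)
})

test_that("denoising improves fidelity on the generative model at 0 dB", {
  wins <- 0L
  for (s in 1:50) {
    g <- gen_channel(100 + s, snr_db = 0)
    r <- lpfsc_denoise(g$noisy, lpfsc_config())
    if (mean((r$denoised - g$clean)^2) < mean((g$noisy - g$clean)^2))
      wins <- wins + 1L
  }
  expect_gte(wins, 49L)
})

test_that("output is insensitive to lambda within the working range", {
  g <- gen_channel(60, snr_db = 0)
  rmse <- vapply(c(0.8, 0.9, 1, 1.1, 1.2), function(l) {
    r <- lpfsc_denoise(g$noisy, lpfsc_config(lam0 = l, lam1 = l))
    sqrt(mean((r$denoised - g$clean)^2))
  }, numeric(1))
  expect_lt((max(rmse) - min(rmse)) / min(rmse), 0.25)
})

test_that("frame denoising is channel-independent and scale-equivariant", {
  set.seed(70)
  fr <- rf_frame(sapply(1:4, function(i) gen_channel(70 + i, n = 256,
                                                     snr_db = 5)$noisy),
                 fs = 108e6)
  cfg <- lpfsc_config()
  den <- lpfsc_denoise_frame(fr, cfg)
  expect_identical(dim(den$data), dim(fr$data))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  den_p <- lpfsc_denoise_frame(rf_frame(fr$data[, perm], fs = fr$fs), cfg)
  expect_equal(den_p$data, den$data[, perm])
  # doubling a channel doubles its output exactly under peak normalization
  fr2 <- fr; fr2$data[, 2] <- 2 * fr2$data[, 2]
  den2 <- lpfsc_denoise_frame(fr2, cfg)
  expect_equal(den2$data[, 2], 2 * den$data[, 2], tolerance = 1e-12)
  # zero frame maps to zero frame
  z <- lpfsc_denoise_frame(rf_frame(matrix(0, 64, 3), fs = 1e6), cfg)
  expect_identical(z$data, matrix(0, 64, 3))
})
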