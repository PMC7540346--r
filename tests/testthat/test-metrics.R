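test_that("psnr matches direct arithmetic in both conventions", {
  ref <- c(1, 0, 0, 0); est <- c(0.9, 0, 0, 0)
  # MSE = 0.0025
  expect_equal(psnr(ref, est), 20 * log10(1 / 0.0025), tolerance = 1e-12)
  expect_equal(round(psnr(ref, est), 2), 52.04)
  expect_identical(psnr(ref, ref), Inf)
  set.seed(101)
  a <- rnorm(100); b <- a + rnorm(100, sd = 0.1)
  mse <- mean((a - b)^2)
  expect_equal(psnr(a, b) - psnr(a, b, "rmse"),
               20 * log10(sqrt(mse) / mse), tolerance = 1e-10)
  expect_error(psnr(a, b[1:10]), "mismatch")
})

test_that("global SSIM follows the printed formula", {
  set.seed(102)
  img <- matrix(runif(64), 8, 8)
  expect_equal(ssim_global(img, img), 1.0)
  other <- matrix(runif(64), 8, 8)
  # symmetric for any fixed pair of stabilization constants
  expect_equal(ssim_global(img, other, c1 = 1e-4, c2 = 1e-4),
               ssim_global(other, img, c1 = 1e-4, c2 = 1e-4))
  # hand-computed 2x2 oracle
  a <- matrix(c(0, 1, 0, 1), 2, 2)
  b <- matrix(c(0, 0.5, 0, 0.5), 2, 2)
  mu_a <- 0.5; mu_b <- 0.25
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  c1 <- 1e-4; c2 <- 1e-4
  ref <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  expect_equal(ssim_global(a, b, c1 = c1, c2 = c2), ref, tolerance = 1e-12)
  expect_error(ssim_global(img, matrix(0, 4, 4)), "mismatch")
  expect_lte(ssim_global(img, other), 1)
})

test_that("CNR matches direct arithmetic and is translation invariant", {
  img <- matrix(2, 40, 40)
  img[10:15, 10:15] <- 10
  set.seed(103)
  img[25:38, 25:38] <- 2 + rnorm(196)
  roi <- roi_spec(inside = c(10, 15, 10, 15), outside = c(25, 38, 25, 38))
  bg <- img[25:38, 25:38]
  ref <- 20 * log10(abs(10 - mean(bg)) / sd(as.vector(bg)))
  expect_equal(cnr(img, roi), ref, tolerance = 1e-12)
  expect_equal(cnr(img + 5, roi), cnr(img, roi), tolerance = 1e-12)
  # simple closed-form case: means 10 vs 2, background sd 2
  img2 <- matrix(0, 20, 20)
  img2[1:5, 1:5] <- 10
  img2[11:20, 11:20] <- rep(c(0, 4), 50)  # mean 2, sd 2 (population ~ sample)
  roi2 <- roi_spec(inside = c(1, 5, 1, 5), outside = c(11, 20, 11, 20))
  expect_equal(cnr(img2, roi2),
               20 * log10(8 / sd(rep(c(0, 4), 50))), tolerance = 1e-12)
  expect_error(roi_spec(inside = c(1, 5, 1, 5), outside = c(3, 8, 3, 8)),
               "disjoint")
  expect_error(cnr(matrix(1, 10, 10),
                   roi_spec(c(1, 2, 1, 2), c(5, 8, 5, 8))), "zero")
})

test_that("fwhm interpolates half-maximum crossings", {
  k <- seq(-60, 60)
  g <- exp(-k^2 / (2 * 10^2))
  expect_lt(abs(fwhm(g) - 2 * sqrt(2 * log(2)) * 10), 0.1)
  tri <- c(seq(0, 1, length.out = 11), seq(1, 0, length.out = 11)[-1])
  expect_equal(fwhm(tri), 10, tolerance = 1e-12)
  expect_equal(fwhm(5 * g, spacing = 2), 2 * fwhm(g), tolerance = 1e-12)
  expect_error(fwhm(seq(0, 1, 0.1)), "away from the ends")
  expect_error(fwhm(c(0.9, 1, 0.9)), "crossing")
})

test_that("evaluate_image composes the individual metrics", {
  set.seed(104)
  px <- matrix(0, 64, 64)
  px[30:34, 20:24] <- outer(exp(-(-2:2)^2 / 2), exp(-(-2:2)^2 / 2))
  px <- px + abs(matrix(rnorm(64 * 64, sd = 0.01), 64, 64))
  ref <- pa_image(px, 1e-4)
  est <- pa_image(px * 0.9 + 0.005, 1e-4)
  roi <- roi_spec(inside = c(28, 36, 18, 26), outside = c(45, 60, 45, 60))
  rep1 <- evaluate_image(ref, est, roi)
  expect_equal(rep1$ssim, ssim_global(ref, est))
  expect_equal(rep1$cnr_db, cnr(est, roi))
  expect_equal(rep1$psnr_db, psnr(ref$pixels, est$pixels))
  expect_equal(nrow(rep1$targets), 1L)
  expect_false(is.na(rep1$targets$fwhm_axial_m))
  ident <- evaluate_image(ref, ref, roi)
  expect_equal(ident$ssim, 1.0)
  # JSON round trip
  p <- file.path(tempdir(), "report.json")
  write_metrics_report(rep1, p)
  rep2 <- read_metrics_report(p)
  expect_equal(rep2$ssim, rep1$ssim)
  expect_equal(rep2$targets$fwhm_axial_m, rep1$targets$fwhm_axial_m)
})
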