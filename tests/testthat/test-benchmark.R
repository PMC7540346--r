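# Small-scale benchmark runs (96 px phantom) exercising the drivers; the
# full-scale study conditions live in test-acceptance.R.
mini_cfg <- function(...) {
  args <- utils::modifyList(
    list(phantom_size = 96L, n_repeats = 1L,
         snr_levels_db = c(5, -5), image_levels_db = c(5, 20),
         n_frames_for_average = 5L, seed = 9L),
    list(...))
  do.call(benchmark_config, args)
}

test_that("signal benchmark is reproducible and has the declared schema", {
  cfg <- mini_cfg(methods = c("lpfsc", "average"))
  t1 <- run_signal_benchmark(cfg)
  t2 <- run_signal_benchmark(cfg)
  expect_identical(t1, t2)
  expect_named(t1, c("method", "snr_db", "rep", "psnr_db"))
  expect_setequal(unique(t1$method), c("lpfsc", "average", "none"))
  expect_true(all(is.finite(t1$psnr_db)))
  # CSV round trip
  p <- file.path(tempdir(), "sig.csv")
  write.csv(t1, p, row.names = FALSE)
  expect_equal(read.csv(p), t1)
})

test_that("averaging PSNR gain matches the sqrt(K) closed form", {
  cfg <- mini_cfg(methods = "average", n_repeats = 2L)
  tab <- run_signal_benchmark(cfg)
  for (lv in unique(tab$snr_db)) {
    gain <- mean(tab$psnr_db[tab$method == "average" & tab$snr_db == lv]) -
      mean(tab$psnr_db[tab$method == "none" & tab$snr_db == lv])
    # MSE shrinks by K = 5; in the Smax/MSE convention that is 20 log10(5)
    expect_lt(abs(gain - 20 * log10(5)), 1)
  }
})

test_that("image benchmark produces valid scores on the common grid", {
  cfg <- mini_cfg(methods = c("lpfsc", "average"))
  tab <- run_image_benchmark(cfg)
  expect_named(tab, c("method", "snr_db", "rep", "ssim", "cnr_db"))
  expect_true(all(tab$ssim >= 0 & tab$ssim <= 1))
  expect_true(all(is.finite(tab$cnr_db)))
  # less noise cannot hurt either score for any method (2 levels here)
  for (m in unique(tab$method)) {
    s <- tab[tab$method == m, ]
    expect_gte(s$ssim[s$snr_db == 20], s$ssim[s$snr_db == 5] - 0.005)
  }
})

test_that("percent improvement aggregates per level then averages", {
  tab <- data.frame(method = rep(c("a", "b"), each = 4),
                    snr_db = rep(c(0, 0, 10, 10), 2),
                    rep = rep(1:2, 4),
                    psnr_db = c(11, 13, 22, 22, 10, 10, 20, 20))
  # level 0: (12 - 10)/10 = 20%; level 10: (22 - 20)/20 = 10%
  expect_equal(percent_improvement(tab, "a", "b"), 15)
})

test_that("frames sweep is seeded and monotone for averaging", {
  cfg <- benchmark_config(seed = 4L, methods = "lpfsc")
  t1 <- run_frames_sweep(cfg, n_frames_range = c(1L, 3L))
  t2 <- run_frames_sweep(cfg, n_frames_range = c(1L, 3L))
  expect_identical(t1, t2)
  expect_named(t1, c("method", "n_frames", "depth_mm", "cnr_db", "ssim"))
  avg <- t1[t1$method == "average", ]
  for (d in unique(avg$depth_mm)) {
    s <- avg[avg$depth_mm == d, ]
    expect_gte(s$cnr_db[s$n_frames == 3], s$cnr_db[s$n_frames == 1])
  }
})
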