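#' Benchmark configuration
#'
#' Controls the reproducible in-silico benchmarks.  Signal PSNR runs use
#' the four stated noise levels 10, 5, -5, -10 dB; image-quality runs use
#' 5, 10, 15, 20 dB.  Everything is derived deterministically from `seed`.
#'
#' @param snr_levels_db noise levels for the signal benchmark (dB).
#' @param image_levels_db noise levels for the image benchmark (dB).
#' @param methods subset of `c("lpfsc", "wavelet", "average")`.
#' @param n_frames_for_average frames averaged by the averaging baseline.
#' @param n_repeats independent noise draws per level.
#' @param seed master seed.
#' @param phantom_size vascular phantom edge in pixels.
#' @param phantom_seed seed of the vascular phantom.
#' @param lpfsc an [lpfsc_config()].
#' @param wavelet a [wavelet_config()].
#' @param sweep_snr_db single-frame SNR used by the frames sweep (dB).
#' @param mu_eff effective attenuation (1/m) of the tube-phantom tissue
#'   emulation used by the frames sweep.
#' @return Object of class `benchmark_config`.
#' @export
benchmark_config <- function(snr_levels_db = c(10, 5, -5, -10),
                             image_levels_db = c(5, 10, 15, 20),
                             methods = c("lpfsc", "wavelet", "average"),
                             n_frames_for_average = 20L,
                             n_repeats = 10L,
                             seed = 1L,
                             phantom_size = 512L,
                             phantom_seed = 7L,
                             lpfsc = lpfsc_config(),
                             wavelet = wavelet_config(),
                             sweep_snr_db = 0,
                             mu_eff = 100) {
  methods <- match.arg(methods, c("lpfsc", "wavelet", "average"),
                       several.ok = TRUE)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1")
  if (length(methods) == 0L) stop("`methods` must be nonempty")
  structure(list(snr_levels_db = snr_levels_db,
                 image_levels_db = image_levels_db, methods = methods,
                 n_frames_for_average = as.integer(n_frames_for_average),
                 n_repeats = n_repeats, seed = as.integer(seed),
                 phantom_size = as.integer(phantom_size),
                 phantom_seed = as.integer(phantom_seed),
                 lpfsc = lpfsc, wavelet = wavelet,
                 sweep_snr_db = sweep_snr_db, mu_eff = mu_eff),
            class = "benchmark_config")
}

# Clean vascular-phantom acquisition shared by the benchmarks, peak
# normalized so PSNR values are on the scale of unit-peak signals.
benchmark_clean_frame <- function(cfg, acq = acquisition_spec()) {
  ph <- make_vessel_phantom(cfg$phantom_size, cfg$phantom_seed)
  fr <- forward_simulate(ph, circular_array(), acq)
  rf_frame(fr$data / max(abs(fr$data)), fs = fr$fs, t0 = fr$t0)
}

denoise_by <- function(method, noisy, clean, cfg, level, rep) {
  switch(method,
         lpfsc = lpfsc_denoise_frame(noisy, cfg$lpfsc),
         wavelet = wavelet_denoise_frame(noisy, cfg$wavelet),
         average = frame_average(noisy_stack(
           clean, level, cfg$n_frames_for_average,
           derive_seed(cfg$seed, 211L, round(level * 10), rep))),
         none = noisy,
         stop("unknown method: ", method))
}

#' Signal-domain denoising benchmark
#'
#' For every (noise level, repeat, method): add calibrated white noise to
#' the clean simulated vascular-phantom frame, denoise, and record the
#' whole-frame PSNR against the clean frame.  The averaging method uses
#' `n_frames_for_average` independent noisy draws; the other methods see a
#' single frame.  Rows with method `"none"` record the noisy input.
#'
#' @param cfg a [benchmark_config()].
#' @param clean optionally a precomputed clean [rf_frame()] (to share the
#'   simulation across benchmarks).
#' @return A data frame with columns `method`, `snr_db`, `rep`, `psnr_db`.
#' @export
run_signal_benchmark <- function(cfg = benchmark_config(), clean = NULL) {
  if (is.null(clean)) clean <- benchmark_clean_frame(cfg)
  rows <- list()
  for (li in seq_along(cfg$snr_levels_db)) {
    level <- cfg$snr_levels_db[li]
    for (rep in seq_len(cfg$n_repeats)) {
      noisy <- add_noise(clean, level, derive_seed(cfg$seed, 101L, li, rep))
      for (method in c(cfg$methods, "none")) {
        den <- denoise_by(method, noisy, clean, cfg, level, rep)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, snr_db = level, rep = rep,
          psnr_db = psnr(clean$data, den$data))
      }
    }
  }
  do.call(rbind, rows)
}

#' Mean percent PSNR (or CNR/SSIM) improvement across noise levels
#'
#' Per level, repeat-averaged values of `method` and `baseline` are turned
#' into a percent improvement `100 * (m - b) / b`, then averaged across
#' levels.
#'
#' @param tab output of a benchmark run.
#' @param method,baseline method names present in `tab$method`.
#' @param value column to compare (default `"psnr_db"`).
#' @return Scalar percent improvement.
#' @export
percent_improvement <- function(tab, method, baseline, value = "psnr_db") {
  lv <- sort(unique(tab$snr_db))
  per_level <- vapply(lv, function(l) {
    m <- mean(tab[tab$method == method & tab$snr_db == l, value])
    b <- mean(tab[tab$method == baseline & tab$snr_db == l, value])
    100 * (m - b) / b
  }, numeric(1))
  mean(per_level)
}

# Fixed CNR ROIs derived from the clean reconstruction: target rectangle
# around the brightest pixel, background rectangle in the quietest corner.
benchmark_roi <- function(clean_img) {
  img <- clean_img$pixels
  ny <- nrow(img); nx <- ncol(img)
  pk <- which(img == max(img), arr.ind = TRUE)[1, ]
  hw <- 5L
  r1 <- max(1L, pk[1] - hw); r2 <- min(ny, pk[1] + hw)
  c1 <- max(1L, pk[2] - hw); c2 <- min(nx, pk[2] + hw)
  # candidate background rectangles at the four mid-edge positions, kept
  # inside the circular aperture (the grid corners are outside the ring)
  sz <- 18L
  cy <- (ny + 1L) %/% 2L; cx <- (nx + 1L) %/% 2L
  half <- sz %/% 2L
  edge <- 10L
  cands <- list(c(cy - half, cy + half, edge, edge + sz),
                c(cy - half, cy + half, nx - edge - sz, nx - edge),
                c(edge, edge + sz, cx - half, cx + half),
                c(ny - edge - sz, ny - edge, cx - half, cx + half))
  energy <- vapply(cands, function(r) mean(rect_pixels(img, r)), numeric(1))
  roi_spec(inside = list(c(r1, r2, c1, c2)),
           outside = cands[[which.min(energy)]])
}

#' Image-domain denoising benchmark
#'
#' For every (noise level, repeat, method): denoise the noisy frame,
#' reconstruct a DAS image, and score it against the clean-signal
#' reconstruction with global SSIM and CNR (fixed ROIs derived from the
#' clean reconstruction).
#'
#' @inheritParams run_signal_benchmark
#' @param grid a [recon_grid()].
#' @return A data frame with columns `method`, `snr_db`, `rep`, `ssim`,
#'   `cnr_db`.
#' @export
run_image_benchmark <- function(cfg = benchmark_config(), clean = NULL,
                                grid = recon_grid()) {
  if (is.null(clean)) clean <- benchmark_clean_frame(cfg)
  geom <- circular_array()
  clean_img <- das_reconstruct(clean, geom, grid)
  roi <- benchmark_roi(clean_img)
  rows <- list()
  for (li in seq_along(cfg$image_levels_db)) {
    level <- cfg$image_levels_db[li]
    for (rep in seq_len(cfg$n_repeats)) {
      noisy <- add_noise(clean, level, derive_seed(cfg$seed, 151L, li, rep))
      for (method in c(cfg$methods, "none")) {
        den <- denoise_by(method, noisy, clean, cfg, level, rep)
        img <- das_reconstruct(den, geom, grid)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, snr_db = level, rep = rep,
          ssim = ssim_global(clean_img, img),
          cnr_db = cnr(img, roi))
      }
    }
  }
  do.call(rbind, rows)
}

#' Frames-versus-quality sweep on the tube phantom
#'
#' Emulates deep-tissue imaging with the three-tube phantom seen by a
#' phased array: for `n_frames` 1..7, the averaging baseline averages the
#' first `n` noisy frames, while LPFSC denoises that same average.  Both
#' are reconstructed and scored (global SSIM of the whole image, CNR per
#' tube depth) against the 10-frame-average reference reconstruction.
#'
#' @param cfg a [benchmark_config()]; `sweep_snr_db` sets the single-frame
#'   noise level and `mu_eff` the depth-dependent fluence decay.
#' @param n_frames_range numbers of averaged frames to test.
#' @return A data frame with columns `method`, `n_frames`, `depth_mm`,
#'   `cnr_db`, `ssim`.
#' @export
run_frames_sweep <- function(cfg = benchmark_config(),
                             n_frames_range = 1:7) {
  ph <- make_tube_phantom(mu_eff = cfg$mu_eff)
  geom <- phased_array()
  acq <- acquisition_spec(n_samples = 2048L)
  clean <- forward_simulate(ph, geom, acq)
  grid <- recon_grid(nx = 64L, ny = 128L, pixel_size = 0.2e-3,
                     origin = c(-6.3e-3, 0.5e-3))
  depths_mm <- c(10, 15, 20)
  # per-depth target ROIs (tube outer radius 0.5 mm -> 5 px at 0.2 mm/px)
  inside <- lapply(depths_mm, function(d) {
    row <- round((d * 1e-3 - grid$origin[2]) / grid$pixel_size) + 1L
    col <- round((0 - grid$origin[1]) / grid$pixel_size) + 1L
    c(row - 4L, row + 4L, col - 4L, col + 4L)
  })
  outside <- c(20L, 110L, 4L, 14L)  # lateral margin, away from the tubes
  rois <- lapply(inside, function(r) roi_spec(list(r), outside))
  draws <- lapply(seq_len(max(c(n_frames_range, 10L))), function(k)
    add_noise(clean, cfg$sweep_snr_db, derive_seed(cfg$seed, 311L, k)))
  ref_img <- das_reconstruct(frame_average(frame_stack(draws[1:10])),
                             geom, grid)
  rows <- list()
  for (n in n_frames_range) {
    avg <- frame_average(frame_stack(draws[seq_len(n)]))
    for (method in intersect(c("average", "lpfsc"), c(cfg$methods, "average"))) {
      den <- if (method == "lpfsc") lpfsc_denoise_frame(avg, cfg$lpfsc) else avg
      img <- das_reconstruct(den, geom, grid)
      s <- ssim_global(ref_img, img)
      for (di in seq_along(depths_mm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, n_frames = n, depth_mm = depths_mm[di],
          cnr_db = cnr(img, rois[[di]]), ssim = s)
      }
    }
  }
  do.call(rbind, rows)
}
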