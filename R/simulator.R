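#' Acquisition specification
#'
#' Sampling and emitted-pulse parameters of the simulated system.  Defaults
#' reproduce the in-silico setup: 1019 samples spaced 9.259 ns (108 MHz),
#' sound speed 1500 m/s, and a band-limited bipolar pulse (Gaussian
#' envelope times a sine at the center frequency, an N-shape-like waveform
#' that preserves the sparse-derivative structure of photoacoustic
#' signals) with center frequency 7.5 MHz and 70% fractional bandwidth,
#' matching a 4-11 MHz transducer band.
#'
#' @param fs sampling frequency (Hz).
#' @param n_samples samples per channel.
#' @param c sound speed (m/s).
#' @param pulse_f0 pulse center frequency (Hz).
#' @param pulse_bw fractional -6 dB bandwidth of the pulse.
#' @return Object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(fs = 1 / 9.259e-9, n_samples = 1019L, c = 1500,
                             pulse_f0 = 7.5e6, pulse_bw = 0.7) {
  if (fs <= 0 || n_samples < 2L || c <= 0 || pulse_f0 <= 0 || pulse_bw <= 0)
    stop("invalid acquisition parameters")
  structure(list(fs = fs, n_samples = as.integer(n_samples), c = c,
                 pulse_f0 = pulse_f0, pulse_bw = pulse_bw),
            class = "acquisition_spec")
}

# Sampled emitted pulse and the index of its t = 0 sample.
pa_pulse <- function(acq) {
  sigma <- sqrt(2 * log(2)) / (pi * acq$pulse_bw * acq$pulse_f0)
  k <- ceiling(4 * sigma * acq$fs)
  t <- (-k:k) / acq$fs
  p <- -sin(2 * pi * acq$pulse_f0 * t) * exp(-t^2 / (2 * sigma^2))
  p <- p / max(abs(p))
  list(p = p, center = k + 1L)
}

#' Synthetic vascular phantom
#'
#' Branching curvilinear absorbers (1-6 px wide random-walk vessels) on a
#' zero background, values in `[0, 1]`, on a 10-mm square grid.  The
#' structure is confined to the central region so that it fits inside the
#' default 9-mm circular array.  Deterministic for a fixed seed.
#'
#' @param size grid edge in pixels (`>= 64`, default 512).
#' @param seed RNG seed.
#' @return A [pa_phantom()].
#' @export
make_vessel_phantom <- function(size = 512L, seed = 1L) {
  size <- as.integer(size)
  if (size < 64L) stop("`size` must be >= 64")
  px <- 10e-3 / size
  img <- matrix(0, size, size)
  ctr <- (size + 1) / 2
  rmax <- 0.38 * size
  stamp <- function(img, r0, c0, w, val) {
    rad <- max(w / 2, 0.5)
    ir <- ceiling(rad)
    rows <- max(1L, floor(r0 - ir)):min(size, ceiling(r0 + ir))
    cols <- max(1L, floor(c0 - ir)):min(size, ceiling(c0 + ir))
    for (rr in rows) for (cc in cols)
      if ((rr - r0)^2 + (cc - c0)^2 <= rad^2 && img[rr, cc] < val)
        img[rr, cc] <- val
    img
  }
  with_seed(seed, {
    queue <- list()
    for (i in 1:3) {
      ang <- runif(1, 0, 2 * pi)
      r <- runif(1, 0, 0.2 * size)
      queue[[length(queue) + 1L]] <- list(
        r = ctr + r * sin(ang), c = ctr + r * cos(ang),
        theta = runif(1, 0, 2 * pi), w = runif(1, 3, 6),
        len = round(0.7 * size), val = runif(1, 0.6, 1))
    }
    n_drawn <- 0L
    while (length(queue) > 0L && n_drawn < 14L) {
      b <- queue[[1L]]; queue[[1L]] <- NULL
      n_drawn <- n_drawn + 1L
      r0 <- b$r; c0 <- b$c; th <- b$theta
      for (s in seq_len(b$len)) {
        img <- stamp(img, r0, c0, b$w, b$val)
        th <- th + rnorm(1, 0, 0.08)
        # steer back towards the center when close to the aperture
        dr <- sqrt((r0 - ctr)^2 + (c0 - ctr)^2)
        if (dr > 0.9 * rmax) {
          back <- atan2(ctr - r0, ctr - c0)
          th <- th + 0.25 * (((back - th + pi) %% (2 * pi)) - pi)
        }
        r0 <- r0 + sin(th); c0 <- c0 + cos(th)
        if (dr > rmax) break
        if (b$w > 1.5 && runif(1) < 0.012 && length(queue) < 12L) {
          queue[[length(queue) + 1L]] <- list(
            r = r0, c = c0,
            theta = th + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
            w = max(1, b$w * runif(1, 0.5, 0.75)),
            len = round(b$len * runif(1, 0.35, 0.6)), val = b$val)
        }
      }
    }
  })
  pa_phantom(img, pixel_size = px)
}

#' Filament phantom preset
#'
#' Two light-absorbing discs of 150 micrometer diameter with centers 1 mm
#' apart, centered in a 10-mm grid (the water-tank filament pair).
#'
#' @param size grid edge in pixels (default 512).
#' @return A [pa_phantom()].
#' @export
make_filament_phantom <- function(size = 512L) {
  size <- as.integer(size)
  px <- 10e-3 / size
  img <- matrix(0, size, size)
  ctr <- (size + 1) / 2
  rad <- 75e-6 / px
  off <- 0.5e-3 / px
  idx <- seq_len(size)
  for (s in c(-1, 1)) {
    c0 <- ctr + s * off
    d2 <- outer((idx - ctr)^2, (idx - c0)^2, "+")
    img[d2 <= rad^2] <- 1
  }
  pa_phantom(img, pixel_size = px)
}

#' Blood-filled tube phantom preset
#'
#' Three tube cross-sections (1 mm outer diameter rings, 0.15 mm wall) at
#' depths 10, 15 and 20 mm below a surface probe, on a 0.1 mm grid
#' (12.8 mm wide, 25.6 mm deep starting 0.5 mm below the array line).
#' Optionally applies an exponential depth decay `exp(-mu_eff * depth)` to
#' emulate fluence loss in tissue.
#'
#' @param mu_eff effective attenuation coefficient (1/m), default 0.
#' @return A [pa_phantom()].
#' @export
make_tube_phantom <- function(mu_eff = 0) {
  px <- 0.1e-3
  nx <- 128L
  ny <- 256L
  origin <- c(-(nx - 1) / 2 * px, 0.5e-3)
  img <- matrix(0, ny, nx)
  xs <- origin[1] + (seq_len(nx) - 1L) * px
  ys <- origin[2] + (seq_len(ny) - 1L) * px
  for (depth in c(10e-3, 15e-3, 20e-3)) {
    d2 <- outer((ys - depth)^2, xs^2, "+")
    ring <- d2 <= (0.5e-3)^2 & d2 >= (0.35e-3)^2
    img[ring] <- exp(-mu_eff * depth)
  }
  pa_phantom(img, pixel_size = px, origin = origin)
}

#' Analytic point-source forward model
#'
#' Each nonzero phantom pixel acts as a point source: it contributes
#' `pulse(t - r / c) * p0 / max(r, r_min)` to every element, with `r` the
#' pixel-element distance and `r_min` one pixel (2-D far-field spreading,
#' clipped to avoid the on-source singularity).  Arrivals are deposited at
#' fractional sample positions by linear interpolation and convolved with
#' the sampled pulse once per channel, so the model is exactly linear in
#' the phantom.
#'
#' @param phantom a [pa_phantom()].
#' @param geometry an [array_geometry()].
#' @param acq an [acquisition_spec()].
#' @param t0 time of the first recorded sample (s), default 0.
#' @return An [rf_frame()] of shape `n_samples x n_elements`.
#' @export
forward_simulate <- function(phantom, geometry, acq = acquisition_spec(),
                             t0 = 0) {
  if (!inherits(phantom, "pa_phantom")) stop("`phantom` must be a pa_phantom")
  if (!inherits(geometry, "array_geometry")) stop("`geometry` must be an array_geometry")
  n <- acq$n_samples
  nel <- geometry$n_elements
  nz <- which(phantom$p0 > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L)
    return(rf_frame(matrix(0, n, nel), fs = acq$fs, t0 = t0))
  co <- grid_coords(phantom)
  pxx <- co$x[nz[, 2]]
  pyy <- co$y[nz[, 1]]
  amp0 <- phantom$p0[nz]
  if (geometry$kind == "circular") {
    ring_r <- sqrt(sum(geometry$positions[1, ]^2))
    if (any(sqrt(pxx^2 + pyy^2) >= ring_r))
      stop("phantom does not fit inside the circular array aperture")
  }
  pl <- pa_pulse(acq)
  lp <- length(pl$p)
  nfft <- stats::nextn(n + lp, 2)
  pf <- fft(c(pl$p, numeric(nfft - lp)))
  r_min <- phantom$pixel_size
  out <- matrix(0, n, nel)
  c_snd <- phantom$c
  for (e in seq_len(nel)) {
    r <- sqrt((pxx - geometry$positions[e, 1])^2 +
              (pyy - geometry$positions[e, 2])^2)
    a <- amp0 / pmax(r, r_min)
    pos <- (r / c_snd - t0) * acq$fs + 1  # 1-based fractional sample
    i0 <- floor(pos)
    frac <- pos - i0
    train <- numeric(n + 1L)
    ok <- i0 >= 1 & i0 <= n
    if (any(ok)) {
      tr <- tapply(a[ok] * (1 - frac[ok]), i0[ok], sum)
      train[as.integer(names(tr))] <- train[as.integer(names(tr))] + tr
      tr2 <- tapply(a[ok] * frac[ok], i0[ok] + 1L, sum)
      train[as.integer(names(tr2))] <- train[as.integer(names(tr2))] + tr2
    }
    conv <- Re(fft(fft(c(train[seq_len(n)], numeric(nfft - n))) * pf,
                   inverse = TRUE)) / nfft
    out[, e] <- conv[pl$center:(pl$center + n - 1L)]
  }
  rf_frame(out, fs = acq$fs, t0 = t0)
}

#' Add calibrated white Gaussian noise to a frame
#'
#' Draws iid Gaussian noise with variance chosen so that
#' `10 * log10(P_signal / P_noise) = snr_db`, where `P_signal` is the mean
#' square over the whole frame.  Deterministic for a fixed seed.
#'
#' @param frame an [rf_frame()] with nonzero power.
#' @param snr_db target signal-to-noise ratio in dB (may be negative).
#' @param seed RNG seed.
#' @return A noisy [rf_frame()].
#' @export
add_noise <- function(frame, snr_db, seed = 1L) {
  if (!inherits(frame, "rf_frame")) stop("`frame` must be an rf_frame")
  if (!is.finite(snr_db)) stop("`snr_db` must be finite")
  p_sig <- mean(frame$data^2)
  if (p_sig == 0) stop("clean frame has zero power")
  sigma <- sqrt(p_sig * 10^(-snr_db / 10))
  w <- with_seed(seed,
                 matrix(rnorm(length(frame$data), sd = sigma),
                        nrow(frame$data), ncol(frame$data)))
  rf_frame(frame$data + w, fs = frame$fs, t0 = frame$t0)
}

#' Draw a stack of independently noisy copies of a clean frame
#'
#' @param frame clean [rf_frame()].
#' @param snr_db SNR level in dB.
#' @param n_frames number of draws.
#' @param seed base seed; draw `k` uses a seed derived from `(seed, k)`.
#' @return A [frame_stack()].
#' @export
noisy_stack <- function(frame, snr_db, n_frames, seed = 1L) {
  frames <- lapply(seq_len(n_frames), function(k)
    add_noise(frame, snr_db, derive_seed(seed, 811L, k)))
  frame_stack(frames, seed_info = list(seed = seed, snr_db = snr_db))
}

# Deterministic positive sub-seed derived from integer components.
derive_seed <- function(...) {
  v <- c(...)
  s <- 0
  for (x in v) s <- (s * 48271 + (as.numeric(x) %% 65536) + 17) %% 2147483647
  as.integer(s + 1)
}
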