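#' Frame averaging
#'
#' Elementwise arithmetic mean of a stack of identically shaped frames;
#' the classic photoacoustic noise-reduction baseline, with amplitude SNR
#' growing as the square root of the number of averaged frames.
#'
#' @param stack a [frame_stack()].
#' @return An [rf_frame()] holding the mean frame (fs/t0 preserved).
#' @export
frame_average <- function(stack) {
  if (!inherits(stack, "frame_stack")) stop("`stack` must be a frame_stack")
  acc <- stack$frames[[1]]$data
  k <- length(stack$frames)
  if (k > 1L) for (i in 2:k) acc <- acc + stack$frames[[i]]$data
  rf_frame(acc / k, fs = stack$frames[[1]]$fs, t0 = stack$frames[[1]]$t0)
}

# Symlet-6 orthogonal filter bank (12 taps, standard published constants).
SYM6_DEC_LO <- c(0.015404109327027373, 0.0034907120842174702,
                 -0.11799011114819057, -0.048311742585633,
                 0.4910559419267466, 0.787641141030194,
                 0.3379294217276218, -0.07263752278646252,
                 -0.021060292512300564, 0.04472490177066578,
                 0.0017677118642428036, -0.007800708325034148)
SYM6_DEC_HI <- rev(SYM6_DEC_LO) * rep_len(c(1, -1), 12L)
SYM6_REC_LO <- rev(SYM6_DEC_LO)
SYM6_REC_HI <- rev(SYM6_DEC_HI)

#' Wavelet shrinkage configuration
#'
#' Defaults follow common photoacoustic practice: Symlet-6 mother wavelet,
#' six decomposition levels, soft thresholding with per-level thresholds
#' chosen by Stein's Unbiased Risk Estimate (SURE).
#'
#' @param family wavelet family; only `"sym6"` is implemented.
#' @param levels decomposition depth (default 6).
#' @param rule threshold selection rule: `"sure"` (default) or `"none"`
#'   (no shrinkage; useful to verify perfect reconstruction).
#' @return Object of class `wavelet_config`.
#' @export
wavelet_config <- function(family = "sym6", levels = 6L, rule = "sure") {
  if (!identical(family, "sym6")) stop("unknown wavelet family: ", family)
  rule <- match.arg(rule, c("sure", "none"))
  levels <- as.integer(levels)
  if (levels < 1L) stop("`levels` must be >= 1")
  structure(list(family = family, levels = levels, rule = rule),
            class = "wavelet_config")
}

# Single-level DWT with symmetric (edge-repeating) boundary extension.
# The signal is extended by the full filter length on both sides, so every
# original sample lies in the exact-reconstruction interior of the
# orthonormal filter bank: the slightly redundant coefficient vectors
# (length ~ n/2 + L/2) invert exactly.  Analysis is correlation against the
# time-reversed decomposition filters, i.e. the orthonormal basis rows
# rec[j - 2i].
dwt_step <- function(x, lo = SYM6_REC_LO, hi = SYM6_REC_HI) {
  n <- length(x)
  L <- length(lo)
  P <- L
  ext <- c(x[pmin(n, P:1L)], x, x[pmax(1L, n:(n - P + 1L))])
  m <- (n + 2L * P - L) %/% 2L + 1L
  idx <- outer(2L * seq_len(m) - 1L, seq_len(L) - 1L, "+")
  ex <- matrix(ext[idx], m, L)
  list(a = as.vector(ex %*% lo), d = as.vector(ex %*% hi), n = n)
}

# Exact inverse of dwt_step on the interior: overlap-add the synthesis
# windows and drop the extension margins.
idwt_step <- function(a, d, n, lo = SYM6_REC_LO, hi = SYM6_REC_HI) {
  L <- length(lo)
  P <- L
  m <- length(a)
  y <- numeric(n + 2L * P + L)
  s <- 2L * seq_len(m) - 1L
  for (t in seq_len(L)) {
    pos <- s + t - 1L
    y[pos] <- y[pos] + a * lo[t] + d * hi[t]
  }
  y[(P + 1L):(P + n)]
}

# Multi-level decomposition: list(a = coarsest approx, d = list of detail
# vectors finest-first, n = original lengths per level).
wavedec <- function(x, levels) {
  d <- vector("list", levels)
  ns <- integer(levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    d[[j]] <- s$d
    ns[j] <- s$n
    a <- s$a
  }
  list(a = a, d = d, n = ns)
}

waverec <- function(dec) {
  a <- dec$a
  for (j in rev(seq_along(dec$d))) a <- idwt_step(a, dec$d[[j]], dec$n[j])
  a
}

# Minimizer of Stein's unbiased risk estimate for soft thresholding of
# coefficients d with noise level sigma.
sure_threshold <- function(d, sigma) {
  m <- length(d)
  if (m == 0L || sigma <= 0) return(0)
  ad <- sort(abs(d))
  cs <- cumsum(ad^2)
  # candidate t = ad[k]: risk = m*sigma^2 + sum(min(d^2, t^2)) - 2*sigma^2*#{|d|<=t}
  k <- seq_len(m)
  risk <- m * sigma^2 + (cs + (m - k) * ad^2) - 2 * sigma^2 * k
  risk0 <- m * sigma^2 + 0 - 0  # t = 0
  tmax <- sigma * sqrt(2 * log(m))  # universal threshold cap
  cand <- c(0, ad)
  risks <- c(risk0, risk)
  t <- cand[which.min(risks)]
  min(t, tmax)
}

#' Wavelet shrinkage denoising
#'
#' Decimated Symlet-6 transform with symmetric boundary extension; detail
#' coefficients at every level are soft-thresholded with a per-level SURE
#' threshold (noise level estimated from the finest details by
#' MAD / 0.6745), then the signal is reconstructed.
#'
#' @param x numeric vector with `length(x) >= 2^levels`.
#' @param cfg a [wavelet_config()].
#' @return Denoised vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, cfg = wavelet_config()) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("`x` must be finite")
  if (length(x) < 2^cfg$levels)
    stop("signal shorter than 2^levels (", 2^cfg$levels, ")")
  dec <- wavedec(x, cfg$levels)
  if (cfg$rule == "sure") {
    sigma <- median(abs(dec$d[[1]])) / 0.6745
    for (j in seq_along(dec$d)) {
      t <- sure_threshold(dec$d[[j]], sigma)
      dec$d[[j]] <- soft_threshold(dec$d[[j]], t)
    }
  }
  waverec(dec)
}

#' Denoise every channel of a frame with the wavelet baseline
#'
#' @param frame an [rf_frame()].
#' @param cfg a [wavelet_config()].
#' @return An [rf_frame()] of denoised channels.
#' @export
wavelet_denoise_frame <- function(frame, cfg = wavelet_config()) {
  if (!inherits(frame, "rf_frame")) stop("`frame` must be an rf_frame")
  out <- frame$data
  for (ch in seq_len(ncol(out))) out[, ch] <- wavelet_denoise(out[, ch], cfg)
  rf_frame(out, fs = frame$fs, t0 = frame$t0)
}
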