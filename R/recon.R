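#' Reconstruction grid
#'
#' Pixel grid for delay-and-sum imaging.  The default covers the 10-mm
#' field of view of the circular-array setup with 128 x 128 pixels,
#' centered on the origin.
#'
#' @param nx,ny grid size in pixels (lateral, axial).
#' @param pixel_size pixel edge (m).
#' @param origin `(x, y)` of the center of pixel `(0, 0)` (m); `NULL`
#'   centers the grid on the origin.
#' @return Object of class `recon_grid`.
#' @export
recon_grid <- function(nx = 128L, ny = 128L, pixel_size = 10e-3 / 128,
                       origin = NULL) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 2L || pixel_size <= 0) stop("invalid grid")
  if (is.null(origin))
    origin <- c(-(nx - 1) / 2, -(ny - 1) / 2) * pixel_size
  structure(list(nx = nx, ny = ny, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "recon_grid")
}

#' Envelope of an RF signal
#'
#' Magnitude of the analytic signal (Hilbert-transform method): the
#' one-sided spectrum is doubled and inverse-transformed, and the modulus
#' returned.  For a pure tone the result is flat at the tone amplitude.
#'
#' @param signal numeric vector, length at least 4.
#' @return Nonnegative vector of the same length, pointwise `>= |signal|`
#'   up to roundoff.
#' @export
envelope <- function(signal) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 4L) stop("signal too short for envelope detection")
  if (!all(is.finite(signal))) stop("signal must be finite")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(fft(fft(signal) * h, inverse = TRUE) / n)
}

# namespace-resolved alias so the `envelope` argument of das_reconstruct
# does not shadow the function
.envelope_vec <- function(x) envelope(x)

#' Delay-and-sum image reconstruction
#'
#' Conventional DAS: every pixel sums, over all elements, the RF sample at
#' the one-way time of flight `||pixel - element|| / c` (linear
#' interpolation between samples; delays beyond the recorded window
#' contribute zero), with uniform element weighting.  The summed image is
#' then envelope-detected along the depth (row) direction and peak
#' normalized to `[0, 1]`; both steps can be disabled to access the raw
#' linear beamformed output.  For circular arrays, pixels on or outside
#' the ring are set to zero: a full ring back-projects a mirror artifact
#' of every source outside the aperture, so only the interior is a valid
#' image region.
#'
#' @param frame an [rf_frame()].
#' @param geometry an [array_geometry()] with as many elements as the
#'   frame has channels.
#' @param grid a [recon_grid()].
#' @param c sound speed (m/s).
#' @param envelope apply per-column envelope detection (default `TRUE`).
#' @param normalize peak-normalize to `[0, 1]` (default `TRUE`).
#' @return A [pa_image()].
#' @export
das_reconstruct <- function(frame, geometry, grid = recon_grid(), c = 1500,
                            envelope = TRUE, normalize = TRUE) {
  if (!inherits(frame, "rf_frame")) stop("`frame` must be an rf_frame")
  if (geometry$n_elements != ncol(frame$data))
    stop("geometry has ", geometry$n_elements, " elements but frame has ",
         ncol(frame$data), " channels")
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1L) * grid$pixel_size
  ys <- grid$origin[2] + (seq_len(grid$ny) - 1L) * grid$pixel_size
  px <- rep(xs, each = grid$ny)
  py <- rep(ys, times = grid$nx)
  n <- nrow(frame$data)
  # For the full ring, envelope detection must happen per channel, not per
  # image column: the ring has no preferred depth axis, and delaying the
  # real-valued bipolar traces makes the +/- lags cancel at the source.
  # Complex (analytic-signal) delay-and-sum is the ring-array realization
  # of "DAS followed by envelope detection".
  complex_das <- envelope && geometry$kind == "circular"
  rf <- if (complex_das) {
    apply(frame$data, 2, function(s) {
      h <- numeric(n)
      if (n %% 2L == 0L) { h[c(1L, n / 2 + 1L)] <- 1; h[2:(n / 2)] <- 2 }
      else { h[1L] <- 1; h[2:((n + 1L) / 2)] <- 2 }
      fft(fft(s) * h, inverse = TRUE) / n
    })
  } else frame$data
  acc <- if (complex_das) complex(real = numeric(grid$ny * grid$nx))
         else numeric(grid$ny * grid$nx)
  for (e in seq_len(geometry$n_elements)) {
    r <- sqrt((px - geometry$positions[e, 1])^2 +
              (py - geometry$positions[e, 2])^2)
    pos <- (r / c - frame$t0) * frame$fs + 1
    i0 <- floor(pos)
    frac <- pos - i0
    ok <- i0 >= 1 & i0 < n
    v <- acc * 0
    ch <- rf[, e]
    v[ok] <- ch[i0[ok]] * (1 - frac[ok]) + ch[i0[ok] + 1L] * frac[ok]
    acc <- acc + v
  }
  img <- matrix(if (complex_das) Mod(acc) else acc, grid$ny, grid$nx)
  if (envelope && !complex_das) img <- apply(img, 2, .envelope_vec)
  if (geometry$kind == "circular") {
    # a full ring back-projects mirror artifacts outside the aperture;
    # only the interior of the ring is a valid image region
    ring_r <- sqrt(sum(geometry$positions[1, ]^2))
    img[matrix(px^2 + py^2, grid$ny, grid$nx) >= ring_r^2] <- 0
  }
  if (normalize) {
    m <- max(abs(img))
    if (m > 0) img <- img / m
  }
  pa_image(img, pixel_size = grid$pixel_size, origin = grid$origin)
}

#' Export a reconstructed image
#'
#' Writes the pixel matrix either as a 16-bit grayscale TIFF (values
#' clipped to `[0, 1]`; requires the `tiff` package) or as a raw numeric
#' CSV matrix, chosen by the file extension.
#'
#' @param image a [pa_image()].
#' @param path destination ending in `.tif`/`.tiff` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_pa_image <- function(image, path) {
  if (!inherits(image, "pa_image")) stop("`image` must be a pa_image")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("TIFF export needs the `tiff` package")
    tiff::writeTIFF(pmin(pmax(image$pixels, 0), 1), path,
                    bits.per.sample = 16L)
  } else if (ext == "csv") {
    utils::write.table(image$pixels, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else stop("unsupported extension: ", ext)
  invisible(path)
}
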