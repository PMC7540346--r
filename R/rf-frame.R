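#' Radio-frequency acquisition frame
#'
#' An `rf_frame` holds one multi-channel photoacoustic acquisition: a
#' samples-by-channels matrix of pressure readings (arbitrary linear units)
#' together with the sampling frequency and the time of the first sample.
#' Sample `k` (0-based) of every channel was recorded at `t0 + k / fs`
#' seconds after the laser firing.
#'
#' @param data numeric matrix, `n_samples x n_channels`, all finite,
#'   `n_samples >= 2`.
#' @param fs sampling frequency in Hz (`> 0`).
#' @param t0 time of the first sample in seconds (default 0, laser firing).
#' @return An object of class `rf_frame` with fields `data`, `fs`, `t0`.
#' @examples
#' f <- rf_frame(matrix(rnorm(40), 20, 2), fs = 108e6)
#' dim(f$data)
#' @export
rf_frame <- function(data, fs, t0 = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be numeric")
  if (nrow(data) < 2L) stop("an RF frame needs at least 2 samples")
  if (ncol(data) < 1L) stop("an RF frame needs at least 1 channel")
  if (!all(is.finite(data))) stop("`data` must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a finite scalar (s)")
  structure(list(data = unname(data), fs = as.numeric(fs), t0 = as.numeric(t0)),
            class = "rf_frame")
}

#' @method print rf_frame
#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d channels, fs = %.4g MHz, t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs / 1e6, x$t0))
  invisible(x)
}

#' @export
dim.rf_frame <- function(x) dim(x$data)

#' Ordered stack of identically shaped RF frames
#'
#' Used for frame averaging: all frames must share dimensions and sampling
#' frequency.
#'
#' @param frames list of [rf_frame()] objects (at least one).
#' @param seed_info optional named list recording how the frames were drawn.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, seed_info = NULL) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of rf_frame objects")
  ok <- vapply(frames, inherits, logical(1), "rf_frame")
  if (!all(ok)) stop("all elements must be rf_frame objects")
  d <- dim(frames[[1]]$data)
  fs <- frames[[1]]$fs
  for (f in frames) {
    if (!identical(dim(f$data), d)) stop("frames differ in shape")
    if (f$fs != fs) stop("frames differ in sampling frequency")
  }
  structure(list(frames = frames, seed_info = seed_info), class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Write an RF frame to disk
#'
#' The on-disk container is a raw little-endian 64-bit float matrix in
#' column-major order (`<path>`) plus a JSON sidecar (`<path>.json`) holding
#' `fs`, `t0`, `shape` and `units`.  Identical frames produce byte-identical
#' files, so archived acquisitions can be compared by checksum.
#'
#' @param frame an [rf_frame()].
#' @param path destination file; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @seealso [read_rf()]
#' @export
write_rf <- function(frame, path) {
  if (!inherits(frame, "rf_frame")) frame <- rf_frame(frame$data, frame$fs, frame$t0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(frame$data), con, size = 8L, endian = "little")
  # fs/t0 serialized as %.17g strings so the doubles round-trip bit-exactly
  meta <- list(format = "lpfsc-rf-v1",
               fs = sprintf("%.17g", frame$fs),
               t0 = sprintf("%.17g", frame$t0),
               shape = dim(frame$data),
               units = "arbitrary", order = "column-major",
               dtype = "float64-le")
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' Read an RF frame written by [write_rf()]
#'
#' @param path file written by [write_rf()].
#' @return The reconstructed [rf_frame()]; the numeric payload round-trips
#'   bit-exactly.
#' @export
read_rf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing metadata sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs) || is.null(meta$shape))
    stop("malformed sidecar: needs `fs` and `shape`")
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  con <- file(path, "rb")
  on.exit(close(con))
  payload <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
  if (length(payload) != n) stop("payload size does not match sidecar shape")
  rf_frame(matrix(payload, shape[1], shape[2]), fs = as.numeric(meta$fs),
           t0 = as.numeric(meta$t0 %||% 0))
}
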