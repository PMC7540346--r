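#' Transducer array geometries
#'
#' Element positions are 2-D coordinates in meters, `x` lateral and `y`
#' axial (depth).  The circular preset encircles the origin; linear and
#' phased arrays lie on the line `y = y0` and look towards positive `y`.
#'
#' @param kind one of `"circular"`, `"linear"`, `"phased"`.
#' @param positions numeric matrix `n_elements x 2` of element centers (m).
#' @return Object of class `array_geometry` with fields `kind`, `positions`,
#'   `n_elements`.
#' @export
array_geometry <- function(kind, positions) {
  kind <- match.arg(kind, c("circular", "linear", "phased"))
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 1L)
    stop("`positions` must be an n x 2 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  structure(list(kind = kind, positions = unname(positions),
                 n_elements = nrow(positions)),
            class = "array_geometry")
}

#' @method print array_geometry
#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> %s, %d elements\n", x$kind, x$n_elements))
  invisible(x)
}

#' Circular array preset
#'
#' Evenly spaced ring of point detectors around the origin.  The default is
#' the 60-element, 9-mm-diameter ring used by the in-silico studies
#' (adjacent angular spacing 6 degrees).
#'
#' @param n_elements number of elements.
#' @param diameter ring diameter in meters.
#' @return An `array_geometry` of kind `"circular"`.
#' @export
circular_array <- function(n_elements = 60L, diameter = 9e-3) {
  theta <- 2 * pi * (seq_len(n_elements) - 1L) / n_elements
  r <- diameter / 2
  array_geometry("circular", cbind(r * cos(theta), r * sin(theta)))
}

#' Linear array preset
#'
#' @param n_elements number of elements.
#' @param pitch element spacing (m).
#' @param y0 axial position of the element line (m).
#' @return An `array_geometry` of kind `"linear"`.
#' @export
linear_array <- function(n_elements = 128L, pitch = 0.3e-3, y0 = 0) {
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  array_geometry("linear", cbind(x, rep(y0, n_elements)))
}

#' Phased array preset
#'
#' Small-aperture sector probe; default matches a 64-element, 9-mm active
#' aperture endoscopic transducer.
#'
#' @param n_elements number of elements.
#' @param aperture total aperture length (m).
#' @param y0 axial position of the element line (m).
#' @return An `array_geometry` of kind `"phased"`.
#' @export
phased_array <- function(n_elements = 64L, aperture = 9e-3, y0 = 0) {
  pitch <- aperture / (n_elements - 1)
  x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  array_geometry("phased", cbind(x, rep(y0, n_elements)))
}

#' Initial-pressure phantom
#'
#' A nonnegative image of initial pressure on a square pixel grid, plus the
#' physical pixel size, homogeneous sound speed and the position of the
#' center of pixel `(0, 0)` (row 0 = smallest `y`, column 0 = smallest `x`).
#'
#' @param p0 nonnegative numeric matrix (rows index `y`/depth, columns `x`).
#' @param pixel_size pixel edge length (m).
#' @param c sound speed (m/s), default 1500.
#' @param origin length-2 numeric, `(x, y)` of the center of pixel `(0, 0)`
#'   in meters.  Default centers the grid on the origin.
#' @return Object of class `pa_phantom`.
#' @export
pa_phantom <- function(p0, pixel_size, c = 1500, origin = NULL) {
  p0 <- as.matrix(p0)
  if (any(!is.finite(p0)) || any(p0 < 0)) stop("`p0` must be finite and >= 0")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  if (c <= 0) stop("sound speed must be positive")
  if (is.null(origin))
    origin <- c(-(ncol(p0) - 1) / 2, -(nrow(p0) - 1) / 2) * pixel_size
  structure(list(p0 = unname(p0), pixel_size = pixel_size, c = c,
                 origin = as.numeric(origin)),
            class = "pa_phantom")
}

#' @method print pa_phantom
#' @export
print.pa_phantom <- function(x, ...) {
  cat(sprintf("<pa_phantom> %d x %d px, %.3g mm/px, c = %g m/s\n",
              nrow(x$p0), ncol(x$p0), x$pixel_size * 1e3, x$c))
  invisible(x)
}

#' Reconstructed photoacoustic image
#'
#' @param pixels numeric matrix of finite pixel values (rows index depth
#'   `y`, columns lateral `x`).
#' @param pixel_size pixel edge length (m).
#' @param origin `(x, y)` of the center of pixel `(0, 0)` (m); default
#'   centers the grid.
#' @return Object of class `pa_image`.
#' @export
pa_image <- function(pixels, pixel_size, origin = NULL) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (is.null(origin))
    origin <- c(-(ncol(pixels) - 1) / 2, -(nrow(pixels) - 1) / 2) * pixel_size
  structure(list(pixels = unname(pixels), pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "pa_image")
}

#' @method print pa_image
#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("<pa_image> %d x %d px, %.3g mm/px\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size * 1e3))
  invisible(x)
}

# Pixel-center coordinates of a phantom or image grid.
grid_coords <- function(obj) {
  nr <- nrow(obj$p0 %||% obj$pixels)
  nc <- ncol(obj$p0 %||% obj$pixels)
  list(x = obj$origin[1] + (seq_len(nc) - 1L) * obj$pixel_size,
       y = obj$origin[2] + (seq_len(nr) - 1L) * obj$pixel_size)
}
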