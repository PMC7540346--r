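#' Peak signal-to-noise ratio of a denoised signal
#'
#' `Smax` is the maximum absolute value of the reference and `MSE` the mean
#' squared difference.  Two decibel conventions are available:
#' `"as_printed"` computes `20 * log10(Smax / MSE)` (the form commonly
#' printed in the photoacoustic denoising literature), `"rmse"` the
#' standard `20 * log10(Smax / sqrt(MSE))`.
#'
#' @param reference clean signal (numeric vector or matrix).
#' @param estimate denoised signal, same shape.
#' @param convention `"as_printed"` (default) or `"rmse"`.
#' @return PSNR in dB; `Inf` if the inputs are identical.
#' @export
psnr <- function(reference, estimate, convention = c("as_printed", "rmse")) {
  convention <- match.arg(convention)
  reference <- as.numeric(reference); estimate <- as.numeric(estimate)
  if (length(reference) != length(estimate)) stop("length mismatch")
  mse <- mean((reference - estimate)^2)
  if (mse == 0) return(Inf)
  smax <- max(abs(reference))
  if (convention == "as_printed") 20 * log10(smax / mse)
  else 20 * log10(smax / sqrt(mse))
}

#' Global structural similarity index
#'
#' Single-statistic SSIM computed from the global means, variances and
#' covariance of the two images (not the windowed variant):
#' `((2 mu_r mu_e + c1) (2 cov + c2)) / ((mu_r^2 + mu_e^2 + c1)
#' (var_r + var_e + c2))`.  By default `c1 = (0.01 L)^2`,
#' `c2 = (0.03 L)^2` with `L` the dynamic range of the reference.
#'
#' @param reference reference image (matrix or [pa_image()]).
#' @param estimate estimated image, same shape.
#' @param c1,c2 stabilization constants (`> 0`); `NULL` for the defaults.
#' @return SSIM value in `[-1, 1]`; 1 exactly when the images are identical.
#' @export
ssim_global <- function(reference, estimate, c1 = NULL, c2 = NULL) {
  a <- if (inherits(reference, "pa_image")) reference$pixels else as.matrix(reference)
  b <- if (inherits(estimate, "pa_image")) estimate$pixels else as.matrix(estimate)
  if (!identical(dim(a), dim(b))) stop("image shape mismatch")
  L <- diff(range(a))
  if (is.null(c1)) c1 <- (0.01 * max(L, .Machine$double.eps))^2
  if (is.null(c2)) c2 <- (0.03 * max(L, .Machine$double.eps))^2
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")
  n <- length(a)
  mu_a <- mean(a); mu_b <- mean(b)
  va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
  cab <- mean((a - mu_a) * (b - mu_b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

#' Region-of-interest specification for CNR
#'
#' Rectangles are given in 1-based pixel coordinates as
#' `c(row_min, row_max, col_min, col_max)` (rows index depth).  The inside
#' rectangles cover the targets; the outside rectangle defines the
#' background.  Inside and outside must be disjoint.
#'
#' @param inside a rectangle or list of rectangles covering the target(s).
#' @param outside a single background rectangle.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(inside, outside) {
  if (!is.list(inside)) inside <- list(inside)
  chk <- function(r) {
    r <- as.integer(r)
    if (length(r) != 4L || r[1] > r[2] || r[3] > r[4] || any(r < 1L))
      stop("rectangle must be c(row_min, row_max, col_min, col_max), 1-based")
    r
  }
  inside <- lapply(inside, chk)
  outside <- chk(outside)
  for (r in inside) {
    if (r[1] <= outside[2] && outside[1] <= r[2] &&
        r[3] <= outside[4] && outside[3] <= r[4])
      stop("inside and outside rectangles must be disjoint")
  }
  structure(list(inside = inside, outside = outside), class = "roi_spec")
}

rect_pixels <- function(img, r) {
  if (r[2] > nrow(img) || r[4] > ncol(img))
    stop("ROI rectangle outside the image bounds")
  img[r[1]:r[2], r[3]:r[4]]
}

#' Contrast-to-noise ratio of an image
#'
#' `20 * log10(|Si - So| / sd(outside))` where `Si` and `So` are the mean
#' intensities inside and outside the target ROIs.
#'
#' @param image matrix or [pa_image()].
#' @param roi an [roi_spec()].
#' @return CNR in dB; `-Inf` when the means coincide.
#' @export
cnr <- function(image, roi) {
  img <- if (inherits(image, "pa_image")) image$pixels else as.matrix(image)
  if (!inherits(roi, "roi_spec")) stop("`roi` must be an roi_spec")
  si <- mean(unlist(lapply(roi$inside, function(r) rect_pixels(img, r))))
  bg <- rect_pixels(img, roi$outside)
  so <- mean(bg)
  sdo <- sd(as.vector(bg))
  if (sdo == 0) stop("background standard deviation is zero")
  if (si == so) return(-Inf)
  20 * log10(abs(si - so) / sdo)
}

#' Full width at half maximum of a profile
#'
#' Width between the two half-maximum crossings nearest the (unique,
#' interior) global peak, with linear interpolation between samples.
#'
#' @param profile numeric vector with its global maximum away from the ends.
#' @param spacing sample spacing (m, or any unit); the width is returned in
#'   the same unit.
#' @return FWHM in units of `spacing`.
#' @export
fwhm <- function(profile, spacing = 1) {
  profile <- as.numeric(profile)
  n <- length(profile)
  k <- which.max(profile)
  if (k == 1L || k == n) stop("profile peak must lie away from the ends")
  half <- profile[k] / 2
  left <- NA_real_
  for (i in seq(k - 1L, 1L)) {
    if (profile[i] <= half) {
      left <- i + (half - profile[i]) / (profile[i + 1L] - profile[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(k + 1L, n)) {
    if (profile[i] <= half) {
      right <- i - (half - profile[i]) / (profile[i - 1L] - profile[i])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("no half-maximum crossing on one side of the peak")
  (right - left) * spacing
}

#' Image quality report
#'
#' Bundles global SSIM, CNR and per-target axial/lateral FWHM (profiles cut
#' through each target's peak in the depth and lateral directions).
#'
#' @param reference reference [pa_image()].
#' @param estimate estimated [pa_image()], same grid.
#' @param roi an [roi_spec()]; each inside rectangle is one target.
#' @param psnr_convention passed through to [psnr()] on the flattened
#'   images.
#' @return Object of class `metrics_report`: a list with scalars `ssim`,
#'   `cnr_db`, `psnr_db` and a data frame `targets` with columns `target`,
#'   `fwhm_axial_m`, `fwhm_lateral_m`.
#' @export
evaluate_image <- function(reference, estimate, roi,
                           psnr_convention = "as_printed") {
  if (!inherits(reference, "pa_image") || !inherits(estimate, "pa_image"))
    stop("`reference` and `estimate` must be pa_image objects")
  if (!identical(dim(reference$pixels), dim(estimate$pixels)))
    stop("image shape mismatch")
  est <- estimate$pixels
  targets <- lapply(seq_along(roi$inside), function(i) {
    r <- roi$inside[[i]]
    sub <- rect_pixels(est, r)
    pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    prow <- r[1] + pk[1] - 1L
    pcol <- r[3] + pk[2] - 1L
    # profiles restricted to a window of twice the ROI extent around the
    # target, so neighbouring targets on the same cut do not steal the peak
    hh <- r[2] - r[1] + 1L
    ww <- r[4] - r[3] + 1L
    rows <- max(1L, r[1] - hh):min(nrow(est), r[2] + hh)
    cols <- max(1L, r[3] - ww):min(ncol(est), r[4] + ww)
    ax <- tryCatch(fwhm(est[rows, pcol], estimate$pixel_size),
                   error = function(e) NA_real_)
    lat <- tryCatch(fwhm(est[prow, cols], estimate$pixel_size),
                    error = function(e) NA_real_)
    data.frame(target = i, fwhm_axial_m = ax, fwhm_lateral_m = lat)
  })
  structure(list(ssim = ssim_global(reference, estimate),
                 cnr_db = cnr(estimate, roi),
                 psnr_db = psnr(reference$pixels, estimate$pixels,
                                psnr_convention),
                 targets = do.call(rbind, targets)),
            class = "metrics_report")
}

#' @method print metrics_report
#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ssim = %.4f, cnr = %.2f dB, psnr = %.2f dB\n",
              x$ssim, x$cnr_db, x$psnr_db))
  print(x$targets)
  invisible(x)
}

#' Write / read a metrics report (JSON)
#' @param report a `metrics_report`.
#' @param path file path.
#' @return `write_metrics_report` returns `path` invisibly;
#'   `read_metrics_report` the reconstructed report.
#' @export
write_metrics_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), dataframe = "columns",
                              auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' @rdname write_metrics_report
#' @export
read_metrics_report <- function(path) {
  v <- jsonlite::fromJSON(path)
  structure(list(ssim = v$ssim, cnr_db = v$cnr_db, psnr_db = v$psnr_db,
                 targets = as.data.frame(v$targets)),
            class = "metrics_report")
}
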