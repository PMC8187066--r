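# Image-quality metrics for scoring reconstructions against ground truth.

as_pixel_matrix <- function(x) {
  if (inherits(x, "phantom_image")) x$pixels else x
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(N * MAX_I^2 / ||X - Xhat||^2)` in dB, with `MAX_I` the
#' maximum pixel value of the ground-truth image and N its pixel count;
#' algebraically identical to the conventional
#' `10 log10(MAX_I^2 / MSE)`. Identical images return `Inf`.
#'
#' @param x_true ground-truth image (matrix or [phantom_image()]).
#' @param x_hat reconstructed image of the same shape.
#' @return PSNR in dB.
#' @export
psnr <- function(x_true, x_hat) {
  xt <- as_pixel_matrix(x_true)
  xh <- as_pixel_matrix(x_hat)
  if (!identical(dim(xt), dim(xh))) stop_invalid("image shapes differ")
  if (sum(xt^2) == 0) stop_invalid("reference image is identically zero")
  err2 <- sum((xt - xh)^2)
  if (err2 == 0) return(Inf)
  10 * log10(length(xt) * max(xt)^2 / err2)
}

#' Normalized reconstruction error (percent)
#'
#' `NMAE = 100 * ||Xhat - X||_2 / ||X||_2`. Despite the conventional
#' "mean absolute error" reading of the acronym, this is a relative
#' 2-norm error on a percent scale — the formula is implemented as
#' printed in the field's quality tables.
#'
#' @inheritParams psnr
#' @return nonnegative percent-scale error.
#' @export
nmae <- function(x_true, x_hat) {
  xt <- as_pixel_matrix(x_true)
  xh <- as_pixel_matrix(x_hat)
  if (!identical(dim(xt), dim(xh))) stop_invalid("image shapes differ")
  nt <- sqrt(sum(xt^2))
  if (nt == 0) stop_invalid("reference image is identically zero")
  100 * sqrt(sum((xh - xt)^2)) / nt
}

#' Quality report for a reconstruction
#'
#' @inheritParams psnr
#' @return list with `psnr_db`, `nmae`, `n_pixels`, `max_intensity`.
#' @export
quality_report <- function(x_true, x_hat) {
  xt <- as_pixel_matrix(x_true)
  list(psnr_db = psnr(x_true, x_hat), nmae = nmae(x_true, x_hat),
       n_pixels = length(xt), max_intensity = max(xt))
}
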