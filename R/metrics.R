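# Evaluation metrics: NRMSE over a region and PSNR.

#' Foreground evaluation region from ground-truth maps
#'
#' The region over which map errors are summarized: pixels whose |S0|
#' exceeds `threshold` times the maximum |S0|. With `threshold = 0` this is
#' the nonzero-S0 support.
#'
#' @param gt_maps a `parameter_maps` object.
#' @param threshold relative |S0| cutoff in (0, 1); default 0.05.
#' @return logical H x W matrix (the region), guaranteed non-empty.
#' @export
make_region <- function(gt_maps, threshold = 0.05) {
  stopifnot(inherits(gt_maps, "parameter_maps"))
  mag <- s0_magnitude(gt_maps)
  region <- mag > threshold * max(mag)
  if (!any(region)) stop("evaluation region is empty")
  region
}

#' Normalized root mean squared error over a region
#'
#' `||x - y|| / ||x||` with both L2 norms restricted to `region`; `x` is
#' the ground truth (it alone sets the denominator). Returned as a
#' fraction; multiply by 100 for the percent convention used in results
#' tables.
#'
#' @param x_gt ground-truth matrix.
#' @param y_est estimate, same shape.
#' @param region logical matrix; default all pixels.
#' @return non-negative scalar (fraction, not percent).
#' @export
nrmse <- function(x_gt, y_est, region = NULL) {
  if (!identical(dim(x_gt), dim(y_est))) stop("shape mismatch")
  if (is.null(region)) region <- array(TRUE, dim = dim(x_gt))
  gt <- x_gt[region]; est <- y_est[region]
  denom <- sqrt(sum(Mod(gt)^2))
  if (denom == 0) stop("ground truth has zero norm over the region")
  sqrt(sum(Mod(gt - est)^2)) / denom
}

#' Peak signal-to-noise ratio over a region
#'
#' `10 log10(L^2 / MSE)` with the mean squared error taken over `region`
#' and the peak `L` defaulting to the ground-truth maximum over the
#' region (the conventional definition; a literal sum-of-squares variant is
#' available for sensitivity checks via `mse = FALSE`). Identical images
#' return `Inf`.
#'
#' @param x_gt ground-truth matrix (magnitude image).
#' @param y_est estimate, same shape.
#' @param region logical matrix; default all pixels.
#' @param peak the peak intensity L; default `max(x_gt[region])`.
#' @param mse if `TRUE` (default) divide by the mean squared error; if
#'   `FALSE` divide by the summed squared error.
#' @return PSNR in dB.
#' @export
psnr <- function(x_gt, y_est, region = NULL, peak = NULL, mse = TRUE) {
  if (!identical(dim(x_gt), dim(y_est))) stop("shape mismatch")
  if (is.null(region)) region <- array(TRUE, dim = dim(x_gt))
  err2 <- Mod(x_gt[region] - y_est[region])^2
  if (is.null(peak)) peak <- max(Mod(x_gt[region]))
  denom <- if (mse) mean(err2) else sum(err2)
  if (denom == 0) return(Inf)
  10 * log10(peak^2 / denom)
}

#' Summarize map errors for one slice
#'
#' T2 NRMSE on the T2 map and S0 NRMSE on the complex S0 magnitude, both
#' over the same foreground region, in percent.
#'
#' @param est,gt `parameter_maps` (estimate and ground truth).
#' @param region logical region; default [make_region()] of the ground truth.
#' @return tibble with columns `parameter`, `nrmse_pct`.
#' @export
map_errors <- function(est, gt, region = NULL) {
  if (is.null(region)) region <- make_region(gt)
  tibble::tibble(
    parameter = c("T2", "S0"),
    nrmse_pct = 100 * c(nrmse(gt$t2, est$t2, region),
                        nrmse(s0_magnitude(gt), s0_magnitude(est), region)))
}
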