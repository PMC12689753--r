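# Classical least-squares parameter estimation (LSF).
#
# Complex variable projection: for the mono-exponential model
# x_i = S0 * w_i(T2), w_i = exp(-TE_i / T2), the least-squares amplitude at
# fixed T2 is S0(T2) = <w, x> / <w, w> (w real), so the residual reduces to
# ||x||^2 - |<w, x>|^2 / <w, w> and only T2 is searched: a log-spaced grid
# scan over the bounds followed by golden-section refinement. Complex
# fitting is used (not magnitude fitting) because the simulated noise is
# complex Gaussian, for which complex least squares is unbiased.

#' Options for least-squares T2/S0 fitting
#'
#' @param t2_bounds search bounds for T2 in ms, `c(min, max)`; default
#'   `c(1, 3000)`.
#' @param grid_size number of log-spaced T2 grid points (default 256).
#' @param tol golden-section refinement tolerance on T2, ms (default 0.01).
#' @param magnitude fit `|x_i| = |S0| w_i` instead of the complex signal
#'   (sensitivity-check variant; default `FALSE`).
#' @return an object of class `fit_options`.
#' @export
fit_options <- function(t2_bounds = c(1, 3000), grid_size = 256L,
                        tol = 0.01, magnitude = FALSE) {
  if (t2_bounds[1] <= 0 || t2_bounds[2] <= t2_bounds[1])
    stop("need 0 < t2_min < t2_max")
  structure(list(t2_bounds = t2_bounds, grid_size = as.integer(grid_size),
                 tol = tol, magnitude = magnitude), class = "fit_options")
}

# Objective to MAXIMIZE at fixed T2 (vectorized over a pixel matrix):
# g(T2) = |<w, x>|^2 / <w, w>. X is n_pix x P (complex), w length P.
varpro_gain <- function(X, tes, t2) {
  w <- exp(-tes / t2)
  num <- Mod(X %*% w)^2
  drop(num / sum(w^2))
}

#' Least-squares fit of one echo train
#'
#' @param signal complex vector of length P (one pixel's echo train).
#' @param schedule the `echo_schedule`.
#' @param opts a [fit_options()].
#' @return list with `t2`, `s0_re`, `s0_im`, `residual`, and `degenerate`
#'   (`TRUE` for an all-zero input, which returns `t2 = t2_min` and zero
#'   amplitude rather than failing).
#' @export
lsf_fit_pixel <- function(signal, schedule, opts = fit_options()) {
  if (length(signal) < 2L) stop("need at least two echoes")
  res <- lsf_fit_matrix(matrix(signal, nrow = 1), schedule$tes, opts)
  list(t2 = res$t2[1], s0_re = res$s0_re[1], s0_im = res$s0_im[1],
       residual = res$residual[1], degenerate = res$degenerate[1])
}

# Vectorized core: X is n_pix x P complex. Returns vectors.
lsf_fit_matrix <- function(X, tes, opts) {
  if (opts$magnitude) X <- Mod(X) + 0i
  n <- nrow(X)
  degenerate <- rowSums(Mod(X)^2) == 0
  lo <- log(opts$t2_bounds[1]); hi <- log(opts$t2_bounds[2])
  grid <- exp(seq(lo, hi, length.out = opts$grid_size))
  # gain matrix: n_pix x grid
  W <- exp(outer(-tes, 1 / grid))                    # P x G
  num <- Mod(X %*% W)^2                              # n x G
  gain <- sweep(num, 2, colSums(W^2), "/")
  best <- max.col(gain, ties.method = "first")
  # golden-section refinement in log-T2 between the neighbours of the best
  # grid point (clamped at the bounds)
  step <- (hi - lo) / (opts$grid_size - 1)
  a <- pmax(lo, log(grid[best]) - step)
  b <- pmin(hi, log(grid[best]) + step)
  gr <- (sqrt(5) - 1) / 2
  gain_at <- function(logt2) {
    # logt2 is a vector (one per pixel); evaluate per-pixel gains
    t2 <- exp(logt2)
    W2 <- exp(outer(-tes, 1 / t2))                   # P x n
    num <- Mod(rowSums(X * t(W2)))^2
    num / colSums(W2^2)
  }
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- gain_at(c1); f2 <- gain_at(c2)
  # absolute tolerance tol on T2 translates to tol / t2 in log space; use
  # the worst case over the bounds so every pixel meets it
  log_tol <- max(opts$tol / opts$t2_bounds[2], 1e-12)
  while (max(b - a) > log_tol) {
    take1 <- f1 >= f2
    b <- ifelse(take1, c2, b); a <- ifelse(take1, a, c1)
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
    f1 <- gain_at(c1); f2 <- gain_at(c2)
  }
  t2 <- exp((a + b) / 2)
  t2[degenerate] <- opts$t2_bounds[1]
  Wopt <- exp(outer(-tes, 1 / t2))                   # P x n
  s0 <- colSums(t(X) * Wopt) / colSums(Wopt^2)
  s0[degenerate] <- 0 + 0i
  residual <- rowSums(Mod(X - t(Wopt) * matrix(s0, n, length(tes)))^2)
  clamped <- !degenerate &
    (t2 <= opts$t2_bounds[1] * (1 + 1e-4) | t2 >= opts$t2_bounds[2] * (1 - 1e-4))
  list(t2 = t2, s0_re = Re(s0), s0_im = Im(s0), residual = residual,
       degenerate = degenerate, clamped = clamped)
}

#' Least-squares fit of a multi-echo image
#'
#' Applies the variable-projection fit pixel-wise over the foreground;
#' background pixels return exact zeros in all three maps.
#'
#' @param x a `multicontrast_image`.
#' @param opts a [fit_options()].
#' @param foreground logical H x W matrix; default: pixels whose echo train
#'   is not identically zero.
#' @return a `parameter_maps` estimate.
#' @export
lsf_fit_image <- function(x, opts = fit_options(), foreground = NULL) {
  stopifnot(inherits(x, "multicontrast_image"))
  d <- dim(x$data)
  Xall <- matrix(x$data, nrow = d[1] * d[2], ncol = d[3])
  if (is.null(foreground))
    foreground <- matrix(rowSums(Mod(Xall)^2) > 0, d[1], d[2])
  idx <- which(as.vector(foreground))
  t2 <- s0_re <- s0_im <- matrix(0, d[1], d[2])
  if (length(idx) > 0) {
    fit <- lsf_fit_matrix(Xall[idx, , drop = FALSE], x$schedule$tes, opts)
    t2[idx] <- fit$t2; s0_re[idx] <- fit$s0_re; s0_im[idx] <- fit$s0_im
  }
  parameter_maps(t2 = t2, s0_re = s0_re, s0_im = s0_im)
}
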