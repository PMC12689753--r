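# Multi-contrast Fourier encoding and Cartesian undersampling.
#
# The encoding operator applies, per echo, the centered orthonormal 2-D DFT
# followed by a binary phase-encode mask (unsampled lines zeroed). Masks are
# 1-D Cartesian: full read-out lines, variable-density random in the
# phase-encode (row) direction with a fully sampled central block, drawn
# independently per echo so the aliasing is incoherent across echoes.

#' Variable-density Cartesian sampling masks, one per echo
#'
#' Each echo receives `round(h / af)` full phase-encode lines: a fully
#' sampled central block of `center_lines` lines plus lines drawn without
#' replacement with probability proportional to a Gaussian density in the
#' distance from the k-space center. Echo masks are drawn independently
#' (temporally incoherent sampling) and the whole set is reproducible from
#' `seed`.
#'
#' @param h,w image matrix size (rows = phase-encode lines).
#' @param p number of echoes.
#' @param af nominal acceleration factor (>= 1); `af = 1` gives full masks.
#' @param center_lines always-sampled central lines; default
#'   `max(2, round(0.04 * h))`.
#' @param seed integer seed for the mask draw.
#' @param density_sd standard deviation of the Gaussian line density, in
#'   lines; default `h / 6`.
#' @return an object of class `sampling_mask_set`: list with `masks`
#'   (H x W x P 0/1 array), `af`, `center_lines`, `seed`, `lines_per_echo`.
#' @export
make_mask_set <- function(h, w, p, af, center_lines = NULL, seed = 1L,
                          density_sd = h / 6) {
  if (af < 1) stop("af must be >= 1")
  if (is.null(center_lines)) center_lines <- max(2L, round(0.04 * h))
  n_lines <- round(h / af)
  if (n_lines < center_lines)
    stop(sprintf("af = %g leaves %d lines, fewer than the %d center lines",
                 af, n_lines, center_lines))
  ctr <- floor(h / 2) + 1L                       # DC row of the centered grid
  half <- floor(center_lines / 2)
  center_idx <- (ctr - half) + seq_len(center_lines) - 1L
  stopifnot(all(center_idx >= 1L), all(center_idx <= h))
  others <- setdiff(seq_len(h), center_idx)
  prob <- stats::dnorm(others - ctr, sd = density_sd)
  masks <- array(0, dim = c(h, w, p))
  n_rand <- n_lines - center_lines
  with_seed(seed, {
    for (i in seq_len(p)) {
      rows <- center_idx
      if (n_rand > 0) rows <- c(rows, sample(others, n_rand, prob = prob))
      masks[rows, , i] <- 1
    }
  })
  structure(list(masks = masks, af = af, center_lines = center_lines,
                 seed = seed, lines_per_echo = n_lines),
            class = "sampling_mask_set")
}

#' @export
print.sampling_mask_set <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf(
    "<sampling_mask_set> %d x %d, %d echoes, AF %g (%d lines/echo, %d central)\n",
    d[1], d[2], d[3], x$af, x$lines_per_echo, x$center_lines))
  invisible(x)
}

full_mask_set <- function(h, w, p) {
  structure(list(masks = array(1, dim = c(h, w, p)), af = 1,
                 center_lines = h, seed = NA_integer_, lines_per_echo = h),
            class = "sampling_mask_set")
}

#' Write the phase-encode line pattern of a mask set as CSV
#'
#' One row per phase-encode line, one column per echo (1 = sampled) — a
#' plain-text debug view of the sampling pattern.
#'
#' @param masks a `sampling_mask_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mask_csv <- function(masks, path) {
  stopifnot(inherits(masks, "sampling_mask_set"))
  lines <- masks$masks[, 1, , drop = TRUE]
  colnames(lines) <- paste0("echo", seq_len(ncol(lines)))
  utils::write.csv(cbind(line = seq_len(nrow(lines)), lines), path,
                   row.names = FALSE)
  invisible(path)
}

#' Multi-echo k-space data
#'
#' @param data complex array H x W x P (centered k-space grids).
#' @param masks optional `sampling_mask_set`; when present, `data` must be
#'   exactly zero off the sampled set.
#' @return an object of class `kspace_set`.
#' @export
kspace_set <- function(data, masks = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (!is.null(masks)) {
    stopifnot(inherits(masks, "sampling_mask_set"),
              identical(dim(masks$masks), dim(data)))
    if (any(data[masks$masks == 0] != 0))
      stop("k-space data must vanish at unsampled points")
  }
  new_kspace_set(data, masks)
}

# internal constructor for data that satisfies the support invariant by
# construction (e.g. freshly masked)
new_kspace_set <- function(data, masks = NULL) {
  structure(list(data = data, masks = masks), class = "kspace_set")
}

#' @export
print.kspace_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_set> %d x %d, %d echoes, %s\n", d[1], d[2], d[3],
              if (is.null(x$masks)) "fully sampled" else
                sprintf("undersampled (AF %g)", x$masks$af)))
  invisible(x)
}

#' Forward multi-contrast encoding: FFT then mask, per echo
#'
#' @param x a `multicontrast_image`.
#' @param masks optional `sampling_mask_set`; omitted = fully sampled.
#' @return a `kspace_set` (zero off the sampled set when masked).
#' @export
encode <- function(x, masks = NULL) {
  stopifnot(inherits(x, "multicontrast_image"))
  k <- fft2c_stack(x$data)
  if (!is.null(masks)) {
    if (!identical(dim(masks$masks), dim(k)))
      stop("mask shape does not match image shape")
    k <- k * masks$masks
  }
  new_kspace_set(k, masks)
}

#' Adjoint of the encoding: mask then inverse FFT, per echo
#'
#' With the unitary transform this is the exact adjoint of [encode()];
#' applied to undersampled data it is the zero-filled reconstruction.
#'
#' @param y a `kspace_set`.
#' @param schedule the `echo_schedule` to attach to the resulting image.
#' @return a `multicontrast_image`.
#' @export
adjoint_encode <- function(y, schedule) {
  stopifnot(inherits(y, "kspace_set"))
  k <- y$data
  if (!is.null(y$masks)) k <- k * y$masks$masks
  new_multicontrast_image(ifft2c_stack(k), schedule)
}

#' Zero-filled reconstruction (baseline method)
#'
#' Alias of [adjoint_encode()] in its role as the classical no-model
#' baseline: unmeasured k-space stays zero and the inverse transform is
#' taken directly.
#'
#' @inheritParams adjoint_encode
#' @return a `multicontrast_image`.
#' @export
zero_fill <- function(y, schedule) adjoint_encode(y, schedule)

#' Closed-form k-space data consistency
#'
#' Blends an estimated k-space with the measured data on the sampled set:
#' off the sampled set the estimate passes through unchanged; on it the
#' output is `(k_est + nu * y) / (1 + nu)`. `nu = Inf` (the default used in
#' the unrolled network) replaces sampled coefficients by the measurements
#' exactly — hard data consistency, appropriate in the noiseless-DC regime.
#'
#' @param k_est `kspace_set` (the network estimate, generally unmasked).
#' @param y measured `kspace_set`, zero off the sampled set.
#' @param masks the `sampling_mask_set` defining the sampled set.
#' @param nu non-negative blend weight, or `Inf` for hard replacement.
#' @return a `kspace_set` with the same support behavior as `k_est`.
#' @export
data_consistency <- function(k_est, y, masks, nu = Inf) {
  stopifnot(inherits(k_est, "kspace_set"), inherits(y, "kspace_set"),
            inherits(masks, "sampling_mask_set"))
  if (!identical(dim(k_est$data), dim(y$data)) ||
      !identical(dim(k_est$data), dim(masks$masks)))
    stop("shape mismatch between k_est, y and masks")
  if (is.na(nu) || nu < 0) stop("nu must be non-negative or Inf")
  m <- masks$masks
  out <- if (is.infinite(nu)) {
    k_est$data * (1 - m) + y$data * m
  } else {
    k_est$data * (1 - m) + ((k_est$data + nu * y$data) / (1 + nu)) * m
  }
  new_kspace_set(out, k_est$masks)
}
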