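#' @keywords internal
#' @useDynLib qdcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Centered, orthonormal 2-D Fourier helpers.
#
# k-space is stored with the DC coefficient at (floor(H/2)+1, floor(W/2)+1),
# the convention of most MRI toolchains. The unitary scaling 1/sqrt(H*W)
# makes encode/adjoint exact adjoints and keeps noise variance identical in
# image and k-space domains.

fftshift_mat <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))),
    c((floor(w / 2) + 1):w, seq_len(floor(w / 2))), drop = FALSE]
}

ifftshift_mat <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((ceiling(h / 2) + 1):h, seq_len(ceiling(h / 2))),
    c((ceiling(w / 2) + 1):w, seq_len(ceiling(w / 2))), drop = FALSE]
}

#' Centered orthonormal 2-D discrete Fourier transform
#'
#' Forward transform of one complex image; DC term lands in the matrix
#' center. `ifft2c()` is its exact inverse (and adjoint, since the scaled
#' transform is unitary).
#'
#' @param x complex (or numeric) matrix.
#' @return complex matrix of the same dimension.
#' @keywords internal
fft2c <- function(x) {
  fftshift_mat(stats::fft(ifftshift_mat(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @keywords internal
ifft2c <- function(x) {
  fftshift_mat(stats::fft(ifftshift_mat(x), inverse = TRUE)) / sqrt(length(x))
}

# Apply fft2c / ifft2c slice-wise over an H x W x P complex array.
fft2c_stack <- function(x) {
  out <- x
  for (i in seq_len(dim(x)[3])) out[, , i] <- fft2c(x[, , i])
  out
}

ifft2c_stack <- function(x) {
  out <- x
  for (i in seq_len(dim(x)[3])) out[, , i] <- ifft2c(x[, , i])
  out
}

#' Pack a complex echo stack into real channels
#'
#' A complex H x W x P array becomes a real H x W x 2P array with the real
#' parts of all echoes first (channels 1..P) and the imaginary parts second
#' (channels P+1..2P). This packing is done here and nowhere else, so the
#' convention cannot drift between the networks and the losses.
#'
#' @param z complex array H x W x P.
#' @return real array H x W x 2P.
#' @export
complex_to_channels <- function(z) {
  stopifnot(length(dim(z)) == 3L)
  p <- dim(z)[3]
  out <- array(0, dim = c(dim(z)[1], dim(z)[2], 2L * p))
  out[, , seq_len(p)] <- Re(z)
  out[, , p + seq_len(p)] <- Im(z)
  out
}

#' @rdname complex_to_channels
#' @param x real array H x W x 2P.
#' @export
channels_to_complex <- function(x) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] %% 2L == 0L)
  p <- dim(x)[3] / 2L
  array(complex(real = x[, , seq_len(p)], imaginary = x[, , p + seq_len(p)]),
        dim = c(dim(x)[1], dim(x)[2], p))
}
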