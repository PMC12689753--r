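# Mono-exponential multi-echo spin-echo signal model.
#
# Each echo image is S(TE) = S0 * exp(-TE / T2) with complex amplitude
# S0 = Re{S0} + i Im{S0}; T2 in milliseconds. The saturation of S0 by
# incomplete T1 recovery is modelled separately via s0_from_pd().

#' Echo-time schedule for a multi-echo spin-echo acquisition
#'
#' @param tes numeric vector of echo times in ms, strictly increasing,
#'   length >= 2.
#' @param tr repetition time in ms; must exceed the last echo time.
#' @return an object of class `echo_schedule` (list with `tes`, `tr`).
#' @examples
#' sched <- echo_schedule(seq(10, 160, by = 10), tr = 7000)
#' @export
echo_schedule <- function(tes, tr) {
  tes <- as.numeric(tes)
  if (length(tes) < 2L) stop("need at least two echo times")
  if (any(tes <= 0)) stop("echo times must be positive")
  if (any(diff(tes) <= 0)) stop("echo times must be strictly increasing")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= max(tes))
    stop("tr must be a scalar exceeding the largest echo time")
  structure(list(tes = tes, tr = as.numeric(tr)), class = "echo_schedule")
}

#' Default 16-echo schedule (TE = 10, 20, ..., 160 ms; TR = 7000 ms)
#' @param p number of echoes kept (see [select_echo_subset()]); default 16.
#' @return an `echo_schedule`.
#' @export
default_schedule <- function(p = 16L) {
  full <- echo_schedule(seq(10, 160, by = 10), tr = 7000)
  if (p == 16L) full else select_echo_subset(full, p)
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat(sprintf("<echo_schedule> %d echoes, TE %g..%g ms, TR %g ms\n",
              length(x$tes), min(x$tes), max(x$tes), x$tr))
  invisible(x)
}

n_echoes <- function(schedule) length(schedule$tes)

#' Quantitative parameter maps (T2, Re S0, Im S0)
#'
#' The per-pixel target of the mapping stage: a T2 map in ms and the real
#' and imaginary parts of the complex amplitude S0. Background pixels carry
#' T2 = 0 and S0 = 0.
#'
#' @param t2 numeric H x W matrix, ms, non-negative.
#' @param s0_re,s0_im numeric H x W matrices, arbitrary units.
#' @return an object of class `parameter_maps`.
#' @export
parameter_maps <- function(t2, s0_re, s0_im = NULL) {
  if (is.null(s0_im)) s0_im <- array(0, dim = dim(s0_re))
  t2 <- as.matrix(t2); s0_re <- as.matrix(s0_re); s0_im <- as.matrix(s0_im)
  if (!identical(dim(t2), dim(s0_re)) || !identical(dim(t2), dim(s0_im)))
    stop("t2, s0_re, s0_im must share one H x W shape")
  if (any(!is.finite(t2)) || any(!is.finite(s0_re)) || any(!is.finite(s0_im)))
    stop("parameter maps must be finite")
  if (any(t2 < 0)) stop("t2 must be non-negative everywhere")
  structure(list(t2 = t2, s0_re = s0_re, s0_im = s0_im),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> %d x %d; T2 range [%.3g, %.3g] ms, max |S0| %.3g\n",
              nrow(x$t2), ncol(x$t2), min(x$t2), max(x$t2),
              max(s0_magnitude(x))))
  invisible(x)
}

s0_complex <- function(params) {
  matrix(complex(real = params$s0_re, imaginary = params$s0_im),
         nrow = nrow(params$t2))
}

#' Magnitude of the complex S0 map
#' @param params a `parameter_maps` object.
#' @return numeric H x W matrix.
#' @export
s0_magnitude <- function(params) sqrt(params$s0_re^2 + params$s0_im^2)

#' Multi-contrast (multi-echo) complex image stack
#'
#' @param data complex array H x W x P, one slice per echo.
#' @param schedule the `echo_schedule` the stack was simulated/acquired with.
#' @return an object of class `multicontrast_image`.
#' @export
multicontrast_image <- function(data, schedule) {
  stopifnot(inherits(schedule, "echo_schedule"))
  if (length(dim(data)) != 3L || dim(data)[3] != n_echoes(schedule))
    stop("data must be H x W x P with P matching the schedule")
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("image data must be finite")
  new_multicontrast_image(data, schedule)
}

# internal constructor: invariants hold by construction on hot paths
new_multicontrast_image <- function(data, schedule) {
  structure(list(data = data, schedule = schedule),
            class = "multicontrast_image")
}

#' @export
print.multicontrast_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multicontrast_image> %d x %d, %d echoes\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Simulate the multi-echo signal from parameter maps
#'
#' Evaluates S_i = S0 exp(-TE_i / T2) per pixel and echo. Pixels with
#' T2 = 0 are admitted only where S0 = 0 (background) and produce zero
#' signal; a positive amplitude with non-positive T2 is a modelling error
#' and is rejected.
#'
#' @param params a `parameter_maps` object.
#' @param schedule an `echo_schedule`.
#' @return a `multicontrast_image` with one complex image per echo.
#' @examples
#' p <- parameter_maps(t2 = matrix(80, 2, 2), s0_re = matrix(1, 2, 2))
#' img <- synthesize_signal(p, default_schedule())
#' Mod(img$data[1, 1, 1])  # exp(-10/80)
#' @export
synthesize_signal <- function(params, schedule) {
  stopifnot(inherits(params, "parameter_maps"),
            inherits(schedule, "echo_schedule"))
  mag2 <- params$s0_re^2 + params$s0_im^2
  if (any(params$t2 <= 0 & mag2 > 0))
    stop("non-positive T2 at pixels with |S0| > 0")
  h <- nrow(params$t2); w <- ncol(params$t2)
  s0 <- s0_complex(params)
  # 1/T2 with the 0/0 background case defined as zero signal
  inv_t2 <- ifelse(params$t2 > 0, 1 / params$t2, 0)
  data <- array(0i, dim = c(h, w, n_echoes(schedule)))
  for (i in seq_along(schedule$tes)) {
    decay <- exp(-schedule$tes[i] * inv_t2)
    decay[params$t2 <= 0] <- 0
    data[, , i] <- s0 * decay
  }
  new_multicontrast_image(data, schedule)
}

#' Complex amplitude S0 from proton density and T1 saturation
#'
#' S0 = PD (1 - exp(-TR / T1)): the steady-state amplitude of a spin-echo
#' readout with repetition time TR and longitudinal relaxation time T1.
#' Background pixels (PD = 0) stay exactly 0 regardless of T1.
#'
#' @param pd proton-density matrix, relative units, non-negative.
#' @param t1 T1 matrix, ms; must be positive wherever pd > 0.
#' @param tr repetition time, ms, positive scalar.
#' @return numeric matrix of S0 amplitudes.
#' @export
s0_from_pd <- function(pd, t1, tr) {
  pd <- as.matrix(pd); t1 <- as.matrix(t1)
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar")
  if (any(pd < 0)) stop("pd must be non-negative")
  if (any(t1 <= 0 & pd > 0)) stop("t1 must be positive wherever pd > 0")
  sat <- ifelse(t1 > 0, 1 - exp(-tr / t1), 1)
  out <- pd * sat
  out[pd == 0] <- 0
  out
}
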