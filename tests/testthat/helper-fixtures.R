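# Shared fixtures, all generated in code.

# Random complex multi-echo image.
random_image <- function(h, w, p, schedule = NULL, seed = 1) {
  if (is.null(schedule))
    schedule <- echo_schedule(seq(10, by = 10, length.out = p), 7000)
  withr_seed(seed)
  multicontrast_image(
    array(complex(real = rnorm(h * w * p), imaginary = rnorm(h * w * p)),
          dim = c(h, w, p)),
    schedule)
}

# Small piecewise-constant parameter maps with a zero background border.
toy_maps <- function(h = 16, w = 16, seed = 1) {
  withr_seed(seed)
  t2 <- matrix(0, h, w); s0 <- matrix(0, h, w)
  inner <- 3:(h - 2)
  t2[inner, inner] <- sample(c(60, 90, 140, 600), length(inner)^2, TRUE)
  s0[inner, inner] <- runif(length(inner)^2, 0.3, 1)
  parameter_maps(t2 = t2, s0_re = s0)
}

withr_seed <- function(seed) set.seed(seed)

# Tiny end-to-end dataset for training smoke tests.
tiny_dataset <- function(h = 32, n_slices = 2, af = 3, p = 4, seed = 11) {
  cfg <- dataset_config(n_cases = 3L, split = c(1L, 1L, 1L),
                        n_slices = n_slices, h = h, w = h,
                        schedule = default_schedule(p), af = af, seed = seed)
  build_dataset(cfg)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), .Machine$double.eps), tol)
}

# Independent oracle for the least-squares fit: exhaustive dense grid
# search over (T2, |S0|, phase). The residual of the mono-exponential
# model is evaluated exactly on the full grid; the quadratic dependence on
# the amplitude lets each (phase, T2) column be minimized over the
# amplitude grid by rounding to the grid point nearest the vertex, which
# selects the same grid minimum as evaluating every amplitude.
brute_force_t2 <- function(X, tes, t2_bounds = c(1, 3000), n_t2 = 200L,
                           n_amp = 200L, n_ph = 72L, amp_max = 1.3) {
  t2_grid <- exp(seq(log(t2_bounds[1]), log(t2_bounds[2]),
                     length.out = n_t2))
  W <- exp(outer(-tes, 1 / t2_grid))               # P x G
  B <- colSums(W^2)
  amp0 <- 0.01
  astep <- (amp_max - amp0) / (n_amp - 1)
  ph <- seq(0, 2 * pi, length.out = n_ph + 1)[seq_len(n_ph)]
  eph <- exp(-1i * ph)
  n <- nrow(X)
  out_t2 <- numeric(n); out_res <- numeric(n)
  Bmat <- matrix(B, n_ph, length(B), byrow = TRUE)
  for (i in seq_len(n)) {
    x <- X[i, ]
    s2 <- sum(Mod(x)^2)
    cross <- drop(t(W) %*% x)                      # sum_i w_i x_i, per T2
    term <- Re(outer(eph, cross))                  # n_ph x G
    a_v <- term / Bmat                             # vertex of the quadratic
    a_n <- pmin(pmax(round((a_v - amp0) / astep), 0), n_amp - 1) *
      astep + amp0
    res <- s2 - 2 * a_n * term + a_n^2 * Bmat
    j <- which.min(res)
    out_t2[i] <- t2_grid[(j - 1) %/% n_ph + 1]
    out_res[i] <- res[j]
  }
  list(t2 = out_t2, residual = out_res,
       step = log(t2_grid[2] / t2_grid[1]))
}
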