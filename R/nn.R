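# Minimal neural-network machinery: dense and 3x3 same-padding
# convolutional layers with hand-written backpropagation, plus Adam.
#
# Convolutions use im2col so the inner loop is a single BLAS matrix
# multiply; backward passes return exact gradients (verified against
# finite differences in the test suite). Parameters live in plain nested
# lists whose leaves are numeric arrays, so the optimizer can walk any
# network structure generically.

# ---- initialization --------------------------------------------------------

# He/variance-scaling initialization for a dense layer.
init_dense <- function(n_in, n_out, scale = sqrt(2)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale / sqrt(n_in)),
                  n_in, n_out),
       b = numeric(n_out))
}

# 3x3 conv layer; weight rows ordered offset-major (9 blocks of c_in).
init_conv <- function(c_in, c_out, scale = sqrt(2)) {
  fan_in <- 9 * c_in
  list(W = matrix(stats::rnorm(fan_in * c_out, sd = scale / sqrt(fan_in)),
                  fan_in, c_out),
       b = numeric(c_out))
}

# ---- dense layers ----------------------------------------------------------

dense_forward <- function(X, par) {
  list(out = dense_fwd_cpp(X, par$W, par$b), X = X)
}

dense_backward <- function(dout, cache, par) {
  list(dX = dout %*% t(par$W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

relu_forward <- function(X) {
  out <- relu_fwd_cpp(X)
  list(out = out, act = out)
}
relu_backward <- function(dout, cache) relu_bwd_cpp(dout, cache$act)

# ---- 3x3 convolution (same padding) ---------------------------------------

# Compiled im2col + BLAS kernels (src/conv3x3.cpp); the im2col matrix is
# kept in the cache so the backward pass reuses it for the weight gradient.

conv_forward <- function(x, par) {
  res <- conv3x3_forward_cpp(x, par$W, par$b)
  list(out = res$out, cols = res$cols, in_dim = dim(x))
}

conv_backward <- function(dout, cache, par) {
  conv3x3_backward_cpp(dout, cache$cols, par$W)
}

# ---- generic parameter-tree helpers ---------------------------------------

# Apply f(leaf_a, leaf_b) elementwise over two parameter trees of the same
# shape (leaves are numeric arrays); b may be NULL for unary maps.
tree_map <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a))
      out[[nm]] <- tree_map(a[[nm]], if (is.null(b)) NULL else b[[nm]], f)
    out
  } else {
    if (is.null(b)) f(a) else f(a, b)
  }
}

tree_zero <- function(params) tree_map(params, NULL, function(x) x * 0)

tree_add <- function(a, b) tree_map(a, b, `+`)
tree_scale <- function(a, s) tree_map(a, NULL, function(x) x * s)

# Sum over leaves of f(leaf); used for diagnostics and tests.
tree_reduce <- function(a, f) {
  if (is.list(a)) sum(vapply(a, tree_reduce, numeric(1), f = f)) else f(a)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_add(tree_scale(state$m, beta1), tree_scale(grads, 1 - beta1))
  state$v <- tree_map(state$v, grads,
                      function(v, g) beta2 * v + (1 - beta2) * g * g)
  mhat <- tree_scale(state$m, 1 / (1 - beta1^state$t))
  vhat <- tree_scale(state$v, 1 / (1 - beta2^state$t))
  step <- tree_map(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(params = tree_map(params, step, `-`), state = state)
}
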