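# The two learned modules and their composition.
#
# f_rec: an unrolled cascade of residual convolutional denoisers, each
# followed by a closed-form k-space data-consistency step (DC-CNN style).
# The denoiser sees all P echoes jointly as 2P real channels so it can
# exploit cross-echo redundancy.
#
# f_map: a fully connected network applied independently to each pixel's
# length-2P echo vector, emitting (T2, Re S0, Im S0). The T2 channel is
# passed through a bounded log-scale transform
# t2_min * (t2_max / t2_min)^sigmoid(z), keeping T2 strictly inside
# (t2_min, t2_max): the data-consistency loss (which exponentiates
# -TE/T2) cannot diverge, and network resolution is uniform in log T2 —
# matching the relative (not absolute) accuracy relaxometry asks for.

#' Configuration of the unrolled reconstruction network
#'
#' @param n_cascades number of unrolled iterations (denoiser + DC blocks).
#' @param convs_per_cascade convolution layers per denoiser (3x3, ReLU
#'   between layers, linear last layer, residual skip around the stack).
#' @param filters channels of the hidden convolution layers.
#' @param dc_weight data-consistency blend `nu`; `Inf` = hard replacement.
#' @param preset `"full"` (5 cascades, 5 convs, 64 filters) or `"desk"`
#'   (2 cascades, 3 convs, 16 filters) — explicit arguments win.
#' @return an object of class `recon_net_config`.
#' @export
recon_net_config <- function(n_cascades = NULL, convs_per_cascade = NULL,
                             filters = NULL, dc_weight = Inf,
                             preset = c("full", "desk")) {
  preset <- match.arg(preset)
  def <- if (preset == "full") c(5L, 5L, 64L) else c(2L, 3L, 16L)
  n_cascades <- if (is.null(n_cascades)) def[1] else as.integer(n_cascades)
  convs_per_cascade <- if (is.null(convs_per_cascade)) def[2] else
    as.integer(convs_per_cascade)
  filters <- if (is.null(filters)) def[3] else as.integer(filters)
  if (convs_per_cascade < 1 || filters < 1 || n_cascades < 0)
    stop("counts must be >= 1 (n_cascades >= 0)")
  if (is.na(dc_weight) || dc_weight < 0) stop("dc_weight must be >= 0 or Inf")
  structure(list(n_cascades = n_cascades,
                 convs_per_cascade = convs_per_cascade,
                 filters = filters, dc_weight = dc_weight),
            class = "recon_net_config")
}

#' Configuration of the pixel-wise mapping network
#'
#' @param hidden_layers number of hidden layers.
#' @param hidden_units units per hidden layer.
#' @param t2_max,t2_min bounds of the log-scale T2 output transform, ms.
#' @param normalize if `TRUE` (default), each pixel vector is divided by
#'   its first-echo magnitude + eps, with that magnitude and phase
#'   appended as two extra inputs; `FALSE` feeds the raw vectors. The
#'   normalized form decouples the decay shape (which determines T2) from
#'   the amplitude and phase, which measurably sharpens T2 accuracy.
#' @return an object of class `map_net_config`.
#' @export
map_net_config <- function(hidden_layers = 4L, hidden_units = 128L,
                           t2_max = 3000, t2_min = 5, normalize = TRUE) {
  stopifnot(hidden_layers >= 1, hidden_units >= 1, t2_max > t2_min,
            t2_min > 0)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_units = as.integer(hidden_units),
                 t2_max = t2_max, t2_min = t2_min,
                 normalize = isTRUE(normalize)),
            class = "map_net_config")
}

fmap_input_width <- function(cfg, p) 2L * p + if (cfg$normalize) 2L else 0L

# additive floor of the first-echo magnitude used by the input
# normalization (shared by forward and backward passes)
FMAP_NORM_EPS <- 1e-2

#' Initialize reconstruction-network weights
#'
#' @param cfg a [recon_net_config()].
#' @param p number of echoes (the denoiser consumes 2P channels).
#' @param seed integer seed (variance-scaling init is deterministic in it).
#' @return nested list of conv-layer parameters, one sublist per cascade.
#' @export
init_frec_weights <- function(cfg, p, seed = 1L) {
  ch <- 2L * p
  with_seed(seed, {
    lapply(seq_len(cfg$n_cascades), function(ci) {
      nl <- cfg$convs_per_cascade
      lapply(seq_len(nl), function(li) {
        c_in <- if (li == 1L) ch else cfg$filters
        c_out <- if (li == nl) ch else cfg$filters
        # last (linear) layer initialized small so the initial residual is
        # near zero and the untrained unroll stays close to zero-fill
        init_conv(c_in, c_out, scale = if (li == nl) 0.1 else sqrt(2))
      })
    })
  })
}

#' Initialize mapping-network weights
#'
#' @param cfg a [map_net_config()].
#' @param p number of echoes.
#' @param seed integer seed.
#' @return list of dense-layer parameters (`hidden_layers + 1` entries).
#' @export
init_fmap_weights <- function(cfg, p, seed = 1L) {
  widths <- c(fmap_input_width(cfg, p),
              rep(cfg$hidden_units, cfg$hidden_layers), 3L)
  with_seed(seed, {
    lapply(seq_len(length(widths) - 1L), function(i) {
      init_dense(widths[i], widths[i + 1L],
                 scale = if (i == length(widths) - 1L) 1 else sqrt(2))
    })
  })
}

#' Number of trainable parameters in a weight tree
#' @param weights nested list of numeric arrays.
#' @return integer count.
#' @export
n_parameters <- function(weights) tree_reduce(weights, length)

# DC gradient/blend factor in k-space: coefficient multiplying the
# estimate on each k-space point.
dc_factor <- function(masks, nu) {
  m <- masks$masks
  if (is.infinite(nu)) 1 - m else (1 - m) + m / (1 + nu)
}

#' Forward pass of the unrolled reconstruction network
#'
#' Runs `n_cascades` blocks of residual convolutional denoising followed by
#' closed-form data consistency against the measured k-space. With zero
#' cascades the output is the zero-filled input unchanged.
#'
#' @param x_zf zero-filled `multicontrast_image` (`zero_fill(y, schedule)`).
#' @param y measured `kspace_set` (zero off the sampled set).
#' @param masks the `sampling_mask_set` of `y`.
#' @param weights from [init_frec_weights()] (or trained).
#' @param cfg the [recon_net_config()].
#' @param want_cache keep intermediate activations for backpropagation.
#' @return a `multicontrast_image`; with `want_cache = TRUE`, a list
#'   `(output, cache)`.
#' @export
frec_forward <- function(x_zf, y, masks, weights, cfg, want_cache = FALSE) {
  stopifnot(inherits(x_zf, "multicontrast_image"), inherits(y, "kspace_set"))
  if (length(weights) != cfg$n_cascades)
    stop("weights do not match n_cascades")
  x <- complex_to_channels(x_zf$data)
  if (cfg$n_cascades > 0 && ncol(weights[[1]][[1]]$W) != cfg$filters &&
      cfg$convs_per_cascade > 1)
    stop("weights do not match filter count")
  if (cfg$n_cascades > 0 && nrow(weights[[1]][[1]]$W) != 9L * dim(x)[3])
    stop("weights do not match the echo count of the input")
  fac <- dc_factor(masks, cfg$dc_weight)
  dc_meas <- if (is.infinite(cfg$dc_weight)) y$data * masks$masks else
    (cfg$dc_weight / (1 + cfg$dc_weight)) * y$data * masks$masks
  caches <- if (want_cache) vector("list", cfg$n_cascades) else NULL
  for (ci in seq_len(cfg$n_cascades)) {
    layers <- weights[[ci]]
    nl <- length(layers)
    a <- x
    lcache <- if (want_cache) vector("list", nl) else NULL
    for (li in seq_len(nl)) {
      cf <- conv_forward(a, layers[[li]])
      if (li < nl) {
        rf <- relu_forward(cf$out)
        a <- rf$out
        if (want_cache) lcache[[li]] <- list(conv = cf, relu = rf)
      } else {
        a <- cf$out
        if (want_cache) lcache[[li]] <- list(conv = cf)
      }
    }
    xm <- x + a                                   # residual skip
    k <- fft2c_stack(channels_to_complex(xm))
    kdc <- k * fac + dc_meas
    xdc <- complex_to_channels(ifft2c_stack(kdc))
    if (want_cache) caches[[ci]] <- list(layers = lcache)
    x <- xdc
  }
  out <- new_multicontrast_image(channels_to_complex(x), x_zf$schedule)
  if (want_cache) list(output = out, cache = caches) else out
}

# Backward pass through the unrolled network. dx: real channel-array
# gradient w.r.t. the output. Returns list(grads, dx) where dx is the
# gradient w.r.t. the zero-filled input.
frec_backward <- function(dx, cache, masks, weights, cfg) {
  fac <- dc_factor(masks, cfg$dc_weight)
  grads <- vector("list", cfg$n_cascades)
  for (ci in rev(seq_len(cfg$n_cascades))) {
    # through the DC block (self-adjoint real-linear operator)
    g <- fft2c_stack(channels_to_complex(dx))
    g <- ifft2c_stack(g * fac)
    dxm <- complex_to_channels(g)
    # through the residual denoiser
    layers <- weights[[ci]]
    lcache <- cache[[ci]]$layers
    nl <- length(layers)
    da <- dxm
    lgrads <- vector("list", nl)
    for (li in rev(seq_len(nl))) {
      if (li < nl) da <- relu_backward(da, lcache[[li]]$relu)
      cb <- conv_backward(da, lcache[[li]]$conv, layers[[li]])
      lgrads[[li]] <- list(W = cb$dW, b = cb$db)
      da <- cb$dx
    }
    grads[[ci]] <- lgrads
    dx <- dxm + da                                # identity skip + conv path
  }
  list(grads = grads, dx = dx)
}

# Arrange an H x W x 2P channel array as an (H*W) x 2P pixel matrix (and
# back); column order = Re of echoes 1..P then Im of echoes 1..P.
channels_to_pixel_matrix <- function(x) {
  d <- dim(x)
  matrix(x, d[1] * d[2], d[3])
}

pixel_matrix_to_channels <- function(X, h, w) {
  array(X, dim = c(h, w, ncol(X)))
}

#' Forward pass of the pixel-wise mapping network
#'
#' Every pixel's echo vector is mapped independently through the shared
#' fully connected network to (T2, Re S0, Im S0); no spatial mixing occurs,
#' so the operation commutes with any spatial permutation.
#'
#' @param x a `multicontrast_image`, or an N x 2P numeric matrix of pixel
#'   vectors (real parts of all echoes, then imaginary parts).
#' @param weights from [init_fmap_weights()] (or trained).
#' @param cfg the [map_net_config()].
#' @param want_cache keep activations for backpropagation.
#' @return a `parameter_maps` (image input) or an N x 3 matrix with columns
#'   (t2, s0_re, s0_im); with `want_cache = TRUE`, a list `(output, cache)`.
#' @export
fmap_forward <- function(x, weights, cfg, want_cache = FALSE) {
  is_image <- inherits(x, "multicontrast_image")
  X <- if (is_image)
    channels_to_pixel_matrix(complex_to_channels(x$data)) else x
  if (any(!is.finite(X))) stop("non-finite inputs to the mapping network")
  p <- ncol(X) / 2L
  norm_cache <- NULL
  if (cfg$normalize) {
    # signal floor: 1% of the normalized S0 peak, below the dictionary's
    # 0.05 amplitude floor. Without it, near-zero background pixels of a
    # reconstructed image yield normalized inputs of order 1/|x1| and blow
    # up the gradients of the joint training.
    eps <- FMAP_NORM_EPS
    m1 <- sqrt(X[, 1]^2 + X[, p + 1]^2) + eps
    ph <- atan2(X[, p + 1], X[, 1])
    Xn <- X / m1
    norm_cache <- list(m1 = m1, X_raw = X)
    X <- cbind(Xn, m1, ph)
  }
  if (ncol(X) != nrow(weights[[1]]$W))
    stop("echo count does not match the mapping-network input width")
  nl <- length(weights)
  a <- X
  lcache <- if (want_cache) vector("list", nl) else NULL
  for (li in seq_len(nl)) {
    df <- dense_forward(a, weights[[li]])
    if (li < nl) {
      rf <- relu_forward(df$out)
      a <- rf$out
      if (want_cache) lcache[[li]] <- list(dense = df, relu = rf)
    } else {
      a <- df$out
      if (want_cache) lcache[[li]] <- list(dense = df)
    }
  }
  sig <- stats::plogis(a[, 1])
  t2 <- cfg$t2_min * exp(log(cfg$t2_max / cfg$t2_min) * sig)
  out <- cbind(t2 = t2, s0_re = a[, 2], s0_im = a[, 3])
  result <- if (is_image) {
    h <- dim(x$data)[1]; w <- dim(x$data)[2]
    parameter_maps(t2 = matrix(out[, 1], h, w),
                   s0_re = matrix(out[, 2], h, w),
                   s0_im = matrix(out[, 3], h, w))
  } else out
  if (want_cache)
    list(output = result,
         cache = list(layers = lcache, sig = sig, t2 = t2,
                      norm = norm_cache, p = p, n = nrow(X)))
  else result
}

# Backward pass of the mapping network. dout: N x 3 gradient w.r.t.
# (t2, s0_re, s0_im). Returns list(grads, dX) with dX w.r.t. the raw
# N x 2P pixel matrix.
fmap_backward <- function(dout, cache, weights, cfg) {
  sig <- cache$sig
  # dT2/dz = T2 * log(t2_max/t2_min) * sig * (1 - sig)
  da <- cbind(dout[, 1] * cache$t2 * log(cfg$t2_max / cfg$t2_min) *
                sig * (1 - sig),
              dout[, 2], dout[, 3])
  nl <- length(weights)
  grads <- vector("list", nl)
  for (li in rev(seq_len(nl))) {
    if (li < nl) da <- relu_backward(da, cache$layers[[li]]$relu)
    db <- dense_backward(da, cache$layers[[li]]$dense, weights[[li]])
    grads[[li]] <- list(W = db$dW, b = db$db)
    da <- db$dX
  }
  if (cfg$normalize) {
    p <- cache$p
    m1 <- cache$norm$m1; X <- cache$norm$X_raw
    eps_m <- m1                                  # |x1| + eps
    dXn <- da[, seq_len(2L * p), drop = FALSE]
    dm1 <- da[, 2L * p + 1L]
    dph <- da[, 2L * p + 2L]
    dX <- dXn / m1
    # d m1 / d x1re = x1re/|x1|, etc.; phase derivative of atan2
    mag <- m1 - FMAP_NORM_EPS
    safe <- mag > 0
    r1 <- X[, 1]; i1 <- X[, p + 1]
    contrib_m <- rowSums(dXn * X) * (-1 / m1^2)  # through the division
    dmag_total <- (dm1 + contrib_m)
    dX[, 1] <- dX[, 1] + ifelse(safe, dmag_total * r1 / pmax(mag, 1e-12), 0) +
      ifelse(safe, dph * (-i1) / pmax(mag^2, 1e-24), 0)
    dX[, p + 1] <- dX[, p + 1] +
      ifelse(safe, dmag_total * i1 / pmax(mag, 1e-12), 0) +
      ifelse(safe, dph * r1 / pmax(mag^2, 1e-24), 0)
    da <- dX
  }
  list(grads = grads, dX = da)
}

#' End-to-end forward pass: undersampled k-space to parameter maps
#'
#' Composes zero-filling, the unrolled reconstruction network and the
#' pixel-wise mapping network. Both intermediates are returned because the
#' image-domain training loss needs the reconstructed contrast images.
#'
#' @param y measured `kspace_set`.
#' @param masks its `sampling_mask_set`.
#' @param weights list with elements `frec` and `fmap`.
#' @param recon_cfg,map_cfg the network configurations.
#' @param schedule the `echo_schedule` of the acquisition.
#' @return list with `x_rec` (a `multicontrast_image`) and `p_rec`
#'   (a `parameter_maps`).
#' @export
qdcnn_forward <- function(y, masks, weights, recon_cfg, map_cfg, schedule) {
  x_zf <- zero_fill(y, schedule)
  x_rec <- frec_forward(x_zf, y, masks, weights$frec, recon_cfg)
  p_rec <- fmap_forward(x_rec, weights$fmap, map_cfg)
  list(x_rec = x_rec, p_rec = p_rec)
}
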