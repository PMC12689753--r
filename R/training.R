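# Training: the three-loss objective, mapping-network pretraining, and the
# end-to-end loop with per-batch mask refresh and early stopping.
#
# All squared-L2 losses are reduced by the MEAN over real elements (image
# losses over 2P*H*W, map losses over 3*H*W). Mean reduction keeps the
# default loss weights stable across image sizes; the weights
# lambda_r = 1, lambda_p = 1e-2, lambda_dc = 1e-6 balance the absolute
# magnitudes of the three terms.
#
# Inside the map loss the T2 channel is expressed in seconds
# (T2_ms / T2_LOSS_SCALE) so that all three map channels are O(1) with
# S0 normalized to [0, 1]; only then do the default lambdas balance the
# three terms, and only then does the joint map MSE weight T2 and S0
# comparably. Public maps remain in ms throughout.

T2_LOSS_SCALE <- 1000

#' Training configuration
#'
#' @param lambda_r,lambda_p,lambda_dc non-negative loss weights (defaults
#'   1, 1e-2, 1e-6).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size slices per gradient step.
#' @param max_epochs upper bound on epochs.
#' @param patience early-stopping patience: training stops once the
#'   validation loss has failed to improve for this many consecutive
#'   epochs (default 10).
#' @param refresh_masks draw a fresh sampling-mask set per batch (default
#'   `TRUE`), regenerating the undersampled input from the stored noisy
#'   fully sampled k-space.
#' @param seed seed for shuffling, mask refresh and weight init.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lambda_r = 1, lambda_p = 1e-2, lambda_dc = 1e-6,
                         lr = 1e-4, batch_size = 4L, max_epochs = 30L,
                         patience = 10L, refresh_masks = TRUE, seed = 1L) {
  if (lambda_r < 0 || lambda_p < 0 || lambda_dc < 0)
    stop("loss weights must be non-negative")
  if (patience < 1) stop("patience must be >= 1")
  structure(list(lambda_r = lambda_r, lambda_p = lambda_p,
                 lambda_dc = lambda_dc, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 refresh_masks = isTRUE(refresh_masks),
                 seed = as.integer(seed)), class = "train_config")
}

params_as_matrix <- function(p) cbind(as.vector(p$t2), as.vector(p$s0_re),
                                      as.vector(p$s0_im))

#' Evaluate the three training losses
#'
#' `l_r` compares reconstructed and ground-truth contrast images, `l_p`
#' compares parameter maps (all three channels jointly), and `l_dc`
#' compares the measured k-space with the k-space predicted from the
#' estimated maps through the signal model and the masked encoding. Each is
#' a mean of squared differences over real elements; the total is the
#' lambda-weighted sum. Within `l_p` the T2 channel is evaluated in seconds
#' so that all three map channels share the O(1) scale of the normalized
#' S0; maps themselves stay in ms.
#'
#' @param x_rec,x_gt `multicontrast_image`s (estimate, ground truth).
#' @param p_rec,p_gt `parameter_maps` (estimate, ground truth).
#' @param y measured `kspace_set` (zero off the sampled set).
#' @param masks the `sampling_mask_set` of `y`.
#' @param schedule the `echo_schedule`.
#' @param lambda_r,lambda_p,lambda_dc loss weights.
#' @return a `loss_record`: list with `l_r`, `l_p`, `l_dc`, `l_total`.
#' @export
compute_losses <- function(x_rec, p_rec, x_gt, p_gt, y, masks, schedule,
                           lambda_r = 1, lambda_p = 1e-2, lambda_dc = 1e-6) {
  if (lambda_r < 0 || lambda_p < 0 || lambda_dc < 0)
    stop("loss weights must be non-negative")
  n_img <- 2 * length(x_gt$data)
  l_r <- sum(Mod(x_gt$data - x_rec$data)^2) / n_img
  n_map <- 3 * length(p_gt$t2)
  l_p <- (sum(((p_gt$t2 - p_rec$t2) / T2_LOSS_SCALE)^2) +
            sum((p_gt$s0_re - p_rec$s0_re)^2) +
            sum((p_gt$s0_im - p_rec$s0_im)^2)) / n_map
  k_pred <- encode(synthesize_signal(p_rec, schedule), masks)
  l_dc <- sum(Mod(y$data - k_pred$data)^2) / n_img
  structure(list(l_r = l_r, l_p = l_p, l_dc = l_dc,
                 l_total = lambda_r * l_r + lambda_p * l_p + lambda_dc * l_dc),
            class = "loss_record")
}

#' @export
print.loss_record <- function(x, ...) {
  cat(sprintf("<loss_record> l_r %.4g  l_p %.4g  l_dc %.4g  total %.4g\n",
              x$l_r, x$l_p, x$l_dc, x$l_total))
  invisible(x)
}

# Gradients of the weighted total loss w.r.t. x_rec (channel array) and
# p_rec (N x 3 matrix), sharing the forward quantities with compute_losses.
loss_gradients <- function(x_rec, p_rec, x_gt, p_gt, y, masks, schedule,
                           lambda_r, lambda_p, lambda_dc) {
  d <- dim(x_gt$data)
  n_img <- 2 * prod(d)
  n_map <- 3 * d[1] * d[2]
  # l_r term
  dx <- complex_to_channels(x_rec$data - x_gt$data) * (2 * lambda_r / n_img)
  # l_p term (T2 channel evaluated in seconds; chain rule back to ms)
  dp <- (params_as_matrix(p_rec) - params_as_matrix(p_gt)) *
    (2 * lambda_p / n_map)
  dp[, 1] <- dp[, 1] / T2_LOSS_SCALE^2
  # l_dc term
  if (lambda_dc > 0) {
    s_img <- synthesize_signal(p_rec, schedule)
    r <- encode(s_img, masks)$data - y$data        # masked residual
    g <- ifft2c_stack(r * masks$masks) * (2 * lambda_dc / n_img)
    s0 <- s0_complex(p_rec)
    inv_t2 <- ifelse(p_rec$t2 > 0, 1 / p_rec$t2, 0)
    dt2 <- matrix(0, d[1], d[2]); dre <- dt2; dim_ <- dt2
    for (i in seq_along(schedule$tes)) {
      te <- schedule$tes[i]
      e <- exp(-te * inv_t2)
      gi <- g[, , i]
      dre <- dre + Re(gi) * e
      dim_ <- dim_ + Im(gi) * e
      dt2 <- dt2 + Re(Conj(gi) * s0) * e * te * inv_t2^2
    }
    dp <- dp + cbind(as.vector(dt2), as.vector(dre), as.vector(dim_))
  }
  list(dx = dx, dp = dp)
}

# ---- early stopping --------------------------------------------------------

#' Early-stopping tracker
#'
#' Bookkeeping object used by the training loops: feed it one validation
#' loss per epoch with `es_update()`; it reports when the loss has failed
#' to improve for `patience` consecutive epochs and remembers the best
#' epoch.
#'
#' @param patience consecutive non-improving epochs tolerated.
#' @return an `early_stopper` list; update it functionally:
#'   `es <- es_update(es, loss)$state`.
#' @export
early_stopper <- function(patience) {
  stopifnot(patience >= 1)
  structure(list(patience = as.integer(patience), best = Inf,
                 best_epoch = 0L, epoch = 0L, stalled = 0L),
            class = "early_stopper")
}

#' @rdname early_stopper
#' @param es an `early_stopper`.
#' @param loss this epoch's validation loss.
#' @return list with `state` (updated tracker), `stop` (halt now?),
#'   `improved` (was this epoch a new best?).
#' @export
es_update <- function(es, loss) {
  es$epoch <- es$epoch + 1L
  improved <- loss < es$best
  if (improved) {
    es$best <- loss
    es$best_epoch <- es$epoch
    es$stalled <- 0L
  } else {
    es$stalled <- es$stalled + 1L
  }
  list(state = es, stop = es$stalled >= es$patience, improved = improved)
}

# ---- mapping-network pretraining ------------------------------------------

# Draw a dictionary of decay curves: T2 ~ U[10, 2500] ms, |S0| ~ U[0.05, 1],
# phase ~ U[0, 2pi), plus complex Gaussian noise at snr_db relative to the
# first-echo magnitude. Returns X (n x 2P) and targets (n x 3).
sample_dictionary <- function(n, schedule, snr_db = Inf, seed = 1L) {
  p <- n_echoes(schedule)
  with_seed(seed, {
    t2 <- stats::runif(n, 10, 2500)
    mag <- stats::runif(n, 0.05, 1)
    ph <- stats::runif(n, 0, 2 * pi)
    s0 <- mag * exp(1i * ph)
    decay <- exp(outer(-1 / t2, schedule$tes))       # n x P
    sig <- decay * s0
    if (is.finite(snr_db)) {
      sd_n <- (mag * exp(-schedule$tes[1] / t2)) * 10^(-snr_db / 20) / sqrt(2)
      noise <- matrix(complex(real = stats::rnorm(n * p),
                              imaginary = stats::rnorm(n * p)), n, p) * sd_n
      sig <- sig + noise
    }
    list(X = cbind(Re(sig), Im(sig)),
         targets = cbind(t2 = t2, s0_re = Re(s0), s0_im = Im(s0)))
  })
}

#' Pretrain the pixel-wise mapping network on a synthetic dictionary
#'
#' Supervised regression of (T2, Re S0, Im S0) from simulated decay curves
#' (T2 uniform on [10, 2500] ms, |S0| uniform on [0.05, 1], uniform random
#' phase, complex Gaussian noise at `snr_db` relative to the first echo;
#' the default dictionary is noiseless — the joint training that follows
#' re-exposes the network to realistic noise). The loss is the
#' mean-squared map loss `l_p`; optimization is minibatch Adam with the
#' learning rate stepped down to 0.2x after half the epochs and 0.04x
#' after three quarters, which is what lets the fit reach percent-level
#' relative accuracy.
#'
#' @param cfg a [map_net_config()].
#' @param schedule the `echo_schedule` the network will be applied to.
#' @param n_samples dictionary size (default 60000).
#' @param epochs passes over the dictionary (default 120).
#' @param batch_size minibatch size (default 256).
#' @param lr initial Adam learning rate (default 1e-3).
#' @param snr_db dictionary noise level, dB (default `Inf` = noiseless).
#' @param seed seed for the dictionary, init and shuffling.
#' @return an object of class `fmap_fit`: list with `weights`, `cfg`,
#'   `schedule`, and a per-epoch `history` tibble.
#' @export
pretrain_fmap <- function(cfg, schedule, n_samples = 60000L, epochs = 120L,
                          batch_size = 256L, lr = 1e-3, snr_db = Inf,
                          seed = 1L) {
  stopifnot(inherits(cfg, "map_net_config"))
  p <- n_echoes(schedule)
  dict <- sample_dictionary(n_samples, schedule, snr_db,
                            seed = derive_seed(seed, "dict"))
  weights <- init_fmap_weights(cfg, p, seed = derive_seed(seed, "init"))
  state <- adam_init(weights)
  n <- nrow(dict$X)
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * if (ep > ceiling(0.75 * epochs)) 0.04 else
      if (ep > ceiling(0.5 * epochs)) 0.2 else 1
    ord <- with_seed(derive_seed(seed, "shuffle", ep), sample.int(n))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      X <- dict$X[idx, , drop = FALSE]
      tgt <- dict$targets[idx, , drop = FALSE]
      fw <- fmap_forward(X, weights, cfg, want_cache = TRUE)
      diff <- fw$output - tgt
      diff[, 1] <- diff[, 1] / T2_LOSS_SCALE       # loss-space T2 (seconds)
      loss <- mean(diff^2)
      dout <- diff * (2 / length(diff))
      dout[, 1] <- dout[, 1] / T2_LOSS_SCALE
      bw <- fmap_backward(dout, fw$cache, weights, cfg)
      st <- adam_step(weights, bw$grads, state, lr_ep)
      weights <- st$params; state <- st$state
      ep_loss <- ep_loss + loss; nb <- nb + 1L
    }
    history[ep] <- ep_loss / nb
  }
  structure(list(weights = weights, cfg = cfg, schedule = schedule,
                 history = tibble::tibble(epoch = seq_len(epochs),
                                          loss = history),
                 seed = seed),
            class = "fmap_fit")
}

#' @export
print.fmap_fit <- function(x, ...) {
  cat(sprintf("<fmap_fit> %d params, %d epochs, final loss %.4g\n",
              n_parameters(x$weights), nrow(x$history),
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

# ---- end-to-end training ---------------------------------------------------

# One slice's forward + backward. Returns loss record and gradients for
# frec (and fmap unless frozen/skipped).
e2e_slice_pass <- function(rec, weights, recon_cfg, map_cfg, schedule, tc,
                           use_fmap, update_fmap) {
  y <- rec$us_kspace; masks <- rec$mask_set
  x_zf <- zero_fill(y, schedule)
  fr <- frec_forward(x_zf, y, masks, weights$frec, recon_cfg,
                     want_cache = TRUE)
  x_rec <- fr$output
  d <- dim(x_rec$data)
  if (use_fmap) {
    fm <- fmap_forward(x_rec, weights$fmap, map_cfg, want_cache = TRUE)
    p_rec <- fm$output
  } else {
    p_rec <- NULL
  }
  if (use_fmap) {
    losses <- compute_losses(x_rec, p_rec, rec$fs_image, rec$gt, y, masks,
                             schedule, tc$lambda_r, tc$lambda_p, tc$lambda_dc)
    lg <- loss_gradients(x_rec, p_rec, rec$fs_image, rec$gt, y, masks,
                         schedule, tc$lambda_r, tc$lambda_p, tc$lambda_dc)
    fb <- fmap_backward(lg$dp, fm$cache, weights$fmap, map_cfg)
    dx <- lg$dx + pixel_matrix_to_channels(fb$dX, d[1], d[2])
    fmap_grads <- if (update_fmap) fb$grads else NULL
  } else {
    n_img <- 2 * prod(d)
    l_r <- sum(Mod(rec$fs_image$data - x_rec$data)^2) / n_img
    losses <- structure(list(l_r = l_r, l_p = 0, l_dc = 0,
                             l_total = tc$lambda_r * l_r),
                        class = "loss_record")
    dx <- complex_to_channels(x_rec$data - rec$fs_image$data) *
      (2 * tc$lambda_r / n_img)
    fmap_grads <- NULL
  }
  rb <- frec_backward(dx, fr$cache, masks, weights$frec, recon_cfg)
  list(losses = losses, frec_grads = rb$grads, fmap_grads = fmap_grads)
}

# Validation loss over a list of slice records (fixed stored masks).
e2e_validation_loss <- function(recs, weights, recon_cfg, map_cfg, schedule,
                                tc, use_fmap) {
  tot <- 0
  for (rec in recs) {
    y <- rec$us_kspace; masks <- rec$mask_set
    x_zf <- zero_fill(y, schedule)
    x_rec <- frec_forward(x_zf, y, masks, weights$frec, recon_cfg)
    if (use_fmap) {
      p_rec <- fmap_forward(x_rec, weights$fmap, map_cfg)
      l <- compute_losses(x_rec, p_rec, rec$fs_image, rec$gt, y, masks,
                          schedule, tc$lambda_r, tc$lambda_p, tc$lambda_dc)
      tot <- tot + l$l_total
    } else {
      tot <- tot + tc$lambda_r *
        sum(Mod(rec$fs_image$data - x_rec$data)^2) / (2 * length(x_rec$data))
    }
  }
  tot / length(recs)
}

#' Train a reconstruction/mapping variant end to end
#'
#' Method `"A"` trains the unrolled reconstruction network and the
#' (pretrained) mapping network jointly under all three losses. Method
#' `"C"` trains the reconstruction network alone under the image loss only
#' (`lambda_p = lambda_dc = 0`); least-squares fitting replaces the mapping
#' network at inference. Method `"D"` trains the reconstruction network
#' under all three losses with the mapping network frozen at its
#' pretrained weights (the frozen network keeps the map and
#' data-consistency losses differentiable; least-squares fitting is used at
#' inference).
#'
#' Each epoch shuffles training slices across cases; with
#' `tc$refresh_masks` the sampling masks (and hence the undersampled
#' input) are redrawn for every batch from the stored noisy fully sampled
#' k-space. The validation loss uses each slice's fixed stored masks;
#' early stopping halts after `tc$patience` non-improving epochs and the
#' best-validation weights are returned.
#'
#' @param method one of `"A"`, `"C"`, `"D"`.
#' @param dataset a `qdcnn_dataset` with train and val splits.
#' @param recon_cfg a [recon_net_config()].
#' @param map_cfg a [map_net_config()] (ignored by method C).
#' @param tc a [train_config()].
#' @param pretrained an optional `fmap_fit` providing the initial (A) or
#'   frozen (D) mapping weights; required for methods A and D.
#' @param state_path optional path for epoch-level training state; when the
#'   file exists, training resumes from the last completed epoch (useful
#'   for long runs on shared machines). The file is removed once early
#'   stopping fires; a run that only reached `max_epochs` leaves it in
#'   place so it can be resumed with a larger cap.
#' @return an object of class `qdcnn_fit`: list with `weights`
#'   (`frec`, `fmap`), `method`, configs, and a per-epoch `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`, `best`).
#' @export
train_variant <- function(method, dataset, recon_cfg, map_cfg = NULL,
                          tc = train_config(), pretrained = NULL,
                          state_path = NULL) {
  if (!method %in% c("A", "C", "D")) stop("unknown method id: ", method)
  train_recs <- dataset_slices(dataset, "train")
  val_recs <- dataset_slices(dataset, "val")
  if (length(train_recs) == 0 || length(val_recs) == 0)
    stop("dataset must contain non-empty train and val splits")
  schedule <- dataset$config$schedule
  p <- n_echoes(schedule)
  use_fmap <- method %in% c("A", "D")
  update_fmap <- method == "A"
  tc_eff <- tc
  if (method == "C") { tc_eff$lambda_p <- 0; tc_eff$lambda_dc <- 0 }
  if (use_fmap && is.null(pretrained))
    stop("methods A and D require a pretrained mapping network")
  weights <- list(
    frec = init_frec_weights(recon_cfg, p, seed = derive_seed(tc$seed, "frec")),
    fmap = if (use_fmap) pretrained$weights else NULL)
  opt_params <- if (update_fmap) weights else list(frec = weights$frec)
  state <- adam_init(opt_params)
  n_train <- length(train_recs)
  es <- early_stopper(tc$patience)
  best_weights <- weights
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  hist_best <- logical(0)
  first_epoch <- 1L
  stopped <- FALSE
  if (!is.null(state_path) && file.exists(state_path)) {
    st0 <- readRDS(state_path)
    stopifnot(identical(st0$method, method))
    weights <- st0$weights; best_weights <- st0$best_weights
    opt_params <- st0$opt_params; state <- st0$state; es <- st0$es
    hist_epoch <- st0$hist_epoch; hist_train <- st0$hist_train
    hist_val <- st0$hist_val; hist_best <- st0$hist_best
    first_epoch <- st0$next_epoch
    stopped <- st0$stopped
  }
  for (ep in if (stopped || first_epoch > tc$max_epochs) integer(0) else
    first_epoch:tc$max_epochs) {
    ord <- with_seed(derive_seed(tc$seed, "shuffle", ep), sample.int(n_train))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n_train, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n_train)]
      batch_grads <- NULL
      batch_loss <- 0
      for (j in seq_along(idx)) {
        rec <- train_recs[[idx[j]]]
        if (tc$refresh_masks) {
          msk <- make_mask_set(dim(rec$fs_kspace$data)[1],
                               dim(rec$fs_kspace$data)[2], p,
                               dataset$config$af,
                               seed = derive_seed(tc$seed, "mask", ep, nb, j))
          rec$mask_set <- msk
          rec$us_kspace <- new_kspace_set(rec$fs_kspace$data * msk$masks, msk)
        }
        pass <- e2e_slice_pass(rec, weights, recon_cfg, map_cfg, schedule,
                               tc_eff, use_fmap, update_fmap)
        g <- if (update_fmap)
          list(frec = pass$frec_grads, fmap = pass$fmap_grads)
        else list(frec = pass$frec_grads)
        batch_grads <- if (is.null(batch_grads)) g else tree_add(batch_grads, g)
        batch_loss <- batch_loss + pass$losses$l_total
      }
      batch_grads <- tree_scale(batch_grads, 1 / length(idx))
      st <- adam_step(opt_params, batch_grads, state, tc$lr)
      opt_params <- st$params; state <- st$state
      weights$frec <- opt_params$frec
      if (update_fmap) weights$fmap <- opt_params$fmap
      ep_loss <- ep_loss + batch_loss / length(idx); nb <- nb + 1L
    }
    val_loss <- e2e_validation_loss(val_recs, weights, recon_cfg, map_cfg,
                                    schedule, tc_eff, use_fmap)
    upd <- es_update(es, val_loss)
    es <- upd$state
    if (upd$improved) best_weights <- weights
    hist_epoch <- c(hist_epoch, ep)
    hist_train <- c(hist_train, ep_loss / nb)
    hist_val <- c(hist_val, val_loss)
    hist_best <- c(hist_best, upd$improved)
    if (upd$stop) stopped <- TRUE
    if (!is.null(state_path)) {
      saveRDS(list(method = method, weights = weights,
                   best_weights = best_weights, opt_params = opt_params,
                   state = state, es = es, hist_epoch = hist_epoch,
                   hist_train = hist_train, hist_val = hist_val,
                   hist_best = hist_best, next_epoch = ep + 1L,
                   stopped = stopped),
              state_path)
    }
    if (stopped) break
  }
  # the state file survives a run that merely reached this call's epoch
  # cap (it may be resumed with a larger cap); early stopping is final
  if (!is.null(state_path) && file.exists(state_path) && stopped)
    unlink(state_path)
  structure(list(weights = best_weights, method = method,
                 recon_cfg = recon_cfg, map_cfg = map_cfg,
                 train_cfg = tc, schedule = schedule,
                 history = tibble::tibble(epoch = hist_epoch,
                                          train_loss = hist_train,
                                          val_loss = hist_val,
                                          best = hist_best),
                 best_val = es$best, best_epoch = es$best_epoch),
            class = "qdcnn_fit")
}

#' @rdname train_variant
#' @param dataset,recon_cfg,map_cfg,tc,pretrained see [train_variant()].
#' @export
train_e2e <- function(dataset, recon_cfg, map_cfg, tc = train_config(),
                      pretrained = NULL) {
  train_variant("A", dataset, recon_cfg, map_cfg, tc, pretrained)
}

#' @export
print.qdcnn_fit <- function(x, ...) {
  cat(sprintf(
    "<qdcnn_fit> method %s, %d epochs (best %d, val %.4g), %d recon params\n",
    x$method, nrow(x$history), x$best_epoch, x$best_val,
    n_parameters(x$weights$frec)))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint embeds the weights, both network configurations, the
#' training configuration (including its seed) and the training history,
#' so a reload reproduces inference exactly.
#'
#' @param fit a `qdcnn_fit` (or `fmap_fit`).
#' @param path file path for the checkpoint.
#' @return `path` invisibly; `load_checkpoint()` returns the fit object.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "qdcnn_fit") || inherits(fit, "fmap_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "qdcnn_fit") || inherits(fit, "fmap_fit"))
  fit
}

#' Apply a trained variant to one undersampled slice
#'
#' @param fit a `qdcnn_fit`.
#' @param y measured `kspace_set`; `masks` its sampling mask set.
#' @param masks the `sampling_mask_set`.
#' @param opts [fit_options()] for the least-squares mapping stage of
#'   methods C and D.
#' @return list with `x_rec` and `p_rec`.
#' @export
predict_maps <- function(fit, y, masks, opts = fit_options()) {
  schedule <- fit$schedule
  x_zf <- zero_fill(y, schedule)
  x_rec <- frec_forward(x_zf, y, masks, fit$weights$frec, fit$recon_cfg)
  p_rec <- if (fit$method == "A") {
    fmap_forward(x_rec, fit$weights$fmap, fit$map_cfg)
  } else {
    lsf_fit_image(x_rec, opts)
  }
  list(x_rec = x_rec, p_rec = p_rec)
}
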