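make_us_slice <- function(h = 16, p = 2, af = 2, seed = 5, noise_db = 30) {
  sched <- default_schedule(p)
  maps <- toy_maps(h = h, w = h, seed = seed)
  img <- synthesize_signal(maps, sched)
  noisy <- add_calibrated_noise(encode(img), noise_db, seed = seed + 1)
  msk <- make_mask_set(h, h, p, af = af, seed = seed + 2)
  list(y = kspace_set(noisy$data * msk$masks, msk), masks = msk,
       img = img, maps = maps, sched = sched)
}

test_that("the unrolled network reduces to zero-fill with zero cascades", {
  s <- make_us_slice()
  cfg <- recon_net_config(n_cascades = 0, convs_per_cascade = 1, filters = 1)
  x_zf <- zero_fill(s$y, s$sched)
  out <- frec_forward(x_zf, s$y, s$masks, list(), cfg)
  expect_identical(out$data, x_zf$data)
})

test_that("a zero-residual denoiser makes the DC layer the only action", {
  s <- make_us_slice()
  cfg <- recon_net_config(n_cascades = 1, convs_per_cascade = 2, filters = 4)
  w <- init_frec_weights(cfg, 2, seed = 3)
  # zero the last conv layer: the residual branch returns exactly zero
  w[[1]][[2]]$W[] <- 0; w[[1]][[2]]$b[] <- 0
  x_zf <- zero_fill(s$y, s$sched)
  out <- frec_forward(x_zf, s$y, s$masks, w, cfg)
  # hard DC: the measured coefficients are restored exactly
  k_out <- encode(out)
  on_idx <- s$masks$masks == 1
  expect_rel_equal(k_out$data[on_idx], s$y$data[on_idx], 1e-10)
  # fully sampled measurements + zero residual: output = input
  full <- qdcnn:::full_mask_set(16, 16, 2)
  y_full <- encode(s$img)
  x_zf_full <- zero_fill(kspace_set(y_full$data, NULL), s$sched)
  out_full <- frec_forward(x_zf_full, y_full, full, w, cfg)
  expect_rel_equal(out_full$data, x_zf_full$data, 1e-8)
})

test_that("hard data consistency never alters measured coefficients", {
  s <- make_us_slice(seed = 8)
  cfg <- recon_net_config(n_cascades = 2, convs_per_cascade = 2, filters = 4)
  w <- init_frec_weights(cfg, 2, seed = 4)
  out <- frec_forward(zero_fill(s$y, s$sched), s$y, s$masks, w, cfg)
  k_out <- qdcnn:::fft2c_stack(out$data)
  on_idx <- s$masks$masks == 1
  expect_rel_equal(k_out[on_idx], s$y$data[on_idx], 1e-10)
})

test_that("the mapping network is pixel-wise permutation equivariant", {
  s <- make_us_slice(h = 8, p = 4, seed = 2)
  for (nrm in c(FALSE, TRUE)) {
    cfg <- map_net_config(hidden_layers = 2, hidden_units = 16,
                          normalize = nrm)
    w <- init_fmap_weights(cfg, 4, seed = 6)
    p_out <- fmap_forward(s$img, w, cfg)
    expect_equal(dim(p_out$t2), c(8L, 8L))
    perm <- sample(64)
    img_p <- s$img
    for (i in 1:4) img_p$data[, , i] <- matrix(s$img$data[, , i][perm], 8, 8)
    p_perm <- fmap_forward(img_p, w, cfg)
    expect_equal(as.vector(p_perm$t2), as.vector(p_out$t2)[perm],
                 tolerance = 1e-12)
    expect_equal(as.vector(p_perm$s0_re), as.vector(p_out$s0_re)[perm],
                 tolerance = 1e-12)
  }
  expect_error(fmap_forward(matrix(c(NA, 1), 1, 2),
                            init_fmap_weights(map_net_config(1, 2), 1),
                            map_net_config(1, 2)),
               "non-finite")
})

test_that("T2 output respects its bounds and parameter counts are stable", {
  cfg <- map_net_config()
  w <- init_fmap_weights(cfg, 16, seed = 1)
  X <- matrix(rnorm(50 * 32, sd = 5), 50, 32)
  out <- fmap_forward(X, w, cfg)
  expect_true(all(out[, 1] > cfg$t2_min & out[, 1] < cfg$t2_max))
  # parameter counts are a pure function of the configs
  expect_equal(n_parameters(w),
               34 * 128 + 128 + 3 * (128 * 128 + 128) + 128 * 3 + 3)
  rcfg <- recon_net_config(preset = "desk")
  wf <- init_frec_weights(rcfg, 16, seed = 1)
  per_cascade <- (9 * 32 * 16 + 16) + (9 * 16 * 16 + 16) + (9 * 16 * 32 + 32)
  expect_equal(n_parameters(wf), 2 * per_cascade)
  # same-config inits are identical; different seeds differ
  expect_identical(init_frec_weights(rcfg, 16, seed = 1), wf)
  expect_false(identical(init_frec_weights(rcfg, 16, seed = 2), wf))
})

test_that("backpropagation matches finite differences end to end", {
  set.seed(5)
  h <- 8; P <- 2
  sched <- echo_schedule(c(20, 60), 7000)
  gt <- parameter_maps(matrix(runif(h * h, 50, 200), h, h),
                       matrix(runif(h * h, 0.2, 1), h, h))
  img <- synthesize_signal(gt, sched)
  noisy <- add_calibrated_noise(encode(img), 30, seed = 2)
  msk <- make_mask_set(h, h, P, af = 2, seed = 3)
  y <- kspace_set(noisy$data * msk$masks, msk)
  rcfg <- recon_net_config(n_cascades = 1, convs_per_cascade = 2, filters = 4)
  mcfg <- map_net_config(hidden_layers = 2, hidden_units = 8)
  wf <- init_frec_weights(rcfg, P, seed = 11)
  wm <- init_fmap_weights(mcfg, P, seed = 12)
  lam <- c(1, 1e-2, 1e-6)
  total_loss <- function(wf, wm) {
    x_rec <- frec_forward(zero_fill(y, sched), y, msk, wf, rcfg)
    p_rec <- fmap_forward(x_rec, wm, mcfg)
    compute_losses(x_rec, p_rec, img, gt, y, msk, sched,
                   lam[1], lam[2], lam[3])$l_total
  }
  rec <- list(us_kspace = y, mask_set = msk, fs_image = img, gt = gt)
  tc <- list(lambda_r = lam[1], lambda_p = lam[2], lambda_dc = lam[3])
  pass <- qdcnn:::e2e_slice_pass(rec, list(frec = wf, fmap = wm), rcfg, mcfg,
                                 sched, tc, TRUE, TRUE)
  eps <- 1e-6
  check_leaf <- function(get, set, agrad, k) {
    v0 <- get()
    set(v0 + eps * (seq_along(v0) == k)); lp <- total_loss(wf, wm)
    set(v0 - eps * (seq_along(v0) == k)); lm <- total_loss(wf, wm)
    set(v0)
    num <- (lp - lm) / (2 * eps)
    if (abs(num) < 1e-8) return(TRUE)
    abs(num - agrad[k]) / max(abs(num), 1e-10) < 1e-4
  }
  for (k in sample(length(wf[[1]][[1]]$W), 3))
    expect_true(check_leaf(function() wf[[1]][[1]]$W,
                           function(v) wf[[1]][[1]]$W <<- matrix(v, 9 * 2 * P),
                           pass$frec_grads[[1]][[1]]$W, k))
  for (k in sample(length(wm[[1]]$W), 3))
    expect_true(check_leaf(function() wm[[1]]$W,
                           function(v) wm[[1]]$W <<- matrix(v, nrow(wm[[1]]$W)),
                           pass$fmap_grads[[1]]$W, k))
  for (k in sample(length(wm[[3]]$b), 2))
    expect_true(check_leaf(function() wm[[3]]$b,
                           function(v) wm[[3]]$b <<- v,
                           pass$fmap_grads[[3]]$b, k))
})

test_that("the composed forward pass is deterministic and shape-correct", {
  s <- make_us_slice(h = 16, p = 2, seed = 12)
  rcfg <- recon_net_config(n_cascades = 1, convs_per_cascade = 2, filters = 4)
  mcfg <- map_net_config(hidden_layers = 2, hidden_units = 8)
  w <- list(frec = init_frec_weights(rcfg, 2, seed = 1),
            fmap = init_fmap_weights(mcfg, 2, seed = 2))
  a <- qdcnn_forward(s$y, s$masks, w, rcfg, mcfg, s$sched)
  b <- qdcnn_forward(s$y, s$masks, w, rcfg, mcfg, s$sched)
  expect_identical(a$p_rec$t2, b$p_rec$t2)
  expect_identical(dim(a$x_rec$data), dim(s$img$data))
  expect_equal(dim(a$p_rec$t2), c(16L, 16L))
})
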