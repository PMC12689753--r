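test_that("the loss record follows its algebra", {
  s_env <- new.env()
  sched <- default_schedule(2)
  maps <- toy_maps(h = 8, w = 8, seed = 1)
  img <- synthesize_signal(maps, sched)
  msk <- make_mask_set(8, 8, 2, af = 2, seed = 1)
  y <- encode(img, msk)
  # exact consistency: all losses vanish
  l0 <- compute_losses(img, maps, img, maps, y, msk, sched)
  expect_equal(l0$l_r, 0); expect_equal(l0$l_p, 0)
  expect_equal(l0$l_dc, 0, tolerance = 1e-25)
  # linearity in the lambdas
  x2 <- img; x2$data <- img$data + (0.1 + 0.05i)
  p2 <- parameter_maps(maps$t2 + 10, maps$s0_re + 0.1, maps$s0_im)
  la <- compute_losses(x2, p2, img, maps, y, msk, sched, 1, 1e-2, 1e-6)
  lb <- compute_losses(x2, p2, img, maps, y, msk, sched, 1, 2e-2, 1e-6)
  expect_equal(lb$l_total - la$l_total, 1e-2 * la$l_p, tolerance = 1e-12)
  expect_equal(la$l_total,
               la$l_r + 1e-2 * la$l_p + 1e-6 * la$l_dc, tolerance = 1e-12)
  expect_error(compute_losses(x2, p2, img, maps, y, msk, sched, -1, 0, 0),
               "non-negative")
})

test_that("the early stopper halts after exactly `patience` stalled epochs", {
  es <- early_stopper(10)
  # first epoch improves from Inf; then the loss is rigged constant
  upd <- es_update(es, 1.0)
  expect_true(upd$improved); expect_false(upd$stop)
  es <- upd$state
  for (i in 1:9) {
    upd <- es_update(es, 1.0)
    es <- upd$state
    expect_false(upd$stop)
  }
  upd <- es_update(es, 1.0)     # 10th consecutive non-improvement
  expect_true(upd$stop)
  expect_equal(upd$state$epoch, 11L)
  expect_equal(upd$state$best_epoch, 1L)
  # an improvement resets the stall counter
  es2 <- early_stopper(3)
  es2 <- es_update(es2, 5)$state
  es2 <- es_update(es2, 5)$state
  es2 <- es_update(es2, 4)$state
  expect_equal(es2$stalled, 0L)
})

test_that("mapping-network pretraining descends and is reproducible", {
  sched <- default_schedule(4)
  cfg <- map_net_config(hidden_layers = 2, hidden_units = 16)
  fit1 <- pretrain_fmap(cfg, sched, n_samples = 2000L, epochs = 5L,
                        batch_size = 128L, seed = 3)
  fit2 <- pretrain_fmap(cfg, sched, n_samples = 2000L, epochs = 5L,
                        batch_size = 128L, seed = 3)
  expect_lt(fit1$history$loss[5], fit1$history$loss[1])
  expect_identical(fit1$weights, fit2$weights)
  expect_equal(nrow(fit1$history), 5L)
  # a short fit already beats ignorance on easy mid-range decays
  d <- qdcnn:::sample_dictionary(500, sched, snr_db = Inf, seed = 77)
  pred <- fmap_forward(d$X, fit1$weights, cfg)
  expect_lt(mean(abs(pred[, 1] - d$targets[, 1])),
            mean(abs(mean(d$targets[, 1]) - d$targets[, 1])))
})

test_that("end-to-end training improves the objective and returns the best", {
  ds <- tiny_dataset(h = 32, n_slices = 2, af = 3, p = 4, seed = 11)
  rcfg <- recon_net_config(n_cascades = 1, convs_per_cascade = 2, filters = 4)
  mcfg <- map_net_config(hidden_layers = 2, hidden_units = 16)
  pre <- pretrain_fmap(mcfg, ds$config$schedule, n_samples = 3000L,
                       epochs = 8L, batch_size = 128L, seed = 5)
  tc <- train_config(max_epochs = 4L, batch_size = 2L, seed = 9,
                     lr = 3e-4)
  fit <- train_e2e(ds, rcfg, mcfg, tc, pretrained = pre)
  expect_s3_class(fit, "qdcnn_fit")
  # the untrained model's validation loss (epoch-0 surrogate): evaluate
  w0 <- list(frec = init_frec_weights(rcfg, 4,
                                      seed = qdcnn:::derive_seed(9, "frec")),
             fmap = pre$weights)
  val <- qdcnn:::dataset_slices(ds, "val")
  l_init <- qdcnn:::e2e_validation_loss(val, w0, rcfg, mcfg,
                                        ds$config$schedule, tc, TRUE)
  expect_lt(fit$best_val, l_init)
  expect_equal(fit$best_val, min(fit$history$val_loss))
  # returned weights reproduce the recorded best validation loss
  l_best <- qdcnn:::e2e_validation_loss(val, fit$weights, rcfg, mcfg,
                                        ds$config$schedule, tc, TRUE)
  expect_equal(l_best, fit$best_val, tolerance = 1e-12)
  # history is tidy-able
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$series), c("train", "validation"))
  expect_equal(glance(fit)$method, "A")
})

test_that("training variants wire their losses and updates correctly", {
  ds <- tiny_dataset(h = 32, n_slices = 1, af = 3, p = 4, seed = 21)
  rcfg <- recon_net_config(n_cascades = 1, convs_per_cascade = 2, filters = 4)
  mcfg <- map_net_config(hidden_layers = 2, hidden_units = 16)
  pre <- pretrain_fmap(mcfg, ds$config$schedule, n_samples = 2000L,
                       epochs = 5L, batch_size = 128L, seed = 5)
  tc <- train_config(max_epochs = 2L, batch_size = 2L, seed = 13)
  fit_a <- train_variant("A", ds, rcfg, mcfg, tc, pretrained = pre)
  fit_c <- train_variant("C", ds, rcfg, mcfg, tc)
  fit_d <- train_variant("D", ds, rcfg, mcfg, tc, pretrained = pre)
  # identical architectures across variants (controlled comparison)
  expect_equal(n_parameters(fit_a$weights$frec),
               n_parameters(fit_c$weights$frec))
  # A and C diverge after an epoch (different gradients)
  expect_false(identical(fit_a$weights$frec, fit_c$weights$frec))
  # D freezes the mapping network at its pretrained weights
  expect_identical(fit_d$weights$fmap, pre$weights)
  # A fine-tunes it
  expect_false(identical(fit_a$weights$fmap, pre$weights))
  expect_error(train_variant("B", ds, rcfg, mcfg, tc), "unknown")
  expect_error(train_variant("A", ds, rcfg, mcfg, tc), "pretrained")
  # with mask refresh off and equal seeds, training is reproducible
  tc2 <- train_config(max_epochs = 1L, batch_size = 2L, seed = 13,
                      refresh_masks = FALSE)
  r1 <- train_variant("C", ds, rcfg, mcfg, tc2)
  r2 <- train_variant("C", ds, rcfg, mcfg, tc2)
  expect_identical(r1$weights$frec, r2$weights$frec)
})

test_that("checkpointed training resumes bit-identically", {
  ds <- tiny_dataset(h = 32, n_slices = 2, af = 3, p = 4, seed = 11)
  rcfg <- recon_net_config(n_cascades = 1, convs_per_cascade = 2, filters = 4)
  mcfg <- map_net_config(hidden_layers = 2, hidden_units = 16)
  pre <- pretrain_fmap(mcfg, ds$config$schedule, n_samples = 2000L,
                       epochs = 5L, batch_size = 128L, seed = 5)
  tc4 <- train_config(max_epochs = 4L, batch_size = 2L, seed = 9)
  one <- train_variant("A", ds, rcfg, mcfg, tc4, pretrained = pre)
  sp <- tempfile()
  tc2 <- tc4; tc2$max_epochs <- 2L
  train_variant("A", ds, rcfg, mcfg, tc2, pretrained = pre, state_path = sp)
  expect_true(file.exists(sp))
  resumed <- train_variant("A", ds, rcfg, mcfg, tc4, pretrained = pre,
                           state_path = sp)
  expect_identical(resumed$weights, one$weights)
  expect_identical(resumed$history, one$history)
  unlink(sp)
})

test_that("the data-consistency loss ignores unmeasured k-space", {
  sched <- default_schedule(2)
  maps <- toy_maps(h = 8, w = 8, seed = 6)
  img <- synthesize_signal(maps, sched)
  msk <- make_mask_set(8, 8, 2, af = 2, seed = 2)
  y <- encode(img, msk)
  ldc <- function(image) {
    k <- qdcnn:::fft2c_stack(image) * msk$masks
    sum(Mod(y$data - k)^2) / (2 * length(image))
  }
  base <- ldc(img$data)
  # perturb only off the sampled set (in k-space) and re-evaluate
  delta_k <- array(complex(real = rnorm(128), imaginary = rnorm(128)),
                   dim = c(8, 8, 2)) * (1 - msk$masks)
  pert <- img$data + qdcnn:::ifft2c_stack(delta_k)
  expect_equal(ldc(pert), base, tolerance = 1e-12)
})
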