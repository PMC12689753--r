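test_that("tissue table validates and phantom labels stay within it", {
  tt <- tissue_table()
  expect_true(all(c("background", "csf", "gray_matter", "white_matter") %in%
                    tt$label))
  expect_error(tissue_table(data.frame(label = c("a", "a"), pd = c(1, 1),
                                       t1 = c(1, 1), t2 = c(1, 1))),
               "unique")
  vol <- generate_phantom(42, 48, 48, 5)
  expect_identical(vol, generate_phantom(42, 48, 48, 5))
  expect_true(all(unique(as.integer(vol)) %in% qdcnn:::LABEL_CODES))
  # different cases differ in at least 1% of voxels
  vol2 <- generate_phantom(43, 48, 48, 5)
  expect_gt(mean(vol != vol2), 0.01)
  # each core tissue covers >= 1% of the foreground on the central slice
  mid <- matrix(vol[3, , ], 48, 48)
  fg <- sum(mid != 0)
  for (lab in c("csf", "gray_matter", "white_matter"))
    expect_gt(sum(mid == qdcnn:::LABEL_CODES[[lab]]) / fg, 0.01)
  expect_error(generate_phantom(1, 16, 16, 2), "too small")
})

test_that("label-to-property lookup is exact", {
  tt <- tissue_table()
  lab <- matrix(0L, 4, 4)
  expect_true(all(labels_to_property_maps(lab, tt)$pd == 0))
  lab2 <- matrix(qdcnn:::LABEL_CODES[["white_matter"]], 4, 4)
  pm <- labels_to_property_maps(lab2, tt)
  wm <- tt[tt$label == "white_matter", ]
  expect_true(all(pm$pd == wm$pd) && all(pm$t1 == wm$t1) && all(pm$t2 == wm$t2))
  # histogram equivalence on a mixed slice
  vol <- generate_phantom(7, 48, 48, 1)
  sl <- matrix(vol[1, , ], 48, 48)
  pm2 <- labels_to_property_maps(sl, tt)
  for (nm in tt$label) {
    code <- qdcnn:::LABEL_CODES[[nm]]
    expect_equal(sum(pm2$t2 == tt$t2[tt$label == nm] &
                       sl == code), sum(sl == code))
  }
  bad <- matrix(9L, 2, 2)
  expect_error(labels_to_property_maps(bad, tt), "9")
})

test_that("k-space noise is calibrated exactly on the reference echo", {
  maps <- toy_maps(h = 24, w = 24, seed = 5)
  sched <- default_schedule(4)
  kf <- encode(synthesize_signal(maps, sched))
  noisy <- add_calibrated_noise(kf, 40, seed = 9)
  ref <- Mod(qdcnn:::ifft2c(kf$data[, , 1]))
  nref <- Mod(qdcnn:::ifft2c(noisy$data[, , 1]))
  expect_equal(psnr(ref, nref, peak = max(ref)), 40, tolerance = 1e-6)
  # later echoes are noisier in PSNR terms
  for (i in 2:4) {
    refi <- Mod(qdcnn:::ifft2c(kf$data[, , i]))
    ni <- Mod(qdcnn:::ifft2c(noisy$data[, , i]))
    expect_lt(psnr(refi, ni, peak = max(refi)), 40)
  }
  # no-noise switch and degenerate input
  expect_identical(add_calibrated_noise(kf, Inf, seed = 1)$data, kf$data)
  zero <- kspace_set(array(0i, dim = dim(kf$data)))
  expect_error(add_calibrated_noise(zero, 40, seed = 1), "zero-signal")
})

test_that("dataset assembly follows the simulation pipeline exactly", {
  ds <- tiny_dataset()
  cfg <- ds$config
  expect_equal(nrow(ds$manifest), 3L)
  expect_equal(ds$manifest$n_slices, cfg$split * cfg$n_slices)
  for (cs in ds$cases) {
    # per-case normalization: max |S0| = 1 across the volume
    s0max <- max(vapply(cs$gt_maps, function(g) max(s0_magnitude(g)),
                        numeric(1)))
    expect_equal(s0max, 1, tolerance = 1e-12)
    for (s in seq_along(cs$gt_maps)) {
      us <- cs$us_kspace[[s]]; m <- cs$mask_sets[[s]]$masks
      # undersampled k-space: exact masking of the noisy full k-space
      expect_identical(us$data, cs$fs_kspace_noisy[[s]]$data * m)
      expect_true(all(us$data[m == 0] == 0))
      # fully sampled round trip differs from the stored noiseless images
      # only by the calibrated k-space noise (40 dB -> ~1% amplitude)
      back <- adjoint_encode(cs$fs_kspace_noisy[[s]], cfg$schedule)
      expect_lt(max(Mod(back$data - cs$fs_images[[s]]$data)) /
                  max(Mod(cs$fs_images[[s]]$data)), 0.1)
    }
  }
  # noiseless round trip to 1e-8: rebuild one slice without noise
  cfg0 <- dataset_config(n_cases = 1L, split = c(1L, 0L, 0L), n_slices = 1L,
                         h = 32L, w = 32L, schedule = default_schedule(4),
                         noise_psnr_db = Inf, af = 3, seed = 2)
  ds0 <- build_dataset(cfg0)
  cs <- ds0$cases[[1]]
  back <- adjoint_encode(cs$fs_kspace_noisy[[1]], cfg0$schedule)
  expect_rel_equal(back$data, cs$fs_images[[1]]$data, 1e-8)
  # bit-identical regeneration from the same config
  ds_b <- build_dataset(ds$config)
  expect_identical(ds$cases[[1]]$us_kspace[[1]]$data,
                   ds_b$cases[[1]]$us_kspace[[1]]$data)
  expect_identical(ds$cases[[2]]$gt_maps[[2]]$t2,
                   ds_b$cases[[2]]$gt_maps[[2]]$t2)
})

test_that("dataset bundles round-trip through disk", {
  ds <- tiny_dataset(h = 32, n_slices = 1, p = 2, seed = 3)
  dir <- tempfile("bundle")
  write_dataset_bundle(ds, dir)
  back <- read_dataset_bundle(dir)
  expect_equal(length(back$cases), length(ds$cases))
  expect_identical(back$cases[[1]]$us_kspace[[1]]$data,
                   ds$cases[[1]]$us_kspace[[1]]$data)
  expect_equal(back$manifest$n_slices, ds$manifest$n_slices)
  unlink(dir, recursive = TRUE)
})
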