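test_that("mask sets have the promised line structure", {
  for (seed in c(1, 2, 99)) {
    msk <- make_mask_set(64, 48, p = 4, af = 4, seed = seed)
    expect_equal(dim(msk$masks), c(64L, 48L, 4L))
    for (i in 1:4) {
      m <- msk$masks[, , i]
      # full read-out lines: constant along the frequency-encode axis
      expect_true(all(m == m[, 1]))
      expect_equal(sum(m[, 1]), round(64 / 4))
      # central block always sampled
      ctr <- floor(64 / 2) + 1
      half <- floor(msk$center_lines / 2)
      expect_true(all(m[(ctr - half):(ctr - half + msk$center_lines - 1), ] == 1))
    }
  }
  # determinism and seed sensitivity
  a <- make_mask_set(64, 64, 4, 4, seed = 5)
  b <- make_mask_set(64, 64, 4, 4, seed = 5)
  c <- make_mask_set(64, 64, 4, 4, seed = 6)
  expect_identical(a$masks, b$masks)
  expect_false(identical(a$masks, c$masks))
  # af = 1 gives full masks; infeasible af rejected
  expect_true(all(make_mask_set(32, 32, 2, 1, seed = 1)$masks == 1))
  expect_error(make_mask_set(64, 64, 2, af = 40, seed = 1), "center")
})

test_that("encoding is unitary under full sampling and adjoint to zero-fill", {
  set.seed(21)
  h <- 24; w <- 20; p <- 3
  x <- random_image(h, w, p, seed = 21)
  # Parseval
  k <- encode(x)
  expect_rel_equal(sqrt(sum(Mod(k$data)^2)), sqrt(sum(Mod(x$data)^2)), 1e-12)
  # unitary round trip
  expect_rel_equal(adjoint_encode(k, x$schedule)$data, x$data, 1e-12)
  # adjoint identity on random masked instances
  msk <- make_mask_set(h, w, p, af = 3, seed = 2)
  y <- array(complex(real = rnorm(h * w * p), imaginary = rnorm(h * w * p)),
             dim = c(h, w, p)) * msk$masks
  lhs <- sum(Re(Conj(encode(x, msk)$data) * y))
  rhs <- sum(Re(Conj(adjoint_encode(kspace_set(y, msk), x$schedule)$data) *
                  x$data))
  expect_rel_equal(lhs, rhs, 1e-12)
  # zero image encodes to zero
  x0 <- multicontrast_image(array(0i, dim = c(h, w, p)), x$schedule)
  expect_true(all(encode(x0, msk)$data == 0))
})

test_that("masked encode-adjoint is a projection", {
  h <- 16; w <- 16; p <- 2
  msk <- make_mask_set(h, w, p, af = 2, seed = 7)
  sched <- default_schedule(p)
  set.seed(8)
  y_dat <- array(complex(real = rnorm(h * w * p), imaginary = rnorm(h * w * p)),
                 dim = c(h, w, p)) * msk$masks
  y <- kspace_set(y_dat, msk)
  # E adjoint(y) = y when y is supported on the sampled set
  back <- encode(adjoint_encode(y, sched), msk)
  expect_rel_equal(back$data, y$data, 1e-12)
  # single sampled k-space point: zero-filled image is a complex sinusoid
  # with constant magnitude everywhere
  k1 <- array(0i, dim = c(h, w, p)); k1[4, 5, ] <- 1
  img <- adjoint_encode(kspace_set(k1, NULL), sched)
  mags <- Mod(img$data[, , 1])
  expect_rel_equal(mags, matrix(mags[1, 1], h, w), 1e-12)
})

test_that("mask line patterns export to CSV", {
  msk <- make_mask_set(32, 32, 3, af = 2, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_mask_csv(msk, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 32L)
  expect_equal(unname(colSums(back[, -1])), rep(16, 3))
  expect_identical(back$echo1, as.integer(msk$masks[, 1, 1]))
  unlink(path)
})

test_that("data consistency blends and hard-replaces correctly", {
  h <- 8; w <- 8; p <- 2
  msk <- make_mask_set(h, w, p, af = 2, seed = 3)
  full <- qdcnn:::full_mask_set(h, w, p)
  set.seed(4)
  ke <- kspace_set(array(complex(real = rnorm(h * w * p),
                                 imaginary = rnorm(h * w * p)), c(h, w, p)))
  yd <- array(complex(real = rnorm(h * w * p), imaginary = rnorm(h * w * p)),
              c(h, w, p))
  # full masks + hard consistency: output equals measurements exactly
  yfull <- kspace_set(yd, NULL)
  out <- data_consistency(ke, yfull, full, nu = Inf)
  expect_identical(out$data, yd)
  # empty masks: estimate untouched
  none <- structure(list(masks = array(0, c(h, w, p)), af = Inf,
                         center_lines = 0, seed = 0, lines_per_echo = 0),
                    class = "sampling_mask_set")
  expect_identical(data_consistency(ke, kspace_set(yd * 0), none, Inf)$data,
                   ke$data)
  # closed form on a sampled point: (2 + 1*0) / (1 + 1) = 1
  ke2 <- kspace_set(array(2 + 0i, c(h, w, p)))
  y0 <- kspace_set(array(0i, c(h, w, p)) * msk$masks, msk)
  dc <- data_consistency(ke2, y0, msk, nu = 1)
  on_idx <- msk$masks == 1
  expect_true(all(dc$data[on_idx] == 1))
  expect_true(all(dc$data[!on_idx] == 2))
  # nu = Inf is idempotent and leaves unsampled coefficients bit-identical
  ym <- kspace_set(yd * msk$masks, msk)
  once <- data_consistency(ke, ym, msk, Inf)
  twice <- data_consistency(once, ym, msk, Inf)
  expect_identical(once$data, twice$data)
  expect_identical(once$data[!on_idx], ke$data[!on_idx])
  expect_error(data_consistency(ke, ym, msk, nu = -1), "non-negative")
})
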