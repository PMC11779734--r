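test_that("predicted kernels have the contracted shape and normalization", {
  set.seed(1)
  cfg <- carafe_config(2L, k_up = 3L, c_m = 8L)
  mod <- carafe_init(3L, cfg)
  x <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  kern <- predict_kernels(x, mod)
  expect_identical(dim(kern), c(8L, 8L, 9L))
  expect_true(all(kern >= 0))
  expect_lt(max(abs(apply(kern, c(1, 2), sum) - 1)), 1e-6)

  # constant field: kernels are identical across positions that share a
  # sub-position offset (the encoder assigns each offset its own channels)
  kk <- predict_kernels(array(2.5, c(3, 4, 4)), mod)
  for (sy in 1:2) {
    for (sx in 1:2) {
      sl <- kk[seq(sy, 8, 2), seq(sx, 8, 2), , drop = FALSE]
      expect_lt(max(apply(sl, 3, function(m) diff(range(m)))), 1e-12)
    }
  }
})

test_that("delta kernels reproduce nearest-neighbor upsampling exactly", {
  set.seed(2)
  x <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  kd <- array(0, c(8, 8, 9))
  kd[, , 5] <- 1 # center tap of a 3x3 kernel
  y <- reassemble(x, kd, 2L)
  expect_equal(y, x[, rep(1:4, each = 2), rep(1:4, each = 2)], tolerance = 1e-14)
})

test_that("constant input is reproduced at interior positions", {
  set.seed(3)
  cfg <- carafe_config(2L, k_up = 3L, c_m = 4L)
  mod <- carafe_init(2L, cfg)
  x <- array(7.5, c(2, 6, 6))
  y <- carafe_upsample(x, mod)
  # interior: source neighborhoods that never touch the zero padding
  expect_lt(max(abs(y[, 3:10, 3:10] - 7.5)), 1e-9)
})

test_that("vectorized reassembly equals the naive loop oracle", {
  set.seed(4)
  for (trial in 1:8) {
    C <- sample(1:3, 1)
    H <- sample(2:8, 1)
    W <- sample(2:8, 1)
    sigma <- sample(2:4, 1)
    kup <- sample(c(3L, 5L), 1)
    x <- array(rnorm(C * H * W), c(C, H, W))
    kern <- array(runif(sigma^2 * H * W * kup^2), c(H * sigma, W * sigma, kup^2))
    kern <- kern / array(rep(apply(kern, c(1, 2), sum), kup^2), dim(kern))
    expect_equal(reassemble(x, kern, sigma), naive_reassemble(x, kern, sigma),
                 tolerance = 1e-5)
  }
  expect_error(reassemble(array(0, c(1, 4, 4)), array(0.25, c(6, 6, 4)), 2L),
               "does not match")
})

test_that("interior outputs are convex combinations of the source neighborhood", {
  set.seed(5)
  cfg <- carafe_config(2L, k_up = 3L, c_m = 8L)
  mod <- carafe_init(2L, cfg)
  x <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  y <- carafe_upsample(x, mod)
  for (oy in 3:10) {
    for (ox in 3:10) {
      sy <- (oy - 1) %/% 2 + 1
      sx <- (ox - 1) %/% 2 + 1
      nbhd <- x[, (sy - 1):(sy + 1), (sx - 1):(sx + 1), drop = FALSE]
      for (c in 1:2) {
        expect_gte(y[c, oy, ox], min(nbhd[c, , ]) - 1e-9)
        expect_lte(y[c, oy, ox], max(nbhd[c, , ]) + 1e-9)
      }
    }
  }
})

test_that("channels share kernels: permuting channels permutes outputs", {
  set.seed(6)
  x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  kern <- array(runif(36 * 9), c(6, 6, 9))
  kern <- kern / array(rep(apply(kern, c(1, 2), sum), 9), dim(kern))
  y <- reassemble(x, kern, 2L)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(reassemble(x[perm, , ], kern, 2L), y[perm, , ],
               tolerance = 1e-12)
})

test_that("upsampling factors compose in size", {
  set.seed(7)
  x <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  m2 <- carafe_init(2L, carafe_config(2L, k_up = 3L, c_m = 4L))
  m4 <- carafe_init(2L, carafe_config(4L, k_up = 3L, c_m = 4L))
  twice <- carafe_upsample(carafe_upsample(x, m2), m2)
  once <- carafe_upsample(x, m4)
  expect_identical(dim(twice), dim(once))
  expect_identical(dim(once), c(2L, 16L, 16L))
})
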