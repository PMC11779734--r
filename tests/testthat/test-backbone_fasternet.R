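test_that("pconv convolves the leading channels and copies the rest bitwise", {
  set.seed(1)
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  spec <- pconv_spec(4, 1, 3)
  w <- array(rnorm(9), c(1, 1, 3, 3))
  y <- pconv_forward(x, spec, w)
  expect_identical(y[2:4, , ], x[2:4, , ])
  expect_equal(y[1, , ], naive_conv(x[1, , , drop = FALSE], w)[1, , ],
               tolerance = 1e-12)

  # full-channel limit: identical to a regular convolution
  spec4 <- pconv_spec(4, 4, 3)
  w4 <- array(rnorm(4 * 4 * 9), c(4, 4, 3, 3))
  expect_equal(pconv_forward(x, spec4, w4), naive_conv(x, w4), tolerance = 1e-10)

  expect_error(pconv_forward(x, pconv_spec(5, 2, 3), array(0, c(2, 2, 3, 3))),
               "channels")
  expect_error(pconv_spec(4, 5), "c_p")
  expect_error(pconv_spec(4, 2, 4), "odd")
})

test_that("pconv_flops matches the instrumented loop oracle and scales as (c_p/c)^2", {
  x <- array(rnorm(1 * 8 * 8), c(1, 8, 8))
  w <- array(rnorm(9), c(1, 1, 3, 3))
  counted <- naive_conv(x, w, count = TRUE)$macs
  f <- pconv_flops(pconv_spec(4, 1, 3), 8, 8)
  expect_identical(f$partial, counted)
  expect_identical(f$partial, 576)
  expect_identical(f$full, 9216)
  expect_equal(f$ratio, (1 / 4)^2)

  expect_equal(pconv_flops(pconv_spec(8, 8, 3), 4, 4)$ratio, 1)
  expect_equal(pconv_flops(pconv_spec(8, 4, 3), 4, 4)$ratio, 1 / 4)

  # strict monotonicity in each argument
  base <- pconv_flops(pconv_spec(8, 2, 3), 6, 6)$partial
  expect_gt(pconv_flops(pconv_spec(8, 2, 3), 7, 6)$partial, base)
  expect_gt(pconv_flops(pconv_spec(8, 2, 3), 6, 7)$partial, base)
  expect_gt(pconv_flops(pconv_spec(8, 2, 5), 6, 6)$partial, base)
  expect_gt(pconv_flops(pconv_spec(8, 3, 3), 6, 6)$partial, base)
})

test_that("fasternet block is residual with preserved shape", {
  set.seed(2)
  p <- fasternet_block_params(16L, 4L)
  x <- array(rnorm(16 * 8 * 8), c(16, 8, 8))
  y <- fasternet_block(x, p)
  expect_identical(dim(y), dim(x))

  # zero branch weights -> exact identity
  pz <- fasternet_block_params(16L, 4L)
  pz$pw2$w$val[] <- 0
  pz$pw2$b$val[] <- 0
  expect_equal(fasternet_block(x, pz), x, tolerance = 1e-12)

  # straight-line composition of the four sub-operations; rebuild the pconv
  # weights in (out, in, ky, kx) order from the stored im2col matrix
  wm <- p$pconv$w$val
  warr <- array(0, c(4, 4, 3, 3))
  for (o in 1:4) warr[o, , , ] <- aperm(array(wm[o, ], c(3, 3, 4)), c(3, 2, 1))
  xp <- x
  conv1 <- naive_conv(x[1:4, , , drop = FALSE], warr)
  for (o in 1:4) conv1[o, , ] <- conv1[o, , ] + p$pconv$b$val[o]
  xp[1:4, , ] <- conv1
  flat <- matrix(aperm(xp, c(1, 3, 2)), nrow = 16)
  h1 <- p$pw1$w$val %*% flat + p$pw1$b$val
  # eval-mode BN at init scales by 1/sqrt(1 + eps) with mean 0, var 1
  h1 <- pmax(h1 / sqrt(1 + 1e-5), 0)
  h2 <- p$pw2$w$val %*% h1 + p$pw2$b$val
  ref <- x + aperm(array(h2, c(16, 8, 8)), c(1, 3, 2))
  expect_equal(y, ref, tolerance = 1e-10)
})

test_that("backbone emits stride-4 and stride-32 maps with configured widths", {
  set.seed(3)
  cfg <- backbone_config(depths = c(1, 1, 1, 1), widths = c(8, 16, 32, 64))
  bb <- backbone_init(cfg)
  out <- backbone_forward(array(rnorm(3 * 64 * 64), c(3, 64, 64)), bb)
  expect_identical(dim(out$low), c(8L, 16L, 16L))
  expect_identical(dim(out$high), c(64L, 2L, 2L))
  expect_error(backbone_forward(array(0, c(3, 100, 100)), bb), "divisible")

  # determinism: fixed weights and input give bit-identical output
  out2 <- backbone_forward(array(0.5, c(3, 64, 64)), bb)
  out3 <- backbone_forward(array(0.5, c(3, 64, 64)), bb)
  expect_identical(out2$high, out3$high)
})

test_that("untouched-channel identity holds across random pconv cases", {
  set.seed(4)
  for (i in 1:10) {
    c <- sample(3:8, 1)
    cp <- sample(seq_len(c - 1L), 1)
    x <- array(rnorm(c * 6 * 6), c(c, 6, 6))
    w <- array(rnorm(cp * cp * 9), c(cp, cp, 3, 3))
    y <- pconv_forward(x, pconv_spec(c, cp, 3), w)
    expect_identical(y[(cp + 1):c, , ], x[(cp + 1):c, , ])
  }
})
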