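test_that("dilated convolution has the documented sampling pattern", {
  set.seed(1)
  # r = 1 equals a regular same-padded convolution
  x <- array(rnorm(2 * 9 * 9), c(2, 9, 9))
  w <- array(rnorm(3 * 2 * 9), c(3, 2, 3, 3))
  expect_equal(dilated_conv(x, 1, w), naive_conv(x, w), tolerance = 1e-10)

  # impulse response: taps land exactly on the r-spaced offsets
  for (r in c(2L, 3L)) {
    xi <- array(0, c(1, 21, 21))
    xi[1, 11, 11] <- 1
    yi <- dilated_conv(xi, r, array(1, c(1, 1, 3, 3)))
    expect_identical(dim(yi), dim(xi))
    nz <- which(yi[1, , ] != 0, arr.ind = TRUE)
    expect_identical(nrow(nz), 9L)
    expect_true(all((nz - 11L) %% r == 0))
    span <- diff(range(nz[, 1]))
    expect_identical(span, 2L * r) # effective span 2r + 1
  }
  expect_error(dilated_conv(x, 0, w), "rate")
})

test_that("pyramid emits the configured width at unchanged spatial size", {
  set.seed(2)
  pyr <- pspa_init(16L, pyramid_config(branch_width = 8L, out_width = 32L,
                                       branch_a_width = 16L))
  x <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  y <- pspa_forward(x, pyr)
  expect_identical(dim(y), c(32L, 16L, 16L))

  # default configuration carries the published widths
  cfg <- pyramid_config()
  expect_identical(cfg$branch_width, 128L)
  expect_identical(cfg$out_width, 256L)
  expect_identical(unlist(cfg$rate_pairs), c(2L, 3L, 5L, 7L))

  # too-small input warns (does not error)
  expect_warning(pspa_forward(array(rnorm(16 * 4 * 4), c(16, 4, 4)), pyr),
                 "span")
})

test_that("pyramid equals a straight-line composition of its branches", {
  set.seed(3)
  cin <- 8L
  cfg <- pyramid_config(branch_width = 4L, out_width = 8L, branch_a_width = 8L)
  pyr <- pspa_init(cin, cfg)
  x <- array(rnorm(cin * 16 * 16), c(cin, 16, 16))
  y <- pspa_forward(x, pyr)

  p <- pyr$params
  bnid <- 1 / sqrt(1 + 1e-5) # eval-mode BN at freshly initialized stats
  conv_cbr <- function(z, cbr, rate = 1L) {
    k <- cbr$conv$k
    warr <- array(0, c(nrow(cbr$conv$w$val), dim(z)[1L], k, k))
    for (o in seq_len(nrow(cbr$conv$w$val))) {
      warr[o, , , ] <- aperm(array(cbr$conv$w$val[o, ], c(k, k, dim(z)[1L])),
                             c(3, 2, 1))
    }
    out <- if (k == 1L) {
      flat <- matrix(aperm(z, c(1, 3, 2)), nrow = dim(z)[1L])
      aperm(array(cbr$conv$w$val %*% flat, c(nrow(cbr$conv$w$val), dim(z)[3L],
                                             dim(z)[2L])), c(1, 3, 2))
    } else {
      dilated_conv(z, rate, warr)
    }
    out <- out + cbr$conv$b$val
    pmax(out * bnid, 0)
  }
  brA <- x
  wm <- p$a_pconv$w$val
  cp <- p$c_p
  warr <- array(0, c(cp, cp, 3, 3))
  for (o in seq_len(cp)) warr[o, , , ] <- aperm(array(wm[o, ], c(3, 3, cp)), c(3, 2, 1))
  conv1 <- naive_conv(x[seq_len(cp), , , drop = FALSE], warr) + p$a_pconv$b$val
  brA[seq_len(cp), , ] <- conv1
  brA <- conv_cbr(brA, p$a_proj)
  rates <- unlist(cfg$rate_pairs)
  dil <- lapply(1:4, function(i) conv_cbr(x, p$dil[[i]], rates[i]))
  pooled <- apply(x, 1, mean)
  pd <- pmax((p$pool$conv$w$val %*% pooled + p$pool$conv$b$val) * bnid, 0)
  brD <- array(rep(pd, times = 16 * 16), c(length(pd), 16, 16))
  stacked <- array(0, c(8L + 4L * 4L + 8L, 16, 16))
  stacked[1:8, , ] <- brA
  for (i in 1:4) stacked[8L + (i - 1L) * 4L + 1:4, , ] <- dil[[i]]
  stacked[25:32, , ] <- brD
  ref <- conv_cbr(stacked, p$fuse)
  expect_equal(y, ref, tolerance = 1e-8)
})

test_that("constant input makes the pooling branch spatially constant", {
  set.seed(4)
  pyr <- pspa_init(6L, pyramid_config(branch_width = 4L, out_width = 8L,
                                      branch_a_width = 8L))
  x <- array(rep(rnorm(6), 32 * 32), c(6, 32, 32))
  y <- pspa_forward(x, pyr)
  # interior of every output channel is constant (borders excluded: the
  # dilated branches see zero padding up to the largest span of 15)
  inner <- y[, 16:17, 16:17, drop = FALSE]
  expect_lt(max(apply(inner, 1, function(z) diff(range(z)))), 1e-8)
})

test_that("rate pairs must be coprime", {
  expect_error(pyramid_config(rate_pairs = list(c(2L, 4L), c(5L, 7L))),
               "coprime")
  expect_silent(pyramid_config())
})

test_that("grid coverage flags shared-rate stacks and the pyramid saves compute", {
  expect_identical(grid_coverage(1L), 1)
  expect_identical(grid_coverage(c(1L, 1L)), 1)
  cov222 <- grid_coverage(c(2L, 2L, 2L))
  expect_lt(cov222, 1)
  expect_equal(cov222, sumset_coverage(c(2L, 2L, 2L)), tolerance = 1e-12)
  expect_equal(grid_coverage(c(2L, 3L)), sumset_coverage(c(2L, 3L)),
               tolerance = 1e-12)
  expect_gt(grid_coverage(c(2L, 3L)), grid_coverage(c(2L, 2L)))
  for (rates in list(c(3L, 3L), c(2L, 2L), c(2L, 3L, 5L), c(5L, 7L))) {
    expect_equal(grid_coverage(rates), sumset_coverage(rates), tolerance = 1e-12)
  }

  f <- pspa_flops(320L, 16L, 16L)
  expect_lt(f$pspa, f$aspp)
  expect_gt(f$saving, 0)
})
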