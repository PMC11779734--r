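stamp_curve <- function(h, w, xs, ys, radius) {
  m <- matrix(0L, h, w)
  for (i in seq_along(xs)) {
    for (dy in -ceiling(radius):ceiling(radius)) {
      for (dx in -ceiling(radius):ceiling(radius)) {
        if (dx^2 + dy^2 <= radius^2) {
          y <- round(ys[i]) + dy
          x <- round(xs[i]) + dx
          if (y >= 1 && y <= h && x >= 1 && x <= w) m[y, x] <- 1L
        }
      }
    }
  }
  m
}

test_that("hilditch thinning yields one-pixel-wide, contained, connected skeletons", {
  # symmetric horizontal ribbon -> single-row centerline
  bar <- matrix(0L, 20, 120)
  bar[10:12, 10:110] <- 1L
  sk <- hilditch_skeletonize(bar)
  rows <- unique(which(sk, arr.ind = TRUE)[, 1])
  expect_lte(length(rows), 2L)
  expect_true(all(sk[bar == 0L] == FALSE))

  # filled disc collapses to a small central cluster
  disc <- matrix(0L, 60, 60)
  for (y in 1:60) for (x in 1:60) if ((x - 30)^2 + (y - 30)^2 <= 400) disc[y, x] <- 1L
  skd <- hilditch_skeletonize(disc)
  expect_lt(sum(skd), 0.02 * sum(disc))

  # L-shaped ribbon keeps one component
  L <- matrix(0L, 60, 60)
  L[10:13, 10:50] <- 1L
  L[10:50, 47:50] <- 1L
  skl <- hilditch_skeletonize(L)
  lab <- dfma:::cpp_label_components(as.integer(t(matrix(as.integer(skl), 60))), 60L, 60L)
  expect_identical(max(lab), 1L)

  # empty input: empty skeleton, no error
  expect_identical(sum(hilditch_skeletonize(matrix(0L, 5, 5))), 0L)

  # property: containment and unit width on random hole-free blobs
  # (thinning preserves topology, so a mask with pin-holes keeps rings
  # around them and those rings are legitimately wider than one pixel)
  set.seed(1)
  fill_holes <- function(m) {
    for (pass in 1:3) {
      h <- nrow(m); w <- ncol(m)
      inner <- m[2:(h - 1), 2:(w - 1)] == 0L &
        m[1:(h - 2), 2:(w - 1)] == 1L & m[3:h, 2:(w - 1)] == 1L &
        m[2:(h - 1), 1:(w - 2)] == 1L & m[2:(h - 1), 3:w] == 1L
      if (!any(inner)) break
      sub <- m[2:(h - 1), 2:(w - 1)]
      sub[inner] <- 1L
      m[2:(h - 1), 2:(w - 1)] <- sub
    }
    m
  }
  for (i in 1:10) {
    m <- fill_holes(stamp_curve(50, 50, runif(30, 10, 40), runif(30, 10, 40), 3))
    s <- hilditch_skeletonize(m)
    expect_true(all(m[s] == 1L))
    h <- nrow(s); w <- ncol(s)
    blocks <- s[-h, -w] & s[-1, -w] & s[-h, -1] & s[-1, -1]
    expect_identical(sum(blocks), 0L)
  }
})

test_that("skeleton_length counts axial and diagonal edges once", {
  line <- matrix(0L, 5, 120)
  line[3, 10:110] <- 1L
  expect_equal(skeleton_length(line == 1), 100)
  diag11 <- matrix(0L, 30, 30)
  for (i in 1:11) diag11[i + 5, i + 5] <- 1L
  expect_equal(skeleton_length(diag11 == 1), 10 * sqrt(2))
  expect_equal(skeleton_length(matrix(FALSE, 3, 3)), 0)
})

test_that("resampled path length tracks analytic arc length on curves", {
  # exact on straight lines
  line <- matrix(0L, 5, 120); line[3, 10:110] <- 1L
  expect_equal(skeleton_path_length(line == 1), 100)
  diag11 <- matrix(0L, 30, 30)
  for (i in 1:11) diag11[i + 5, i + 5] <- 1L
  expect_equal(skeleton_path_length(diag11 == 1), 10 * sqrt(2), tolerance = 1e-9)

  # quarter-circle arc, radius 100: skeleton within 3% of 50*pi
  t <- seq(0, pi / 2, length.out = 2000)
  qc <- stamp_curve(130, 130, 11 + 100 * cos(t), 11 + 100 * sin(t), 2.5)
  len <- skeleton_path_length(hilditch_skeletonize(qc))
  expect_lt(abs(len - 50 * pi) / (50 * pi), 0.03)
})

test_that("length measurement is rotation-robust", {
  t <- seq(0, 1, length.out = 800)
  mk <- function(angle) {
    stamp_curve(140, 140, 70 + 50 * (2 * t - 1) * cos(angle),
                70 + 50 * (2 * t - 1) * sin(angle), 2.5)
  }
  l0 <- skeleton_path_length(hilditch_skeletonize(mk(0)))
  l90 <- skeleton_path_length(hilditch_skeletonize(mk(pi / 2)))
  l45 <- skeleton_path_length(hilditch_skeletonize(mk(pi / 4)))
  expect_equal(l0, l90, tolerance = 1e-9)
  expect_lt(abs(l45 - l0) / l0, 0.08)
})

test_that("the coin detector recovers synthetic discs and rejects blanks", {
  img <- array(20, c(240, 260, 3))
  g <- expand.grid(y = 0:239, x = 0:259)
  inside <- (g$x - 120)^2 + (g$y - 100)^2 <= 2500
  for (c in 1:3) {
    pl <- img[, , c]
    pl[cbind(g$y + 1, g$x + 1)[inside, ]] <- 210
    img[, , c] <- pl
  }
  fit <- detect_coin(img)
  expect_lt(abs(fit$x - 120), 2)
  expect_lt(abs(fit$y - 100), 2)
  expect_lt(abs(fit$r - 50), 2)

  set.seed(2)
  noisy <- pmin(pmax(img + array(rnorm(length(img), sd = 10), dim(img)), 0), 255)
  fitn <- detect_coin(noisy)
  expect_lt(abs(fitn$x - 120), 2)
  expect_lt(abs(fitn$y - 100), 2)
  expect_lt(abs(fitn$r - 50), 2)

  expect_error(detect_coin(array(20, c(100, 100, 3))), "no coin")
})

test_that("calibration inverts the coin diameter", {
  expect_equal(calibrate(list(r = 50))$mm_per_pixel, 0.25)
  expect_equal(calibrate(list(r = 12.5))$mm_per_pixel, 1)
  expect_equal(calibrate(list(r = 100))$mm_per_pixel,
               calibrate(list(r = 50))$mm_per_pixel / 2)
  expect_error(calibrate(list(r = -1)), "positive")

  # identity: a straight skeleton of coin-diameter pixel length measures
  # the coin diameter in mm
  line <- matrix(0L, 5, 120)
  line[3, 11:111] <- 1L # 100 axial steps = one 50-px-radius coin diameter
  mm <- skeleton_length(line == 1) * calibrate(list(r = 50))$mm_per_pixel
  expect_lt(abs(mm - 25) / 25, 0.03)
})

test_that("measure_seedlings separates instances and converts units", {
  cal <- list(mm_per_pixel = 0.25)
  mask <- matrix(0L, 40, 260)
  mask[20, 10:210] <- 1L # a 200-step axial shoot
  res <- measure_seedlings(mask, cal)
  expect_identical(nrow(res), 1L)
  expect_equal(res$shoot_mm, 50, tolerance = 0.01)
  expect_equal(res$root_px, 0)
  expect_false(res$seed_present)

  # two disjoint seedlings -> exactly two measurements
  mask2 <- matrix(0L, 60, 120)
  mask2[10, 10:60] <- 1L
  mask2[11, 10:60] <- 3L
  mask2[40, 20:90] <- 2L
  res2 <- measure_seedlings(mask2, cal)
  expect_identical(nrow(res2), 2L)

  # a seed-only component is skipped with a message
  mask3 <- matrix(0L, 20, 20)
  mask3[5:8, 5:8] <- 3L
  expect_message(res3 <- measure_seedlings(mask3, cal), "skipped")
  expect_identical(nrow(res3), 0L)
})

test_that("mm outputs are invariant to uniform scene scale", {
  mk_scene <- function(s) {
    scene_spec(canvas = c(round(220 * s), round(220 * s)), n_seedlings = 1L,
               seed_axes = c(5, 7) * s, shoot_len = c(70, 70) * s,
               root_len = c(55, 55) * s, shoot_width = c(4, 4) * s,
               root_width = c(3, 3) * s, coin_radius = c(20, 20) * s,
               noise_sd = 0, margin = 5, max_turn = 30, seed = 77)
  }
  get_mm <- function(s) {
    sc <- generate_scene(mk_scene(s))
    res <- measure_image(sc$sample$image, sc$sample$mask)
    c(res$shoot_mm[1], res$root_mm[1])
  }
  a <- get_mm(1)
  b <- get_mm(2)
  expect_lt(max(abs(a - b) / a), 0.05)
})

test_that("measurement recovers generator truth lengths across scenes", {
  errs <- c()
  for (i in 1:12) {
    sc <- generate_scene(scene_spec(seed = 500 + i))
    s <- sc$sample
    res <- measure_image(s$image, s$mask)
    expect_lt(abs(res$coin_r[1] - sc$truth$coin$r), 2)
    h <- nrow(s$mask); w <- ncol(s$mask)
    lab <- matrix(dfma:::cpp_label_components(
      as.integer(t(matrix(as.integer(s$mask != 0), h, w))), h, w), h, byrow = TRUE)
    for (t in sc$truth$seedlings) {
      id <- lab[round(t$seed_center[2]) + 1, round(t$seed_center[1]) + 1]
      row <- res[res$instance_id == id, ]
      expect_identical(nrow(row), 1L)
      errs <- c(errs, abs(row$shoot_mm - t$shoot_mm) / t$shoot_mm,
                abs(row$root_mm - t$root_mm) / t$root_mm)
    }
  }
  expect_lt(mean(errs), 0.05)
})
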