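test_that("confusion matrix counts truth-by-prediction pixels and is additive", {
  cm <- confusion(c(0, 1, 1, 1), c(0, 0, 1, 1))
  expect_identical(cm[1, 1], 1L)
  expect_identical(cm[1, 2], 1L)
  expect_identical(cm[2, 2], 2L)
  expect_identical(sum(cm), 4L)

  set.seed(1)
  a_pred <- sample(0:3, 50, TRUE); a_truth <- sample(0:3, 50, TRUE)
  b_pred <- sample(0:3, 70, TRUE); b_truth <- sample(0:3, 70, TRUE)
  expect_identical(confusion(a_pred, a_truth) + confusion(b_pred, b_truth),
                   confusion(c(a_pred, b_pred), c(a_truth, b_truth)))
  expect_error(confusion(c(0, 4), c(0, 0)), "labels")
  expect_error(confusion(c(0, 1), c(0, 0, 1)), "shape")
})

test_that("miou and per-class metrics match hand enumeration and set oracles", {
  cm <- confusion(c(0, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(suppressMessages(miou(cm)), 7 / 12)
  pra <- precision_recall_accuracy(cm, 1)
  expect_equal(pra$precision, 2 / 3)
  expect_equal(pra$recall, 1)
  expect_equal(pra$accuracy, 3 / 4)

  # perfect prediction
  p <- sample(0:3, 30, TRUE)
  expect_equal(suppressMessages(miou(confusion(p, p))), 1)
  prap <- precision_recall_accuracy(confusion(p, p), 0)
  expect_equal(unlist(prap), c(precision = 1, recall = 1, accuracy = 1))

  # vacuous class: undefined precision/recall, accuracy 1
  cm2 <- confusion(c(0, 0, 1), c(0, 0, 1))
  v <- precision_recall_accuracy(cm2, 3)
  expect_true(is.na(v$precision) && is.na(v$recall))
  expect_equal(v$accuracy, 1)

  # 200 random small mask pairs against the brute-force set computation
  set.seed(2)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    pred <- sample(0:3, n, TRUE, prob = runif(4))
    truth <- sample(0:3, n, TRUE, prob = runif(4))
    cm3 <- confusion(pred, truth)
    expect_equal(suppressMessages(miou(cm3)), set_miou(pred, truth),
                 tolerance = 1e-12)
    m <- suppressMessages(miou(cm3))
    expect_true(m >= 0 && m <= 1)
  }
  expect_error(miou(matrix(0L, 4, 4)), "no class")
})

test_that("segmentation loss has the closed-form and limiting behavior", {
  # uniform logits over 2 classes, balanced truth: CE = ln 2 per pixel
  lg <- array(0, c(2, 2, 2))
  truth <- matrix(c(0L, 1L, 0L, 1L), 2, 2)
  l <- seg_loss(lg, truth)
  expect_equal(l$ce, log(2), tolerance = 1e-12)

  # strong correct logits: loss decays to the smoothing floor
  lg2 <- array(0, c(4, 4, 4))
  truth2 <- matrix(sample(0:3, 16, TRUE), 4, 4)
  for (c in 1:4) lg2[c, , ] <- ifelse(truth2 == c - 1L, 50, -50)
  l2 <- seg_loss(lg2, truth2)
  expect_lt(l2$total, 1e-6)

  # analytic gradient matches central finite differences on a 2x2 toy
  set.seed(3)
  lg3 <- array(rnorm(4 * 2 * 2), c(4, 2, 2))
  truth3 <- matrix(sample(0:3, 4, TRUE), 2, 2)
  target <- as.integer(t(truth3))
  tp <- dfma:::ag_tape(grad = TRUE)
  node <- dfma:::ag_input(tp, dfma:::as_fmat(lg3))
  loss <- dfma:::ag_seg_loss(tp, node, target)
  dfma:::ag_backward(tp, loss)
  g <- node$grad
  for (i in seq_along(lg3)) {
    eps <- 1e-5
    up <- lg3; up[i] <- up[i] + eps
    dn <- lg3; dn[i] <- dn[i] - eps
    fd <- (seg_loss(up, truth3)$total - seg_loss(dn, truth3)$total) / (2 * eps)
    gi <- dfma:::as_farr(dfma:::tmat(g, 2L, 2L, 1L))[i]
    expect_equal(gi, fd, tolerance = 1e-4)
  }
})

test_that("cosine schedule spans the published endpoints", {
  expect_equal(cosine_lr(0, 500), 0.005)
  expect_equal(cosine_lr(499, 500), 0.0001)
  mid <- cosine_lr(0:499, 500)
  expect_true(all(diff(mid) < 0))
  expect_true(all(mid <= 0.005 & mid >= 0.0001))
})

test_that("early stopping fires exactly when patience is exhausted", {
  trace <- c(5, 4, 3, 2, 1, rep(1, 30)) # improves 5 epochs, then flat
  expect_identical(early_stop_epoch(trace, 20L), 25L)
  expect_identical(early_stop_epoch(c(3, 2, 1), 20L), 3L)
  expect_identical(early_stop_epoch(rep(1, 10), 3L), 4L)
  # never stops while the loss keeps improving
  expect_identical(early_stop_epoch(seq(10, 1), 5L), 10L)
})

test_that("augmentation transforms image and mask coherently", {
  sc <- generate_scene(scene_spec(seed = 6))

  # right-angle rotations preserve the class histogram
  set.seed(1)
  cfg_rot <- augment_config(scale_range = c(1, 1), flip_prob = 0,
                            hsv = c(0, 0, 0), rotations = c(90L, 180L, 270L))
  for (i in 1:5) {
    a <- augment(sc$sample, cfg_rot)
    expect_identical(tabulate(a$mask + 1L, 4), tabulate(sc$sample$mask + 1L, 4))
    expect_true(all(a$mask %in% 0:3))
  }

  # shrink: the padded region is 128 in the image and background in the mask
  set.seed(2)
  cfg_pad <- augment_config(scale_range = c(0.5, 0.5), flip_prob = 0,
                            hsv = c(0, 0, 0), rotations = integer(0))
  a <- augment(sc$sample, cfg_pad)
  expect_identical(dim(a$mask), dim(sc$sample$mask))
  n_pad <- sum(a$image[, , 1] == 128)
  expect_gt(n_pad, 0.5 * length(a$mask)) # more than half the canvas is padding
  expect_gte(sum(a$mask == 0L), n_pad)

  # flipping twice with the same geometry restores the original
  flip <- function(s) {
    list(id = s$id, image = s$image[, rev(seq_len(ncol(s$mask))), , drop = FALSE],
         mask = s$mask[, rev(seq_len(ncol(s$mask))), drop = FALSE])
  }
  expect_identical(flip(flip(sc$sample))$mask, sc$sample$mask)
  expect_identical(flip(flip(sc$sample))$image, sc$sample$image)
})

test_that("the training loop is seed-deterministic and stops early", {
  set.seed(4)
  train_s <- lapply(1:6, function(i) {
    generate_scene(smoke_scene_spec(300 + i))$sample
  })
  val_s <- lapply(1:2, function(i) generate_scene(smoke_scene_spec(400 + i))$sample)
  tc <- train_config(lr_init = 1e-3, lr_end = 1e-4, optimizer = "adam",
                     batch_size = 3L, max_epochs = 3L, patience = 2L, seed = 11)
  run <- function() {
    model <- dfma_init(tiny_model_config(), seed = 21)
    suppressWarnings(suppressMessages(train(model, train_s, val_s, tc)))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1$history, r2$history)
  expect_identical(nrow(r1$history), 3L)
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss", "val_miou") %in%
                    names(r1$history)))
  expect_equal(r1$history$lr[1], 1e-3)
  expect_error(suppressWarnings(train(dfma_init(tiny_model_config(), seed = 1),
                                      list(), val_s, tc)), "empty")
})
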