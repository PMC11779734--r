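# Minimal reverse-mode autodiff over channels-first feature matrices.
#
# A feature map with C channels, spatial size H x W and batch size N is a
# C x (N*H*W) matrix whose column for pixel (x, y) of sample n (0-based) is
# (n*H + y)*W + x — x fastest, then y, then sample. The spatial geometry is
# carried in the "fdim" attribute c(h, w, n). Per-channel quantities recycle
# naturally down columns, which keeps most layer arithmetic allocation-light.

tmat <- function(m, h, w, n) {
  attr(m, "fdim") <- c(h, w, n)
  m
}

fdim <- function(m) attr(m, "fdim")

#' @noRd
as_fmat <- function(arr) {
  d <- dim(arr)
  stopifnot(length(d) == 3L)
  tmat(matrix(aperm(arr, c(1L, 3L, 2L)), nrow = d[1L]), d[2L], d[3L], 1L)
}

#' @noRd
as_farr <- function(m) {
  d <- fdim(m)
  aperm(array(m, dim = c(nrow(m), d[2L], d[1L])), c(1L, 3L, 2L))
}

ag_tape <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$grad <- isTRUE(grad)
  tp
}

ag_node <- function(tape, val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  if (tape$grad && !is.null(backward)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes)) {
      tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    }
    tape$nodes[[tape$n]] <- nd
  }
  nd
}

ag_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
}

ag_backward <- function(tape, loss) {
  loss$grad <- 1
  if (!is.null(loss$backward)) loss$backward(loss)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (identical(nd, loss)) next
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# --- parameters -------------------------------------------------------------

ag_param <- function(val) {
  p <- new.env(parent = emptyenv())
  p$val <- val
  p$grad <- NULL
  class(p) <- "ag_param"
  p
}

ag_leaf <- function(tape, param) {
  ag_node(tape, param$val, backward = function(nd) {
    param$grad <- if (is.null(param$grad)) nd$grad else param$grad + nd$grad
  })
}

ag_input <- function(tape, m) ag_node(tape, m)

collect_params <- function(x) {
  if (inherits(x, "ag_param")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# --- elementwise ------------------------------------------------------------

ag_relu <- function(tape, x) {
  y <- x$val
  y[y < 0] <- 0
  ag_node(tape, y, backward = function(nd) {
    ag_acc(x, nd$grad * (x$val > 0))
  })
}

ag_sigmoid <- function(tape, x) {
  y <- tmat(1 / (1 + exp(-x$val)), fdim(x$val)[1L], fdim(x$val)[2L], fdim(x$val)[3L])
  ag_node(tape, y, backward = function(nd) {
    ag_acc(x, nd$grad * y * (1 - y))
  })
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$val + b$val, backward = function(nd) {
    ag_acc(a, nd$grad)
    ag_acc(b, nd$grad)
  })
}

# Elementwise product; b may have a single row, broadcast across channels.
ag_mul <- function(tape, a, b) {
  broadcast <- nrow(b$val) == 1L && nrow(a$val) > 1L
  bb <- if (broadcast) rep(as.numeric(b$val), each = nrow(a$val)) else b$val
  y <- a$val * bb
  attr(y, "fdim") <- fdim(a$val)
  ag_node(tape, y, backward = function(nd) {
    ag_acc(a, nd$grad * bb)
    if (broadcast) {
      gb <- matrix(colSums(nd$grad * a$val), nrow = 1L)
      attr(gb, "fdim") <- fdim(b$val)
      ag_acc(b, gb)
    } else {
      ag_acc(b, nd$grad * a$val)
    }
  })
}

ag_concat <- function(tape, a, b) {
  ca <- nrow(a$val)
  y <- rbind(a$val, b$val)
  attr(y, "fdim") <- fdim(a$val)
  ag_node(tape, y, backward = function(nd) {
    ga <- nd$grad[seq_len(ca), , drop = FALSE]
    gb <- nd$grad[-seq_len(ca), , drop = FALSE]
    attr(ga, "fdim") <- fdim(a$val)
    attr(gb, "fdim") <- fdim(b$val)
    ag_acc(a, ga)
    ag_acc(b, gb)
  })
}

ag_slice_rows <- function(tape, x, rows) {
  y <- x$val[rows, , drop = FALSE]
  attr(y, "fdim") <- fdim(x$val)
  ag_node(tape, y, backward = function(nd) {
    g <- matrix(0, nrow(x$val), ncol(x$val))
    g[rows, ] <- nd$grad
    attr(g, "fdim") <- fdim(x$val)
    ag_acc(x, g)
  })
}

# Column gather (possibly many-to-one); backward scatters with accumulation.
ag_gather_cols <- function(tape, x, idx, newfd) {
  y <- x$val[, idx, drop = FALSE]
  attr(y, "fdim") <- newfd
  ag_node(tape, y, backward = function(nd) {
    g <- t(rowsum(t(nd$grad), group = idx))
    gx <- matrix(0, nrow(x$val), ncol(x$val))
    gx[, as.integer(colnames(g))] <- g
    attr(gx, "fdim") <- fdim(x$val)
    ag_acc(x, gx)
  })
}

# Bijective relayout of the full value vector (pixel shuffle, group fold).
ag_index <- function(tape, x, idx, newc, newfd) {
  y <- matrix(as.numeric(x$val)[idx], nrow = newc)
  attr(y, "fdim") <- newfd
  ag_node(tape, y, backward = function(nd) {
    g <- numeric(length(x$val))
    g[idx] <- as.numeric(nd$grad)
    g <- matrix(g, nrow = nrow(x$val))
    attr(g, "fdim") <- fdim(x$val)
    ag_acc(x, g)
  })
}

ag_sum_rows <- function(tape, x) {
  y <- matrix(colSums(x$val), nrow = 1L)
  attr(y, "fdim") <- fdim(x$val)
  ag_node(tape, y, backward = function(nd) {
    g <- matrix(rep(as.numeric(nd$grad), each = nrow(x$val)), nrow = nrow(x$val))
    attr(g, "fdim") <- fdim(x$val)
    ag_acc(x, g)
  })
}

# --- softmax over channels (per column) ------------------------------------

ag_softmax_rows <- function(tape, x) {
  nr <- nrow(x$val)
  mx <- x$val[1L, ]
  if (nr > 1L) for (i in 2:nr) mx <- pmax(mx, x$val[i, ])
  e <- exp(x$val - rep(mx, each = nr))
  y <- e / rep(colSums(e), each = nr)
  attr(y, "fdim") <- fdim(x$val)
  ag_node(tape, y, backward = function(nd) {
    dot <- colSums(nd$grad * y)
    g <- y * (nd$grad - rep(dot, each = nr))
    attr(g, "fdim") <- fdim(x$val)
    ag_acc(x, g)
  })
}

# --- convolution ------------------------------------------------------------

ag_conv2d <- function(tape, x, w, b, k, stride = 1L, pad = 0L, dil = 1L) {
  d <- fdim(x$val)
  h <- d[1L]; wd <- d[2L]; n <- d[3L]
  cin <- nrow(x$val)
  if (k == 1L && stride == 1L) {
    y <- w$val %*% x$val + b$val
    ho <- h; wo <- wd
    patches <- NULL
  } else {
    patches <- cpp_im2col(x$val, cin, h, wd, n, k, stride, pad, dil)
    y <- w$val %*% patches + b$val
    keff <- dil * (k - 1L) + 1L
    ho <- (h + 2L * pad - keff) %/% stride + 1L
    wo <- (wd + 2L * pad - keff) %/% stride + 1L
  }
  attr(y, "fdim") <- c(ho, wo, n)
  if (!tape$grad) patches <- NULL
  ag_node(tape, y, backward = function(nd) {
    g <- nd$grad
    ag_acc(b, rowSums(g))
    if (k == 1L && stride == 1L) {
      ag_acc(w, g %*% t(x$val))
      gx <- crossprod(w$val, g)
    } else {
      ag_acc(w, g %*% t(patches))
      gp <- crossprod(w$val, g)
      gx <- cpp_col2im(gp, cin, h, wd, n, k, stride, pad, dil)
    }
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
  })
}

# --- normalization ----------------------------------------------------------

# Batch norm over (batch, spatial) per channel. `stats` is an environment
# holding running mean/var, updated in-place during training.
ag_bn <- function(tape, x, gamma, beta, stats, training, momentum = 0.1,
                  eps = 1e-5) {
  nr <- nrow(x$val)
  if (training) {
    mu <- rowMeans(x$val)
    xc <- x$val - mu
    v <- rowMeans(xc * xc)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
    xc <- x$val - mu
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  y <- xhat * gamma$val + beta$val
  attr(y, "fdim") <- fdim(x$val)
  ag_node(tape, y, backward = function(nd) {
    g <- nd$grad
    ag_acc(gamma, rowSums(g * xhat))
    ag_acc(beta, rowSums(g))
    gxh <- g * gamma$val
    if (training) {
      gx <- istd * (gxh - rowMeans(gxh) - xhat * rowMeans(gxh * xhat))
    } else {
      gx <- gxh * istd
    }
    attr(gx, "fdim") <- fdim(x$val)
    ag_acc(x, gx)
  })
}

bn_stats <- function(c) {
  s <- new.env(parent = emptyenv())
  s$mean <- numeric(c)
  s$var <- rep(1, c)
  s
}

# Group norm with one group spanning the whole sample block (layer-norm
# style over C*H*W per sample), affine per channel.
ag_gn <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- fdim(x$val)
  n <- d[3L]
  m <- nrow(x$val) * d[1L] * d[2L]
  blk <- matrix(as.numeric(x$val), nrow = m)
  mu <- colMeans(blk)
  xc <- blk - rep(mu, each = m)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- matrix(xc * rep(istd, each = m), nrow = nrow(x$val))
  y <- xhat * gamma$val + beta$val
  attr(y, "fdim") <- d
  ag_node(tape, y, backward = function(nd) {
    g <- nd$grad
    ag_acc(gamma, rowSums(g * xhat))
    ag_acc(beta, rowSums(g))
    gxh <- matrix(g * gamma$val, nrow = m)
    xh <- matrix(xhat, nrow = m)
    gmean <- colMeans(gxh)
    gdot <- colMeans(gxh * xh)
    gx <- (gxh - rep(gmean, each = m) - xh * rep(gdot, each = m)) *
      rep(istd, each = m)
    gx <- matrix(gx, nrow = nrow(x$val))
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
  })
}

# --- pooling and resampling -------------------------------------------------

ag_pool_w <- function(tape, x) {
  d <- fdim(x$val)
  h <- d[1L]; wd <- d[2L]; n <- d[3L]
  a <- array(x$val, dim = c(nrow(x$val), wd, h * n))
  y <- colMeans(aperm(a, c(2L, 1L, 3L)))
  dim(y) <- c(nrow(x$val), h * n)
  attr(y, "fdim") <- c(h, 1L, n)
  ag_node(tape, y, backward = function(nd) {
    gx <- nd$grad[, rep(seq_len(h * n), each = wd), drop = FALSE] / wd
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
  })
}

ag_pool_h <- function(tape, x) {
  d <- fdim(x$val)
  h <- d[1L]; wd <- d[2L]; n <- d[3L]
  a <- array(x$val, dim = c(nrow(x$val), wd, h, n))
  y <- colMeans(aperm(a, c(3L, 1L, 2L, 4L)))
  dim(y) <- c(nrow(x$val), wd * n)
  attr(y, "fdim") <- c(1L, wd, n)
  idx <- unlist(lapply(seq_len(n) - 1L, function(nn) rep(nn * wd + seq_len(wd), times = h)))
  ag_node(tape, y, backward = function(nd) {
    gx <- nd$grad[, idx, drop = FALSE] / h
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
  })
}

ag_gap <- function(tape, x) {
  d <- fdim(x$val)
  hw <- d[1L] * d[2L]
  a <- array(x$val, dim = c(nrow(x$val), hw, d[3L]))
  y <- colMeans(aperm(a, c(2L, 1L, 3L)))
  dim(y) <- c(nrow(x$val), d[3L])
  attr(y, "fdim") <- c(1L, 1L, d[3L])
  ag_node(tape, y, backward = function(nd) {
    gx <- nd$grad[, rep(seq_len(d[3L]), each = hw), drop = FALSE] / hw
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
  })
}

# Broadcast per-sample column vectors back to full spatial size.
ag_expand_gap <- function(tape, x, h, w) {
  d <- fdim(x$val)
  ag_gather_cols(tape, x, rep(seq_len(d[3L]), each = h * w), c(h, w, d[3L]))
}

ag_expand_w <- function(tape, x, w) {
  d <- fdim(x$val) # (h, 1, n), columns (y, n)
  ag_gather_cols(tape, x, rep(seq_len(d[1L] * d[3L]), each = w), c(d[1L], w, d[3L]))
}

ag_expand_h <- function(tape, x, h) {
  d <- fdim(x$val) # (1, w, n), columns (x, n)
  idx <- unlist(lapply(seq_len(d[3L]) - 1L, function(nn) {
    rep(nn * d[2L] + seq_len(d[2L]), times = h)
  }))
  ag_gather_cols(tape, x, idx, c(h, d[2L], d[3L]))
}

upsample_nearest_idx <- function(h, w, n, s) {
  oy <- rep(rep(seq_len(h), each = s), each = w * s)
  ox <- rep(rep(seq_len(w), each = s), times = h * s)
  one <- (oy - 1L) * w + ox
  unlist(lapply(seq_len(n) - 1L, function(nn) nn * h * w + one))
}

ag_upsample_nearest <- function(tape, x, s) {
  d <- fdim(x$val)
  idx <- upsample_nearest_idx(d[1L], d[2L], d[3L], s)
  ag_gather_cols(tape, x, idx, c(d[1L] * s, d[2L] * s, d[3L]))
}

# Replicate (edge-clamp) spatial padding by p pixels, as a column gather.
ag_pad_replicate <- function(tape, x, p) {
  d <- fdim(x$val)
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  yy <- pmin(pmax(seq_len(h + 2L * p) - p, 1L), h)
  xx <- pmin(pmax(seq_len(w + 2L * p) - p, 1L), w)
  one <- as.integer((rep(yy, each = w + 2L * p) - 1L) * w + rep(xx, times = h + 2L * p))
  idx <- unlist(lapply(seq_len(n) - 1L, function(nn) nn * h * w + one))
  ag_gather_cols(tape, x, idx, c(h + 2L * p, w + 2L * p, n))
}

# Bilinear upsampling by integer factor s (align_corners = FALSE convention),
# expressed as a fixed sparse linear map: four gathers with scalar weights.
ag_upsample_bilinear <- function(tape, x, s) {
  d <- fdim(x$val)
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  ho <- h * s; wo <- w * s
  sy <- (seq_len(ho) - 0.5) / s - 0.5
  sx <- (seq_len(wo) - 0.5) / s - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1L)
  x0 <- pmin(pmax(floor(sx), 0), w - 1L)
  y1 <- pmin(y0 + 1L, h - 1L)
  x1 <- pmin(x0 + 1L, w - 1L)
  fy <- pmin(pmax(sy - y0, 0), 1)
  fx <- pmin(pmax(sx - x0, 0), 1)
  oy0 <- rep(y0, each = wo); oy1 <- rep(y1, each = wo); ofy <- rep(fy, each = wo)
  ox0 <- rep(x0, times = ho); ox1 <- rep(x1, times = ho); ofx <- rep(fx, times = ho)
  base <- function(yy, xx) as.integer(yy * w + xx + 1L)
  i00 <- base(oy0, ox0); i01 <- base(oy0, ox1)
  i10 <- base(oy1, ox0); i11 <- base(oy1, ox1)
  w00 <- (1 - ofy) * (1 - ofx); w01 <- (1 - ofy) * ofx
  w10 <- ofy * (1 - ofx); w11 <- ofy * ofx
  off <- rep((seq_len(n) - 1L) * h * w, each = ho * wo)
  I00 <- rep(i00, n) + off; I01 <- rep(i01, n) + off
  I10 <- rep(i10, n) + off; I11 <- rep(i11, n) + off
  W00 <- rep(w00, n); W01 <- rep(w01, n); W10 <- rep(w10, n); W11 <- rep(w11, n)
  nr <- nrow(x$val)
  y <- x$val[, I00, drop = FALSE] * rep(W00, each = nr) +
    x$val[, I01, drop = FALSE] * rep(W01, each = nr) +
    x$val[, I10, drop = FALSE] * rep(W10, each = nr) +
    x$val[, I11, drop = FALSE] * rep(W11, each = nr)
  attr(y, "fdim") <- c(ho, wo, n)
  ag_node(tape, y, backward = function(nd) {
    gx <- matrix(0, nr, ncol(x$val))
    scatter <- function(idx, wt) {
      g <- t(rowsum(t(nd$grad * rep(wt, each = nr)), group = idx))
      gx[, as.integer(colnames(g))] <<- gx[, as.integer(colnames(g))] + g
    }
    scatter(I00, W00); scatter(I01, W01); scatter(I10, W10); scatter(I11, W11)
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
  })
}

# --- CARAFE reassembly ------------------------------------------------------

ag_carafe_reassemble <- function(tape, x, kern, sigma, kup) {
  d <- fdim(x$val)
  y <- cpp_carafe_forward(x$val, kern$val, nrow(x$val), d[1L], d[2L], d[3L],
                          sigma, kup)
  attr(y, "fdim") <- c(d[1L] * sigma, d[2L] * sigma, d[3L])
  ag_node(tape, y, backward = function(nd) {
    g <- cpp_carafe_backward(nd$grad, x$val, kern$val, nrow(x$val), d[1L],
                             d[2L], d[3L], sigma, kup)
    gx <- g$gx
    attr(gx, "fdim") <- d
    ag_acc(x, gx)
    gk <- g$gk
    attr(gk, "fdim") <- c(d[1L] * sigma, d[2L] * sigma, d[3L])
    ag_acc(kern, gk)
  })
}

# --- segmentation loss ------------------------------------------------------

# Cross-entropy plus soft Dice from raw logits. `target` is an integer vector
# of 0-based class labels, one per column. Dice is averaged over classes
# present in the target, with additive smoothing.
ag_seg_loss <- function(tape, logits, target, dice_eps = 1) {
  nc <- nrow(logits$val)
  npix <- ncol(logits$val)
  mx <- logits$val[1L, ]
  for (i in 2:nc) mx <- pmax(mx, logits$val[i, ])
  e <- exp(logits$val - rep(mx, each = nc))
  p <- e / rep(colSums(e), each = nc)
  ti <- target + 1L
  ptrue <- p[matrix(c(ti, seq_len(npix)), ncol = 2L)]
  ce <- -mean(log(pmax(ptrue, 1e-12)))
  onehot <- matrix(0, nc, npix)
  onehot[matrix(c(ti, seq_len(npix)), ncol = 2L)] <- 1
  S <- rowSums(p)
  Y <- rowSums(onehot)
  I <- rowSums(p * onehot)
  present <- which(Y > 0)
  d <- (2 * I + dice_eps) / (S + Y + dice_eps)
  dice <- 1 - mean(d[present])
  nd <- ag_node(tape, ce + dice, backward = function(nd) {
    gce <- (p - onehot) / npix
    gp <- matrix(0, nc, npix)
    denom <- (S + Y + dice_eps)^2
    for (c in present) {
      gp[c, ] <- -(2 * onehot[c, ] * (S[c] + Y[c] + dice_eps) - (2 * I[c] + dice_eps)) /
        denom[c] / length(present)
    }
    dot <- colSums(gp * p)
    gdice <- p * (gp - rep(dot, each = nc))
    g <- (gce + gdice) * nd$grad
    attr(g, "fdim") <- fdim(logits$val)
    ag_acc(logits, g)
  })
  nd$ce <- ce
  nd$dice <- dice
  nd
}
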