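# Independent reference implementations used as oracles, plus shared small
# configurations. These stay deliberately naive (straight loop nests) so they
# check the vectorized package code without sharing any of its machinery.

# Same-padded stride-1 convolution as an explicit loop nest; also counts
# multiply-accumulates when `count` is TRUE.
naive_conv <- function(x, w, count = FALSE) {
  k <- dim(w)[3L]
  pad <- (k - 1L) %/% 2L
  H <- dim(x)[2L]
  W <- dim(x)[3L]
  out <- array(0, c(dim(w)[1L], H, W))
  macs <- 0
  for (o in seq_len(dim(w)[1L])) {
    for (y in seq_len(H)) {
      for (xx in seq_len(W)) {
        s <- 0
        for (i in seq_len(dim(w)[2L])) {
          for (ky in seq_len(k)) {
            for (kx in seq_len(k)) {
              yy <- y + ky - 1L - pad
              xc <- xx + kx - 1L - pad
              if (yy >= 1L && yy <= H && xc >= 1L && xc <= W) {
                s <- s + w[o, i, ky, kx] * x[i, yy, xc]
              }
              macs <- macs + 1
            }
          }
        }
        out[o, y, xx] <- s
      }
    }
  }
  if (count) list(out = out, macs = macs) else out
}

# CARAFE reassembly as a four-nested-loop reference.
naive_reassemble <- function(x, kern, sigma) {
  C <- dim(x)[1L]; H <- dim(x)[2L]; W <- dim(x)[3L]
  kup <- as.integer(sqrt(dim(kern)[3L]))
  rad <- (kup - 1L) %/% 2L
  out <- array(0, c(C, H * sigma, W * sigma))
  for (oy in seq_len(H * sigma)) {
    for (ox in seq_len(W * sigma)) {
      sy <- (oy - 1L) %/% sigma + 1L
      sx <- (ox - 1L) %/% sigma + 1L
      for (ky in seq_len(kup)) {
        for (kx in seq_len(kup)) {
          iy <- sy + ky - 1L - rad
          ix <- sx + kx - 1L - rad
          if (iy >= 1L && iy <= H && ix >= 1L && ix <= W) {
            out[, oy, ox] <- out[, oy, ox] +
              kern[oy, ox, (ky - 1L) * kup + kx] * x[, iy, ix]
          }
        }
      }
    }
  }
  out
}

# Per-class IoU by explicit pixel-set operations.
set_miou <- function(pred, truth, k = 4L) {
  ious <- c()
  for (cls in 0:(k - 1L)) {
    a <- which(pred == cls)
    b <- which(truth == cls)
    if (length(a) == 0L && length(b) == 0L) next
    ious <- c(ious, length(intersect(a, b)) / length(union(a, b)))
  }
  mean(ious)
}

# Influence coverage of stacked dilated 3x3 convolutions by direct sum-set
# enumeration of reachable tap offsets (independent of the package's
# influence-map propagation).
sumset_coverage <- function(rates) {
  offs <- list(0L)
  reach <- 0L
  for (r in rates) {
    reach <- reach + r
    offs <- unique(unlist(lapply(offs, function(o) o + r * (-1:1))))
  }
  axis <- length(unique(offs))
  (axis / (2L * reach + 1L))^2
}

# Axis-aligned rectangle polygon through pixel centers [x0..x1] x [y0..y1],
# consistent with the half-open pixel-center rasterization rule.
rect_poly <- function(x0, y0, x1, y1) {
  list(list(x0 - 0.5, y0 - 0.5), list(x1 + 0.5, y0 - 0.5),
       list(x1 + 0.5, y1 + 0.5), list(x0 - 0.5, y1 + 0.5))
}

# Conditions of the end-to-end smoke experiment: 128 x 128 single-seedling
# scenes and a width-reduced model.
smoke_scene_spec <- function(seed) {
  scene_spec(canvas = c(128L, 128L), n_seedlings = 1L,
             seed_axes = c(4, 6), shoot_len = c(25, 55), root_len = c(20, 45),
             shoot_width = c(4, 6), root_width = c(3, 4),
             coin_radius = c(10, 14), noise_sd = 4, margin = 4, seed = seed)
}

smoke_model_config <- function() {
  model_config(
    backbone = backbone_config(depths = c(1, 1, 2, 1), widths = c(8, 16, 32, 64)),
    ema = ema_config(4L),
    aspp = pyramid_config(branch_width = 32L, out_width = 64L, branch_a_width = 64L),
    k_up = 5L, c_m = 16L, low_level_width = 16L)
}

tiny_model_config <- function() {
  model_config(
    backbone = backbone_config(depths = c(1, 1, 1, 1), widths = c(4, 8, 8, 8)),
    ema = ema_config(2L),
    aspp = pyramid_config(branch_width = 4L, out_width = 8L, branch_a_width = 8L),
    k_up = 3L, c_m = 4L, low_level_width = 4L)
}
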