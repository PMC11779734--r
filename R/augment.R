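#' Augmentation configuration
#'
#' Online train-time augmentation: one of the right-angle rotations,
#' horizontal flipping, random rescaling, random crop/shift with grey
#' padding, and HSV jitter. Geometric transforms are applied identically to
#' image and mask (nearest-neighbor for the mask, padding label =
#' background); photometric jitter touches the image only.
#'
#' @param scale_range Multiplicative rescaling range.
#' @param flip_prob Probability of a horizontal flip.
#' @param pad_value Grey intensity used to pad the image (mask pads with 0).
#' @param hsv Jitter amplitudes for hue, saturation, value (fractions).
#' @param rotations Set of right-angle rotations sampled uniformly together
#'   with "no rotation".
#' @param crop_size Output `c(H, W)`; `NULL` keeps the input size.
#' @return Configuration list.
#' @export
augment_config <- function(scale_range = c(0.25, 2), flip_prob = 0.5,
                           pad_value = 128, hsv = c(0.015, 0.3, 0.3),
                           rotations = c(90L, 180L, 270L), crop_size = NULL) {
  stopifnot(all(scale_range > 0), pad_value >= 0, pad_value <= 255)
  list(scale_range = scale_range, flip_prob = flip_prob,
       pad_value = pad_value, hsv = hsv, rotations = as.integer(rotations),
       crop_size = crop_size)
}

rot90_mat <- function(m, deg) {
  switch(as.character(deg %% 360L),
         "0" = m,
         "90" = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
         "180" = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
         "270" = t(m)[rev(seq_len(ncol(m))), , drop = FALSE])
}

rot90_img <- function(img, deg) {
  if (deg %% 360L == 0L) return(img)
  chans <- lapply(1:3, function(c) rot90_mat(img[, , c], deg))
  d <- dim(chans[[1L]])
  array(unlist(chans), dim = c(d, 3L))
}

resize_nearest <- function(m, h, w) {
  yi <- pmin(pmax(ceiling((seq_len(h) - 0.5) / h * nrow(m)), 1L), nrow(m))
  xi <- pmin(pmax(ceiling((seq_len(w) - 0.5) / w * ncol(m)), 1L), ncol(m))
  m[yi, xi, drop = FALSE]
}

resize_bilinear <- function(m, h, w) {
  sy <- (seq_len(h) - 0.5) / h * nrow(m) - 0.5
  sx <- (seq_len(w) - 0.5) / w * ncol(m) - 0.5
  y0 <- pmin(pmax(floor(sy), 0), nrow(m) - 1L)
  x0 <- pmin(pmax(floor(sx), 0), ncol(m) - 1L)
  y1 <- pmin(y0 + 1, nrow(m) - 1L)
  x1 <- pmin(x0 + 1, ncol(m) - 1L)
  fy <- pmin(pmax(sy - y0, 0), 1)
  fx <- pmin(pmax(sx - x0, 0), 1)
  a <- m[y0 + 1L, x0 + 1L, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y0 + 1L, x1 + 1L, drop = FALSE] * outer(1 - fy, fx) +
    m[y1 + 1L, x0 + 1L, drop = FALSE] * outer(fy, 1 - fx) +
    m[y1 + 1L, x1 + 1L, drop = FALSE] * outer(fy, fx)
  a
}

resize_img <- function(img, h, w, method = "bilinear") {
  f <- if (method == "bilinear") resize_bilinear else resize_nearest
  chans <- lapply(1:3, function(c) f(img[, , c], h, w))
  array(unlist(chans), dim = c(h, w, 3L))
}

hsv_jitter <- function(img, amp) {
  rgbm <- rbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]),
                as.vector(img[, , 3L]))
  hsvm <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
  dh <- runif(1, -amp[1L], amp[1L])
  ds <- 1 + runif(1, -amp[2L], amp[2L])
  dv <- 1 + runif(1, -amp[3L], amp[3L])
  hsvm[1L, ] <- (hsvm[1L, ] + dh) %% 1
  hsvm[2L, ] <- pmin(pmax(hsvm[2L, ] * ds, 0), 1)
  hsvm[3L, ] <- pmin(pmax(hsvm[3L, ] * dv, 0), 1)
  cols <- grDevices::hsv(hsvm[1L, ], hsvm[2L, ], hsvm[3L, ])
  out <- grDevices::col2rgb(cols)
  d <- dim(img)
  array(c(matrix(out[1L, ], d[1L], d[2L]), matrix(out[2L, ], d[1L], d[2L]),
          matrix(out[3L, ], d[1L], d[2L])), dim = d)
}

# Place `img`/`mask` into an output canvas at offset (oy, ox), grey-padding
# the uncovered area.
place_crop <- function(img, mask, hout, wout, oy, ox, pad_value) {
  oimg <- array(pad_value, dim = c(hout, wout, 3L))
  omask <- matrix(0L, hout, wout)
  ys <- max(1L, 1L - oy):min(nrow(mask), hout - oy)
  xs <- max(1L, 1L - ox):min(ncol(mask), wout - ox)
  if (length(ys) > 0L && length(xs) > 0L) {
    oimg[ys + oy, xs + ox, ] <- img[ys, xs, , drop = FALSE]
    omask[ys + oy, xs + ox] <- mask[ys, xs]
  }
  list(image = oimg, mask = omask)
}

#' Augment one training sample
#'
#' Draws transform parameters from the current RNG stream; seed the stream
#' for reproducibility. The output is fixed to `crop_size` (default: the
#' input size).
#'
#' @param sample List with `image` (`H x W x 3`, 0-255) and `mask`
#'   (`H x W`, 0-based labels).
#' @param cfg An [augment_config()].
#' @return Augmented sample with the same structure.
#' @export
augment <- function(sample, cfg = augment_config()) {
  img <- sample$image
  mask <- sample$mask
  stopifnot(!is.null(mask), all(dim(img)[1:2] == dim(mask)))
  out_hw <- if (is.null(cfg$crop_size)) dim(mask) else cfg$crop_size
  degs <- c(0L, cfg$rotations)
  deg <- degs[sample.int(length(degs), 1L)]
  img <- rot90_img(img, deg)
  mask <- rot90_mat(mask, deg)
  if (runif(1) < cfg$flip_prob) {
    img <- img[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  s <- exp(runif(1, log(cfg$scale_range[1L]), log(cfg$scale_range[2L])))
  nh <- max(2L, round(nrow(mask) * s))
  nw <- max(2L, round(ncol(mask) * s))
  img <- resize_img(img, nh, nw)
  mask <- resize_nearest(mask, nh, nw)
  oy <- if (nh >= out_hw[1L]) -sample.int(nh - out_hw[1L] + 1L, 1L) + 1L else
    sample.int(out_hw[1L] - nh + 1L, 1L) - 1L
  ox <- if (nw >= out_hw[2L]) -sample.int(nw - out_hw[2L] + 1L, 1L) + 1L else
    sample.int(out_hw[2L] - nw + 1L, 1L) - 1L
  pc <- place_crop(img, mask, out_hw[1L], out_hw[2L], oy, ox, cfg$pad_value)
  pc$image <- hsv_jitter(pc$image, cfg$hsv)
  list(id = sample$id, image = pc$image, mask = pc$mask, truth = sample$truth)
}
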