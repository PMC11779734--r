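#' Synthetic scene specification
#'
#' Scenes emulate germination-board photographs: a dark cloth background
#' with Gaussian sensor noise, seeds as filled ellipses, shoot and root as
#' strokes along quadratic Bezier curves leaving opposite ends of the seed
#' (roots thinner than shoots, as in real seedlings), and one bright filled
#' reference disc standing in for the calibration coin. Every curve's
#' centerline arc length is integrated over a fine polyline and recorded as
#' ground truth, together with the coin geometry, so the measurement
#' pipeline can be validated without real data.
#'
#' @param canvas `c(H, W)` canvas size in pixels.
#' @param n_seedlings Number of seedlings to place.
#' @param seed_axes Range of ellipse semi-axes (px).
#' @param shoot_len,root_len Centerline arc-length ranges (px).
#' @param shoot_width,root_width Stroke width ranges (px).
#' @param coin_radius Range of the reference-disc radius (px).
#' @param noise_sd Gaussian intensity noise (0-255 scale).
#' @param margin Minimum clearance between objects (px).
#' @param max_turn Maximum Bezier turning angle (degrees); bounds curvature
#'   so strokes cannot self-intersect.
#' @param bg Background intensity.
#' @param seed Optional RNG seed; scenes are bit-identical under a fixed
#'   seed.
#' @return Specification list.
#' @export
scene_spec <- function(canvas = c(320L, 320L), n_seedlings = 3L,
                       seed_axes = c(5, 9), shoot_len = c(60, 140),
                       root_len = c(50, 120), shoot_width = c(4, 6),
                       root_width = c(3, 4), coin_radius = c(25, 40),
                       noise_sd = 4, margin = 6, max_turn = 45, bg = 22,
                       seed = NULL) {
  stopifnot(all(canvas >= 64L), n_seedlings >= 0L, all(shoot_len > 0),
            all(root_len > 0), all(coin_radius > 0))
  list(canvas = as.integer(canvas), n_seedlings = as.integer(n_seedlings),
       seed_axes = seed_axes, shoot_len = shoot_len, root_len = root_len,
       shoot_width = shoot_width, root_width = root_width,
       coin_radius = coin_radius, noise_sd = noise_sd, margin = margin,
       max_turn = max_turn, bg = bg, seed = seed)
}

runif1 <- function(range) runif(1, range[1L], range[2L])

# Quadratic Bezier with bounded turning, rescaled about its start so the
# polyline arc length hits `target` exactly (up to polyline resolution).
bezier_stroke <- function(p0, dir, target, max_turn, npts = 1500L) {
  u <- 0.6 * target
  phi <- runif(1, -max_turn, max_turn) * pi / 180
  d1 <- c(cos(dir), sin(dir))
  d2 <- c(cos(dir + phi), sin(dir + phi))
  p1 <- p0 + u * d1
  p2 <- p1 + u * d2
  t <- seq(0, 1, length.out = npts)
  px <- (1 - t)^2 * p0[1L] + 2 * t * (1 - t) * p1[1L] + t^2 * p2[1L]
  py <- (1 - t)^2 * p0[2L] + 2 * t * (1 - t) * p1[2L] + t^2 * p2[2L]
  len <- sum(sqrt(diff(px)^2 + diff(py)^2))
  s <- target / len
  px <- p0[1L] + (px - p0[1L]) * s
  py <- p0[2L] + (py - p0[2L]) * s
  list(x = px, y = py,
       arc_length = sum(sqrt(diff(px)^2 + diff(py)^2)))
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# Pixel rows/cols (1-based matrix indices) covered by stamping discs of
# `width/2` along the polyline; NULL if any pixel falls off canvas.
stroke_pixels <- function(curve, width, h, w, clip = FALSE) {
  step <- max(1L, floor(length(curve$x) / max(2 * curve$arc_length, 10)))
  sel <- seq(1L, length(curve$x), by = step)
  offs <- disc_offsets(width / 2)
  cx <- round(rep(curve$x[sel], each = nrow(offs)) + offs$dx)
  cy <- round(rep(curve$y[sel], each = nrow(offs)) + offs$dy)
  inside <- cx >= 0 & cx < w & cy >= 0 & cy < h
  if (!clip && any(!inside)) return(NULL)
  unique(cy[inside] * w + cx[inside]) # 0-based linear index, x fastest
}

ellipse_pixels <- function(cx, cy, a, b, theta, h, w) {
  r <- ceiling(max(a, b))
  xs <- max(0, floor(cx - r)):min(w - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(h - 1, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - cx
  dy <- g$y - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  g$y[inside] * w + g$x[inside]
}

disc_pixels <- function(cx, cy, r, h, w) {
  offs <- disc_offsets(r)
  px <- round(cx) + offs$dx
  py <- round(cy) + offs$dy
  keep <- px >= 0 & px < w & py >= 0 & py < h
  py[keep] * w + px[keep]
}

paint <- function(img, idx0, col) {
  for (c in 1:3) {
    plane <- img[, , c]
    plane[idx_to_rc(idx0, dim(img)[2L])] <- col[c]
    img[, , c] <- plane
  }
  img
}

idx_to_rc <- function(idx0, w) {
  cbind(idx0 %/% w + 1L, idx0 %% w + 1L)
}

generate_scene_impl <- function(spec) {
  h <- spec$canvas[1L]
  w <- spec$canvas[2L]
  img <- array(spec$bg, dim = c(h, w, 3L))
  mask <- matrix(0L, h, w)
  occupied <- rep(FALSE, h * w)
  m <- spec$margin
  # reference coin
  r <- runif1(spec$coin_radius)
  cx <- runif(1, r + m, w - 1 - r - m)
  cy <- runif(1, r + m, h - 1 - r - m)
  coin_idx <- disc_pixels(cx, cy, r, h, w)
  img <- paint(img, coin_idx, c(208, 208, 214))
  occupied[disc_pixels(cx, cy, r + m, h, w) + 1L] <- TRUE
  seedlings <- list()
  cols <- list(shoot = c(150, 205, 140), root = c(205, 200, 195),
               seed = c(185, 155, 85))
  for (i in seq_len(spec$n_seedlings)) {
    placed <- FALSE
    for (try in 1:100) {
      a <- runif1(spec$seed_axes)
      b <- runif(1, spec$seed_axes[1L], a)
      theta <- runif(1, 0, 2 * pi)
      buff <- max(a, b) + m + 4
      scx <- runif(1, buff, w - 1 - buff)
      scy <- runif(1, buff, h - 1 - buff)
      s_len <- runif1(spec$shoot_len)
      r_len <- runif1(spec$root_len)
      s_w <- runif1(spec$shoot_width)
      r_w <- runif1(spec$root_width)
      tip <- c(scx + a * cos(theta), scy + a * sin(theta))
      tail <- c(scx - a * cos(theta), scy - a * sin(theta))
      shoot <- bezier_stroke(tip, theta, s_len, spec$max_turn)
      root <- bezier_stroke(tail, theta + pi, r_len, spec$max_turn)
      spx <- stroke_pixels(shoot, s_w, h, w)
      rpx <- stroke_pixels(root, r_w, h, w)
      if (is.null(spx) || is.null(rpx)) next
      epx <- ellipse_pixels(scx, scy, a, b, theta, h, w)
      allpx <- unique(c(spx, rpx, epx))
      if (any(occupied[allpx + 1L])) next
      # render: strokes first, seed last so the junction belongs to the seed
      mask[idx_to_rc(spx, w)] <- 1L
      img <- paint(img, spx, cols$shoot)
      mask[idx_to_rc(rpx, w)] <- 2L
      img <- paint(img, rpx, cols$root)
      mask[idx_to_rc(epx, w)] <- 3L
      img <- paint(img, epx, cols$seed)
      grow <- unique(c(stroke_pixels(shoot, s_w + 2 * m, h, w, clip = TRUE),
                       stroke_pixels(root, r_w + 2 * m, h, w, clip = TRUE),
                       ellipse_pixels(scx, scy, a + m, b + m, theta, h, w)))
      occupied[grow + 1L] <- TRUE
      mm_per_px <- 25 / (2 * r)
      seedlings[[length(seedlings) + 1L]] <- list(
        instance = i,
        shoot_px = shoot$arc_length, root_px = root$arc_length,
        shoot_mm = shoot$arc_length * mm_per_px,
        root_mm = root$arc_length * mm_per_px,
        seed_center = c(scx, scy), seed_axes = c(a, b), angle = theta,
        shoot_width = s_w, root_width = r_w,
        shoot_curve = list(x = shoot$x, y = shoot$y),
        root_curve = list(x = root$x, y = root$y))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place seedling ", i,
           " without overlap; use a larger canvas or fewer seedlings")
    }
  }
  if (spec$noise_sd > 0) {
    img <- img + array(rnorm(length(img), sd = spec$noise_sd), dim = dim(img))
  }
  img <- pmin(pmax(round(img), 0), 255)
  truth <- list(coin = list(x = cx, y = cy, r = r), seedlings = seedlings)
  sample <- list(id = "scene", image = img, mask = mask, truth = seedlings)
  list(sample = sample, truth = truth)
}

#' Generate one synthetic seedling scene
#'
#' @param spec A [scene_spec()].
#' @return List with `sample` (`id`, `image`, `mask`, `truth`) and `truth`
#'   (coin geometry plus per-seedling centerline lengths in px and mm).
#' @export
generate_scene <- function(spec = scene_spec()) {
  if (is.null(spec$seed)) generate_scene_impl(spec)
  else with_seed(spec$seed, generate_scene_impl(spec))
}

# Labelme-style polygon outline of a stroke: offset the decimated centerline
# by half the width on each side.
stroke_polygon <- function(curve, width) {
  sel <- unique(c(seq(1L, length(curve$x), by = 40L), length(curve$x)))
  x <- curve$x[sel]
  y <- curve$y[sel]
  tx <- c(diff(x), x[length(x)] - x[length(x) - 1L])
  ty <- c(diff(y), y[length(y)] - y[length(y) - 1L])
  nrm <- sqrt(tx^2 + ty^2)
  nx <- -ty / nrm
  ny <- tx / nrm
  hw <- width / 2
  cbind(c(x + nx * hw, rev(x - nx * hw)), c(y + ny * hw, rev(y - ny * hw)))
}

ellipse_polygon <- function(center, axes, theta, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- axes[1L] * cos(t)
  v <- axes[2L] * sin(t)
  cbind(center[1L] + u * cos(theta) - v * sin(theta),
        center[2L] + u * sin(theta) + v * cos(theta))
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `images/`, `masks/`, `labelme/` (polygon annotations mirroring the
#' rendered geometry) and a `truth.json` with the exact generator record for
#' every scene. Scene i uses seed `spec$seed + i`, so the dataset is fully
#' reproducible.
#'
#' @param spec A [scene_spec()].
#' @param n_scenes Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of scene ids.
#' @export
generate_dataset <- function(spec, n_scenes, out_dir) {
  for (d in file.path(out_dir, c("images", "masks", "labelme"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  base_seed <- if (is.null(spec$seed)) 0L else spec$seed
  truth_all <- list()
  ids <- character(n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- spec
    sp$seed <- base_seed + i
    sc <- generate_scene(sp)
    id <- sprintf("scene_%04d", i)
    ids[i] <- id
    png::writePNG(sc$sample$image / 255,
                  file.path(out_dir, "images", paste0(id, ".png")))
    write_mask_png(sc$sample$mask,
                   file.path(out_dir, "masks", paste0(id, ".png")))
    shapes <- list()
    for (s in sc$truth$seedlings) {
      add <- function(label, pts) {
        shapes[[length(shapes) + 1L]] <<- list(
          label = label, shape_type = "polygon",
          points = lapply(seq_len(nrow(pts)), function(j) as.list(pts[j, ])))
      }
      add("shoot", stroke_polygon(s$shoot_curve, s$shoot_width))
      add("root", stroke_polygon(s$root_curve, s$root_width))
      add("seed", ellipse_polygon(s$seed_center, s$seed_axes, s$angle))
    }
    ann <- list(version = "5.0.0", flags = structure(list(), names = character()),
                shapes = shapes,
                imagePath = file.path("..", "images", paste0(id, ".png")),
                imageData = NULL,
                imageHeight = spec$canvas[1L], imageWidth = spec$canvas[2L])
    jsonlite::write_json(ann, file.path(out_dir, "labelme", paste0(id, ".json")),
                         auto_unbox = TRUE, null = "null", digits = NA)
    st <- sc$truth
    st$seedlings <- lapply(st$seedlings, function(s) {
      s$shoot_curve <- NULL
      s$root_curve <- NULL
      s
    })
    truth_all[[id]] <- st
  }
  jsonlite::write_json(truth_all, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(ids)
}
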