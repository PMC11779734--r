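#' Detect the reference coin by Hough-gradient voting
#'
#' Sobel gradients are computed on the grey image; pixels above a relative
#' gradient-magnitude threshold form the edge set. Every edge point casts
#' votes along its gradient direction, at each candidate radius in both
#' directions, into a center accumulator binned per radius; the smoothed
#' (3x3) accumulator peak over all radii fixes the circle. The fit is then
#' refined by a least-squares circle through the edge points that lie on the
#' detected circle and whose gradient points radially, which gives sub-pixel
#' center and radius even in cluttered scenes.
#'
#' @param image `H x W x 3` array (0-255) or `H x W` grey matrix.
#' @param rmin,rmax Radius search range in pixels.
#' @param edge_quantile Relative threshold: edges are pixels whose gradient
#'   magnitude exceeds this fraction of the maximum.
#' @param min_votes Minimum accumulator peak; below it a "no coin found"
#'   error is raised.
#' @return List with `x`, `y` (0-based center coordinates, image
#'   convention), `r` (radius, px) and `votes`.
#' @export
detect_coin <- function(image, rmin = 10, rmax = 200, edge_quantile = 0.25,
                        min_votes = 30) {
  g <- if (length(dim(image)) == 3L) {
    (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  } else {
    image
  }
  h <- nrow(g); w <- ncol(g)
  rmax <- min(rmax, floor(max(h, w) / 2))
  pad <- function(m) {
    m <- rbind(m[1L, ], m, m[nrow(m), ])
    cbind(m[, 1L], m, m[, ncol(m)])
  }
  gp <- pad(g)
  ctr <- function(dy, dx) gp[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
  gx <- (ctr(-1L, 1L) + 2 * ctr(0L, 1L) + ctr(1L, 1L)) -
    (ctr(-1L, -1L) + 2 * ctr(0L, -1L) + ctr(1L, -1L))
  gy <- (ctr(1L, -1L) + 2 * ctr(1L, 0L) + ctr(1L, 1L)) -
    (ctr(-1L, -1L) + 2 * ctr(-1L, 0L) + ctr(-1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  thr <- max(mag) * edge_quantile
  edge <- which(mag > pmax(thr, 1e-8), arr.ind = TRUE)
  if (nrow(edge) < 16L) stop("no coin found: too few gradient edges")
  ex <- edge[, 2L] - 1
  ey <- edge[, 1L] - 1
  m <- mag[edge]
  ux <- gx[edge] / m
  uy <- gy[edge] / m
  hit <- cpp_hough_circle(ex, ey, ux, uy, h, w, rmin, rmax)
  cx <- hit[1L]; cy <- hit[2L]; r <- hit[3L]; votes <- hit[4L]
  if (votes < min_votes) stop("no coin found: accumulator peak too weak")
  # geometric refinement: least-squares circle through radially aligned
  # edge points on the detected circle, iterated to tighten the support
  for (it in 1:2) {
    dx <- ex - cx
    dy <- ey - cy
    dist <- sqrt(dx^2 + dy^2)
    align <- abs(dx * ux + dy * uy) / pmax(dist, 1e-9)
    sup <- abs(dist - r) <= 3 & align > 0.9
    if (sum(sup) < 8L) break
    fit <- kasa_circle(ex[sup], ey[sup])
    cx <- fit$x; cy <- fit$y; r <- fit$r
  }
  list(x = cx, y = cy, r = r, votes = votes)
}

# Algebraic (Kasa) least-squares circle fit.
kasa_circle <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  co <- qr.solve(A, b)
  list(x = -co[1L] / 2, y = -co[2L] / 2,
       r = sqrt(co[1L]^2 / 4 + co[2L]^2 / 4 - co[3L]))
}

#' Pixel-to-millimetre calibration from a detected coin
#'
#' The reference coin has a known physical diameter (25 mm by default), so
#' `mm_per_pixel = coin_diameter_mm / (2 * r)`.
#'
#' @param fit Circle fit from [detect_coin()] (any list with `r`).
#' @param coin_diameter_mm Physical coin diameter.
#' @return List with `mm_per_pixel`, `coin_diameter_mm`, `coin_diameter_px`.
#' @export
calibrate <- function(fit, coin_diameter_mm = 25) {
  if (is.null(fit$r) || fit$r <= 0) stop("invalid circle fit: radius must be positive")
  list(mm_per_pixel = coin_diameter_mm / (2 * fit$r),
       coin_diameter_mm = coin_diameter_mm,
       coin_diameter_px = 2 * fit$r)
}
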