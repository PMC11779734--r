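#' Hilditch skeletonization
#'
#' Iterative boundary thinning of a binary region down to a one-pixel-wide,
#' 8-connected medial line. A pixel is removed when its neighbour count lies
#' in \[2, 6\], the 8-neighbourhood cycle shows a single 0-to-1 transition,
#' and the connectivity-preservation tests on the north and east neighbours
#' pass; passes repeat until a fixed point (capped at `max_passes`).
#'
#' @param mask Logical or 0/1 integer `H x W` matrix.
#' @param max_passes Iteration cap.
#' @return Logical `H x W` skeleton matrix. Empty input yields an empty
#'   skeleton.
#' @export
hilditch_skeletonize <- function(mask, max_passes = 500L) {
  m <- matrix(as.integer(mask != 0), nrow(mask))
  if (!any(m == 1L)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  # C++ kernel works on an x-fastest vector
  v <- cpp_hilditch(as.integer(t(m)), nrow(m), ncol(m), as.integer(max_passes))
  matrix(as.logical(v), nrow(m), byrow = TRUE)
}

#' Geodesic length of a skeleton
#'
#' Sums the 8-connectivity edges of the skeleton: 1 per axial step, sqrt(2)
#' per diagonal step, each edge counted once and summed over all components.
#' A diagonal edge that merely shortcuts two existing axial edges (an
#' L-corner) is not counted, so rasterized straight lines measure exactly
#' their Euclidean length.
#'
#' @param skel Logical `H x W` skeleton matrix.
#' @return Length in pixels.
#' @export
skeleton_length <- function(skel) {
  s <- skel != 0
  h <- nrow(s); w <- ncol(s)
  if (h < 2L || w < 2L) return(0)
  axial <- sum(s[, -w] & s[, -1L]) + sum(s[-h, ] & s[-1L, ])
  se <- s[-h, -w] & s[-1L, -1L] & !s[-h, -1L] & !s[-1L, -w]
  sw <- s[-h, -1L] & s[-1L, -w] & !s[-h, -w] & !s[-1L, -1L]
  axial + sqrt(2) * (sum(se) + sum(sw))
}

#' Chord-resampled skeleton length
#'
#' Decomposes the skeleton into simple chains (between endpoints and
#' junctions), orders the pixels along each chain, and sums chord lengths
#' over every `step`-th pixel (plus the remainder). Resampling across the
#' raster staircase removes the systematic overestimate of the per-edge
#' (1, sqrt 2) sum at intermediate orientations while staying exact on
#' straight axial and diagonal lines; this is the estimator the measurement
#' pipeline uses.
#'
#' @param skel Logical `H x W` skeleton matrix.
#' @param step Resampling stride in pixels along the chain.
#' @return Length in pixels, summed over all chains and components.
#' @export
skeleton_path_length <- function(skel, step = 5L) {
  pix <- which(skel != 0, arr.ind = TRUE)
  n <- nrow(pix)
  if (n < 2L) return(0)
  w <- ncol(skel)
  key <- (pix[, 1L] - 1L) * w + pix[, 2L] # 0-based linear, x fastest per row
  id <- integer(max(key) + 1L)
  id[key + 1L] <- seq_len(n)
  offs <- c(-w - 1L, -w, -w + 1L, -1L, 1L, w - 1L, w, w + 1L)
  dxs <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  present <- matrix(FALSE, n, 8L)
  raw <- matrix(0L, n, 8L)
  maxkey <- length(id)
  x <- key %% w
  for (o in seq_len(8L)) {
    nk <- key + offs[o]
    ok <- nk >= 0L & nk < maxkey & (x + dxs[o]) >= 0L & (x + dxs[o]) < w
    hit <- ok
    hit[ok] <- id[nk[ok] + 1L] > 0L
    present[, o] <- hit
    raw[hit, o] <- id[nk[hit] + 1L]
  }
  # drop diagonal links that shortcut two axial links (L-corners), so
  # staircase chains stay simple paths of degree 2
  shortcut <- list(c(1L, 2L, 4L), c(3L, 2L, 5L), c(6L, 7L, 4L), c(8L, 7L, 5L))
  for (s in shortcut) {
    veto <- present[, s[1L]] & (present[, s[2L]] | present[, s[3L]])
    present[veto, s[1L]] <- FALSE
    raw[veto, s[1L]] <- 0L
  }
  nbr <- raw
  deg <- as.integer(rowSums(present))
  chain_len <- function(path_idx) {
    ys <- pix[path_idx, 1L]
    xs <- pix[path_idx, 2L]
    m <- length(path_idx)
    samp <- unique(c(seq(1L, m, by = step), m))
    sum(sqrt(diff(ys[samp])^2 + diff(xs[samp])^2))
  }
  visited_edge <- new.env(parent = emptyenv())
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  total <- 0
  used <- rep(FALSE, n)
  walk <- function(start, first) {
    path <- c(start, first)
    prev <- start
    cur <- first
    repeat {
      if (deg[cur] != 2L) break
      nxt <- setdiff(nbr[cur, nbr[cur, ] > 0L], prev)
      if (length(nxt) == 0L) break
      prev <- cur
      cur <- nxt[1L]
      path <- c(path, cur)
      if (cur == start) break
    }
    path
  }
  terminals <- which(deg != 2L)
  for (t in terminals) {
    for (nb in nbr[t, nbr[t, ] > 0L]) {
      ek <- edge_key(t, nb)
      if (!is.null(visited_edge[[ek]])) next
      path <- walk(t, nb)
      for (i in seq_len(length(path) - 1L)) {
        visited_edge[[edge_key(path[i], path[i + 1L])]] <- TRUE
      }
      used[path] <- TRUE
      total <- total + chain_len(path)
    }
  }
  # pure cycles (no terminals)
  for (s in which(!used & deg == 2L)) {
    if (used[s]) next
    nb <- nbr[s, nbr[s, ] > 0L][1L]
    if (!is.null(visited_edge[[edge_key(s, nb)]])) next
    path <- walk(s, nb)
    for (i in seq_len(length(path) - 1L)) {
      visited_edge[[edge_key(path[i], path[i + 1L])]] <- TRUE
    }
    used[path] <- TRUE
    total <- total + chain_len(path)
  }
  total
}

# Weighted longest shortest-path (two-sweep Dijkstra) through a skeleton
# component; used by the optional longest-path length mode.
skeleton_longest_path <- function(skel) {
  pix <- which(skel != 0, arr.ind = TRUE)
  n <- nrow(pix)
  if (n == 0L) return(0)
  if (n == 1L) return(0)
  key <- (pix[, 1L] - 1L) * ncol(skel) + pix[, 2L]
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  nbrs <- vector("list", n)
  wts <- vector("list", n)
  for (i in seq_len(n)) {
    y <- pix[i, 1L]; x <- pix[i, 2L]
    nb <- integer(0); wt <- numeric(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      k <- as.character((y + dy - 1L) * ncol(skel) + (x + dx))
      j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1L]]
      if (!is.null(j)) {
        nb <- c(nb, j)
        wt <- c(wt, if (dy != 0L && dx != 0L) sqrt(2) else 1)
      }
    }
    nbrs[[i]] <- nb
    wts[[i]] <- wt
  }
  sweep <- function(src) {
    dist <- rep(Inf, n)
    dist[src] <- 0
    done <- rep(FALSE, n)
    for (it in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      for (j in seq_along(nbrs[[u]])) {
        v <- nbrs[[u]][j]
        alt <- dist[u] + wts[[u]][j]
        if (alt < dist[v]) dist[v] <- alt
      }
    }
    dist[!is.finite(dist)] <- -Inf
    dist
  }
  d1 <- sweep(1L)
  far <- which.max(d1)
  max(sweep(far))
}
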