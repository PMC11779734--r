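#' EMA attention configuration
#'
#' Efficient Multi-scale Attention re-weights a feature map without changing
#' its shape. Channels are folded into `groups` sub-feature groups that are
#' processed as independent samples; each group is described by three
#' parallel routes (two directional-pooling 1x1 routes and one 3x3 route)
#' whose pooled descriptors exchange attention across routes, yielding one
#' per-pixel multiplicative weight in (0, 1) per group.
#'
#' @param groups Number of channel groups; must divide the channel count.
#' @return Configuration list.
#' @export
ema_config <- function(groups = 8L) {
  stopifnot(groups >= 1L)
  list(groups = as.integer(groups))
}

# Bijective index folding g channel groups into the sample axis
# (group index fastest within each original sample).
group_fold_idx <- function(C, h, w, n, g) {
  cg <- C %/% g
  len <- C * h * w * n
  e <- 0:(len - 1L)
  cgi <- e %% cg
  t2 <- e %/% cg
  x <- t2 %% w
  t3 <- t2 %/% w
  y <- t3 %% h
  t4 <- t3 %/% h
  gi <- t4 %% g
  nn <- t4 %/% g
  src_c <- gi * cg + cgi
  src_t <- (nn * h + y) * w + x
  as.integer(src_c + C * src_t + 1L)
}

make_ema <- function(C, cfg) {
  if (C %% cfg$groups != 0L) {
    stop("groups (", cfg$groups, ") must divide channel count (", C, ")")
  }
  cg <- C %/% cfg$groups
  list(
    conv1 = make_conv(cg, cg, 1L),
    conv3 = make_conv(cg, cg, 3L),
    gn = make_gn(cg)
  )
}

fwd_ema <- function(tape, x, p, cfg, keep_attention = FALSE) {
  d <- fdim(x$val)
  h <- d[1L]; w <- d[2L]; n <- d[3L]
  C <- nrow(x$val)
  g <- cfg$groups
  cg <- C %/% g
  idx <- group_fold_idx(C, h, w, n, g)
  xr <- ag_index(tape, x, idx, cg, c(h, w, n * g))
  # 1x1 route: directional pooling, shared pointwise conv, per-direction gates
  ah <- ag_sigmoid(tape, fwd_conv(tape, ag_pool_w(tape, xr), p$conv1))
  aw <- ag_sigmoid(tape, fwd_conv(tape, ag_pool_h(tape, xr), p$conv1))
  x1 <- ag_mul(tape, ag_mul(tape, xr, ag_expand_w(tape, ah, w)),
               ag_expand_h(tape, aw, h))
  x1 <- ag_gn(tape, x1, ag_leaf(tape, p$gn$gamma), ag_leaf(tape, p$gn$beta))
  # 3x3 route (replicate padding so a spatially uniform input stays uniform)
  x2 <- fwd_conv(tape, ag_pad_replicate(tape, xr, 1L), p$conv3)
  # cross-spatial aggregation of softmax-pooled descriptors
  s1 <- ag_softmax_rows(tape, ag_gap(tape, x1))
  s2 <- ag_softmax_rows(tape, ag_gap(tape, x2))
  t1 <- ag_sum_rows(tape, ag_mul(tape, x2, ag_expand_gap(tape, s1, h, w)))
  t2 <- ag_sum_rows(tape, ag_mul(tape, x1, ag_expand_gap(tape, s2, h, w)))
  wmap <- ag_sigmoid(tape, ag_add(tape, t1, t2))
  y <- ag_mul(tape, xr, wmap)
  inv <- integer(length(idx))
  inv[idx] <- seq_along(idx)
  out <- ag_index(tape, y, inv, C, d)
  if (keep_attention) list(out = out, attention = wmap$val) else out
}

#' Initialize an EMA attention module
#'
#' @param channels Channel count of the feature map the module will see.
#' @param cfg An [ema_config()].
#' @return List with `params` and `cfg`.
#' @export
ema_init <- function(channels, cfg = ema_config()) {
  list(params = make_ema(channels, cfg), cfg = cfg)
}

#' EMA attention forward pass
#'
#' @param x Numeric array `C x H x W`.
#' @param ema Module from [ema_init()].
#' @return Array of the same shape; the per-group attention map (values in
#'   (0, 1)) is attached as attribute `"attention"`, a `groups x H x W`
#'   array.
#' @export
ema_forward <- function(x, ema) {
  tp <- ag_tape(grad = FALSE)
  r <- fwd_ema(tp, ag_input(tp, as_fmat(x)), ema$params, ema$cfg,
               keep_attention = TRUE)
  out <- as_farr(r$out$val)
  d <- dim(x)
  att <- aperm(array(r$attention, dim = c(d[3L], d[2L], ema$cfg$groups)),
               c(3L, 2L, 1L))
  attr(out, "attention") <- att
  out
}
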