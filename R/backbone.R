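#' Partial convolution specification
#'
#' A partial convolution (PConv) applies an ordinary k x k convolution to the
#' first `c_p` of `c` input channels and passes the remaining `c - c_p`
#' channels through untouched. This cuts the convolution cost by the factor
#' `(c_p / c)^2` while the pointwise convolutions that follow in a FasterNet
#' block still mix all channels.
#'
#' @param c Total number of channels.
#' @param c_p Number of channels actually convolved (`1 <= c_p <= c`).
#' @param k Odd kernel size.
#' @return A list with elements `c`, `c_p`, `k`.
#' @export
pconv_spec <- function(c, c_p, k = 3L) {
  c <- as.integer(c); c_p <- as.integer(c_p); k <- as.integer(k)
  if (c_p < 1L || c_p > c) stop("c_p must satisfy 1 <= c_p <= c")
  if (k %% 2L == 0L) stop("kernel size must be odd")
  list(c = c, c_p = c_p, k = k)
}

#' Partial convolution forward pass
#'
#' @param x Numeric array `c x H x W`.
#' @param spec A [pconv_spec()].
#' @param weights Numeric array `c_p x c_p x k x k` (out, in, ky, kx); the
#'   convolution is same-padded, stride 1, without bias.
#' @return Array `c x H x W`: the first `c_p` channels convolved, the rest
#'   copied bitwise from the input.
#' @export
pconv_forward <- function(x, spec, weights) {
  if (dim(x)[1L] != spec$c) stop("input has ", dim(x)[1L], " channels, spec expects ", spec$c)
  stopifnot(all(dim(weights) == c(spec$c_p, spec$c_p, spec$k, spec$k)))
  out <- x
  xp <- x[seq_len(spec$c_p), , , drop = FALSE]
  wmat <- conv_weight_matrix(weights)
  tp <- ag_tape(grad = FALSE)
  xin <- ag_input(tp, as_fmat(xp))
  y <- ag_conv2d(tp, xin, ag_node(tp, wmat), ag_node(tp, numeric(spec$c_p)),
                 spec$k, pad = (spec$k - 1L) %/% 2L)
  out[seq_len(spec$c_p), , ] <- as_farr(y$val)
  out
}

# Reshape an (out, in, ky, kx) weight array to the im2col row layout.
conv_weight_matrix <- function(w) {
  d <- dim(w)
  t(matrix(aperm(w, c(4L, 3L, 2L, 1L)), ncol = d[1L]))
}

#' Multiply-accumulate count of a partial convolution
#'
#' For a same-padded stride-1 convolution on an `h x w` grid, a PConv costs
#' `h * w * k^2 * c_p^2` multiply-accumulates against `h * w * k^2 * c^2` for
#' the full convolution — a reduction by `(c_p / c)^2`.
#'
#' @param spec A [pconv_spec()].
#' @param h,w Spatial dimensions.
#' @return A list with `partial`, `full` and `ratio` (= partial / full).
#' @export
pconv_flops <- function(spec, h, w) {
  stopifnot(h >= 1, w >= 1)
  partial <- h * w * spec$k^2 * spec$c_p^2
  full <- h * w * spec$k^2 * spec$c^2
  list(partial = partial, full = full, ratio = partial / full)
}

# --- FasterNet block --------------------------------------------------------

make_fasternet_block <- function(c, c_p, expand = 2L) {
  hid <- c * expand
  list(
    pconv = make_conv(c_p, c_p, 3L),
    pw1 = make_conv(c, hid, 1L),
    bn = make_bn(hid),
    pw2 = make_conv(hid, c, 1L),
    c_p = as.integer(c_p)
  )
}

fwd_pconv <- function(tape, x, p, c_p) {
  cin <- nrow(x$val)
  if (c_p == cin) {
    return(fwd_conv(tape, x, p, pad = (p$k - 1L) %/% 2L))
  }
  head <- ag_slice_rows(tape, x, seq_len(c_p))
  tail <- ag_slice_rows(tape, x, (c_p + 1L):cin)
  conv <- fwd_conv(tape, head, p, pad = (p$k - 1L) %/% 2L)
  ag_concat(tape, conv, tail)
}

fwd_fasternet_block <- function(tape, x, p, training) {
  y <- fwd_pconv(tape, x, p$pconv, p$c_p)
  y <- fwd_conv(tape, y, p$pw1)
  y <- ag_bn(tape, y, ag_leaf(tape, p$bn$gamma), ag_leaf(tape, p$bn$beta),
             p$bn$stats, training)
  y <- ag_relu(tape, y)
  y <- fwd_conv(tape, y, p$pw2)
  ag_add(tape, x, y)
}

#' One FasterNet block applied to a feature array
#'
#' Residual block `x + PWConv2(ReLU(BN(PWConv1(PConv(x)))))`; channels and
#' spatial dimensions are preserved.
#'
#' @param x Numeric array `c x H x W`.
#' @param params Block parameters from [fasternet_block_params()].
#' @param training Logical; use batch statistics (`TRUE`) or running
#'   statistics for the normalization.
#' @return Array with the same dimensions as `x`.
#' @export
fasternet_block <- function(x, params, training = FALSE) {
  tp <- ag_tape(grad = FALSE)
  y <- fwd_fasternet_block(tp, ag_input(tp, as_fmat(x)), params, training)
  as_farr(y$val)
}

#' @rdname fasternet_block
#' @param c Channel count of the block.
#' @param c_p Convolved channel count of the internal PConv.
#' @export
fasternet_block_params <- function(c, c_p = max(1L, c %/% 4L)) {
  make_fasternet_block(as.integer(c), as.integer(c_p))
}

# --- backbone ---------------------------------------------------------------

#' Backbone configuration
#'
#' Four stages of FasterNet blocks preceded by a 4x4 stride-4 patch embedding
#' and separated by 2x2 stride-2 merging convolutions, so stages run at
#' strides 4, 8, 16 and 32. The stage-1 output is kept as the low-level
#' (stride 4) feature map; the stage-4 output is the high-level (stride 32)
#' map.
#'
#' @param depths Number of blocks per stage.
#' @param widths Channel width per stage.
#' @param partial_ratio Fraction `c_p / c` convolved by each PConv.
#' @return Configuration list.
#' @export
backbone_config <- function(depths = c(1L, 2L, 8L, 2L),
                            widths = c(40L, 80L, 160L, 320L),
                            partial_ratio = 0.25) {
  stopifnot(length(depths) == 4L, length(widths) == 4L, all(depths >= 1L),
            partial_ratio > 0, partial_ratio <= 1)
  list(depths = as.integer(depths), widths = as.integer(widths),
       partial_ratio = partial_ratio)
}

make_backbone <- function(cfg, in_ch = 3L) {
  w <- cfg$widths
  cp <- pmax(1L, as.integer(round(w * cfg$partial_ratio)))
  stages <- lapply(1:4, function(s) {
    lapply(seq_len(cfg$depths[s]), function(i) make_fasternet_block(w[s], cp[s]))
  })
  merges <- lapply(1:3, function(s) make_cbr(w[s], w[s + 1L], 2L))
  list(embed = make_cbr(in_ch, w[1L], 4L), stages = stages, merges = merges)
}

fwd_backbone <- function(tape, x, p, training) {
  y <- fwd_cbr(tape, x, p$embed, training, stride = 4L)
  for (blk in p$stages[[1L]]) y <- fwd_fasternet_block(tape, y, blk, training)
  low <- y
  for (s in 2:4) {
    y <- fwd_cbr(tape, y, p$merges[[s - 1L]], training, stride = 2L)
    for (blk in p$stages[[s]]) y <- fwd_fasternet_block(tape, y, blk, training)
  }
  list(low = low, high = y)
}

#' Initialize a backbone
#'
#' @param cfg A [backbone_config()].
#' @return List with `params` and `cfg`.
#' @export
backbone_init <- function(cfg = backbone_config()) {
  list(params = make_backbone(cfg), cfg = cfg)
}

#' Backbone forward pass
#'
#' @param image Numeric array `3 x H x W`; `H` and `W` must be divisible
#'   by 32.
#' @param bb A backbone from [backbone_init()].
#' @param training Logical batch-statistics switch.
#' @return List with `low` (stride-4 feature array) and `high` (stride-32).
#' @export
backbone_forward <- function(image, bb, training = FALSE) {
  d <- dim(image)
  if (d[2L] %% 32L != 0L || d[3L] %% 32L != 0L) {
    stop("input spatial dimensions must be divisible by 32, got ",
         d[2L], "x", d[3L])
  }
  tp <- ag_tape(grad = FALSE)
  out <- fwd_backbone(tp, ag_input(tp, as_fmat(image)), bb$params, training)
  list(low = as_farr(out$low$val), high = as_farr(out$high$val))
}
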