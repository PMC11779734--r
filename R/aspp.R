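#' Series-parallel atrous pyramid configuration
#'
#' The pyramid (PSPA-ASPP) replaces the classical ASPP's 1x1 first branch by
#' a 3x3 partial convolution and splits each 256-wide dilated branch into a
#' pair of 128-wide dilated convolutions at coprime rates, concatenated
#' channel-wise. Pairing rates without a common divisor greater than one
#' keeps the stacked sampling lattices offset from each other and suppresses
#' the gridding effect.
#'
#' @param branch_width Width of each dilated convolution (128).
#' @param rate_pairs List of dilation-rate pairs; rates within a pair must be
#'   coprime.
#' @param out_width Width of the fused output (256).
#' @param branch_a_width Width of the partial-convolution branch.
#' @param serial If `TRUE`, the second rate pair consumes the first pair's
#'   output instead of the pyramid input.
#' @return Configuration list.
#' @export
pyramid_config <- function(branch_width = 128L,
                           rate_pairs = list(c(2L, 3L), c(5L, 7L)),
                           out_width = 256L, branch_a_width = 256L,
                           serial = FALSE) {
  for (pr in rate_pairs) {
    stopifnot(length(pr) == 2L, all(pr >= 1L))
    if (gcd2(pr[1L], pr[2L]) > 1L) {
      stop("dilation rates within a pair must be coprime, got ",
           pr[1L], " and ", pr[2L])
    }
  }
  list(branch_width = as.integer(branch_width),
       rate_pairs = lapply(rate_pairs, as.integer),
       out_width = as.integer(out_width),
       branch_a_width = as.integer(branch_a_width),
       serial = isTRUE(serial))
}

gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)

#' Dilated (atrous) convolution of a feature array
#'
#' Same-padded convolution whose kernel taps are spaced `rate` pixels apart;
#' the effective span is `k + (k - 1) * (rate - 1)` while spatial dimensions
#' are preserved.
#'
#' @param x Numeric array `C x H x W`.
#' @param rate Dilation rate (>= 1); `rate = 1` is a regular convolution.
#' @param weights Array `width x C x k x k`.
#' @return Array `width x H x W`.
#' @export
dilated_conv <- function(x, rate, weights) {
  rate <- as.integer(rate)
  if (rate < 1L) stop("dilation rate must be >= 1")
  k <- dim(weights)[3L]
  tp <- ag_tape(grad = FALSE)
  y <- ag_conv2d(tp, ag_input(tp, as_fmat(x)),
                 ag_node(tp, conv_weight_matrix(weights)),
                 ag_node(tp, numeric(dim(weights)[1L])),
                 k, pad = rate * ((k - 1L) %/% 2L), dil = rate)
  as_farr(y$val)
}

make_pspa <- function(cin, cfg) {
  cp <- max(1L, cin %/% 4L)
  rates <- unlist(cfg$rate_pairs)
  dil_in <- if (cfg$serial) {
    c(rep(cin, 2L), rep(2L * cfg$branch_width, 2L))
  } else {
    rep(cin, 4L)
  }
  list(
    a_pconv = make_conv(cp, cp, 3L),
    a_proj = make_cbr(cin, cfg$branch_a_width, 1L),
    dil = lapply(seq_along(rates), function(i) {
      make_cbr(dil_in[i], cfg$branch_width, 3L)
    }),
    pool = make_cbr(cin, cfg$out_width, 1L),
    fuse = make_cbr(cfg$branch_a_width + 4L * cfg$branch_width + cfg$out_width,
                    cfg$out_width, 1L),
    c_p = cp
  )
}

fwd_pspa <- function(tape, x, p, cfg, training) {
  d <- fdim(x$val)
  rates <- unlist(cfg$rate_pairs)
  span <- max(3L + 2L * (rates - 1L))
  if (d[1L] < span || d[2L] < span) {
    warning("pyramid input ", d[1L], "x", d[2L],
            " is smaller than the largest effective kernel span ", span)
  }
  a <- fwd_cbr(tape, fwd_pconv(tape, x, p$a_pconv, p$c_p), p$a_proj, training)
  br <- function(i, src) {
    fwd_cbr(tape, src, p$dil[[i]], training, pad = rates[i], dil = rates[i])
  }
  b <- ag_concat(tape, br(1L, x), br(2L, x))
  csrc <- if (cfg$serial) b else x
  cc <- ag_concat(tape, br(3L, csrc), br(4L, csrc))
  pooled <- fwd_cbr(tape, ag_gap(tape, x), p$pool, training)
  dd <- ag_expand_gap(tape, pooled, d[1L], d[2L])
  y <- ag_concat(tape, ag_concat(tape, a, b), ag_concat(tape, cc, dd))
  fwd_cbr(tape, y, p$fuse, training)
}

#' Initialize a PSPA-ASPP pyramid
#'
#' @param channels Input channel count.
#' @param cfg A [pyramid_config()].
#' @return List with `params` and `cfg`.
#' @export
pspa_init <- function(channels, cfg = pyramid_config()) {
  list(params = make_pspa(channels, cfg), cfg = cfg)
}

#' PSPA-ASPP forward pass
#'
#' @param x Numeric array `C x H x W` (typically the stride-32 backbone map).
#' @param pyr Module from [pspa_init()].
#' @param training Logical batch-statistics switch.
#' @return Array `out_width x H x W`.
#' @export
pspa_forward <- function(x, pyr, training = FALSE) {
  tp <- ag_tape(grad = FALSE)
  y <- fwd_pspa(tp, ag_input(tp, as_fmat(x)), pyr$params, pyr$cfg, training)
  as_farr(y$val)
}

#' Gridding-effect coverage of stacked dilated convolutions
#'
#' Propagates an influence map through a stack of same-padded `k x k`
#' convolutions with the given dilation rates and reports the fraction of
#' positions inside the stacked receptive field that can influence the
#' central output. Stacks whose rates share a common divisor leave periodic
#' gaps (the gridding effect) and score below 1.
#'
#' @param rates Integer vector of dilation rates, applied in order.
#' @param k Kernel size (odd).
#' @return Fraction in (0, 1].
#' @export
grid_coverage <- function(rates, k = 3L) {
  stopifnot(length(rates) >= 1L, all(rates >= 1L), k %% 2L == 1L)
  half <- (k - 1L) %/% 2L
  R <- sum(rates) * half
  side <- 2L * R + 1L
  f <- matrix(FALSE, side, side)
  f[R + 1L, R + 1L] <- TRUE
  for (r in rates) {
    nf <- matrix(FALSE, side, side)
    for (dy in (-half:half) * r) {
      for (dx in (-half:half) * r) {
        ys <- pmax(1L, 1L - dy):pmin(side, side - dy)
        xs <- pmax(1L, 1L - dx):pmin(side, side - dx)
        nf[ys + dy, xs + dx] <- nf[ys + dy, xs + dx] | f[ys, xs]
      }
    }
    f <- nf
  }
  sum(f) / length(f)
}

# --- analytic multiply-accumulate counters ---------------------------------

conv_macs <- function(cin, cout, k, h, w) as.numeric(h) * w * k^2 * cin * cout

#' Multiply-accumulate counts of the pyramid versus a standard ASPP
#'
#' Counts the convolution multiply-accumulates of the configured pyramid and
#' of a standard ASPP (1x1 branch plus three 256-wide 3x3 dilated branches,
#' image pooling and fusion) at the same input size.
#'
#' @param cin Input channels.
#' @param h,w Input spatial size.
#' @param cfg A [pyramid_config()].
#' @return List with `pspa`, `aspp` and `saving` (aspp - pspa).
#' @export
pspa_flops <- function(cin, h, w, cfg = pyramid_config()) {
  cp <- max(1L, cin %/% 4L)
  bw <- cfg$branch_width
  pspa <- conv_macs(cp, cp, 3L, h, w) +
    conv_macs(cin, cfg$branch_a_width, 1L, h, w) +
    4L * conv_macs(cin, bw, 3L, h, w) +
    conv_macs(cin, cfg$out_width, 1L, 1L, 1L) +
    conv_macs(cfg$branch_a_width + 4L * bw + cfg$out_width, cfg$out_width,
              1L, h, w)
  aspp <- conv_macs(cin, 256L, 1L, h, w) +
    3L * conv_macs(cin, 256L, 3L, h, w) +
    conv_macs(cin, 256L, 1L, 1L, 1L) +
    conv_macs(5L * 256L, 256L, 1L, h, w)
  list(pspa = pspa, aspp = aspp, saving = aspp - pspa)
}
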