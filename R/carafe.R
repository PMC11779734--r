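#' CARAFE upsampler configuration
#'
#' Content-aware reassembly of features: a kernel prediction module
#' compresses the input to `c_m` channels, encodes each position's
#' neighborhood with a `k_encoder x k_encoder` convolution into
#' `sigma^2 * k_up^2` channels, pixel-shuffles them to one `k_up x k_up`
#' kernel per output position, and normalizes each kernel by softmax. Every
#' output value is then the convex combination of the `k_up x k_up` source
#' neighborhood around `floor(output / sigma)`, with all channels at a
#' position sharing the same kernel.
#'
#' @param sigma Integer upsampling factor (>= 2).
#' @param k_up Odd reassembly kernel size.
#' @param k_encoder Odd kernel size of the content encoder.
#' @param c_m Compressed channel count fed to the encoder.
#' @return Configuration list.
#' @export
carafe_config <- function(sigma, k_up = 5L, k_encoder = 3L, c_m = 64L) {
  sigma <- as.integer(sigma)
  stopifnot(sigma >= 2L, k_up %% 2L == 1L, k_encoder %% 2L == 1L, c_m >= 1L)
  list(sigma = sigma, k_up = as.integer(k_up),
       k_encoder = as.integer(k_encoder), c_m = as.integer(c_m))
}

make_carafe <- function(cin, cfg) {
  list(
    compress = make_conv(cin, cfg$c_m, 1L),
    encoder = make_conv(cfg$c_m, cfg$sigma^2 * cfg$k_up^2, cfg$k_encoder)
  )
}

# Bijective pixel-shuffle index: (sigma^2*kup^2) x (H*W) channels to
# kup^2 x (sigma*H x sigma*W). Encoder channel q = w0*sigma^2 + sy*sigma + sx
# supplies kernel weight w0 of output sub-position (sy, sx).
pixel_shuffle_idx <- function(h, w, n, sigma, kup2) {
  Q <- sigma^2 * kup2
  ho <- h * sigma; wo <- w * sigma
  len <- kup2 * ho * wo * n
  e <- 0:(len - 1L)
  w0 <- e %% kup2
  colout <- e %/% kup2
  X0 <- colout %% wo
  rest <- colout %/% wo
  Y0 <- rest %% ho
  nn <- rest %/% ho
  sx <- X0 %% sigma; x <- X0 %/% sigma
  sy <- Y0 %% sigma; y <- Y0 %/% sigma
  q <- w0 * sigma^2 + sy * sigma + sx
  tin <- (nn * h + y) * w + x
  as.integer(q + Q * tin + 1L)
}

fwd_predict_kernels <- function(tape, x, p, cfg) {
  d <- fdim(x$val)
  z <- fwd_conv(tape, x, p$compress)
  z <- ag_relu(tape, z)
  # replicate padding keeps kernel prediction translation-invariant on
  # constant fields right up to the border
  z <- fwd_conv(tape, ag_pad_replicate(tape, z, (cfg$k_encoder - 1L) %/% 2L),
                p$encoder)
  idx <- pixel_shuffle_idx(d[1L], d[2L], d[3L], cfg$sigma, cfg$k_up^2)
  z <- ag_index(tape, z, idx, cfg$k_up^2,
                c(d[1L] * cfg$sigma, d[2L] * cfg$sigma, d[3L]))
  ag_softmax_rows(tape, z)
}

fwd_carafe <- function(tape, x, p, cfg) {
  kern <- fwd_predict_kernels(tape, x, p, cfg)
  ag_carafe_reassemble(tape, x, kern, cfg$sigma, cfg$k_up)
}

#' Initialize a CARAFE module
#'
#' @param channels Input channel count.
#' @param cfg A [carafe_config()].
#' @return List with `params` and `cfg`.
#' @export
carafe_init <- function(channels, cfg) {
  list(params = make_carafe(channels, cfg), cfg = cfg)
}

#' Predict normalized reassembly kernels
#'
#' @param x Numeric array `C x H x W`.
#' @param mod Module from [carafe_init()].
#' @return Array `(sigma*H) x (sigma*W) x k_up^2`; each position's weights
#'   are non-negative and sum to one.
#' @export
predict_kernels <- function(x, mod) {
  tp <- ag_tape(grad = FALSE)
  kern <- fwd_predict_kernels(tp, ag_input(tp, as_fmat(x)), mod$params,
                              mod$cfg)
  d <- fdim(kern$val)
  aperm(array(kern$val, dim = c(mod$cfg$k_up^2, d[2L], d[1L])), c(3L, 2L, 1L))
}

#' Reassemble features under per-position kernels
#'
#' @param x Numeric array `C x H x W`.
#' @param kernels Array `(sigma*H) x (sigma*W) x k_up^2` of reassembly
#'   weights (see [predict_kernels()]).
#' @param sigma Integer upsampling factor.
#' @return Array `C x (sigma*H) x (sigma*W)`; each output position `l'` is
#'   the weighted sum of the `k_up x k_up` input neighborhood centered on
#'   `floor(l' / sigma)`, zero-padded at borders.
#' @export
reassemble <- function(x, kernels, sigma) {
  d <- dim(x)
  kd <- dim(kernels)
  kup <- as.integer(sqrt(kd[3L]))
  stopifnot(kup * kup == kd[3L])
  if (kd[1L] != d[2L] * sigma || kd[2L] != d[3L] * sigma) {
    stop("kernel grid ", kd[1L], "x", kd[2L], " does not match input ",
         d[2L], "x", d[3L], " upsampled by ", sigma)
  }
  kmat <- matrix(aperm(kernels, c(3L, 2L, 1L)), nrow = kd[3L])
  y <- cpp_carafe_forward(as_fmat(x), kmat, d[1L], d[2L], d[3L], 1L,
                          sigma, kup)
  out <- tmat(y, d[2L] * sigma, d[3L] * sigma, 1L)
  as_farr(out)
}

#' Content-aware upsampling
#'
#' Composition of [predict_kernels()] and [reassemble()]: spatial dimensions
#' are multiplied by `sigma`, the channel count is preserved.
#'
#' @param x Numeric array `C x H x W`.
#' @param mod Module from [carafe_init()].
#' @return Array `C x (sigma*H) x (sigma*W)`.
#' @export
carafe_upsample <- function(x, mod) {
  tp <- ag_tape(grad = FALSE)
  y <- fwd_carafe(tp, ag_input(tp, as_fmat(x)), mod$params, mod$cfg)
  as_farr(y$val)
}
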