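# Layer parameter constructors. Conv weights are (c_out) x (c_in * k * k)
# matrices matching the im2col patch layout (channel-major, then ky, kx),
# He-initialized. All constructors draw from the current RNG stream so model
# initialization is reproducible under a caller-provided seed.

make_conv <- function(cin, cout, k = 1L) {
  fan_in <- cin * k * k
  list(
    w = ag_param(matrix(rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                        nrow = cout)),
    b = ag_param(numeric(cout)),
    k = as.integer(k)
  )
}

make_bn <- function(c) {
  list(
    gamma = ag_param(rep(1, c)),
    beta = ag_param(numeric(c)),
    stats = bn_stats(c)
  )
}

make_gn <- function(c) {
  list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)))
}

# conv -> BN -> ReLU block used throughout the decoder and pyramid.
make_cbr <- function(cin, cout, k = 1L) {
  list(conv = make_conv(cin, cout, k), bn = make_bn(cout))
}

fwd_conv <- function(tape, x, p, stride = 1L, pad = 0L, dil = 1L) {
  ag_conv2d(tape, x, ag_leaf(tape, p$w), ag_leaf(tape, p$b), p$k,
            stride = stride, pad = pad, dil = dil)
}

fwd_cbr <- function(tape, x, p, training, stride = 1L, pad = 0L, dil = 1L,
                    act = TRUE) {
  y <- fwd_conv(tape, x, p$conv, stride = stride, pad = pad, dil = dil)
  y <- ag_bn(tape, y, ag_leaf(tape, p$bn$gamma), ag_leaf(tape, p$bn$beta),
             p$bn$stats, training)
  if (act) y <- ag_relu(tape, y) else y
}

# Serialize / restore every parameter and running statistic of a nested
# parameter list as plain numeric objects (used by checkpoints).
params_state <- function(x) {
  if (inherits(x, "ag_param")) return(x$val)
  if (is.environment(x)) return(list(mean = x$mean, var = x$var))
  if (is.list(x)) return(lapply(x, params_state))
  x
}

params_restore <- function(x, state) {
  if (inherits(x, "ag_param")) {
    x$val <- state
    return(invisible(NULL))
  }
  if (is.environment(x)) {
    x$mean <- state$mean
    x$var <- state$var
    return(invisible(NULL))
  }
  if (is.list(x)) {
    for (nm in seq_along(x)) params_restore(x[[nm]], state[[nm]])
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
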