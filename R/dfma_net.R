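#' Full model configuration
#'
#' Assembles the encoder-decoder: FasterNet backbone, EMA attention on the
#' stride-32 map, PSPA-ASPP pyramid, 8x CARAFE upsampling to stride 4,
#' fusion with the 1x1-projected low-level map, partial-convolution
#' refinement, a final 4x upsample and a 1x1 classifier. Output logits match
#' the input resolution.
#'
#' @param backbone A [backbone_config()].
#' @param ema An [ema_config()]; `ema_pre_aspp` / `ema_post_aspp` gate where
#'   the attention is applied.
#' @param aspp A [pyramid_config()].
#' @param k_up,k_encoder,c_m CARAFE kernel settings shared by both
#'   upsampling stages.
#' @param num_classes Number of output classes (4: background, shoot, root,
#'   seed).
#' @param low_level_width Width of the projected low-level map.
#' @param decoder_blocks Number of FasterNet refinement blocks after fusion.
#' @param final_upsample `"carafe"` or `"bilinear"` for the last 4x stage.
#' @param ema_pre_aspp,ema_post_aspp Logical gates for the attention module.
#' @return Configuration list.
#' @export
model_config <- function(backbone = backbone_config(), ema = ema_config(),
                         aspp = pyramid_config(), k_up = 5L, k_encoder = 3L,
                         c_m = 64L, num_classes = 4L, low_level_width = 48L,
                         decoder_blocks = 1L, final_upsample = c("carafe", "bilinear"),
                         ema_pre_aspp = TRUE, ema_post_aspp = FALSE) {
  final_upsample <- match.arg(final_upsample)
  list(backbone = backbone, ema = ema, aspp = aspp,
       carafe_mid = carafe_config(8L, k_up, k_encoder, c_m),
       carafe_final = carafe_config(4L, k_up, k_encoder, c_m),
       num_classes = as.integer(num_classes),
       low_level_width = as.integer(low_level_width),
       decoder_blocks = as.integer(decoder_blocks),
       final_upsample = final_upsample,
       ema_pre_aspp = isTRUE(ema_pre_aspp),
       ema_post_aspp = isTRUE(ema_post_aspp))
}

#' Initialize a full model
#'
#' Draws all parameters from the current RNG stream; wrap in a seeded block
#' (or pass `seed`) for reproducible initialization.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for initialization.
#' @return Model object (list of parameter trees plus `cfg`).
#' @export
dfma_init <- function(cfg = model_config(), seed = NULL) {
  build <- function() {
    whigh <- cfg$backbone$widths[4L]
    wlow <- cfg$backbone$widths[1L]
    ow <- cfg$aspp$out_width
    dec_in <- ow + cfg$low_level_width
    list(
      backbone = make_backbone(cfg$backbone),
      ema = if (cfg$ema_pre_aspp) make_ema(whigh, cfg$ema),
      ema_post = if (cfg$ema_post_aspp) make_ema(ow, cfg$ema),
      aspp = make_pspa(whigh, cfg$aspp),
      carafe_mid = make_carafe(ow, cfg$carafe_mid),
      low_proj = make_cbr(wlow, cfg$low_level_width, 1L),
      decoder = lapply(seq_len(cfg$decoder_blocks), function(i) {
        make_fasternet_block(dec_in, max(1L, dec_in %/% 4L))
      }),
      refine = make_cbr(dec_in, ow, 3L),
      carafe_final = if (cfg$final_upsample == "carafe") make_carafe(ow, cfg$carafe_final),
      classifier = make_conv(ow, cfg$num_classes, 1L)
    )
  }
  params <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(params = params, cfg = cfg), class = "dfma_model")
}

fwd_dfma <- function(tape, x, model, training, stages = FALSE) {
  p <- model$params
  cfg <- model$cfg
  bb <- fwd_backbone(tape, x, p$backbone, training)
  high <- bb$high
  if (cfg$ema_pre_aspp) high <- fwd_ema(tape, high, p$ema, cfg$ema)
  aspp <- fwd_pspa(tape, high, p$aspp, cfg$aspp, training)
  if (cfg$ema_post_aspp) aspp <- fwd_ema(tape, aspp, p$ema_post, cfg$ema)
  up <- fwd_carafe(tape, aspp, p$carafe_mid, cfg$carafe_mid)
  low <- fwd_cbr(tape, bb$low, p$low_proj, training)
  y <- ag_concat(tape, up, low)
  for (blk in p$decoder) y <- fwd_fasternet_block(tape, y, blk, training)
  y <- fwd_cbr(tape, y, p$refine, training, pad = 1L)
  y <- if (cfg$final_upsample == "carafe") {
    fwd_carafe(tape, y, p$carafe_final, cfg$carafe_final)
  } else {
    ag_upsample_bilinear(tape, y, 4L)
  }
  logits <- fwd_conv(tape, y, p$classifier)
  if (stages) {
    list(logits = logits, aspp = aspp, carafe_mid = up, low = low,
         refined = y)
  } else {
    logits
  }
}

check_divisible <- function(h, w) {
  if (h %% 32L != 0L || w %% 32L != 0L) {
    stop("input spatial dimensions must be divisible by 32, got ", h, "x", w)
  }
}

#' Model forward pass
#'
#' @param image Numeric array `3 x H x W` with intensities in \[0, 1\];
#'   `H`, `W` divisible by 32.
#' @param model A [dfma_init()] model.
#' @param training Logical batch-statistics switch.
#' @param return_stages If `TRUE`, also return the ASPP output and the
#'   8x-upsampled map.
#' @return Logits array `num_classes x H x W`, or a list of stage arrays.
#' @export
dfma_forward <- function(image, model, training = FALSE,
                         return_stages = FALSE) {
  d <- dim(image)
  check_divisible(d[2L], d[3L])
  tp <- ag_tape(grad = FALSE)
  out <- fwd_dfma(tp, ag_input(tp, as_fmat(image)), model, training,
                  stages = return_stages)
  if (return_stages) {
    list(logits = as_farr(out$logits$val), aspp = as_farr(out$aspp$val),
         carafe_mid = as_farr(out$carafe_mid$val))
  } else {
    as_farr(out$val)
  }
}

#' Predict a class mask
#'
#' Per-pixel argmax over the logits; exact ties resolve to the lower class
#' index.
#'
#' @inheritParams dfma_forward
#' @return Integer `H x W` matrix of class labels (0-based).
#' @export
predict_mask <- function(image, model) {
  logits <- dfma_forward(image, model)
  logits_to_mask(logits)
}

logits_to_mask <- function(logits) {
  d <- dim(logits)
  flat <- matrix(logits, nrow = d[1L])
  cls <- max.col(t(flat), ties.method = "first") - 1L
  matrix(cls, nrow = d[2L], ncol = d[3L])
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint stores every weight and running statistic together with
#' the full model configuration and the class scheme.
#'
#' @param model A model object.
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(state = params_state(model$params), cfg = model$cfg,
               classes = class_scheme()), path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns the restored model.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- dfma_init(ck$cfg, seed = 0L)
  params_restore(model$params, ck$state)
  model
}
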