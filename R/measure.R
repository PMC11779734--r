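#' Measure shoot and root lengths of every seedling in a mask
#'
#' Seedling instances are the 8-connected components of the union of all
#' non-background classes. Within each instance the shoot-class and
#' root-class pixels are skeletonized (Hilditch) and their geodesic skeleton
#' length taken as the length in pixels; millimetres follow from the
#' calibration. Components containing neither shoot nor root pixels are
#' skipped (with a message). By default the length of a branched skeleton is
#' its total length; `longest_path = TRUE` reports the longest geodesic path
#' instead.
#'
#' @param mask Integer `H x W` matrix of class labels 0..3.
#' @param cal Calibration from [calibrate()].
#' @param longest_path Report the longest path through the skeleton rather
#'   than its total length.
#' @return Data frame with one row per seedling: `instance_id`, `shoot_px`,
#'   `shoot_mm`, `root_px`, `root_mm`, `seed_present`.
#' @export
measure_seedlings <- function(mask, cal, longest_path = FALSE) {
  stopifnot(all(mask %in% 0:3), cal$mm_per_pixel > 0)
  h <- nrow(mask); w <- ncol(mask)
  union <- matrix(as.integer(mask != 0L), h, w)
  lab <- matrix(cpp_label_components(as.integer(t(union)), h, w), h,
                byrow = TRUE)
  out <- NULL
  class_len <- function(sel) {
    if (!any(sel)) return(0)
    sk <- hilditch_skeletonize(sel)
    if (longest_path) skeleton_longest_path(sk) else skeleton_path_length(sk)
  }
  for (id in setdiff(sort(unique(as.integer(lab))), 0L)) {
    comp <- lab == id
    shoot <- comp & mask == 1L
    root <- comp & mask == 2L
    if (!any(shoot) && !any(root)) {
      message("component ", id, " has neither shoot nor root pixels; skipped")
      next
    }
    spx <- class_len(shoot)
    rpx <- class_len(root)
    out <- rbind(out, data.frame(
      instance_id = id,
      shoot_px = spx, shoot_mm = spx * cal$mm_per_pixel,
      root_px = rpx, root_mm = rpx * cal$mm_per_pixel,
      seed_present = any(comp & mask == 3L)))
  }
  if (is.null(out)) {
    out <- data.frame(instance_id = integer(0), shoot_px = numeric(0),
                      shoot_mm = numeric(0), root_px = numeric(0),
                      root_mm = numeric(0), seed_present = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' End-to-end measurement of one coin-bearing image
#'
#' Detects the reference coin on the image, calibrates, and measures every
#' seedling in the mask.
#'
#' @param image `H x W x 3` array (0-255) containing the reference coin.
#' @param mask Integer `H x W` class mask (e.g. from [predict_mask()]).
#' @param coin_mm Physical coin diameter in millimetres.
#' @param ... Passed to [detect_coin()].
#' @return Data frame as in [measure_seedlings()], with the calibration
#'   (`mm_per_pixel`) and coin fit (`coin_x`, `coin_y`, `coin_r`) appended
#'   as columns.
#' @export
measure_image <- function(image, mask, coin_mm = 25, ...) {
  fit <- detect_coin(image, ...)
  cal <- calibrate(fit, coin_mm)
  res <- measure_seedlings(mask, cal)
  res$mm_per_pixel <- cal$mm_per_pixel
  res$coin_x <- fit$x
  res$coin_y <- fit$y
  res$coin_r <- fit$r
  res
}
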