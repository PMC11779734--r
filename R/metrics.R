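#' Class scheme of the segmentation task
#'
#' Four classes: background (0), shoot (1), root (2), seed (3). Index 0 is
#' always background and the name/index mapping is bijective.
#'
#' @return Named integer vector of class indices.
#' @export
class_scheme <- function() {
  c(background = 0L, shoot = 1L, root = 2L, seed = 3L)
}

#' Pixel confusion matrix
#'
#' Rows index the true class, columns the predicted class; entry `[t, p]`
#' counts pixels with truth `t` and prediction `p`. Matrices from different
#' images can simply be added.
#'
#' @param pred,truth Integer vectors or matrices of 0-based class labels
#'   with identical shape.
#' @param n_classes Number of classes.
#' @return `n_classes x n_classes` integer matrix.
#' @export
confusion <- function(pred, truth, n_classes = 4L) {
  if (length(pred) != length(truth)) stop("pred and truth differ in shape")
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(p < 0L | p >= n_classes) || any(t < 0L | t >= n_classes)) {
    stop("labels outside 0..", n_classes - 1L)
  }
  counts <- tabulate(t * n_classes + p + 1L, nbins = n_classes^2)
  matrix(counts, n_classes, n_classes, byrow = TRUE,
         dimnames = list(truth = NULL, pred = NULL))
}

#' Mean intersection over union
#'
#' Mean over classes of `TP / (TP + FP + FN)`. Classes absent from both
#' truth and prediction carry no information and are excluded from the mean
#' (reported via a message).
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Fraction in \[0, 1\].
#' @export
miou <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  present <- (tp + fp + fn) > 0
  if (!any(present)) stop("no class present in truth or prediction")
  if (any(!present)) {
    message("excluding ", sum(!present), " class(es) absent from both truth and prediction")
  }
  mean(tp[present] / (tp + fp + fn)[present])
}

#' Per-class precision, recall and accuracy
#'
#' One-vs-rest reduction of the confusion matrix for class `class_index`,
#' then `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`. Undefined ratios (zero denominator)
#' are returned as `NA` rather than raising an error.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param class_index 0-based class label.
#' @return List with `precision`, `recall`, `accuracy`.
#' @export
precision_recall_accuracy <- function(cm, class_index) {
  i <- class_index + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    accuracy = (tp + tn) / sum(cm)
  )
}

#' Combined cross-entropy and Dice loss
#'
#' `L = CE + Dice` with unit weights; the Dice term is computed per class
#' with additive smoothing and averaged over the classes present in the
#' truth.
#'
#' @param logits Numeric array `num_classes x H x W` of raw scores.
#' @param truth Integer `H x W` matrix of 0-based labels.
#' @param dice_eps Dice smoothing constant.
#' @return List with `total`, `ce` and `dice` components.
#' @export
seg_loss <- function(logits, truth, dice_eps = 1) {
  tp <- ag_tape(grad = FALSE)
  node <- ag_input(tp, as_fmat(logits))
  target <- as.integer(t(truth)) # x fastest to match the column layout
  l <- ag_seg_loss(tp, node, target, dice_eps = dice_eps)
  list(total = l$val, ce = l$ce, dice = l$dice)
}
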