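#' Pixel-wise segmentation metrics
#'
#' Pools the confusion counts over all pixels of all images (micro
#' averaging) with the foreground class (1) as positive, and reports
#' precision, recall, F1, accuracy and mean IoU. mIoU is the mean of the
#' foreground and background intersection-over-union. Ratios with a zero
#' denominator are reported as 0 and recorded in the `degenerate` field.
#'
#' @param pred predicted binary mask(s): `H x W`, `H x W x N`, or a list.
#' @param truth ground-truth binary mask(s), same shape as `pred`.
#' @return an object of class `metrics_report` with fields `precision`,
#'   `recall`, `f1`, `accuracy`, `miou`, the confusion counts `tp`, `fp`,
#'   `fn`, `tn`, and `degenerate` (names of zero-denominator metrics).
#' @export
evaluate <- function(pred, truth) {
  pred <- as_mask_batch(pred)
  truth <- as_mask_batch(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction and truth shapes differ")
  }
  check_binary(pred, "prediction")
  check_binary(truth, "truth")

  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)

  degenerate <- character(0)
  ratio <- function(num, den, what, vacuous = 0) {
    if (den == 0) {
      degenerate <<- c(degenerate, what)
      return(vacuous)
    }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  accuracy <- ratio(tp + tn, tp + fp + fn + tn, "accuracy")
  # a class absent from both prediction and truth (empty union) has a
  # vacuously perfect IoU
  iou_fg <- ratio(tp, tp + fp + fn, "iou_fg", vacuous = 1)
  iou_bg <- ratio(tn, tn + fn + fp, "iou_bg", vacuous = 1)

  structure(list(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy, miou = (iou_fg + iou_bg) / 2,
                 iou_fg = iou_fg, iou_bg = iou_bg,
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f  mIoU %.4f\n",
    x$precision, x$recall, x$f1, x$accuracy, x$miou))
  cat(sprintf("counts: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  if (length(x$degenerate)) {
    cat("zero-denominator metrics reported as 0:",
        paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate probability maps against binary truth
#'
#' Binarizes by the foreground probability (foreground iff strictly greater
#' than `threshold`; at the default 0.5 this equals the channel argmax with
#' ties going to background) and calls [evaluate()].
#'
#' @param pred an `H x W x 2` probability map or an `H x W x 2 x N` batch.
#' @param truth binary truth mask(s).
#' @param threshold foreground decision threshold.
#' @return a `metrics_report`.
#' @export
evaluate_probmap <- function(pred, truth, threshold = 0.5) {
  d <- dim(pred)
  if (length(d) == 3L) dim(pred) <- c(d, 1L)
  fg <- pred[, , 2, , drop = TRUE]
  mask <- (fg > threshold) * 1
  dim(mask) <- dim(pred)[c(1, 2, 4)]
  evaluate(mask, truth)
}
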