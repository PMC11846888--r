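# Training objectives: binary cross-entropy, teacher-student consistency,
# and the prediction exponential-moving-average (EMA) penalty.
#
# Squared-distance losses average over samples; within each sample the
# squared Euclidean distance over the full prediction map is averaged over
# pixels (and summed over the two class channels) so that magnitudes are
# comparable across image sizes.

# foreground-probability channel of a prob map batch; accepts either an
# H x W x 2 (x N) softmax output or a plain foreground-probability array
fg_prob <- function(yhat) {
  d <- dim(yhat)
  if (!is.null(d) && length(d) >= 3L && d[3] == 2L) {
    idx <- rep(list(quote(expr = )), length(d))
    idx[[3]] <- 2L
    do.call(`[`, c(list(yhat), idx, list(drop = TRUE)))
  } else {
    yhat
  }
}

pred_sqdist <- function(a, b) {
  d <- dim(a)
  n <- if (length(d) == 4L) d[4] else 1L
  sum((a - b)^2) / (d[1] * d[2] * n)
}

loss_value <- function(components) {
  structure(list(total = sum(unlist(components)), components = components),
            class = "stseg_loss")
}

#' @export
print.stseg_loss <- function(x, ...) {
  comp <- paste(sprintf("%s = %.6g", names(x$components),
                        unlist(x$components)), collapse = ", ")
  cat(sprintf("loss %.6g (%s)\n", x$total, comp))
  invisible(x)
}

#' Binary cross-entropy loss
#'
#' Negative Bernoulli log-likelihood of the binary masks under the
#' foreground-probability channel, averaged over all pixels of all samples.
#' Probabilities are clamped to `[eps, 1 - eps]`.
#'
#' @param y binary mask(s): `H x W`, `H x W x N`, or a list of masks.
#' @param yhat predicted probabilities: an `H x W x 2 (x N)` probability
#'   map batch, or an array of foreground probabilities shaped like `y`.
#' @param eps clamping constant.
#' @return the scalar loss.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  y <- as.numeric(as_mask_batch(y))
  check_binary(y, "label")
  p <- as.numeric(fg_prob(yhat))
  if (length(p) != length(y)) stop("prediction and label shapes differ")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Consistency loss between student and teacher predictions
#'
#' Mean over samples of the squared Euclidean distance between the two
#' prediction maps (averaged over pixels within a sample). When used as a
#' training signal the teacher prediction is a constant: no gradient flows
#' into the teacher through this term.
#'
#' @param f_student,f_teacher probability map batches of identical shape.
#' @return the scalar loss (0 iff the predictions are identical).
#' @export
consistency_loss <- function(f_student, f_teacher) {
  if (!identical(dim(f_student), dim(f_teacher))) {
    stop("student and teacher prediction shapes differ")
  }
  pred_sqdist(f_student, f_teacher)
}

#' Per-sample prediction EMA state
#'
#' Holds one exponentially smoothed prediction map per training sample,
#' keyed by a stable sample identifier. The smoothing update is
#' `ema <- alpha * yhat + (1 - alpha) * ema_previous`, i.e. `alpha` weights
#' the current prediction.
#'
#' @param alpha smoothing factor in (0, 1].
#' @return an object of class `ema_state`.
#' @export
ema_state <- function(alpha = 0.1) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  st <- new.env(parent = emptyenv())
  st$alpha <- alpha
  st$maps <- list()
  class(st) <- "ema_state"
  st
}

#' Update the EMA state for one sample
#'
#' An unseen `sample_id` is initialized to `yhat` itself.
#'
#' @param state an [ema_state()].
#' @param sample_id character identifier of the sample.
#' @param yhat the sample's current prediction map.
#' @return the state, invisibly (updated in place).
#' @export
ema_update <- function(state, sample_id, yhat) {
  prev <- state$maps[[sample_id]]
  state$maps[[sample_id]] <- if (is.null(prev)) yhat else
    state$alpha * yhat + (1 - state$alpha) * prev
  invisible(state)
}

#' Prediction-EMA loss
#'
#' Mean over batch samples of the squared distance between each current
#' prediction and its stored EMA. Samples not yet in the state are
#' initialized to their current prediction and contribute zero.
#'
#' @param yhat an `H x W x 2 x N` (or `H x W x 2`) prediction batch.
#' @param sample_ids character identifiers, one per batch sample.
#' @param state an [ema_state()].
#' @return the scalar loss.
#' @export
ema_loss <- function(yhat, sample_ids, state) {
  d <- dim(yhat)
  if (length(d) == 3L) dim(yhat) <- c(d, 1L)
  n <- dim(yhat)[4]
  stopifnot(length(sample_ids) == n)
  total <- 0
  for (i in seq_len(n)) {
    cur <- yhat[, , , i, drop = FALSE]
    dim(cur) <- dim(cur)[1:3]
    if (is.null(state$maps[[sample_ids[i]]])) {
      state$maps[[sample_ids[i]]] <- cur
    }
    total <- total + pred_sqdist(cur, state$maps[[sample_ids[i]]])
  }
  total / n
}

#' Combined objectives
#'
#' The student objective is `BCE + consistency`; the teacher objective is
#' `BCE + EMA`, both unweighted sums.
#'
#' @param bce,consistency,ema scalar component losses.
#' @return an object of class `stseg_loss` with the total and a component
#'   breakdown.
#' @export
student_objective <- function(bce, consistency) {
  loss_value(list(bce = bce, consistency = consistency))
}

#' @rdname student_objective
#' @export
teacher_objective <- function(bce, ema) {
  loss_value(list(bce = bce, ema = ema))
}
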