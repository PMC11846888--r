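# Iterative self-training of the teacher and pseudo-label generation.

# One supervised training run (BCE) over `samples`, continuing an existing
# Adam state when given. Each epoch reseeds the RNG from
# (seed, epoch_offset + epoch) so that a K-iteration self-training run with
# no unlabeled data is bit-identical to one continuous supervised run.
train_supervised <- function(model, samples, epochs, batch_size = 8L,
                             lr = 1e-3, seed = 1L, epoch_offset = 0L,
                             opt = NULL) {
  if (length(samples) == 0L) stop("no training samples")
  if (is.null(opt)) opt <- adam_new(model$params, lr = lr)
  epoch_losses <- numeric(epochs)
  for (e in seq_len(epochs)) {
    set.seed(derive_seed(seed, sprintf("epoch-%d", epoch_offset + e)))
    ord <- sample.int(length(samples))
    batch_losses <- c()
    for (start in seq(1L, length(samples), by = batch_size)) {
      idx <- ord[start:min(length(samples), start + batch_size - 1L)]
      x <- as_image_batch(lapply(samples[idx], `[[`, "image"))
      y <- as_mask_batch(lapply(samples[idx], `[[`, "mask"))
      wts <- NULL
      has_w <- any(vapply(samples[idx], function(s)
        !is.null(s$loss_weight), logical(1)))
      if (has_w) {
        wts <- as.numeric(as_mask_batch(lapply(samples[idx], function(s)
          s$loss_weight %||% array(1, dim(s$mask)))))
      }
      tape <- ad_tape()
      fw <- model_forward(model, x, tape, training = TRUE,
                          dropout_active = TRUE)
      loss <- op_bce(tape, fw$probs, y, weights = wts)
      if (!is.finite(loss$value)) stop("non-finite training loss")
      ad_zero_grads(model$params)
      ad_backward(tape, loss)
      adam_step(opt, model$params)
      batch_losses <- c(batch_losses, loss$value)
    }
    epoch_losses[e] <- mean(batch_losses)
  }
  list(opt = opt, epoch_losses = epoch_losses)
}

#' Threshold foreground probabilities into a binary mask
#'
#' A pixel is labeled foreground iff its foreground probability strictly
#' exceeds `tau`; a probability equal to `tau` stays background.
#'
#' @param fg_prob array of foreground probabilities.
#' @param tau confidence threshold, strictly inside (0, 1).
#' @return a 0/1 array shaped like `fg_prob`.
#' @export
threshold_probs <- function(fg_prob, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must be strictly inside (0, 1)")
  (fg_prob > tau) * 1
}

#' Generate thresholded pseudo-labels
#'
#' Runs the teacher in inference mode (dropout disabled) on the unlabeled
#' images and labels a pixel foreground iff its predicted foreground
#' probability strictly exceeds `tau`; all other pixels become background.
#'
#' @param teacher a trained teacher model.
#' @param unlabeled a list of samples (each with `id` and `image`) or a
#'   `data_split` (its `unlabeled` part is used).
#' @param tau confidence threshold, strictly inside (0, 1).
#' @return an object of class `pseudo_label_set`: per-sample binary `masks`
#'   and foreground-probability maps `probs` (both named by sample id), and
#'   the `tau` used.
#' @export
generate_pseudo_labels <- function(teacher, unlabeled, tau = 0.7) {
  if (tau <= 0 || tau >= 1) stop("tau must be strictly inside (0, 1)")
  if (inherits(unlabeled, "data_split")) unlabeled <- unlabeled$unlabeled
  ids <- vapply(unlabeled, `[[`, character(1), "id")
  masks <- list()
  probs <- list()
  for (i in seq_along(unlabeled)) {
    p <- predict_probs(teacher, unlabeled[[i]]$image)
    fg <- p[, , 2]
    masks[[ids[i]]] <- threshold_probs(fg, tau)
    probs[[ids[i]]] <- fg
  }
  structure(list(ids = ids, masks = masks, probs = probs, tau = tau),
            class = "pseudo_label_set")
}

#' Summarize pseudo-label coverage
#'
#' @param pl a `pseudo_label_set`.
#' @return list with `foreground_fraction` (pooled over all pixels) and a
#'   per-image data frame of foreground fraction and mean confidence (mean
#'   of the max class probability).
#' @export
pseudo_label_coverage <- function(pl) {
  stopifnot(inherits(pl, "pseudo_label_set"), length(pl$ids) > 0L)
  per <- data.frame(
    id = pl$ids,
    foreground_fraction = vapply(pl$masks, mean, numeric(1)),
    mean_confidence = vapply(pl$probs, function(p)
      mean(pmax(p, 1 - p)), numeric(1)),
    row.names = NULL
  )
  fg <- sum(vapply(pl$masks, sum, numeric(1)))
  tot <- sum(vapply(pl$masks, length, numeric(1)))
  list(foreground_fraction = fg / tot, per_image = per)
}

#' Self-training configuration
#'
#' @param iterations maximum number of self-training iterations `K`.
#' @param epochs training epochs within each iteration.
#' @param warmup_epochs epochs of the first (labeled-only) iteration;
#'   defaults to `epochs`. Pseudo-labeling only helps once the initial
#'   teacher fits the labeled subset, so with very small labeled pools a
#'   longer warmup guards against the self-confirmation collapse in which
#'   an undertrained teacher floods the training set with wrong labels.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param tau pseudo-label confidence threshold.
#' @param tol stop early when validation mIoU improves by less than `tol`
#'   between iterations; `NA` disables early stopping (always run `K`).
#' @param seed global seed for initialization, shuffling and dropout.
#' @param teacher a [teacher_spec()].
#' @param ignore_low_confidence if `TRUE`, pixels whose maximum class
#'   probability does not exceed `tau` are excluded from the retraining
#'   loss instead of being labeled background (the default keeps the
#'   literal rule: below-threshold pixels become background).
#' @return a list of class `self_train_config`.
#' @export
self_train_config <- function(iterations = 5L, epochs = 10L,
                              warmup_epochs = epochs, batch_size = 8L,
                              lr = 1e-3, tau = 0.7, tol = 1e-3, seed = 1L,
                              teacher = teacher_spec(),
                              ignore_low_confidence = FALSE) {
  structure(list(iterations = as.integer(iterations),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 batch_size = as.integer(batch_size), lr = lr, tau = tau,
                 tol = tol, seed = as.integer(seed), teacher = teacher,
                 ignore_low_confidence = ignore_low_confidence),
            class = "self_train_config")
}

#' Iterative self-training of the teacher
#'
#' Iteration 1 trains the teacher on the labeled subset only. Every later
#' iteration starts from the previous iteration's weights (and optimizer
#' state), regenerates pseudo-labels for the whole unlabeled pool with the
#' current teacher, and retrains on the union of labeled and pseudo-labeled
#' data. Training stops after `iterations` rounds or when the validation
#' mIoU gain falls below `tol`. With an empty unlabeled pool the procedure
#' degenerates to plain supervised training.
#'
#' @param split a `data_split` with at least one labeled sample.
#' @param config a [self_train_config()].
#' @param verbose print per-iteration validation mIoU.
#' @return an object of class `self_train_state`: the trained `teacher`,
#'   the per-iteration validation `history` (list of `metrics_report`),
#'   `iterations_run`, and the final `pseudo` label set (or `NULL`).
#' @export
self_train_teacher <- function(split, config = self_train_config(),
                               verbose = FALSE) {
  if (length(split$labeled) == 0L) stop("self-training needs labeled samples")
  teacher <- build_teacher(config$teacher, seed = config$seed)
  opt <- NULL
  history <- list()
  val_imgs <- lapply(split$validation, `[[`, "image")
  val_masks <- as_mask_batch(lapply(split$validation, `[[`, "mask"))
  k_run <- 0L
  for (k in seq_len(config$iterations)) {
    if (k == 1L || length(split$unlabeled) == 0L) {
      train_samples <- split$labeled
    } else {
      pl <- generate_pseudo_labels(teacher, split$unlabeled, config$tau)
      pseudo_samples <- lapply(split$unlabeled, function(s) {
        out <- list(id = s$id, image = s$image, mask = pl$masks[[s$id]])
        if (config$ignore_low_confidence) {
          p <- pl$probs[[s$id]]
          out$loss_weight <- (pmax(p, 1 - p) > config$tau) * 1
        }
        out
      })
      train_samples <- c(split$labeled, pseudo_samples)
    }
    n_epochs <- if (k == 1L) config$warmup_epochs else config$epochs
    offset <- if (k == 1L) 0L else
      config$warmup_epochs + (k - 2L) * config$epochs
    res <- train_supervised(teacher, train_samples, n_epochs,
                            config$batch_size, config$lr, config$seed,
                            epoch_offset = offset, opt = opt)
    opt <- res$opt
    k_run <- k
    rep <- evaluate_probmap(predict_probs(teacher, val_imgs), val_masks)
    history[[k]] <- rep
    if (verbose) {
      message(sprintf("self-training iteration %d: validation mIoU %.4f",
                      k, rep$miou))
    }
    if (!is.na(config$tol) && k >= 2L &&
        history[[k]]$miou - history[[k - 1L]]$miou < config$tol) {
      break
    }
  }
  pseudo <- if (length(split$unlabeled) > 0L) {
    generate_pseudo_labels(teacher, split$unlabeled, config$tau)
  }
  structure(list(teacher = teacher, history = history,
                 iterations_run = k_run, pseudo = pseudo, config = config),
            class = "self_train_state")
}
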