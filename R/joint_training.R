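# Joint teacher-student training.
#
# Per batch the student takes a gradient step on BCE + consistency (the
# teacher's prediction is a constant in the consistency term), then the
# teacher takes a step on BCE (ground-truth labels only) + the prediction
# EMA penalty. The two models have disjoint parameter sets, so one model's
# step never touches the other's weights.

#' Joint training configuration
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size (labeled and unlabeled samples are
#'   mixed by shuffling the pooled training set, so batch composition is
#'   proportional to the pool sizes on average).
#' @param lr_student,lr_teacher Adam learning rates.
#' @param alpha EMA smoothing factor in (0, 1]; weights the current
#'   prediction.
#' @param seed global seed.
#' @param mode `"semi_supervised"` (teacher + consistency + pseudo-labels)
#'   or `"supervised_only"` (student trained with BCE on the labeled subset
#'   alone; no teacher, consistency or EMA terms).
#' @param consistency_on_labeled apply the consistency term to labeled
#'   samples too (default); if `FALSE` it covers only unlabeled samples
#'   (still averaged over the batch size).
#' @param student a [student_spec()] used when no student model is passed.
#' @param validate_every compute validation metrics every this many epochs.
#' @return a list of class `joint_train_config`.
#' @export
joint_train_config <- function(epochs = 30L, batch_size = 8L,
                               lr_student = 1e-3, lr_teacher = 1e-3,
                               alpha = 0.1, seed = 1L,
                               mode = c("semi_supervised", "supervised_only"),
                               consistency_on_labeled = TRUE,
                               student = student_spec(),
                               validate_every = 1L) {
  mode <- match.arg(mode)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_student = lr_student, lr_teacher = lr_teacher,
                 alpha = alpha, seed = as.integer(seed), mode = mode,
                 consistency_on_labeled = consistency_on_labeled,
                 student = student,
                 validate_every = as.integer(validate_every)),
            class = "joint_train_config")
}

#' Train the student jointly with the teacher
#'
#' In semi-supervised mode the student's BCE uses ground-truth masks for
#' labeled samples and thresholded pseudo-labels for unlabeled samples,
#' while its consistency term penalizes disagreement with the teacher's
#' prediction on the same inputs. The teacher is simultaneously updated by
#' BCE on the labeled samples plus a penalty tying its prediction to a
#' per-sample exponential moving average of its past predictions (updated
#' exactly once per sample per epoch). In supervised-only mode the student
#' is trained with plain BCE on the labeled subset and the teacher is not
#' used.
#'
#' @param split a `data_split`.
#' @param pseudo a `pseudo_label_set` covering all unlabeled samples
#'   (required in semi-supervised mode with a non-empty unlabeled pool).
#' @param teacher a self-trained teacher model (semi-supervised mode).
#' @param student a built student model, or `NULL` to build one from
#'   `config$student`.
#' @param config a [joint_train_config()].
#' @param verbose print per-epoch losses.
#' @return an object of class `joint_train_result`: the trained `student`
#'   and `teacher`, and a per-epoch `trace` data frame of loss components
#'   and validation metrics.
#' @export
train_joint <- function(split, pseudo = NULL, teacher = NULL, student = NULL,
                        config = joint_train_config(), verbose = FALSE) {
  if (is.null(student)) student <- build_student(config$student,
                                                seed = config$seed)
  semi <- config$mode == "semi_supervised"
  if (semi && is.null(teacher)) {
    stop("semi-supervised mode requires a teacher model")
  }
  val_imgs <- lapply(split$validation, `[[`, "image")
  val_masks <- as_mask_batch(lapply(split$validation, `[[`, "mask"))

  samples <- lapply(split$labeled, function(s)
    list(id = s$id, image = s$image, mask = s$mask, labeled = TRUE))
  if (semi) {
    for (s in split$unlabeled) {
      mask <- pseudo$masks[[s$id]]
      if (is.null(mask)) {
        stop(sprintf("missing pseudo-label for unlabeled sample '%s'", s$id))
      }
      samples[[length(samples) + 1L]] <-
        list(id = s$id, image = s$image, mask = mask, labeled = FALSE)
    }
  }

  opt_s <- adam_new(student$params, lr = config$lr_student)
  opt_t <- if (semi) adam_new(teacher$params, lr = config$lr_teacher)
  ema <- if (semi) ema_state(config$alpha)

  trace <- list()
  for (e in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, sprintf("joint-epoch-%d", e)))
    ord <- sample.int(length(samples))
    acc <- list()
    for (start in seq(1L, length(samples), by = config$batch_size)) {
      idx <- ord[start:min(length(samples), start + config$batch_size - 1L)]
      batch <- samples[idx]
      x <- as_image_batch(lapply(batch, `[[`, "image"))
      y <- as_mask_batch(lapply(batch, `[[`, "mask"))
      labeled <- vapply(batch, `[[`, logical(1), "labeled")
      ids <- vapply(batch, `[[`, character(1), "id")
      nb <- length(batch)

      t_probs_val <- NULL
      fw_t <- NULL
      tape_t <- NULL
      if (semi) {
        tape_t <- ad_tape()
        fw_t <- teacher_forward(teacher, x, tape_t, training = TRUE,
                                dropout_active = FALSE)
        t_probs_val <- fw_t$probs$value
      }

      # ---- student step ----
      tape_s <- ad_tape()
      fw_s <- student_forward(student, x, tape_s, training = TRUE)
      bce_s <- op_bce(tape_s, fw_s$probs, y)
      if (semi) {
        target <- t_probs_val
        if (!config$consistency_on_labeled && any(labeled)) {
          target[, , , labeled] <- fw_s$probs$value[, , , labeled]
        }
        cons_s <- op_pred_sqdist(tape_s, fw_s$probs, target)
        loss_s <- op_add_scalars(tape_s, list(bce_s, cons_s))
      } else {
        cons_s <- NULL
        loss_s <- bce_s
      }
      if (!is.finite(loss_s$value)) {
        stop(sprintf("non-finite student loss in epoch %d", e))
      }
      ad_zero_grads(student$params)
      ad_backward(tape_s, loss_s)
      adam_step(opt_s, student$params)

      # ---- teacher step ----
      if (semi) {
        d <- dim(t_probs_val)
        ema_target <- array(0, d)
        for (i in seq_len(nb)) {
          cur <- t_probs_val[, , , i, drop = FALSE]
          dim(cur) <- d[1:3]
          if (is.null(ema$maps[[ids[i]]])) ema$maps[[ids[i]]] <- cur
          ema_target[, , , i] <- ema$maps[[ids[i]]]
        }
        ema_t <- op_pred_sqdist(tape_t, fw_t$probs, ema_target)
        if (any(labeled)) {
          wts <- array(0, dim(y))
          wts[, , labeled] <- 1
          bce_t <- op_bce(tape_t, fw_t$probs, y, weights = as.numeric(wts))
          loss_t <- op_add_scalars(tape_t, list(bce_t, ema_t))
          bce_t_val <- bce_t$value
        } else {
          loss_t <- ema_t
          bce_t_val <- 0
        }
        if (!is.finite(loss_t$value)) {
          stop(sprintf("non-finite teacher loss in epoch %d", e))
        }
        ad_zero_grads(teacher$params)
        ad_backward(tape_t, loss_t)
        adam_step(opt_t, teacher$params)
        for (i in seq_len(nb)) {
          cur <- t_probs_val[, , , i, drop = FALSE]
          dim(cur) <- d[1:3]
          ema_update(ema, ids[i], cur)
        }
      }

      row <- list(student_total = loss_s$value, student_bce = bce_s$value)
      if (semi) {
        row$student_consistency <- cons_s$value
        row$teacher_total <- loss_t$value
        row$teacher_bce <- bce_t_val
        row$teacher_ema <- ema_t$value
      }
      acc[[length(acc) + 1L]] <- row
    }
    rec <- as.list(colMeans(do.call(rbind, lapply(acc, as.data.frame))))
    rec$epoch <- e
    if (e %% config$validate_every == 0L || e == config$epochs) {
      rep <- evaluate_probmap(predict_probs(student, val_imgs), val_masks)
      rec$val_miou <- rep$miou
      rec$val_f1 <- rep$f1
      rec$val_accuracy <- rep$accuracy
    } else {
      rec$val_miou <- NA_real_
      rec$val_f1 <- NA_real_
      rec$val_accuracy <- NA_real_
    }
    trace[[e]] <- as.data.frame(rec)
    if (verbose) {
      message(sprintf("epoch %d: student loss %.4f%s", e, rec$student_total,
                      if (semi) sprintf(", teacher loss %.4f",
                                        rec$teacher_total) else ""))
    }
  }
  trace <- do.call(rbind, trace)
  structure(list(student = student, teacher = if (semi) teacher,
                 trace = trace, ema = ema, config = config),
            class = "joint_train_result")
}
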