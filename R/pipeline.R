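# Run configuration and end-to-end pipeline orchestration.

#' Default run configuration
#'
#' A nested configuration mirroring every stage's parameters. Unknown keys
#' are rejected when a configuration is validated or loaded from YAML;
#' missing keys fall back to these defaults. The defaults describe a small
#' synthetic end-to-end run.
#'
#' @return a nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 17L,
    mode = "semi_supervised",
    data = list(n_images = 64L, n_validation = 16L, size = 64L,
                labeled_fraction = 0.2, color_jitter_sd = 0.06),
    normalize = list(enabled = TRUE),
    teacher = list(filters = c(8L, 16L, 32L, 64L, 128L), dropout_rate = 0.3),
    self_train = list(iterations = 3L, epochs = 5L, warmup_epochs = 30L,
                      batch_size = 8L, lr = 1e-3, tau = 0.7, tol = 1e-3,
                      ignore_low_confidence = TRUE),
    student = list(upper_filters = c(16L, 64L),
                   lower_filters = c(16L, 32L, 64L, 128L),
                   bottleneck_filters = 256L),
    joint = list(epochs = 8L, batch_size = 8L, lr_student = 1e-3,
                 lr_teacher = 1e-3, alpha = 0.1,
                 consistency_on_labeled = TRUE),
    uncertainty = list(enabled = TRUE, passes = 30L)
  ), class = "run_config")
}

check_keys <- function(x, template, path = "") {
  extra <- setdiff(names(x), names(template))
  if (length(extra)) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(extra) > 1) "s" else "",
                 paste0(path, extra, collapse = ", ")))
  }
  for (nm in names(x)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      if (!is.list(x[[nm]])) stop(sprintf("'%s%s' must be a section", path, nm))
      check_keys(x[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(x, template) {
  for (nm in names(template)) {
    if (is.null(x[[nm]])) {
      x[[nm]] <- template[[nm]]
    } else if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      x[[nm]] <- merge_config(x[[nm]], template[[nm]])
    }
  }
  x
}

#' Validate (and complete) a run configuration
#'
#' @param config a partial or full nested configuration list.
#' @return the completed `run_config`; unknown keys raise an error.
#' @export
validate_run_config <- function(config) {
  template <- default_run_config()
  check_keys(config, template)
  config <- merge_config(config, template)
  if (!config$mode %in% c("semi_supervised", "supervised_only")) {
    stop("mode must be 'semi_supervised' or 'supervised_only'")
  }
  class(config) <- "run_config"
  config
}

#' Load / save a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `run_config`.
#' @return `load_run_config` returns the validated `run_config`.
#' @export
load_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("stage=%s %s", stage, msg)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(line)
}

run_stage <- function(name, log_path, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(force(expr), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log_line(log_path, name,
           sprintf("elapsed=%.2fs", proc.time()[["elapsed"]] - t0))
  result
}

#' Run the full pipeline end-to-end
#'
#' Generates (or loads) data, applies Reinhard color normalization,
#' self-trains the teacher, generates pseudo-labels, trains the student
#' jointly with the teacher, evaluates on the validation set and renders
#' Monte Carlo dropout uncertainty maps. All artifacts — the resolved
#' configuration snapshot, checkpoints, pseudo-labels, the training trace,
#' metrics and logs — are written under `out_dir`. In supervised-only mode
#' the self-training, pseudo-labeling, consistency and uncertainty stages
#' are skipped.
#'
#' @param config a (possibly partial) run configuration; see
#'   [default_run_config()].
#' @param out_dir run directory to create.
#' @param overwrite allow writing into an existing run directory.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir, overwrite = FALSE) {
  config <- validate_run_config(config)
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)) > 0) {
    stop(sprintf("run directory '%s' exists; use overwrite = TRUE", out_dir))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("run seed=%d mode=%s\n", config$seed, config$mode),
      file = log_path)
  save_run_config(config, file.path(out_dir, "config.yaml"))
  semi <- config$mode == "semi_supervised"

  split <- run_stage("data", log_path, {
    generate_dataset(synth_config(
      n_images = config$data$n_images,
      n_validation = config$data$n_validation,
      size = config$data$size,
      labeled_fraction = config$data$labeled_fraction,
      color_jitter_sd = config$data$color_jitter_sd,
      seed = derive_seed(config$seed, "data")))
  })

  if (isTRUE(config$normalize$enabled)) {
    split <- run_stage("normalize", log_path, {
      ref_stats <- channel_stats(rgb_to_lab(split$labeled[[1]]$image))
      write_channel_stats(ref_stats,
                          file.path(out_dir, "reference_stats.json"))
      for (part in c("labeled", "unlabeled", "validation")) {
        split[[part]] <- lapply(split[[part]], function(s) {
          s$image <- reinhard_normalize(s$image, ref_stats)
          s
        })
      }
      split
    })
  }

  teacher <- NULL
  pseudo <- NULL
  if (semi) {
    state <- run_stage("self_train", log_path, {
      self_train_teacher(split, self_train_config(
        iterations = config$self_train$iterations,
        epochs = config$self_train$epochs,
        warmup_epochs = config$self_train$warmup_epochs,
        batch_size = config$self_train$batch_size,
        lr = config$self_train$lr,
        tau = config$self_train$tau,
        tol = config$self_train$tol,
        seed = derive_seed(config$seed, "self-train"),
        teacher = teacher_spec(config$teacher$filters,
                               config$teacher$dropout_rate),
        ignore_low_confidence = config$self_train$ignore_low_confidence))
    })
    teacher <- state$teacher
    pseudo <- state$pseudo
    run_stage("pseudo_labels", log_path, {
      hist_df <- data.frame(
        iteration = seq_along(state$history),
        miou = vapply(state$history, `[[`, numeric(1), "miou"),
        f1 = vapply(state$history, `[[`, numeric(1), "f1"),
        accuracy = vapply(state$history, `[[`, numeric(1), "accuracy"))
      utils::write.csv(hist_df, file.path(out_dir, "self_train_history.csv"),
                       row.names = FALSE)
      save_model(teacher, file.path(out_dir, "teacher.rds"))
      if (!is.null(pseudo)) {
        pl_dir <- file.path(out_dir, "pseudo_labels")
        dir.create(pl_dir, showWarnings = FALSE)
        for (id in pseudo$ids) {
          write_mask(pseudo$masks[[id]],
                     file.path(pl_dir, paste0(id, ".png")))
          write_prob_map(pseudo$probs[[id]],
                         file.path(pl_dir, paste0(id, "_confidence.tiff")))
        }
        cov <- pseudo_label_coverage(pseudo)
        utils::write.csv(cov$per_image,
                         file.path(out_dir, "pseudo_label_coverage.csv"),
                         row.names = FALSE)
      }
      NULL
    })
  }

  result <- run_stage("joint_train", log_path, {
    train_joint(split, pseudo, teacher, student = NULL,
                config = joint_train_config(
                  epochs = config$joint$epochs,
                  batch_size = config$joint$batch_size,
                  lr_student = config$joint$lr_student,
                  lr_teacher = config$joint$lr_teacher,
                  alpha = config$joint$alpha,
                  seed = derive_seed(config$seed, "joint"),
                  mode = config$mode,
                  consistency_on_labeled = config$joint$consistency_on_labeled,
                  student = student_spec(config$student$upper_filters,
                                         config$student$lower_filters,
                                         config$student$bottleneck_filters)))
  })

  run_stage("evaluate", log_path, {
    utils::write.csv(result$trace, file.path(out_dir, "trace.csv"),
                     row.names = FALSE)
    save_model(result$student, file.path(out_dir, "student.rds"))
    rep <- evaluate_probmap(
      predict_probs(result$student,
                    lapply(split$validation, `[[`, "image")),
      as_mask_batch(lapply(split$validation, `[[`, "mask")))
    jsonlite::write_json(
      rep[c("precision", "recall", "f1", "accuracy", "miou",
            "tp", "fp", "fn", "tn")],
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    NULL
  })

  if (semi && isTRUE(config$uncertainty$enabled)) {
    run_stage("uncertainty", log_path, {
      maps <- mc_dropout_predict(teacher, split$validation[[1]]$image,
                                 passes = config$uncertainty$passes,
                                 seed = derive_seed(config$seed, "mc"))
      un_dir <- file.path(out_dir, "uncertainty")
      render_uncertainty(maps, un_dir)
      write_prob_map(maps$mean, file.path(un_dir, "mean.tiff"))
      write_prob_map(maps$variance, file.path(un_dir, "variance.tiff"))
      NULL
    })
  }
  invisible(out_dir)
}
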