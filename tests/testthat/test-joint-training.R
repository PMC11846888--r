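small_student_spec <- student_spec(c(4L, 8L), c(4L, 6L, 8L, 8L), 16L)

test_that("supervised-only mode is plain BCE without teacher terms", {
  split <- tiny_split(n = 6, frac = 0.5, seed = 14, n_val = 4)
  cfg <- joint_train_config(epochs = 2L, batch_size = 4L, seed = 3,
                            mode = "supervised_only",
                            student = small_student_spec)
  res <- train_joint(split, config = cfg)
  expect_null(res$teacher)
  expect_null(res$ema)
  expect_false(any(c("student_consistency", "teacher_total", "teacher_bce",
                     "teacher_ema") %in% names(res$trace)))
  expect_identical(nrow(res$trace), 2L)
  expect_true(all(is.finite(res$trace$student_total)))
  expect_equal(res$trace$student_total, res$trace$student_bce)
})

test_that("consistency is zero between models with identical weights", {
  teacher <- tiny_teacher(seed = 21)
  clone <- clone_model(teacher)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(consistency_loss(predict_probs(teacher, x),
                                    predict_probs(clone, x)), 0)
})

test_that("teacher and student updates are isolated from each other", {
  split <- tiny_split(n = 6, frac = 0.5, seed = 15, n_val = 4)
  teacher <- tiny_teacher(seed = 22)
  pl <- generate_pseudo_labels(teacher, split, tau = 0.7)
  snapshot <- function(m) lapply(m$params, function(p) p$value)
  # zero student learning rate: only the teacher may move
  student <- build_student(small_student_spec, seed = 4)
  s0 <- snapshot(student)
  t0 <- snapshot(teacher)
  res <- train_joint(split, pl, teacher, student,
                     joint_train_config(epochs = 1L, batch_size = 4L,
                                        lr_student = 0, seed = 5,
                                        student = small_student_spec))
  expect_identical(snapshot(res$student), s0)
  expect_false(identical(snapshot(res$teacher), t0))
  # zero teacher learning rate: only the student may move
  teacher2 <- tiny_teacher(seed = 22)
  t1 <- snapshot(teacher2)
  res2 <- train_joint(split, pl, teacher2, NULL,
                      joint_train_config(epochs = 1L, batch_size = 4L,
                                         lr_teacher = 0, seed = 5,
                                         student = small_student_spec))
  expect_identical(snapshot(res2$teacher), t1)
  expect_false(identical(snapshot(res2$student),
                         snapshot(build_student(small_student_spec,
                                                seed = 5))))
})

test_that("EMA state covers every sample and stores valid probability maps", {
  split <- tiny_split(n = 6, frac = 0.5, seed = 16, n_val = 4)
  teacher <- tiny_teacher(seed = 23)
  pl <- generate_pseudo_labels(teacher, split, tau = 0.7)
  res <- train_joint(split, pl, teacher, NULL,
                     joint_train_config(epochs = 2L, batch_size = 4L,
                                        alpha = 0.2, seed = 6,
                                        student = small_student_spec))
  ids <- c(vapply(split$labeled, `[[`, character(1), "id"),
           vapply(split$unlabeled, `[[`, character(1), "id"))
  expect_setequal(names(res$ema$maps), ids)
  for (m in res$ema$maps) {
    expect_lt(max(abs(m[, , 1] + m[, , 2] - 1)), 1e-6)
  }
})

test_that("missing pseudo-labels for an unlabeled sample abort training", {
  split <- tiny_split(n = 6, frac = 0.5, seed = 17, n_val = 4)
  teacher <- tiny_teacher(seed = 24)
  pl <- generate_pseudo_labels(teacher, split, tau = 0.7)
  pl$masks[[split$unlabeled[[1]]$id]] <- NULL
  expect_error(train_joint(split, pl, teacher, NULL,
                           joint_train_config(epochs = 1L, batch_size = 4L,
                                              student = small_student_spec)),
               "missing pseudo-label")
})

test_that("the student training loss decreases over a seeded run", {
  split <- tiny_split(n = 12, frac = 0.25, seed = 18, n_val = 4)
  teacher <- tiny_teacher(seed = 25)
  stseg:::train_supervised(teacher, split$labeled, epochs = 5L,
                           batch_size = 4L, seed = 26)
  pl <- generate_pseudo_labels(teacher, split, tau = 0.7)
  res <- train_joint(split, pl, teacher, NULL,
                     joint_train_config(epochs = 5L, batch_size = 4L,
                                        seed = 7,
                                        student = small_student_spec))
  expect_lt(res$trace$student_total[5], res$trace$student_total[1])
  expect_true(all(is.finite(res$trace$student_total)))
  expect_true(all(is.finite(res$trace$teacher_total)))
  expect_equal(res$trace$student_total,
               res$trace$student_bce + res$trace$student_consistency,
               tolerance = 1e-12)
})

test_that("identical seeds and configuration give identical weights", {
  split <- tiny_split(n = 6, frac = 0.5, seed = 19, n_val = 4)
  run_once <- function() {
    teacher <- tiny_teacher(seed = 27)
    pl <- generate_pseudo_labels(teacher, split, tau = 0.7)
    train_joint(split, pl, teacher, NULL,
                joint_train_config(epochs = 2L, batch_size = 4L, seed = 8,
                                   student = small_student_spec))
  }
  r1 <- run_once()
  r2 <- run_once()
  for (nm in names(r1$student$params)) {
    expect_identical(r1$student$params[[nm]]$value,
                     r2$student$params[[nm]]$value)
  }
  for (nm in names(r1$teacher$params)) {
    expect_identical(r1$teacher$params[[nm]]$value,
                     r2$teacher$params[[nm]]$value)
  }
})
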