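test_that("teacher maps 128x128x3 to per-pixel two-class probabilities", {
  teacher <- build_teacher(teacher_spec(), seed = 3)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3))
  p <- predict_probs(teacher, x)
  expect_identical(dim(p), c(128L, 128L, 2L))
  expect_lt(max(abs(p[, , 1] + p[, , 2] - 1)), 1e-5)
  expect_true(all(p >= 0 & p <= 1))
  # encoder filter schedule read back from the built weights
  filters <- vapply(1:5, function(i)
    dim(teacher$params[[sprintf("enc%d_W", i)]]$value)[4], integer(1))
  expect_identical(filters, c(32L, 64L, 128L, 256L, 512L))
  # kernel sizes: 3x3 encoder, 2x2 then 3x3 decoder
  expect_identical(dim(teacher$params$enc1_W$value)[1:2], c(3L, 3L))
  expect_identical(dim(teacher$params$dec1_up_W$value)[1:2], c(2L, 2L))
  expect_identical(dim(teacher$params$dec1_conv_W$value)[1:2], c(3L, 3L))
})

test_that("inference without dropout is deterministic", {
  teacher <- tiny_teacher(rate = 0.3)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_probs(teacher, x)
  p2 <- predict_probs(teacher, x)
  expect_lt(max(abs(p1 - p2)), 1e-7)
})

test_that("input sizes are validated", {
  expect_error(predict_probs(tiny_teacher(), array(0.5, c(48, 48, 3))),
               "divisible by 32")
  expect_error(predict_probs(tiny_student(), array(0.5, c(24, 24, 3))),
               "divisible by 16")
})

test_that("student dual-encoder shapes and attention maps are as designed", {
  student <- build_student(student_spec(), seed = 4)
  x <- array(runif(128 * 128 * 3), c(128, 128, 3, 1))
  fw <- stseg:::student_forward(student, x, collect_attention = TRUE)
  expect_identical(fw$upper_dim, c(8L, 8L, 256L, 1L))
  expect_identical(fw$lower_dim, c(8L, 8L, 512L, 1L))
  # concatenated bottleneck input: 256 + 512 channels into 1024 filters
  expect_identical(dim(student$params$bottleneck_W$value), c(3L, 3L, 768L, 1024L))
  p <- fw$probs$value
  expect_identical(dim(p), c(128L, 128L, 2L, 1L))
  expect_lt(max(abs(p[, , 1, ] + p[, , 2, ] - 1)), 1e-5)
  # one single-channel attention map per lower-encoder block, values in (0,1)
  expect_identical(sort(names(fw$attention)),
                   c("att1", "att2", "att3", "att4"))
  for (s in fw$attention) {
    expect_identical(dim(s)[3], 1L)
    expect_true(all(s > 0 & s < 1))
  }
})

test_that("spatial attention follows the two-convolution sigmoid gate", {
  f <- array(seq_len(2 * 2 * 3) / 6, c(2, 2, 3))
  # zero weights: sigmoid(0) = 0.5 exactly, gate halves the features
  res <- spatial_attention(f, weights = list(w1 = rep(0, 3), b1 = 0,
                                             w2 = 0, b2 = 0))
  expect_true(all(res$s == 0.5))
  expect_equal(res$f_att, 0.5 * f, tolerance = 1e-12)
  # zero features stay zero regardless of weights
  res0 <- spatial_attention(array(0, c(2, 2, 3)),
                            weights = list(w1 = rnorm(3), b1 = 1,
                                           w2 = 2, b2 = -1))
  expect_true(all(res0$f_att == 0))
  # hand-set 1x1 weights against an elementwise oracle
  w1 <- c(0.2, -0.4, 0.6)
  res2 <- spatial_attention(f, weights = list(w1 = w1, b1 = 0.1,
                                              w2 = 1.5, b2 = -0.2))
  for (i in 1:2) for (j in 1:2) {
    favg <- sum(f[i, j, ] * w1) + 0.1
    s <- 1 / (1 + exp(-(favg * 1.5 - 0.2)))
    expect_equal(res2$s[i, j, 1], s, tolerance = 1e-6)
    expect_equal(res2$f_att[i, j, ], s * f[i, j, ], tolerance = 1e-6)
  }
  # default weights are uniform channel averaging with a zero second layer
  res3 <- spatial_attention(f)
  expect_true(all(res3$s == 0.5))
})

test_that("attention_merge concatenates channels in gate-first order", {
  a <- array(1, c(8, 8, 64))
  b <- array(2, c(8, 8, 64))
  m <- attention_merge(a, b)
  expect_identical(dim(m), c(8L, 8L, 128L))
  expect_true(all(m[, , 1:64] == 1) && all(m[, , 65:128] == 2))
  m2 <- attention_merge(b, a)
  expect_true(all(m2[, , 1:64] == 2) && all(m2[, , 65:128] == 1))
  empty <- array(0, c(8, 8, 0))
  expect_equal(attention_merge(empty, a), a)
  expect_error(attention_merge(array(0, c(4, 4, 2)), a),
               "spatial dimensions")
})

test_that("parameter counts are exact and size-invariant", {
  # closed form for one convolution: kh*kw*cin*cout + cout
  expect_identical(length(stseg:::he_init(3, 3, 3, 32)) + 32L, 896L)
  teacher <- tiny_teacher()
  f <- c(4L, 6L, 8L, 8L, 8L)
  fd <- rev(f)
  expected <- 0L
  cin <- 3L
  for (i in 1:5) {
    expected <- expected + 9L * cin * f[i] + f[i] + 2L * f[i]
    cin <- f[i]
  }
  cin <- f[5]
  for (j in 1:5) {
    expected <- expected + 4L * cin * fd[j] + fd[j] + 2L * fd[j] +
      9L * 2L * fd[j] * fd[j] + fd[j] + 2L * fd[j]
    cin <- fd[j]
  }
  expected <- expected + f[1] * 2L + 2L
  expect_identical(as.integer(count_parameters(teacher)), expected)

  # the default teacher is the lightweight model
  expect_lt(count_parameters(build_teacher(teacher_spec())),
            count_parameters(build_student(student_spec())))

  # convolutional weight sharing: the count never depends on input size
  n_before <- count_parameters(teacher)
  invisible(predict_probs(teacher, array(0.5, c(64, 64, 3))))
  invisible(predict_probs(teacher, array(0.5, c(32, 32, 3))))
  expect_identical(count_parameters(teacher), n_before)
})

test_that("one optimization step decreases the training loss", {
  set.seed(20)
  split <- tiny_split(n = 8, frac = 1)
  x <- stseg:::as_image_batch(lapply(split$labeled[1:4], `[[`, "image"))
  y <- stseg:::as_mask_batch(lapply(split$labeled[1:4], `[[`, "mask"))
  for (build in list(function() tiny_teacher(rate = 0),
                     function() tiny_student())) {
    model <- build()
    loss_eval <- function() {
      fw <- stseg:::model_forward(model, x, training = FALSE)
      stseg:::op_bce(stseg:::ad_tape(), fw$probs, y)$value
    }
    before <- loss_eval()
    tape <- stseg:::ad_tape()
    fw <- stseg:::model_forward(model, x, tape, training = FALSE)
    loss <- stseg:::op_bce(tape, fw$probs, y)
    stseg:::ad_zero_grads(model$params)
    stseg:::ad_backward(tape, loss)
    opt <- stseg:::adam_new(model$params, lr = 1e-3)
    stseg:::adam_step(opt, model$params)
    expect_lt(loss_eval(), before)
  }
})

test_that("the model summary lists layers and the parameter total", {
  teacher <- tiny_teacher()
  out <- capture.output(print(teacher))
  expect_true(any(grepl("enc1", out)))
  expect_true(any(grepl("3x3", out)))
  expect_true(any(grepl(sprintf("total trainable parameters: %d",
                                as.integer(count_parameters(teacher))),
                        out)))
})

test_that("checkpoints restore identical models", {
  teacher <- tiny_teacher(seed = 9)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  p1 <- predict_probs(teacher, x)
  path <- tempfile(fileext = ".rds")
  save_model(teacher, path)
  restored <- load_model(path)
  expect_identical(predict_probs(restored, x), p1)
  copy <- clone_model(teacher)
  copy$params$head_b$value <- copy$params$head_b$value + 1
  expect_identical(predict_probs(teacher, x), p1)
})
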