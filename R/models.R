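#' Teacher network specification
#'
#' The teacher is a lightweight U-Net-style encoder-decoder. Five encoder
#' blocks (3x3 convolution, batch normalization, ReLU, 2x2 max-pool) apply
#' the filter schedule in `filters`; five mirrored decoder blocks (nearest
#' upsample x2, 2x2 convolution + batch norm, skip concatenation, 3x3
#' convolution + ReLU + batch norm) restore full resolution, followed by a
#' 1x1 convolution and a per-pixel softmax over the two classes. Dropout
#' after every encoder and decoder block supports Monte Carlo uncertainty
#' estimation at inference.
#'
#' @param filters integer vector of 5 encoder filter counts.
#' @param dropout_rate dropout probability in `[0, 1)` applied after each
#'   block (active during training and during Monte Carlo inference).
#' @param num_classes number of output classes (2: background, foreground).
#' @return an object of class `teacher_spec`.
#' @export
teacher_spec <- function(filters = c(32L, 64L, 128L, 256L, 512L),
                         dropout_rate = 0.3, num_classes = 2L) {
  stopifnot(length(filters) == 5L, all(filters >= 1))
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  structure(list(filters = as.integer(filters),
                 dropout_rate = dropout_rate,
                 num_classes = as.integer(num_classes)),
            class = "teacher_spec")
}

#' Student network specification
#'
#' The student has two parallel encoders. The upper (context) encoder uses
#' two 5x5 convolution blocks with 4x4 max-pooling; the lower (detail)
#' encoder uses four double-3x3-convolution blocks with 2x2 max-pooling.
#' Both reach 1/16 of the input resolution and are concatenated before a
#' 3x3 bottleneck convolution. Four decoder blocks (upsample x2, two 3x3
#' convolutions) mirror the lower encoder; each decoder block receives the
#' matching lower-encoder feature map through a spatial attention gate.
#'
#' @param upper_filters two filter counts for the upper encoder.
#' @param lower_filters four filter counts for the lower encoder.
#' @param bottleneck_filters filters of the bottleneck convolution.
#' @param num_classes number of output classes.
#' @return an object of class `student_spec`.
#' @export
student_spec <- function(upper_filters = c(64L, 256L),
                         lower_filters = c(64L, 128L, 256L, 512L),
                         bottleneck_filters = 1024L,
                         num_classes = 2L) {
  stopifnot(length(upper_filters) == 2L, length(lower_filters) == 4L)
  structure(list(upper_filters = as.integer(upper_filters),
                 lower_filters = as.integer(lower_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 num_classes = as.integer(num_classes)),
            class = "student_spec")
}

# He-uniform initialization for a (kh, kw, cin, cout) kernel
he_init <- function(kh, kw, cin, cout) {
  lim <- sqrt(6 / (kh * kw * cin))
  array(stats::runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
}

new_model <- function(type, spec) {
  list(type = type, spec = spec,
       params = list(), bn = list())
}

add_conv <- function(model, name, kh, kw, cin, cout) {
  model$params[[paste0(name, "_W")]] <- ad_leaf(he_init(kh, kw, cin, cout))
  model$params[[paste0(name, "_b")]] <- ad_leaf(rep(0, cout))
  model
}

add_bn <- function(model, name, c) {
  model$params[[paste0(name, "_gamma")]] <- ad_leaf(rep(1, c))
  model$params[[paste0(name, "_beta")]] <- ad_leaf(rep(0, c))
  e <- new.env(parent = emptyenv())
  e$running_mean <- rep(0, c)
  e$running_var <- rep(1, c)
  model$bn[[name]] <- e
  model
}

# attention gate: a 1x1 channel-averaging convolution (initialized to the
# uniform average) followed by a 1x1 convolution with a single filter and
# sigmoid activation
add_attention <- function(model, name, cin) {
  model$params[[paste0(name, "_W1")]] <-
    ad_leaf(array(1 / cin, c(1, 1, cin, 1)))
  model$params[[paste0(name, "_b1")]] <- ad_leaf(0)
  model$params[[paste0(name, "_W2")]] <- ad_leaf(he_init(1, 1, 1, 1))
  model$params[[paste0(name, "_b2")]] <- ad_leaf(0)
  model
}

#' Build the teacher segmentation network
#'
#' @param spec a [teacher_spec()].
#' @param seed integer seed for the weight initialization.
#' @return a model object usable with [predict_probs()], the training
#'   routines and [mc_dropout_predict()].
#' @export
build_teacher <- function(spec = teacher_spec(), seed = 1L) {
  stopifnot(inherits(spec, "teacher_spec"))
  set.seed(derive_seed(seed, "teacher-init"))
  f <- spec$filters
  m <- new_model("teacher", spec)
  cin <- 3L
  for (i in 1:5) {
    m <- add_conv(m, paste0("enc", i), 3, 3, cin, f[i])
    m <- add_bn(m, paste0("enc", i, "_bn"), f[i])
    cin <- f[i]
  }
  fd <- rev(f)
  cin <- f[5]
  for (j in 1:5) {
    m <- add_conv(m, paste0("dec", j, "_up"), 2, 2, cin, fd[j])
    m <- add_bn(m, paste0("dec", j, "_bn1"), fd[j])
    m <- add_conv(m, paste0("dec", j, "_conv"), 3, 3, 2L * fd[j], fd[j])
    m <- add_bn(m, paste0("dec", j, "_bn2"), fd[j])
    cin <- fd[j]
  }
  m <- add_conv(m, "head", 1, 1, f[1], spec$num_classes)
  class(m) <- c("teacher_model", "stseg_model")
  m
}

teacher_forward <- function(model, x, tape = NULL, training = FALSE,
                            dropout_active = training) {
  if (is.null(tape)) tape <- ad_tape()
  x <- as_image_batch(x)
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("teacher input height and width must be divisible by 32")
  }
  p <- model$params
  rate <- model$spec$dropout_rate
  h <- ad_leaf(x)
  skips <- vector("list", 5)
  for (i in 1:5) {
    nm <- paste0("enc", i)
    h <- op_conv2d(tape, h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    h <- op_batchnorm(tape, h, p[[paste0(nm, "_bn_gamma")]],
                      p[[paste0(nm, "_bn_beta")]],
                      model$bn[[paste0(nm, "_bn")]], training)
    h <- op_relu(tape, h)
    skips[[i]] <- h
    h <- op_maxpool(tape, h, 2)
    h <- op_dropout(tape, h, rate, dropout_active)
  }
  for (j in 1:5) {
    nm <- paste0("dec", j)
    h <- op_upsample(tape, h, 2)
    h <- op_conv2d(tape, h, p[[paste0(nm, "_up_W")]], p[[paste0(nm, "_up_b")]])
    h <- op_batchnorm(tape, h, p[[paste0(nm, "_bn1_gamma")]],
                      p[[paste0(nm, "_bn1_beta")]],
                      model$bn[[paste0(nm, "_bn1")]], training)
    h <- op_concat_ch(tape, skips[[6 - j]], h)
    h <- op_conv2d(tape, h, p[[paste0(nm, "_conv_W")]],
                   p[[paste0(nm, "_conv_b")]])
    h <- op_relu(tape, h)
    h <- op_batchnorm(tape, h, p[[paste0(nm, "_bn2_gamma")]],
                      p[[paste0(nm, "_bn2_beta")]],
                      model$bn[[paste0(nm, "_bn2")]], training)
    h <- op_dropout(tape, h, rate, dropout_active)
  }
  h <- op_conv2d(tape, h, p[["head_W"]], p[["head_b"]])
  list(probs = op_softmax_ch(tape, h), tape = tape)
}

#' Build the dual-encoder student segmentation network
#'
#' @param spec a [student_spec()].
#' @param seed integer seed for the weight initialization.
#' @return a model object usable with [predict_probs()] and [train_joint()].
#' @export
build_student <- function(spec = student_spec(), seed = 1L) {
  stopifnot(inherits(spec, "student_spec"))
  set.seed(derive_seed(seed, "student-init"))
  u <- spec$upper_filters
  l <- spec$lower_filters
  m <- new_model("student", spec)
  cin <- 3L
  for (i in 1:2) {
    m <- add_conv(m, paste0("up", i), 5, 5, cin, u[i])
    m <- add_bn(m, paste0("up", i, "_bn"), u[i])
    cin <- u[i]
  }
  cin <- 3L
  for (i in 1:4) {
    m <- add_conv(m, paste0("low", i, "a"), 3, 3, cin, l[i])
    m <- add_bn(m, paste0("low", i, "a_bn"), l[i])
    m <- add_conv(m, paste0("low", i, "b"), 3, 3, l[i], l[i])
    m <- add_bn(m, paste0("low", i, "b_bn"), l[i])
    m <- add_attention(m, paste0("att", i), l[i])
    cin <- l[i]
  }
  m <- add_conv(m, "bottleneck", 3, 3, u[2] + l[4], spec$bottleneck_filters)
  m <- add_bn(m, "bottleneck_bn", spec$bottleneck_filters)
  fd <- rev(l)
  cin <- spec$bottleneck_filters
  for (j in 1:4) {
    skip_c <- l[5 - j]
    m <- add_conv(m, paste0("dec", j, "a"), 3, 3, cin + skip_c, fd[j])
    m <- add_bn(m, paste0("dec", j, "a_bn"), fd[j])
    m <- add_conv(m, paste0("dec", j, "b"), 3, 3, fd[j], fd[j])
    m <- add_bn(m, paste0("dec", j, "b_bn"), fd[j])
    cin <- fd[j]
  }
  m <- add_conv(m, "head", 1, 1, fd[4], spec$num_classes)
  class(m) <- c("student_model", "stseg_model")
  m
}

attention_forward <- function(tape, f, p, name) {
  favg <- op_conv2d(tape, f, p[[paste0(name, "_W1")]], p[[paste0(name, "_b1")]])
  s <- op_sigmoid(tape, op_conv2d(tape, favg, p[[paste0(name, "_W2")]],
                                  p[[paste0(name, "_b2")]]))
  list(s = s, fatt = op_gate_mul(tape, s, f))
}

student_forward <- function(model, x, tape = NULL, training = FALSE,
                            collect_attention = FALSE) {
  if (is.null(tape)) tape <- ad_tape()
  x <- as_image_batch(x)
  d <- dim(x)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    stop("student input height and width must be divisible by 16")
  }
  p <- model$params
  xin <- ad_leaf(x)

  h <- xin
  for (i in 1:2) {
    nm <- paste0("up", i)
    h <- op_conv2d(tape, h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
    h <- op_batchnorm(tape, h, p[[paste0(nm, "_bn_gamma")]],
                      p[[paste0(nm, "_bn_beta")]],
                      model$bn[[paste0(nm, "_bn")]], training)
    h <- op_relu(tape, h)
    h <- op_maxpool(tape, h, 4)
  }
  upper_out <- h

  h <- xin
  skips <- vector("list", 4)
  for (i in 1:4) {
    for (half in c("a", "b")) {
      nm <- paste0("low", i, half)
      h <- op_conv2d(tape, h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
      h <- op_batchnorm(tape, h, p[[paste0(nm, "_bn_gamma")]],
                        p[[paste0(nm, "_bn_beta")]],
                        model$bn[[paste0(nm, "_bn")]], training)
      h <- op_relu(tape, h)
    }
    skips[[i]] <- h
    h <- op_maxpool(tape, h, 2)
  }
  lower_out <- h

  h <- op_concat_ch(tape, upper_out, lower_out)
  h <- op_conv2d(tape, h, p[["bottleneck_W"]], p[["bottleneck_b"]])
  h <- op_batchnorm(tape, h, p[["bottleneck_bn_gamma"]],
                    p[["bottleneck_bn_beta"]], model$bn[["bottleneck_bn"]],
                    training)
  h <- op_relu(tape, h)

  attention <- if (collect_attention) list() else NULL
  for (j in 1:4) {
    i <- 5L - j
    h <- op_upsample(tape, h, 2)
    att <- attention_forward(tape, skips[[i]], p, paste0("att", i))
    if (collect_attention) attention[[paste0("att", i)]] <- att$s$value
    h <- op_concat_ch(tape, att$fatt, h)
    for (half in c("a", "b")) {
      nm <- paste0("dec", j, half)
      h <- op_conv2d(tape, h, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]])
      h <- op_batchnorm(tape, h, p[[paste0(nm, "_bn_gamma")]],
                        p[[paste0(nm, "_bn_beta")]],
                        model$bn[[paste0(nm, "_bn")]], training)
      h <- op_relu(tape, h)
    }
  }
  h <- op_conv2d(tape, h, p[["head_W"]], p[["head_b"]])
  out <- list(probs = op_softmax_ch(tape, h), tape = tape,
              upper_dim = dim(upper_out$value), lower_dim = dim(lower_out$value))
  if (collect_attention) out$attention <- attention
  out
}

model_forward <- function(model, x, tape = NULL, training = FALSE,
                          dropout_active = FALSE) {
  if (model$type == "teacher") {
    teacher_forward(model, x, tape, training, dropout_active)
  } else {
    if (dropout_active) stop("the student model has no dropout layers")
    student_forward(model, x, tape, training)
  }
}

#' Predict class probability maps
#'
#' Runs the model in inference mode (batch-norm running statistics, dropout
#' disabled) and returns per-pixel softmax probabilities. Channel 1 is the
#' background class, channel 2 the foreground tissue class.
#'
#' @param model a built teacher or student model.
#' @param images a single `H x W x 3` image, a list of such images, or an
#'   `H x W x 3 x N` array, with values in `[0, 1]`.
#' @param batch_size maximum number of images per forward pass.
#' @return an `H x W x 2` array for a single image, else `H x W x 2 x N`.
#' @export
predict_probs <- function(model, images, batch_size = 8L) {
  single <- !is.list(images) && length(dim(images)) == 3L
  x <- as_image_batch(images)
  n <- dim(x)[4]
  out <- array(0, c(dim(x)[1], dim(x)[2], model$spec$num_classes, n))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    fw <- model_forward(model, x[, , , idx, drop = FALSE], training = FALSE)
    out[, , , idx] <- fw$probs$value
  }
  drop_batch(out, single)
}

#' Spatial attention gate
#'
#' Computes the single-channel attention map `S` and the gated feature map
#' from a feature map `F`: a 1x1 convolution averages the channels, a second
#' 1x1 convolution with one filter and a sigmoid yields `S` in (0, 1), and
#' the gate is applied by broadcast multiplication over the channels.
#'
#' @param f an `H x W x C` feature map.
#' @param weights list with `w1` (length-`C` vector or `1x1xCx1` array),
#'   `b1`, `w2`, `b2` (scalars). Defaults to uniform channel averaging with
#'   a zero-initialized second convolution, giving `S = 0.5` everywhere.
#' @return list with `s` (`H x W x 1` attention map, values in (0, 1)) and
#'   `f_att` (`H x W x C` gated features).
#' @export
spatial_attention <- function(f, weights = NULL) {
  d <- dim(f)
  stopifnot(length(d) == 3L, d[3] >= 1L)
  if (is.null(weights)) {
    weights <- list(w1 = rep(1 / d[3], d[3]), b1 = 0, w2 = 0, b2 = 0)
  }
  w1 <- array(weights$w1, c(1, 1, d[3], 1))
  w2 <- array(weights$w2, c(1, 1, 1, 1))
  x <- array(f, c(d, 1L))
  favg <- conv2d_forward_cpp(x, w1, weights$b1)
  s <- 1 / (1 + exp(-conv2d_forward_cpp(favg, w2, weights$b2)))
  srep <- x
  srep[] <- s[, , rep(1L, d[3]), , drop = FALSE]
  list(s = array(s, c(d[1], d[2], 1L)), f_att = array(x * srep, d))
}

#' Concatenate attention-gated features with decoder features
#'
#' Channel-wise concatenation of the gated skip features (first) with the
#' decoder feature map (second); both must share spatial dimensions.
#'
#' @param f_att an `H x W x C1` feature map.
#' @param d an `H x W x C2` feature map.
#' @return an `H x W x (C1 + C2)` feature map.
#' @export
attention_merge <- function(f_att, d) {
  da <- dim(f_att)
  db <- dim(d)
  if (!all(da[1:2] == db[1:2])) {
    stop("feature maps must share spatial dimensions")
  }
  c1 <- if (length(da) == 3L) da[3] else 1L
  c2 <- if (length(db) == 3L) db[3] else 1L
  out <- array(0, c(da[1], da[2], c1 + c2))
  if (c1 > 0) out[, , seq_len(c1)] <- f_att
  if (c2 > 0) out[, , c1 + seq_len(c2)] <- d
  out
}

#' Count trainable parameters of a model
#'
#' @param model a built teacher or student model.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' @export
print.stseg_model <- function(x, ...) {
  cat(sprintf("stseg %s model\n", x$type))
  cat(sprintf("%-16s %-7s %6s %6s %10s\n",
              "layer", "kernel", "in", "out", "params"))
  for (nm in grep("_W[12]?$", names(x$params), value = TRUE)) {
    w <- x$params[[nm]]$value
    d <- dim(w)
    bias_nm <- sub("_W([12]?)$", "_b\\1", nm)
    n <- length(w) + length(x$params[[bias_nm]]$value)
    cat(sprintf("%-16s %-7s %6d %6d %10d\n", sub("_W[12]?$", "", nm),
                sprintf("%dx%d", d[1], d[2]), d[3], d[4], n))
  }
  cat(sprintf("total trainable parameters: %d\n",
              as.integer(count_parameters(x))))
  invisible(x)
}

#' Save / load model checkpoints
#'
#' The specification, weights, and batch-norm running statistics are stored
#' together so a checkpoint rebuilds an identical model.
#'
#' @param model a built model.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored model.
#' @export
save_model <- function(model, path) {
  ck <- list(type = model$type, spec = model$spec,
             params = lapply(model$params, function(p) p$value),
             bn = lapply(model$bn, function(e)
               list(running_mean = e$running_mean,
                    running_var = e$running_var)))
  saveRDS(ck, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  model <- if (ck$type == "teacher") build_teacher(ck$spec) else
    build_student(ck$spec)
  for (nm in names(ck$params)) model$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$bn)) {
    model$bn[[nm]]$running_mean <- ck$bn[[nm]]$running_mean
    model$bn[[nm]]$running_var <- ck$bn[[nm]]$running_var
  }
  model
}

#' Copy a model (detached weights)
#'
#' @param model a built model.
#' @return a deep copy whose parameters are independent of the original.
#' @export
clone_model <- function(model) {
  copy <- if (model$type == "teacher") build_teacher(model$spec) else
    build_student(model$spec)
  for (nm in names(model$params)) copy$params[[nm]]$value <- model$params[[nm]]$value
  for (nm in names(model$bn)) {
    copy$bn[[nm]]$running_mean <- model$bn[[nm]]$running_mean
    copy$bn[[nm]]$running_var <- model$bn[[nm]]$running_var
  }
  copy
}
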