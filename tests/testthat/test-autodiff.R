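# Finite-difference gradient checks of every differentiable operation and
# of the assembled networks.

ad_tape <- stseg:::ad_tape
ad_leaf <- stseg:::ad_leaf
ad_node <- stseg:::ad_node
ad_backward <- stseg:::ad_backward

# reduce an op's output to a scalar with a fixed random projection so that
# every output element gets a gradient signal
project <- function(tape, node, co) {
  ad_node(tape, sum(node$value * co), list(node), function(g) list(g * co))
}

grad_check <- function(fwd, x, tol = 1e-6) {
  tape <- ad_tape()
  leaf <- ad_leaf(x)
  loss <- fwd(tape, leaf)
  ad_backward(tape, loss)
  ng <- num_grad(function(z) fwd(ad_tape(), ad_leaf(z))$value, x)
  expect_lt(max(abs(ng - leaf$grad)), tol)
}

test_that("convolution gradients match finite differences", {
  set.seed(42)
  h <- 6L; w <- 5L; cin <- 3L; cout <- 4L; n <- 2L
  x <- array(rnorm(h * w * cin * n), c(h, w, cin, n))
  co <- array(rnorm(h * w * cout * n), c(h, w, cout, n))
  for (k in c(1L, 2L, 3L, 5L)) {
    wgt <- ad_leaf(array(rnorm(k * k * cin * cout) * 0.3, c(k, k, cin, cout)))
    b <- ad_leaf(rnorm(cout))
    grad_check(function(tp, xl)
      project(tp, stseg:::op_conv2d(tp, xl, wgt, b), co), x)
    # weight and bias gradients (clear accumulation from the checks above)
    wgt$grad <- NULL
    b$grad <- NULL
    tape <- ad_tape()
    out <- stseg:::op_conv2d(tape, ad_leaf(x), wgt, b)
    ad_backward(tape, project(tape, out, co))
    ngw <- num_grad(function(z) sum(stseg:::conv2d_forward_cpp(
      x, structure(z, dim = dim(wgt$value)), b$value) * co), wgt$value)
    expect_lt(max(abs(ngw - wgt$grad)), 1e-6)
    ngb <- num_grad(function(z) sum(stseg:::conv2d_forward_cpp(
      x, wgt$value, z) * co), b$value)
    expect_lt(max(abs(ngb - b$grad)), 1e-6)
  }
})

test_that("pooling, upsampling, gating and concatenation gradients match", {
  set.seed(7)
  h <- 6L; w <- 6L; c <- 3L; n <- 2L
  x <- array(rnorm(h * w * c * n), c(h, w, c, n))
  co_pool <- array(rnorm(h * w * c * n / 4), c(h / 2, w / 2, c, n))
  grad_check(function(tp, xl)
    project(tp, stseg:::op_maxpool(tp, xl, 2L), co_pool), x)
  co_up <- array(rnorm(4 * h * w * c * n), c(2 * h, 2 * w, c, n))
  grad_check(function(tp, xl)
    project(tp, stseg:::op_upsample(tp, xl, 2L), co_up), x)
  co_x <- array(rnorm(h * w * c * n), c(h, w, c, n))
  s <- array(runif(h * w * n), c(h, w, 1L, n))
  grad_check(function(tp, xl)
    project(tp, stseg:::op_gate_mul(tp, ad_leaf(s), xl), co_x), x)
  grad_check(function(tp, sl)
    project(tp, stseg:::op_gate_mul(tp, sl, ad_leaf(x)), co_x), s)
  other <- array(rnorm(h * w * c * n), c(h, w, c, n))
  co_cat <- array(rnorm(h * w * 2 * c * n), c(h, w, 2L * c, n))
  grad_check(function(tp, xl)
    project(tp, stseg:::op_concat_ch(tp, xl, ad_leaf(other)), co_cat), x)
})

test_that("batch normalization gradients match in both modes", {
  set.seed(8)
  h <- 5L; w <- 4L; c <- 3L; n <- 3L
  x <- array(rnorm(h * w * c * n), c(h, w, c, n))
  co <- array(rnorm(h * w * c * n), c(h, w, c, n))
  gamma <- ad_leaf(runif(c, 0.5, 1.5))
  beta <- ad_leaf(rnorm(c))
  fresh_bn <- function() {
    e <- new.env()
    e$running_mean <- rnorm(c) * 0.1
    e$running_var <- runif(c, 0.5, 2)
    e
  }
  bn_eval <- fresh_bn()
  grad_check(function(tp, xl)
    project(tp, stseg:::op_batchnorm(tp, xl, gamma, beta, fresh_bn(), TRUE),
            co), x, tol = 1e-5)
  grad_check(function(tp, xl)
    project(tp, stseg:::op_batchnorm(tp, xl, gamma, beta, bn_eval, FALSE),
            co), x)
})

test_that("softmax-based loss gradients match finite differences", {
  set.seed(9)
  h <- 4L; w <- 4L; n <- 2L
  x <- array(rnorm(h * w * 2 * n), c(h, w, 2L, n))
  y <- array(rbinom(h * w * n, 1, 0.5), c(h, w, n))
  grad_check(function(tp, xl)
    stseg:::op_bce(tp, stseg:::op_softmax_ch(tp, xl), y), x, tol = 1e-5)
  wts <- array(rbinom(h * w * n, 1, 0.6), c(h, w, n))
  grad_check(function(tp, xl)
    stseg:::op_bce(tp, stseg:::op_softmax_ch(tp, xl), y,
                   weights = as.numeric(wts)), x, tol = 1e-5)
  tgt <- rand_probmap(h, w, n)
  grad_check(function(tp, xl)
    stseg:::op_pred_sqdist(tp, stseg:::op_softmax_ch(tp, xl), tgt), x,
    tol = 1e-5)
})

test_that("end-to-end network gradients match finite differences", {
  set.seed(10)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  y <- matrix(rbinom(32 * 32, 1, 0.4), 32, 32)
  check_model <- function(model, forward, n_probe = 4L) {
    loss_at <- function() {
      fw <- forward(ad_tape())
      stseg:::op_bce(ad_tape(), fw$probs, y)$value
    }
    tape <- ad_tape()
    fw <- forward(tape)
    loss <- stseg:::op_bce(tape, fw$probs, y)
    stseg:::ad_zero_grads(model$params)
    ad_backward(tape, loss)
    set.seed(11)
    for (probe in seq_len(n_probe)) {
      nm <- sample(names(model$params), 1L)
      i <- sample(length(model$params[[nm]]$value), 1L)
      orig <- model$params[[nm]]$value[i]
      h <- 1e-4
      model$params[[nm]]$value[i] <- orig + h
      up <- loss_at()
      model$params[[nm]]$value[i] <- orig - h
      dn <- loss_at()
      model$params[[nm]]$value[i] <- orig
      g_analytic <- if (is.null(model$params[[nm]]$grad)) 0 else
        model$params[[nm]]$grad[i]
      expect_lt(abs((up - dn) / (2 * h) - g_analytic), 1e-4)
    }
  }
  teacher <- tiny_teacher(rate = 0)
  check_model(teacher, function(tp)
    stseg:::teacher_forward(teacher, x, tp, training = FALSE))
  student <- tiny_student()
  check_model(student, function(tp)
    stseg:::student_forward(student, x, tp, training = FALSE))
})
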