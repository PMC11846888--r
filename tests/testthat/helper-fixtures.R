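# Shared fixtures and independent oracles for the test suite.

tiny_teacher <- function(rate = 0.3, seed = 1L) {
  build_teacher(teacher_spec(c(4L, 6L, 8L, 8L, 8L), dropout_rate = rate),
                seed = seed)
}

tiny_student <- function(seed = 1L) {
  build_student(student_spec(c(4L, 8L), c(4L, 6L, 8L, 8L), 16L), seed = seed)
}

tiny_split <- function(n = 12L, size = 32L, frac = 0.5, seed = 1L,
                       n_val = 6L) {
  generate_dataset(synth_config(n_images = n, n_validation = n_val,
                                size = size, labeled_fraction = frac,
                                seed = seed))
}

val_images <- function(split) lapply(split$validation, `[[`, "image")
val_masks <- function(split) {
  stseg:::as_mask_batch(lapply(split$validation, `[[`, "mask"))
}

# independent sRGB -> CIELAB reference (D65, standard companding)
srgb_to_lab_ref <- function(rgb) {
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  xyz <- c(
    0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3],
    0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3],
    0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3])
  t <- xyz / c(0.95047, 1, 1.08883)
  f <- ifelse(t > (6 / 29)^3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  c(116 * f[2] - 16, 500 * (f[1] - f[2]), 200 * (f[2] - f[3]))
}

# brute-force per-pixel confusion counts
confusion_oracle <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

rand_probmap <- function(h, w, n = 1L) {
  fg <- array(stats::runif(h * w * n), c(h, w, n))
  p <- array(0, c(h, w, 2L, n))
  p[, , 1, ] <- 1 - fg
  p[, , 2, ] <- fg
  p
}

# central finite differences of f at x
num_grad <- function(f, x, h = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x
    xp[i] <- xp[i] + h
    xm <- x
    xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
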