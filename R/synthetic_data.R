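# Synthetic histology-like image generator.
#
# Real stained tissue sections show darker, roughly blob-shaped tissue
# regions on a lighter stained background, with noticeable slide-to-slide
# color shifts. The generator emulates exactly those properties — a tinted
# textured background, unions of random ellipses as foreground with an
# exact rasterized mask, and per-image global color jitter — so that every
# stage of the pipeline (color normalization, self-training, joint
# training, evaluation) can run end-to-end without external data.

#' Synthetic dataset configuration
#'
#' @param n_images number of training images (labeled + unlabeled).
#' @param n_validation number of validation images.
#' @param size image height and width in pixels.
#' @param labeled_fraction fraction of training images carrying masks.
#' @param n_blobs_range inclusive range of foreground blobs per image.
#' @param radius_range inclusive range of ellipse semi-axes in pixels.
#' @param fg_color,bg_color base RGB colors of the two "stain palettes";
#'   the defaults loosely evoke hematoxylin (purple tissue) on an eosin
#'   (pink) background but carry no biological claim.
#' @param texture_sd standard deviation of the per-pixel Gaussian texture.
#' @param color_jitter_sd standard deviation of the per-image global color
#'   shift (per channel), emulating slide-to-slide stain variation.
#' @param seed RNG seed; the dataset is a deterministic function of the
#'   configuration.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_images = 340L, n_validation = 32L,
                         size = c(128L, 128L), labeled_fraction = 0.2,
                         n_blobs_range = c(1L, 4L), radius_range = c(8, 28),
                         fg_color = c(0.42, 0.28, 0.58),
                         bg_color = c(0.93, 0.80, 0.87),
                         texture_sd = 0.035, color_jitter_sd = 0.06,
                         seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    stop("labeled_fraction must be in (0, 1]")
  }
  if (max(radius_range) >= min(size)) {
    stop("blob radius must be smaller than the image size")
  }
  structure(list(n_images = as.integer(n_images),
                 n_validation = as.integer(n_validation),
                 size = as.integer(size),
                 labeled_fraction = labeled_fraction,
                 n_blobs_range = as.integer(n_blobs_range),
                 radius_range = radius_range,
                 fg_color = fg_color, bg_color = bg_color,
                 texture_sd = texture_sd,
                 color_jitter_sd = color_jitter_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# exact rasterization of a union of axis-aligned ellipses; pixel centers
# sit at integer coordinates (row, col) starting at 1
rasterize_ellipses <- function(h, w, blobs) {
  mask <- matrix(0, h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  for (b in blobs) {
    mask[((ys - b$cy) / b$ry)^2 + ((xs - b$cx) / b$rx)^2 <= 1] <- 1
  }
  mask
}

# one image + exact mask; consumes the current RNG stream
synth_one <- function(cfg) {
  h <- cfg$size[1]
  w <- cfg$size[2]
  n_blobs <- if (cfg$n_blobs_range[1] == cfg$n_blobs_range[2]) {
    cfg$n_blobs_range[1]
  } else {
    sample(cfg$n_blobs_range[1]:cfg$n_blobs_range[2], 1L)
  }
  blobs <- lapply(seq_len(n_blobs), function(b) {
    list(cy = stats::runif(1, 1, h), cx = stats::runif(1, 1, w),
         ry = stats::runif(1, cfg$radius_range[1], cfg$radius_range[2]),
         rx = stats::runif(1, cfg$radius_range[1], cfg$radius_range[2]))
  })
  mask <- rasterize_ellipses(h, w, blobs)
  jitter <- stats::rnorm(3, 0, cfg$color_jitter_sd)
  img <- array(0, c(h, w, 3))
  for (k in 1:3) {
    base <- ifelse(mask == 1, cfg$fg_color[k], cfg$bg_color[k]) + jitter[k]
    img[, , k] <- base + stats::rnorm(h * w, 0, cfg$texture_sd)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, blobs = blobs)
}

#' Generate a synthetic partially-labeled dataset
#'
#' Produces a training pool split deterministically into labeled and
#' unlabeled subsets plus a labeled validation set. The split is a
#' deterministic function of `(seed, labeled_fraction)`.
#'
#' @param config a [synth_config()].
#' @return an object of class `data_split` with elements `labeled`,
#'   `unlabeled` and `validation`; each sample is a list with `id`,
#'   `image` (`H x W x 3`) and, where available, `mask` (`H x W`).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "synth-images"))
  train <- lapply(seq_len(config$n_images), function(i) {
    s <- synth_one(config)
    list(id = sprintf("train_%03d", i), image = s$image, mask = s$mask)
  })
  val <- lapply(seq_len(config$n_validation), function(i) {
    s <- synth_one(config)
    list(id = sprintf("val_%03d", i), image = s$image, mask = s$mask)
  })
  set.seed(derive_seed(config$seed, "synth-split"))
  n_lab <- max(1L, round(config$n_images * config$labeled_fraction))
  perm <- sample.int(config$n_images)
  lab_idx <- sort(perm[seq_len(n_lab)])
  unlabeled <- lapply(train[setdiff(seq_len(config$n_images), lab_idx)],
                      function(s) s[c("id", "image")])
  structure(list(labeled = train[lab_idx],
                 unlabeled = unlabeled,
                 validation = val),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data_split: %d labeled, %d unlabeled, %d validation\n",
              length(x$labeled), length(x$unlabeled), length(x$validation)))
  invisible(x)
}

#' Apply per-image global color shifts
#'
#' Adds an independent Gaussian mean shift per channel to every image in
#' the split (masks untouched), emulating the inter-slide color variation
#' that Reinhard normalization is meant to remove.
#'
#' @param split a `data_split`.
#' @param jitter_sd standard deviation of the channel shifts.
#' @param seed RNG seed.
#' @return the corrupted `data_split`.
#' @export
corrupt_colors <- function(split, jitter_sd, seed = 1L) {
  if (jitter_sd == 0) return(split)
  set.seed(derive_seed(seed, "corrupt-colors"))
  shift_one <- function(s) {
    delta <- stats::rnorm(3, 0, jitter_sd)
    for (k in 1:3) s$image[, , k] <- s$image[, , k] + delta[k]
    s$image <- pmin(pmax(s$image, 0), 1)
    s
  }
  for (part in c("labeled", "unlabeled", "validation")) {
    split[[part]] <- lapply(split[[part]], shift_one)
  }
  split
}
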