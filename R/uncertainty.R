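# Monte Carlo dropout uncertainty estimation.

#' Monte Carlo dropout prediction
#'
#' Runs `passes` stochastic forward passes with dropout kept active (batch
#' normalization uses its running statistics, so dropout is the only source
#' of stochasticity) and returns the per-pixel, per-class sample mean and
#' population variance of the softmax outputs. Low variance marks pixels
#' the teacher is consistently confident about; high variance flags
#' unreliable pseudo-labels.
#'
#' @param model a teacher model (built with dropout layers).
#' @param image an `H x W x 3` image in `[0, 1]`.
#' @param passes number of stochastic forward passes `T >= 1`.
#' @param seed RNG seed for the dropout masks.
#' @param keep_passes also return the individual pass outputs.
#' @return an object of class `uncertainty_maps`: `mean` and `variance`
#'   (`H x W x 2` each), `passes`, and optionally `pass_values` (a list of
#'   the `T` individual probability maps).
#' @export
mc_dropout_predict <- function(model, image, passes = 30L, seed = 1L,
                               keep_passes = FALSE) {
  if (model$type != "teacher") {
    stop("Monte Carlo dropout requires a model with dropout layers")
  }
  stopifnot(passes >= 1L)
  x <- as_image_batch(image)
  if (model$spec$dropout_rate == 0) {
    # no stochasticity: every pass is the deterministic forward pass
    p <- teacher_forward(model, x, training = FALSE)$probs$value
    p <- array(p, dim(p)[1:3])
    return(structure(list(mean = p, variance = array(0, dim(p)),
                          passes = as.integer(passes),
                          pass_values = if (keep_passes)
                            rep(list(p), passes)),
                     class = "uncertainty_maps"))
  }
  set.seed(derive_seed(seed, "mc-dropout"))
  s1 <- NULL
  s2 <- NULL
  pass_values <- if (keep_passes) vector("list", passes)
  for (t in seq_len(passes)) {
    p <- teacher_forward(model, x, training = FALSE,
                         dropout_active = TRUE)$probs$value
    p <- array(p, dim(p)[1:3])
    if (is.null(s1)) {
      s1 <- p
      s2 <- p * p
    } else {
      s1 <- s1 + p
      s2 <- s2 + p * p
    }
    if (keep_passes) pass_values[[t]] <- p
  }
  mean_map <- s1 / passes
  var_map <- pmax(s2 / passes - mean_map^2, 0)
  structure(list(mean = mean_map, variance = var_map,
                 passes = as.integer(passes), pass_values = pass_values),
            class = "uncertainty_maps")
}

# viridis-like color ramp (dark purple -> yellow), anchors hard-coded
heat_colors <- function(v) {
  anchors <- c("#440154", "#46327E", "#365C8D", "#277F8E", "#1FA187",
               "#4AC16D", "#A0DA39", "#FDE725")
  ramp <- grDevices::colorRamp(anchors)
  ramp(pmin(pmax(v, 0), 1)) / 255
}

render_heatmap <- function(map, path) {
  lo <- min(map)
  hi <- max(map)
  v <- if (hi > lo) (map - lo) / (hi - lo) else array(0, dim(map))
  cols <- heat_colors(as.numeric(v))
  img <- array(0, c(dim(map)[1], dim(map)[2], 3))
  img[] <- cols
  png::writePNG(img, path)
  list(file = path, min = lo, max = hi)
}

#' Render uncertainty heatmaps
#'
#' Writes one heatmap PNG per class for the mean probability and for the
#' variance (linearly scaled to each map's own range; darker purple = low,
#' yellow = high), a colorbar legend PNG, and a JSON sidecar annotating
#' each map's true minimum and maximum.
#'
#' @param maps an `uncertainty_maps` object.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, a list with `files` and the `annotations` (per-map
#'   min/max) that were written.
#' @export
render_uncertainty <- function(maps, dir, prefix = "uncertainty") {
  stopifnot(inherits(maps, "uncertainty_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  class_names <- c("background", "foreground")
  files <- character(0)
  annotations <- list()
  for (what in c("mean", "variance")) {
    for (k in 1:2) {
      path <- file.path(dir, sprintf("%s_%s_%s.png", prefix, what,
                                     class_names[k]))
      info <- render_heatmap(maps[[what]][, , k], path)
      files <- c(files, path)
      annotations[[sprintf("%s_%s", what, class_names[k])]] <-
        list(min = info$min, max = info$max)
    }
  }
  bar <- matrix(rep(seq(1, 0, length.out = 128L), times = 16L), 128L, 16L)
  bar_path <- file.path(dir, sprintf("%s_colorbar.png", prefix))
  cols <- heat_colors(as.numeric(bar))
  bar_img <- array(0, c(128L, 16L, 3L))
  bar_img[] <- cols
  png::writePNG(bar_img, bar_path)
  files <- c(files, bar_path)
  ann_path <- file.path(dir, sprintf("%s_annotations.json", prefix))
  jsonlite::write_json(annotations, ann_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, ann_path)
  invisible(list(files = files, annotations = annotations))
}
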