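# Reinhard statistical color transfer in CIELAB space.
#
# Stain appearance varies between slides (staining protocol, scanner,
# illumination); matching the per-channel mean and standard deviation of
# each image to a reference image in a perceptual color space removes most
# of this variation. Color-space conversions go through
# grDevices::convertColor (sRGB companding, D65 white point).

#' Convert between RGB and CIELAB images
#'
#' @param image an `H x W x 3` array; RGB values in `[0, 1]` for
#'   `rgb_to_lab`, CIELAB channels (L in `[0, 100]`, a, b) for
#'   `lab_to_rgb`.
#' @return the converted `H x W x 3` array; `lab_to_rgb` clips out-of-gamut
#'   values to `[0, 1]`.
#' @export
rgb_to_lab <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 RGB image")
  lab <- grDevices::convertColor(matrix(image, ncol = 3L),
                                 from = "sRGB", to = "Lab")
  array(lab, d)
}

#' @rdname rgb_to_lab
#' @export
lab_to_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 Lab image")
  rgb <- grDevices::convertColor(matrix(image, ncol = 3L),
                                 from = "Lab", to = "sRGB")
  array(pmin(pmax(rgb, 0), 1), d)
}

#' Per-channel statistics of a Lab image
#'
#' Arithmetic mean and population standard deviation (divide by the pixel
#' count) of each channel over all pixels.
#'
#' @param image an `H x W x 3` Lab image.
#' @return list of class `channel_stats` with `mean` and `std` (3-vectors).
#' @export
channel_stats <- function(image) {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3] == 3L, d[1] * d[2] >= 1L)
  m <- matrix(image, ncol = 3L)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  structure(list(mean = unname(mu), std = unname(sd_pop)),
            class = "channel_stats")
}

#' Reinhard color normalization
#'
#' Transfers the reference per-channel Lab mean and standard deviation onto
#' the target image: each Lab channel is standardized by the target's own
#' statistics (a degenerate standard deviation is floored at `eps`) and
#' re-scaled to the reference statistics, then converted back to RGB and
#' clipped to `[0, 1]`.
#'
#' @param target an `H x W x 3` RGB image in `[0, 1]`.
#' @param reference_stats a `channel_stats` from the reference image's Lab
#'   representation, or an `H x W x 3` RGB reference image.
#' @param eps floor for the target standard deviation.
#' @return the normalized RGB image.
#' @export
reinhard_normalize <- function(target, reference_stats, eps = 1e-6) {
  if (is.array(reference_stats)) {
    reference_stats <- channel_stats(rgb_to_lab(reference_stats))
  }
  stopifnot(inherits(reference_stats, "channel_stats"))
  lab <- rgb_to_lab(target)
  st <- channel_stats(lab)
  for (k in 1:3) {
    lab[, , k] <- (lab[, , k] - st$mean[k]) / max(st$std[k], eps) *
      reference_stats$std[k] + reference_stats$mean[k]
  }
  lab_to_rgb(lab)
}

#' Write / read cached reference statistics
#'
#' @param stats a `channel_stats` object.
#' @param path JSON file path.
#' @return `write_channel_stats` returns `path` invisibly;
#'   `read_channel_stats` returns the `channel_stats`.
#' @export
write_channel_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, std = stats$std), path,
                       digits = NA)
  invisible(path)
}

#' @rdname write_channel_stats
#' @export
read_channel_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), std = as.numeric(x$std)),
            class = "channel_stats")
}
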