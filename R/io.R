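# Image, mask and probability-map I/O (PNG / TIFF).

read_any_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           tif = ,
           tiff = tiff::readTIFF(path),
           stop("unsupported image format: ", ext)),
    error = function(e) stop(sprintf("cannot read '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  img
}

#' Read an RGB image
#'
#' PNG or TIFF; gray images are replicated to three channels, alpha is
#' dropped, and 8/16-bit values arrive scaled to `[0, 1]`.
#'
#' @param path image file path.
#' @return an `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  img <- read_any_image(path)
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop(sprintf("'%s' is not an RGB image", path))
  img
}

#' Read a binary mask
#'
#' Any stored value strictly above half intensity (127 on an 8-bit scale)
#' becomes foreground (1).
#'
#' @param path mask file path (PNG or TIFF).
#' @return an `H x W` matrix of 0/1.
#' @export
read_mask <- function(path) {
  img <- read_any_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  (img > 127 / 255) * 1
}

#' Write images, masks and probability maps
#'
#' Masks are stored as 8-bit PNG with values 0/255; probability and
#' variance maps as 32-bit TIFF.
#'
#' @param image,mask,map the array to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask == 1), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_prob_map <- function(map, path) {
  tiff::writeTIFF(map, path, bits.per.sample = 32L)
  invisible(path)
}

#' Load an image directory as dataset samples
#'
#' Images are matched to masks by file-name stem. Each returned sample has
#' `id`, `image` and (when `masks_dir` is given) `mask`.
#'
#' @param dir directory of PNG/TIFF images.
#' @param masks_dir optional directory of masks; every image must have one.
#' @return a list of samples (empty, with a warning, for an empty
#'   directory).
#' @export
load_images <- function(dir, masks_dir = NULL) {
  paths <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0L) {
    warning(sprintf("no images found in '%s'", dir))
    return(list())
  }
  mask_paths <- NULL
  if (!is.null(masks_dir)) {
    mask_paths <- sort(list.files(masks_dir, pattern = "\\.(png|tif|tiff)$",
                                  ignore.case = TRUE, full.names = TRUE))
    names(mask_paths) <- tools::file_path_sans_ext(basename(mask_paths))
  }
  lapply(paths, function(p) {
    id <- tools::file_path_sans_ext(basename(p))
    out <- list(id = id, image = read_image(p))
    if (!is.null(masks_dir)) {
      if (!id %in% names(mask_paths)) {
        stop(sprintf("image '%s' has no mask in '%s'", id, masks_dir))
      }
      mp <- mask_paths[[id]]
      out$mask <- read_mask(mp)
    }
    out
  })
}

#' Write a data split to disk
#'
#' Writes `images/`, `masks/` (labeled and validation) and a `splits.json`
#' listing the sample ids per subset.
#'
#' @param split a `data_split`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(split, dir) {
  img_dir <- file.path(dir, "images")
  mask_dir <- file.path(dir, "masks")
  dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(mask_dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("labeled", "unlabeled", "validation")) {
    for (s in split[[part]]) {
      write_image(s$image, file.path(img_dir, paste0(s$id, ".png")))
      if (!is.null(s$mask)) {
        write_mask(s$mask, file.path(mask_dir, paste0(s$id, ".png")))
      }
    }
  }
  ids <- lapply(split[c("labeled", "unlabeled", "validation")],
                function(part) vapply(part, `[[`, character(1), "id"))
  jsonlite::write_json(ids, file.path(dir, "splits.json"))
  invisible(dir)
}
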