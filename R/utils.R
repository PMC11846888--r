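# shared internal helpers

#' Derive a stage-specific RNG seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a stable string hash,
#' so that re-running a single stage reproduces exactly what the full
#' pipeline did. The result always fits in a 32-bit integer.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# coerce a single image / list of images / 4-d array to (H, W, C, N)
as_image_batch <- function(x, channels = 3L) {
  if (is.list(x)) {
    d <- dim(x[[1]])
    out <- array(0, c(d[1], d[2], d[3], length(x)))
    for (i in seq_along(x)) out[, , , i] <- x[[i]]
    return(out)
  }
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L || dim(x)[3] != channels) {
    stop(sprintf("expected images with %d channels (H x W x %d [x N])",
                 channels, channels))
  }
  x
}

# coerce masks to (H, W, N)
as_mask_batch <- function(y) {
  if (is.list(y)) {
    d <- dim(y[[1]])
    out <- array(0, c(d[1], d[2], length(y)))
    for (i in seq_along(y)) out[, , i] <- y[[i]]
    return(out)
  }
  d <- dim(y)
  if (length(d) == 2L) dim(y) <- c(d, 1L)
  y
}

# drop the batch dimension again if the caller passed a single image
drop_batch <- function(x, single) {
  if (single) {
    d <- dim(x)
    dim(x) <- d[-length(d)]
  }
  x
}

check_binary <- function(y, what = "mask") {
  if (!all(y %in% c(0, 1))) stop(sprintf("%s values must be 0 or 1", what))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
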