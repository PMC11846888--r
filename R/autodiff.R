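# Minimal reverse-mode automatic differentiation tape.
#
# Every forward pass records its operations on a fresh tape; ad_backward()
# walks the tape in reverse creation order and accumulates gradients into
# parent nodes. Model parameters are leaf nodes that persist across steps,
# so their $grad slot is what the optimizer consumes.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 128L)
  tp$n <- 0L
  tp
}

ad_leaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$leaf <- TRUE
  nd
}

#' @noRd
ad_node <- function(tape, value, parents, backward) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_accumulate <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(nd)
}

# Seed the (scalar) loss node with gradient 1 and propagate backwards.
ad_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(gs)) {
      if (!is.null(gs[[j]])) ad_accumulate(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
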