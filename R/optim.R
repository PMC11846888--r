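# Adam optimizer over a named list of parameter leaves.

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$lr <- lr
  st$beta1 <- beta1
  st$beta2 <- beta2
  st$eps <- eps
  st$t <- 0L
  # zero states shaped exactly like each parameter (same attributes)
  st$m <- lapply(params, function(p) p$value * 0)
  st$v <- st$m
  st
}

adam_step <- function(st, params) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in names(params)) {
    g <- params[[nm]]$grad
    if (is.null(g)) next
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g * g
    mhat <- st$m[[nm]] / bc1
    vhat <- st$v[[nm]] / bc2
    params[[nm]]$value <- params[[nm]]$value -
      st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}
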