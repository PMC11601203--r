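# Adam optimizer over the flat parameter list.

adam_init <- function(params) {
  zero <- lapply(params, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
  list(m = zero, v = zero, t = 0L)
}

# Scale a gradient list so its global L2 norm is at most max_norm.
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(x) sum(x * x), numeric(1))))
  if (total > max_norm) grads <- lapply(grads, function(x) x * (max_norm / total))
  grads
}

# One Adam update. `mask` (optional character vector) restricts the update to
# the named parameters -- used to freeze everything else structurally: frozen
# parameters are never touched, so they stay bit-identical.
adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, mask = NULL) {
  state$t <- state$t + 1L
  t <- state$t
  names_upd <- if (is.null(mask)) names(params) else intersect(mask, names(params))
  for (nm in names_upd) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr * gr
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
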