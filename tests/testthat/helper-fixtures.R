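# Shared tiny fixtures: a 1-layer, d=16 model keeps every forward/backward
# call in the low-millisecond range.

tiny_config <- function(seed = 1L) {
  model_config(n_layers = 1L, n_heads = 2L, embed_dim = 16L, max_len = 128L,
               seed = seed)
}

tiny_model <- function(seed = 1L) init_model(tiny_config(seed))

random_seq <- function(L, seed = 1L) {
  v <- aa_vocab()
  thermlm:::with_seed(seed, paste(sample(v$residues, L, replace = TRUE),
                                  collapse = ""))
}

# Central finite-difference check of an analytic gradient list against a
# scalar loss function of the model; returns the worst relative error over
# a few sampled coordinates of the named parameters.
fd_worst_rel_err <- function(model, loss_fn, grads, param_names,
                             n_per_param = 3L, eps = 1e-5, seed = 42L) {
  worst <- 0
  thermlm:::with_seed(seed, {
    for (nm in param_names) {
      x <- model$params[[nm]]
      for (k in sample(seq_along(x), min(n_per_param, length(x)))) {
        m2 <- model
        m2$params[[nm]][k] <- x[k] + eps
        lp <- loss_fn(m2)
        m2$params[[nm]][k] <- x[k] - eps
        lm_ <- loss_fn(m2)
        num <- (lp - lm_) / (2 * eps)
        an <- grads[[nm]][k]
        worst <- max(worst, abs(num - an) / max(1e-8, abs(num) + abs(an)))
      }
    }
  })
  worst
}
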