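#' Pretraining configuration
#'
#' Desk-scale defaults: 1024 tokens per micro-batch with no gradient
#' accumulation; the published-scale setting (4096 tokens x 32 accumulation
#' steps) is available as `preset = "paper"` for reference. Learning rate
#' defaults to 1e-4 (Adam).
#'
#' @param learning_rate Adam learning rate.
#' @param tokens_per_microbatch Token budget per mini-batch.
#' @param gradient_accumulation_steps Micro-batches per optimizer update.
#' @param total_steps Optimizer updates to run.
#' @param seed Run seed; all batch sampling, noising and mutant draws derive
#'   from it.
#' @param task_order Round-robin task schedule over the three objectives.
#' @param align_N Mutants per correlation-alignment sample.
#' @param align_stop_gradient Which side of the correlation alignment is a
#'   fixed target: `"temperatures"` (default; the alignment feeds back from
#'   predicted OGTs into the MLM scores and leaves the OGT head label-driven),
#'   `"scores"`, or `"none"` (both sides receive gradients).
#' @param noise A [noise_config()].
#' @param weights Loss weights `c(mlm, ogt, corr)`; default `c(1, 0.01, 1)`.
#' @param clip_norm Global gradient-norm clip applied before each Adam
#'   update (default 1.0; `Inf` disables). The correlation-alignment loss has
#'   unbounded gradients as the prediction variance shrinks, which is exactly
#'   the early-training state of a small model; clipping keeps any one step
#'   from dominating the optimizer's moment statistics while leaving the
#'   objective untouched once variances are healthy.
#' @param init_output_bias Set the OGT head's output bias to the mean
#'   training label before the first step (default `TRUE`). With a bounded
#'   tanh bottleneck ahead of the output, a large common-mode error drives
#'   the bottleneck into saturation and destroys input sensitivity; starting
#'   at the label mean leaves only the differential signal to learn.
#' @param preset `"desk"` or `"paper"` batch geometry.
#' @return A `thermlm_pretrain_config` list.
#' @export
pretrain_config <- function(learning_rate = 1e-4, tokens_per_microbatch = NULL,
                            gradient_accumulation_steps = NULL,
                            total_steps = 300L, seed = 1L,
                            task_order = c("mlm", "ogt", "corr"),
                            align_N = 16L,
                            align_stop_gradient = c("temperatures", "scores", "none"),
                            noise = noise_config(),
                            weights = c(mlm = 1, ogt = 0.01, corr = 1),
                            clip_norm = 1.0, init_output_bias = TRUE,
                            preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") list(tok = 1024L, acc = 1L) else list(tok = 4096L, acc = 32L)
  stopifnot(all(sort(task_order) == sort(c("mlm", "ogt", "corr"))))
  structure(list(
    learning_rate = learning_rate,
    tokens_per_microbatch = as.integer(tokens_per_microbatch %||% base$tok),
    gradient_accumulation_steps = as.integer(gradient_accumulation_steps %||% base$acc),
    total_steps = as.integer(total_steps),
    seed = as.integer(seed),
    task_order = task_order,
    align_N = as.integer(align_N),
    align_stop_gradient = match.arg(align_stop_gradient),
    noise = noise,
    weights = weights,
    clip_norm = clip_norm,
    init_output_bias = isTRUE(init_output_bias),
    preset = preset
  ), class = "thermlm_pretrain_config")
}

# Tokenize a corpus data.frame (columns id, sequence[, ogt]); sequences over
# max_len are skipped with a message reporting the count.
tokenize_corpus <- function(corpus, max_len) {
  stopifnot(is.data.frame(corpus), "sequence" %in% names(corpus))
  ids <- if ("id" %in% names(corpus)) corpus$id else paste0("seq", seq_len(nrow(corpus)))
  toks <- lapply(seq_len(nrow(corpus)), function(i)
    tokenize(corpus$sequence[i], id = ids[i]))
  keep <- vapply(toks, function(tk) tk$L <= max_len, logical(1))
  if (any(!keep))
    message(sum(!keep), " sequence(s) exceed max_len and were skipped")
  list(tokens = toks[keep], keep = keep)
}

# Draw alignment mutants (positions + substitutions only; no scoring).
draw_alignment_mutants <- function(seq, N, seed, vocab = aa_vocab()) {
  with_seed(seed, {
    positions <- sample.int(seq$L, N, replace = TRUE)
    wt_tokens <- seq$tokens[positions]
    mut_tokens <- vapply(wt_tokens, function(w)
      sample(setdiff(seq_len(vocab$n_residues), w), 1L), integer(1))
    mutant_tokens <- lapply(seq_len(N), function(i) {
      tk <- seq$tokens; tk[positions[i]] <- mut_tokens[i]; tk
    })
    list(base_tokens = seq$tokens, positions = positions,
         wt_tokens = wt_tokens, mut_tokens = mut_tokens,
         mutant_tokens = mutant_tokens)
  })
}

#' Alternating multitask pretraining
#'
#' Round-robins over the three objectives with each mini-batch iteration:
#' masked-LM reconstruction on noised batches, OGT mean-squared-error
#' regression on clean batches, and Pearson correlation alignment on randomly
#' drawn single-point mutants of one batch sequence. Adam updates throughout;
#' fully deterministic given `(corpus, config seed)`.
#'
#' @param model A `thermlm_model` to train (returned updated).
#' @param corpus data.frame with columns `sequence` and `ogt` (degC), plus
#'   optional `id`.
#' @param cfg A [pretrain_config()].
#' @return List with `model` (trained), `log` (data.frame: step, task, loss,
#'   weighted_loss), and `skipped` (count of over-length sequences).
#' @export
pretrain_alternating <- function(model, corpus, cfg = pretrain_config()) {
  if (nrow(corpus) == 0L) stop("empty corpus")
  if (!"ogt" %in% names(corpus)) stop("corpus must carry an 'ogt' label per record")
  tc <- tokenize_corpus(corpus, model$config$max_len)
  toks <- tc$tokens
  ogts <- corpus$ogt[tc$keep]
  if (length(toks) == 0L) stop("no usable sequences after length filtering")
  n <- length(toks)
  if (isTRUE(cfg$init_output_bias)) model$params$ogt.FC4b <- mean(ogts)
  mean_len <- mean(vapply(toks, function(x) x$L, numeric(1)))
  batch_n <- max(1L, floor(cfg$tokens_per_microbatch / mean_len))
  opt <- adam_init(model$params)
  w <- cfg$weights
  log <- vector("list", cfg$total_steps)
  for (step in seq_len(cfg$total_steps)) {
    task <- cfg$task_order[((step - 1L) %% length(cfg$task_order)) + 1L]
    acc <- cfg$gradient_accumulation_steps
    g_acc <- grad_zero(model)
    loss_acc <- 0
    for (micro in seq_len(acc)) {
      sd_step <- derive_seed(cfg$seed, "step", step, micro)
      idx <- with_seed(sd_step, sample.int(n, min(batch_n, n)))
      if (task == "mlm") {
        noised <- lapply(seq_along(idx), function(j)
          apply_noise(toks[[idx[j]]], cfg$noise,
                      seed = derive_seed(sd_step, "noise", j)))
        lg <- loss_grad_mlm_batch(model, noised, g = g_acc,
                                  gscale = w[["mlm"]] / acc)
        loss <- lg$loss
        g_acc <- lg$grads
      } else if (task == "ogt") {
        lg <- loss_grad_ogt(model, toks[idx], ogts[idx],
                            weight = w[["ogt"]] / acc, g = g_acc)
        loss <- lg$loss
        g_acc <- lg$grads
      } else {
        base <- toks[[idx[1]]]
        ms <- draw_alignment_mutants(base, cfg$align_N,
                                     derive_seed(sd_step, "align"))
        lg <- loss_grad_corr(model, ms,
                             stop_gradient = cfg$align_stop_gradient %||% "temperatures",
                             g = g_acc, gscale = w[["corr"]] / acc)
        loss <- lg$loss
        g_acc <- lg$grads
      }
      loss_acc <- loss_acc + loss / acc
    }
    g_acc <- clip_global_norm(g_acc, cfg$clip_norm %||% Inf)
    upd <- adam_step(model$params, g_acc, opt, lr = cfg$learning_rate)
    model$params <- upd$params
    opt <- upd$state
    wt <- switch(task, mlm = w[["mlm"]], ogt = w[["ogt"]], corr = w[["corr"]])
    log[[step]] <- data.frame(step = step, task = task, loss = loss_acc,
                              weighted_loss = wt * loss_acc)
  }
  list(model = model, log = do.call(rbind, log), skipped = sum(!tc$keep))
}

#' Fine-tune on homologous sequences (MLM only)
#'
#' Unsupervised fine-tuning of the encoder and MLM head on homologs of a
#' target protein, with the same noising scheme and hyperparameters as
#' pretraining. OGT-head parameters are excluded from the optimizer's update
#' set, so they remain bit-identical. Homolog sets larger than `cap` are
#' truncated to the first `cap` sequences.
#'
#' @param model A `thermlm_model`.
#' @param homologs Character vector of sequences (or data.frame with a
#'   `sequence` column).
#' @param cfg A [pretrain_config()]; only the MLM task runs.
#' @param cap Maximum number of homologs used (default 30000).
#' @return List with `model`, `log`, `n_used`.
#' @export
finetune_homologs <- function(model, homologs, cfg = pretrain_config(),
                              cap = 30000L) {
  if (is.data.frame(homologs)) homologs <- homologs$sequence
  if (length(homologs) == 0L) stop("empty homolog set")
  if (length(homologs) > cap) homologs <- homologs[seq_len(cap)]
  tc <- tokenize_corpus(data.frame(sequence = homologs,
                                   stringsAsFactors = FALSE),
                        model$config$max_len)
  toks <- tc$tokens
  if (length(toks) == 0L) stop("no usable homologs after length filtering")
  n <- length(toks)
  mean_len <- mean(vapply(toks, function(x) x$L, numeric(1)))
  batch_n <- max(1L, floor(cfg$tokens_per_microbatch / mean_len))
  trainable <- setdiff(names(model$params), ogt_param_names(model$params))
  opt <- adam_init(model$params)
  log <- vector("list", cfg$total_steps)
  for (step in seq_len(cfg$total_steps)) {
    sd_step <- derive_seed(cfg$seed, "ft", step)
    idx <- with_seed(sd_step, sample.int(n, min(batch_n, n)))
    noised <- lapply(seq_along(idx), function(j)
      apply_noise(toks[[idx[j]]], cfg$noise,
                  seed = derive_seed(sd_step, "noise", j)))
    lg <- loss_grad_mlm_batch(model, noised)
    loss <- lg$loss
    g <- clip_global_norm(lg$grads, cfg$clip_norm %||% Inf)
    upd <- adam_step(model$params, g, opt, lr = cfg$learning_rate,
                     mask = trainable)
    model$params <- upd$params
    opt <- upd$state
    log[[step]] <- data.frame(step = step, task = "mlm", loss = loss,
                              weighted_loss = loss)
  }
  list(model = model, log = do.call(rbind, log), n_used = n)
}

#' Mean MLM loss of a model over a sequence set
#'
#' Convenience diagnostic: average reconstruction loss over freshly noised
#' copies of the given sequences.
#'
#' @param model A `thermlm_model`.
#' @param sequences Character vector of sequences.
#' @param cfg A [noise_config()].
#' @param seed Noising seed.
#' @return Mean loss (scalar).
#' @export
mean_mlm_loss <- function(model, sequences, cfg = noise_config(), seed = 1L) {
  losses <- vapply(seq_along(sequences), function(i) {
    tk <- tokenize(sequences[i], id = paste0("s", i))
    ns <- apply_noise(tk, cfg, seed = derive_seed(seed, "eval", i))
    P <- mlm_distributions(model, encode(model, ns$tokens)$H)
    mlm_loss(P, ns)
  }, numeric(1))
  mean(losses)
}

# --- supervised regression protocol ------------------------------------------

#' Regressor configuration
#'
#' Hyperparameters of the frozen-backbone supervised protocol: learning rate
#' 1e-4, batch size 16, 5-fold dynamic epoch selection with early-stopping
#' patience 20 and at most 200 epochs, and a 5-seed ensemble by default.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param folds Folds for the dynamic-epoch rule.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param max_epochs Cap on training epochs.
#' @param seeds Seed list for ensembling.
#' @return A `thermlm_regressor_config` list.
#' @export
regressor_config <- function(learning_rate = 1e-4, batch_size = 16L,
                             folds = 5L, patience = 20L, max_epochs = 200L,
                             seeds = 1:5) {
  stopifnot(folds >= 2L, patience < max_epochs)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 folds = as.integer(folds), patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seeds = as.integer(seeds)),
            class = "thermlm_regressor_config")
}

# Backbone features r for a set of variants, with optional cross-call cache.
variant_features <- function(model, wild_type, variants, cache = NULL) {
  R <- matrix(NA_real_, length(variants), model$config$embed_dim)
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    if (is.character(v)) v <- parse_variant(v, wild_type)
    key <- v$string
    if (!is.null(cache) && !is.null(cache[[key]])) {
      R[i, ] <- cache[[key]]
    } else {
      R[i, ] <- sequence_representation(model, apply_variant(wild_type, v))
      if (!is.null(cache)) cache[[key]] <- R[i, ]
    }
  }
  R
}

# Initialize fresh FC3/FC4 head parameters from a seed.
init_head <- function(d, seed) {
  with_seed(seed, list(
    FC3W = matrix(stats::rnorm(d * d, sd = 1 / sqrt(d)), d, d),
    FC3b = numeric(d),
    FC4w = stats::rnorm(d, sd = 1 / sqrt(d)),
    FC4b = 0
  ))
}

head_predict <- function(head, R) {
  T3 <- tanh(sweep(R %*% head$FC3W, 2, head$FC3b, `+`))
  drop(T3 %*% head$FC4w) + head$FC4b
}

# Train the FC3/FC4 head on cached features by Adam + MSE. If `val` indices
# are given, tracks validation MSE per epoch and early-stops; returns the
# best epoch. Only the four head parameters receive gradients -- everything
# upstream is frozen by construction.
train_head <- function(R, y, cfg, seed, epochs = NULL, val_idx = NULL) {
  d <- ncol(R)
  head <- init_head(d, seed)
  opt <- adam_init(head)
  train_idx <- setdiff(seq_len(nrow(R)), val_idx)
  Rtr <- R[train_idx, , drop = FALSE]; ytr <- y[train_idx]
  best_val <- Inf; best_epoch <- 1L; best_head <- head; wait <- 0L
  max_ep <- epochs %||% cfg$max_epochs
  for (ep in seq_len(max_ep)) {
    ord <- with_seed(derive_seed(seed, "shuffle", ep), sample.int(nrow(Rtr)))
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      Rb <- Rtr[bi, , drop = FALSE]; yb <- ytr[bi]
      T3 <- tanh(sweep(Rb %*% head$FC3W, 2, head$FC3b, `+`))
      yhat <- drop(T3 %*% head$FC4w) + head$FC4b
      dy <- 2 * (yhat - yb) / length(yb)
      gr <- list(FC3W = crossprod(Rb, (dy %o% head$FC4w) * (1 - T3^2)),
                 FC3b = colSums((dy %o% head$FC4w) * (1 - T3^2)),
                 FC4w = drop(crossprod(T3, dy)),
                 FC4b = sum(dy))
      upd <- adam_step(head, gr, opt, lr = cfg$learning_rate)
      head <- upd$params; opt <- upd$state
    }
    if (!is.null(val_idx)) {
      vhat <- head_predict(head, R[val_idx, , drop = FALSE])
      vloss <- mean((vhat - y[val_idx])^2)
      if (vloss < best_val - 1e-12) {
        best_val <- vloss; best_epoch <- ep; best_head <- head; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  if (is.null(val_idx)) list(head = head, epochs = max_ep)
  else list(head = best_head, epochs = best_epoch, val_loss = best_val)
}

#' Dynamic epoch selection by cross-validation
#'
#' Splits the labeled set into `folds` seeded folds; for each fold, trains
#' the regression head on the remainder with early stopping on that fold's
#' validation loss and records the best epoch. Returns the rounded
#' (half-up) mean of the per-fold epochs, at least 1.
#'
#' @param model Backbone `thermlm_model`.
#' @param wild_type A `thermlm_tokens`.
#' @param assay data.frame with `variant` and `fitness` columns.
#' @param cfg A [regressor_config()].
#' @param seed Fold-split / head-init seed.
#' @param cache Optional environment for feature caching.
#' @return Integer epoch count.
#' @export
determine_epochs <- function(model, wild_type, assay, cfg = regressor_config(),
                             seed = 1L, cache = NULL) {
  n <- nrow(assay)
  if (n < cfg$folds)
    stop("need at least ", cfg$folds, " labeled records (have ", n,
         "); use a smaller fold count")
  R <- variant_features(model, wild_type, as.list(assay$variant), cache)
  ys <- scale_labels(assay$fitness)
  fold_id <- with_seed(derive_seed(seed, "folds"),
                       sample(rep_len(seq_len(cfg$folds), n)))
  stops <- vapply(seq_len(cfg$folds), function(f) {
    res <- train_head(R, ys$y, cfg, seed = derive_seed(seed, "fold", f),
                      val_idx = which(fold_id == f))
    res$epochs
  }, numeric(1))
  max(1L, round_half_up(mean(stops)))
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

scale_labels <- function(y) {
  m <- mean(y); s <- stats::sd(y)
  if (!is.finite(s) || s == 0) s <- 1
  list(y = (y - m) / s, mean = m, sd = s)
}

#' Fit the frozen-backbone supervised regressor
#'
#' Implements the low-N transfer protocol: all backbone parameters (encoder,
#' MLM head, pooling, FC1/FC2) stay frozen; the last two fully connected
#' layers (FC3/FC4) are rerandomized from `seed` and trained with MSE on the
#' (internally z-scored) fitness labels, for a number of epochs chosen by
#' [determine_epochs()] (no validation set in the final fit).
#'
#' @inheritParams determine_epochs
#' @param epochs Optional fixed epoch count (skips the dynamic rule).
#' @return A `thermlm_regressor`: backbone reference, trained head, label
#'   scaling, `epochs`, `seed`, and `updated` (names of the only trained
#'   parameter tensors).
#' @export
fit_regressor <- function(model, wild_type, assay, cfg = regressor_config(),
                          seed = 1L, epochs = NULL, cache = NULL) {
  n <- nrow(assay)
  if (n < cfg$folds) stop("need at least ", cfg$folds, " labeled records")
  variants <- lapply(assay$variant, function(v)
    if (is.character(v)) parse_variant(v, wild_type) else v)
  R <- variant_features(model, wild_type, variants, cache)
  ys <- scale_labels(assay$fitness)
  if (is.null(epochs))
    epochs <- determine_epochs(model, wild_type, assay, cfg, seed, cache)
  res <- train_head(R, ys$y, cfg, seed = derive_seed(seed, "final"),
                    epochs = epochs)
  structure(list(model = model, head = res$head, y_mean = ys$mean,
                 y_sd = ys$sd, epochs = epochs, seed = seed,
                 updated = c("ogt.FC3W", "ogt.FC3b", "ogt.FC4w", "ogt.FC4b")),
            class = "thermlm_regressor")
}

#' Predict fitness with a fitted regressor
#'
#' @param regressor A `thermlm_regressor`.
#' @param wild_type A `thermlm_tokens`.
#' @param variants List of variants (or notation strings).
#' @param cache Optional feature-cache environment.
#' @return Numeric vector of predicted fitness on the original label scale.
#' @export
predict_fitness <- function(regressor, wild_type, variants, cache = NULL) {
  R <- variant_features(regressor$model, wild_type, variants, cache)
  head_predict(regressor$head, R) * regressor$y_sd + regressor$y_mean
}

# --- ensembling --------------------------------------------------------------

#' Bundle models into an ensemble
#'
#' @param members List of `thermlm_model`s with identical architecture.
#' @return A `thermlm_ensemble` (aggregation rule: mean).
#' @export
make_ensemble <- function(members) {
  stopifnot(length(members) >= 1L)
  cfgs <- lapply(members, function(m) m$config[c("n_layers", "n_heads", "embed_dim")])
  if (length(unique(vapply(cfgs, function(x) paste(unlist(x), collapse = ","),
                           character(1)))) != 1L)
    stop("ensemble members must share an architecture")
  structure(list(members = members, aggregation = "mean"),
            class = "thermlm_ensemble")
}

#' Fine-tune an ensemble on homologs with distinct seeds
#'
#' Runs [finetune_homologs()] once per seed and bundles the results; this is
#' the 5-seed protocol used before saturation scoring.
#'
#' @param model Base `thermlm_model`.
#' @param homologs Sequences (see [finetune_homologs()]).
#' @param cfg A [pretrain_config()]; its seed field is replaced per member.
#' @param seeds Integer seeds, one per member (default 1:5).
#' @param cap Homolog cap.
#' @return A `thermlm_ensemble`.
#' @export
finetune_homolog_ensemble <- function(model, homologs, cfg = pretrain_config(),
                                      seeds = 1:5, cap = 30000L) {
  members <- lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    finetune_homologs(model, homologs, cfg, cap)$model
  })
  make_ensemble(members)
}

#' Average per-variant scores across ensemble members
#'
#' @param member_scores List (one element per member) of data.frames with
#'   `variant` and `score` columns, or named numeric vectors.
#' @return data.frame with `variant` and `score` (arithmetic mean).
#' @export
ensemble_average <- function(member_scores) {
  stopifnot(length(member_scores) >= 1L)
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$score, x$variant) else x
  }
  vs <- lapply(member_scores, as_named)
  ref <- names(vs[[1]])
  for (i in seq_along(vs)) {
    miss <- setdiff(ref, names(vs[[i]]))
    extra <- setdiff(names(vs[[i]]), ref)
    if (length(miss) > 0L || length(extra) > 0L)
      stop("variant set mismatch across members: ",
           paste(utils::head(c(miss, extra), 5), collapse = ", "))
  }
  mat <- vapply(vs, function(v) v[ref], numeric(length(ref)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1, dimnames = list(ref, NULL))
  data.frame(variant = ref, score = rowMeans(mat), stringsAsFactors = FALSE)
}
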