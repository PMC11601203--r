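#' Model configuration
#'
#' Architecture hyperparameters for the encoder and heads. The desk-scale
#' default (2 layers, 4 heads, embedding 64) is small enough to train on one
#' CPU core in seconds; `preset = "paper"` records the published 650M-scale
#' geometry (33 layers, 20 heads, embedding 1280) for reference -- it is not
#' intended to be trained here.
#'
#' @param n_layers Number of transformer blocks.
#' @param n_heads Attention heads; must divide `embed_dim`.
#' @param embed_dim Hidden width d.
#' @param ffn_dim Feed-forward width; defaults to `4 * embed_dim`.
#' @param max_len Maximum sequence length accepted by [encode()].
#' @param tie_weights Tie the MLM output projection to the input embedding
#'   (the ESM-style convention); if `FALSE` a separate 20 x d projection is
#'   allocated.
#' @param seed Integer seed used for parameter initialization.
#' @param preset `"desk"` (default) or `"paper"`; explicit arguments override
#'   preset values.
#' @return A `thermlm_config` list.
#' @export
model_config <- function(n_layers = NULL, n_heads = NULL, embed_dim = NULL,
                         ffn_dim = NULL, max_len = NULL, tie_weights = TRUE,
                         seed = 1L, preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(n_layers = 2L, n_heads = 4L, embed_dim = 64L, max_len = 512L)
  } else {
    list(n_layers = 33L, n_heads = 20L, embed_dim = 1280L, max_len = 1024L)
  }
  cfg <- list(
    n_layers = as.integer(n_layers %||% base$n_layers),
    n_heads = as.integer(n_heads %||% base$n_heads),
    embed_dim = as.integer(embed_dim %||% base$embed_dim),
    max_len = as.integer(max_len %||% base$max_len),
    tie_weights = isTRUE(tie_weights),
    seed = as.integer(seed),
    preset = preset
  )
  cfg$ffn_dim <- as.integer(ffn_dim %||% (4L * cfg$embed_dim))
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  structure(cfg, class = "thermlm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- parameter initialization ------------------------------------------------

#' Initialize a model
#'
#' Draws all parameters from seeded normals (sd 0.02 for weights, zeros for
#' biases, ones for LayerNorm gains), so a given `(config, seed)` pair always
#' yields bit-identical parameters.
#'
#' @param config A [model_config()].
#' @return A `thermlm_model` list with `config`, `params` (flat named list of
#'   matrices/vectors) and `vocab`.
#' @export
init_model <- function(config = model_config()) {
  vocab <- aa_vocab()
  d <- config$embed_dim
  f <- config$ffn_dim
  with_seed(config$seed, {
    rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
    p <- list()
    p$emb <- rmat(vocab$size, d)
    p$mlm_b <- numeric(vocab$n_residues)
    if (!config$tie_weights) p$mlm_W <- rmat(vocab$n_residues, d)
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("L", l, ".")
      p[[paste0(pre, "ln1.g")]] <- rep(1, d)
      p[[paste0(pre, "ln1.b")]] <- numeric(d)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- rmat(d, d)
      for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- numeric(d)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d)
      p[[paste0(pre, "ln2.b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- rmat(d, f)
      p[[paste0(pre, "b1")]] <- numeric(f)
      p[[paste0(pre, "W2")]] <- rmat(f, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
    }
    p$lnf.g <- rep(1, d); p$lnf.b <- numeric(d)
    # OGT head: fresh LayerNorm, projection-softmax pooling, FC1..FC4.
    # Head weights use fan-in (LeCun) scaling, not the encoder's 0.02
    # residual-stack convention: the head is shallow and must pass input
    # variation through, not keep a deep residual stream stable.
    hmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
    p$ogt.lnp.g <- rep(1, d); p$ogt.lnp.b <- numeric(d)
    p$ogt.w <- stats::rnorm(d, sd = 1 / sqrt(d)); p$ogt.b <- 0
    p$ogt.FC1W <- hmat(d, f); p$ogt.FC1b <- numeric(f)
    p$ogt.FC2W <- hmat(f, d); p$ogt.FC2b <- numeric(d)
    p$ogt.FC3W <- hmat(d, d); p$ogt.FC3b <- numeric(d)
    # output bias starts at the midpoint of the stated 0-100 degC range so
    # early training shapes differences between sequences, not the offset
    p$ogt.FC4w <- stats::rnorm(d, sd = 1 / sqrt(d)); p$ogt.FC4b <- 50
    structure(list(config = config, params = p, vocab = vocab),
              class = "thermlm_model")
  })
}

#' @export
print.thermlm_model <- function(x, ...) {
  n <- sum(vapply(x$params, length, numeric(1)))
  cat("<thermlm_model> layers=", x$config$n_layers, " heads=", x$config$n_heads,
      " d=", x$config$embed_dim, " params=", n, "\n", sep = "")
  invisible(x)
}

# Names of OGT-head parameters (used by freezing contracts).
ogt_param_names <- function(params) grep("^ogt\\.", names(params), value = TRUE)

# --- forward-pass counter ----------------------------------------------------

.pass_counter <- new.env(parent = emptyenv())
.pass_counter$n <- 0L

#' Reset or read the encoder pass counter
#'
#' Every call to [encode()] increments a package-level counter; used to verify
#' that saturation scoring reuses forward passes as promised.
#' @return The current count (for `encoder_pass_count`).
#' @export
reset_pass_counter <- function() { .pass_counter$n <- 0L; invisible(NULL) }

#' @rdname reset_pass_counter
#' @export
encoder_pass_count <- function() .pass_counter$n

# --- encoder forward ---------------------------------------------------------

# Memoized rotary tables keyed by (L, dh).
.rope_cache <- new.env(parent = emptyenv())

rope_tables_cached <- function(L, dh) {
  key <- paste0(L, ".", dh)
  tab <- .rope_cache[[key]]
  if (is.null(tab)) {
    tab <- rope_tables(L, dh)
    .rope_cache[[key]] <- tab
  }
  tab
}

# Stacked forward pass over a list of sequences: all position-wise work
# (LayerNorm, projections, rotary rotation, GELU feed-forward) runs on one
# (sum L_i) x d matrix; only the attention products are per-sequence.
stack_forward <- function(model, token_list, cache = FALSE) {
  p <- model$params
  cfg <- model$config
  d <- cfg$embed_dim; nh <- cfg$n_heads; dh <- d %/% nh; half <- dh %/% 2L
  lens <- vapply(token_list, length, integer(1))
  if (any(lens < 1L)) stop("empty sequence")
  if (any(lens > cfg$max_len))
    stop("sequence length ", max(lens), " exceeds max_len ", cfg$max_len)
  .pass_counter$n <- .pass_counter$n + length(token_list)
  nseq <- length(token_list)
  starts <- cumsum(c(1L, lens))[seq_len(nseq)]
  tokens_all <- unlist(token_list, use.names = FALSE)
  N <- length(tokens_all)
  # full-width rotary tables: per-position cos/sin tiled across heads, plus
  # the half-swap permutation and sign vector realizing rotate-half per head
  tabs <- lapply(lens, rope_tables_cached, dh = dh)
  cos_small <- do.call(rbind, lapply(tabs, `[[`, "cos"))
  sin_small <- do.call(rbind, lapply(tabs, `[[`, "sin"))
  tile <- rep(seq_len(dh), nh)
  cosF <- cos_small[, tile, drop = FALSE]
  sinF <- sin_small[, tile, drop = FALSE]
  permF <- as.integer(outer(c((half + 1L):dh, seq_len(half)),
                            (seq_len(nh) - 1L) * dh, `+`))
  sgnF <- rep(rep(c(-1, 1), each = half), nh)
  sgn_row <- rep(sgnF, each = N)
  rope_f <- function(X) X * cosF + (X[, permF, drop = FALSE] * sgn_row) * sinF
  X <- p$emb[tokens_all, , drop = FALSE]
  layers <- if (cache) vector("list", cfg$n_layers) else NULL
  seq_rows <- lapply(seq_len(nseq), function(s)
    starts[s]:(starts[s] + lens[s] - 1L))
  inv_sqrt_dh <- 1 / sqrt(dh)
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, ".")
    Xin <- X
    lc1 <- ln_forward(Xin, p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    A <- lc1$Y
    Qr <- rope_f(addb(A %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]]))
    Kr <- rope_f(addb(A %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]]))
    V <- addb(A %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    O <- matrix(0, N, d)
    Ps <- if (cache) vector("list", nseq) else NULL
    for (s in seq_len(nseq)) {
      rows <- seq_rows[[s]]
      Ph <- if (cache) vector("list", nh) else NULL
      for (h in seq_len(nh)) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        P <- softmax_rows(tcrossprod(Qr[rows, idx, drop = FALSE],
                                     Kr[rows, idx, drop = FALSE]) * inv_sqrt_dh)
        O[rows, idx] <- P %*% V[rows, idx, drop = FALSE]
        if (cache) Ph[[h]] <- P
      }
      if (cache) Ps[[s]] <- Ph
    }
    attn <- addb(O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    X1 <- Xin + attn
    lc2 <- ln_forward(X1, p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    B <- lc2$Y
    A1 <- addb(B %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    if (cache) {
      gf <- gelu_fwd(A1)
      Hg <- gf$y
    } else Hg <- gelu(A1)
    Fo <- addb(Hg %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    X <- X1 + Fo
    if (cache) layers[[l]] <- list(lc1 = lc1, A = A, Qr = Qr, Kr = Kr, V = V,
                                   Ps = Ps, O = O, lc2 = lc2, B = B,
                                   Gg = gf$grad, Hg = Hg)
  }
  lcf <- ln_forward(X, p$lnf.g, p$lnf.b)
  out <- list(H = lcf$Y, lens = lens, starts = starts)
  if (cache) out$cache <- list(tokens_all = tokens_all, lens = lens,
                               starts = starts, N = N, nseq = nseq,
                               seq_rows = seq_rows, cosF = cosF, sinF = sinF,
                               permF = permF, sgn_row = sgn_row,
                               layers = layers, lcf = lcf)
  out
}

#' Run the transformer encoder
#'
#' Pre-LayerNorm transformer with rotary position embeddings and GELU
#' feed-forward blocks, following the ESM-2 block structure at configurable
#' scale. Deterministic: the forward pass involves no randomness.
#'
#' @param model A `thermlm_model`.
#' @param tokens A `thermlm_tokens` object or integer token vector.
#' @param cache Keep intermediates for backpropagation.
#' @return A list with `H` (L x d matrix of hidden vectors) and, if requested,
#'   `cache`.
#' @export
encode <- function(model, tokens, cache = FALSE) {
  if (inherits(tokens, "thermlm_tokens")) tokens <- tokens$tokens
  stack_forward(model, list(tokens), cache = cache)
}

#' Encode a batch of sequences
#'
#' Convenience wrapper that encodes each sequence independently; per-sequence
#' outputs are identical to single [encode()] calls by construction.
#'
#' @param model A `thermlm_model`.
#' @param token_list List of `thermlm_tokens` or integer vectors.
#' @return List of `H` matrices.
#' @export
encode_batch <- function(model, token_list) {
  lapply(token_list, function(tk) encode(model, tk)$H)
}

# --- MLM head ----------------------------------------------------------------

# Residue logits (L x 20). With tied weights the output projection is the
# residue block of the input embedding.
mlm_logits <- function(model, H) {
  W <- if (model$config$tie_weights) {
    model$params$emb[seq_len(model$vocab$n_residues), , drop = FALSE]
  } else model$params$mlm_W
  addb(H %*% t(W), model$params$mlm_b)
}

#' Per-position residue distributions from the MLM head
#'
#' @param model A `thermlm_model`.
#' @param H Encoder output matrix (L x d), e.g. `encode(model, tokens)$H`.
#' @param log Return log-probabilities instead of probabilities.
#' @return L x 20 matrix; each row a distribution over the residues, columns
#'   named by residue symbol.
#' @export
mlm_distributions <- function(model, H, log = FALSE) {
  Z <- mlm_logits(model, H)
  P <- if (log) log_softmax_rows(Z) else softmax_rows(Z)
  colnames(P) <- model$vocab$residues
  P
}

# --- OGT head ----------------------------------------------------------------

#' Attention pooling over encoder outputs
#'
#' LayerNorms the hidden vectors, computes per-position weights
#' `s_i = softmax(W h_i + b)` with a learned projection, and returns the
#' weighted sum `c = sum_i s_i h_i`.
#'
#' @param model A `thermlm_model`.
#' @param H Encoder output (L x d).
#' @return List with `c` (pooled vector, length d) and `weights` (`s`,
#'   nonnegative, summing to 1).
#' @export
attention_pool <- function(model, H) {
  if (is.null(dim(H)) || nrow(H) < 1L) stop("attention_pool needs at least one hidden vector")
  p <- model$params
  lc <- ln_forward(H, p$ogt.lnp.g, p$ogt.lnp.b)
  Hn <- lc$Y
  s <- softmax_vec(drop(Hn %*% p$ogt.w) + p$ogt.b)
  list(c = drop(crossprod(Hn, s)), weights = s)
}

# Full OGT head forward from H; cache for backprop. Returns raw (unclamped) y.
ogt_head_forward <- function(model, H, cache = FALSE) {
  if (is.null(dim(H)) || nrow(H) < 1L) stop("OGT head needs at least one hidden vector")
  p <- model$params
  lc <- ln_forward(H, p$ogt.lnp.g, p$ogt.lnp.b)
  Hn <- lc$Y
  logits <- drop(Hn %*% p$ogt.w) + p$ogt.b
  s <- softmax_vec(logits)
  cvec <- drop(crossprod(Hn, s))
  a1 <- drop(cvec %*% p$ogt.FC1W) + p$ogt.FC1b
  h1 <- gelu(a1)
  a2 <- drop(h1 %*% p$ogt.FC2W) + p$ogt.FC2b
  r <- a2 + cvec
  a3 <- drop(r %*% p$ogt.FC3W) + p$ogt.FC3b
  t3 <- tanh(a3)
  y <- sum(p$ogt.FC4w * t3) + p$ogt.FC4b
  out <- list(y = y, r = r, s = s)
  if (cache) out$cache <- list(lc = lc, Hn = Hn, s = s, cvec = cvec, a1 = a1,
                               h1 = h1, r = r, a3 = a3, t3 = t3)
  out
}

#' Predict optimal growth temperature for a sequence
#'
#' Runs the encoder and the OGT head: attention pooling, a residual
#' GELU MLP (`r = FC2 g(FC1 c) + c`), then `y = FC4 tanh(FC3 r)`. The raw
#' head output is unbounded (and is what training gradients see); at
#' inference the result is clamped to the 0--100 degC contract by default.
#'
#' @param model A `thermlm_model`.
#' @param tokens A `thermlm_tokens` or integer vector.
#' @param clamp Clamp output into [0, 100] degC (default `TRUE`).
#' @return Temperature in degC (scalar).
#' @export
predict_ogt <- function(model, tokens, clamp = TRUE) {
  H <- encode(model, tokens)$H
  y <- ogt_head_forward(model, H)$y
  if (clamp) y <- min(100, max(0, y))
  y
}

#' Predict OGT for a batch of sequences
#'
#' One stacked encoder pass for the whole batch; otherwise identical to
#' calling [predict_ogt()] per sequence.
#'
#' @param model A `thermlm_model`.
#' @param token_list List of `thermlm_tokens` or integer vectors.
#' @param clamp Clamp outputs into [0, 100] degC.
#' @return Numeric vector of temperatures.
#' @export
predict_ogt_batch <- function(model, token_list, clamp = TRUE) {
  token_list <- lapply(token_list, function(tk)
    if (inherits(tk, "thermlm_tokens")) tk$tokens else tk)
  enc <- stack_forward(model, token_list)
  ends <- enc$starts + enc$lens - 1L
  y <- vapply(seq_along(token_list), function(i) {
    ogt_head_forward(model, enc$H[enc$starts[i]:ends[i], , drop = FALSE])$y
  }, numeric(1))
  if (clamp) y <- pmin(100, pmax(0, y))
  y
}

#' Sequence representation for transfer learning
#'
#' The pooled residual feature `r` (the input of FC3), computed with the
#' frozen backbone; this is the feature the supervised regression protocol
#' trains FC3/FC4 on.
#'
#' @param model A `thermlm_model`.
#' @param tokens A `thermlm_tokens` or integer vector.
#' @return Numeric vector of length `embed_dim`.
#' @export
sequence_representation <- function(model, tokens) {
  H <- encode(model, tokens)$H
  ogt_head_forward(model, H)$r
}

# --- checkpoints -------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the format version, configuration,
#' initialization seed and all parameter tensors.
#'
#' @param model A `thermlm_model`.
#' @param path Destination file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(version = CHECKPOINT_VERSION, config = unclass(model$config),
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("unsupported checkpoint version: ", obj$version)
  structure(list(config = structure(obj$config, class = "thermlm_config"),
                 params = obj$params, vocab = aa_vocab()),
            class = "thermlm_model")
}
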