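# Numeric primitives for the transformer: LayerNorm, GELU, softmax, rotary
# position embedding, and their hand-derived backward passes. All forwards
# cache what the backward needs. Shapes are rows = positions, cols = channels.

LN_EPS <- 1e-5

# --- seeded evaluation -------------------------------------------------------

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from a base seed and a stream label; stays < 2^31.
# The multiplier keeps h * mult below 2^53 so double arithmetic stays exact,
# and two closing scramble rounds decorrelate near-identical inputs.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "|")
  bytes <- utf8ToInt(parts)
  M <- 2147483563
  h <- 377424577
  for (b in bytes) h <- (h * 65599 + b) %% M
  h <- (h * 69069 + 12345) %% M
  h <- (h * 65539 + 7919) %% M
  as.integer(h)
}

# --- LayerNorm ---------------------------------------------------------------

ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- Xc * inv
  n <- nrow(X)
  Y <- xhat * rep(g, each = n) + rep(b, each = n)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_backward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dX = dX,
       dg = colSums(dY * xhat),
       db = colSums(dY))
}

# --- GELU (tanh approximation) -----------------------------------------------

GELU_C <- sqrt(2 / pi)

gelu <- function(x) {
  x2 <- x * x
  0.5 * x * (1 + tanh(GELU_C * x * (1 + 0.044715 * x2)))
}

gelu_grad <- function(x) {
  x2 <- x * x
  t <- tanh(GELU_C * x * (1 + 0.044715 * x2))
  0.5 * (1 + t) + 0.5 * x * (1 - t * t) * GELU_C * (1 + 0.134145 * x2)
}

# Value and derivative in one pass (shared tanh); used on the training path.
gelu_fwd <- function(x) {
  x2 <- x * x
  t <- tanh(GELU_C * x * (1 + 0.044715 * x2))
  list(y = 0.5 * x * (1 + t),
       grad = 0.5 * (1 + t) + 0.5 * x * (1 - t * t) * GELU_C * (1 + 0.134145 * x2))
}

# --- softmax -----------------------------------------------------------------

# Row maxima without apply(): max.col is C-level.
row_max <- function(Z) Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]

# Add a bias (length = ncol) to every row without sweep().
addb <- function(X, b) X + rep(b, each = nrow(X))

softmax_rows <- function(Z) {
  E <- exp(Z - row_max(Z))
  E / rowSums(E)
}

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Backward of row-wise softmax: given dP and P, return dZ.
softmax_rows_backward <- function(dP, P) {
  (dP - rowSums(dP * P)) * P
}

log_softmax_rows <- function(Z) {
  Zs <- Z - row_max(Z)
  Zs - log(rowSums(exp(Zs)))
}

# --- rotary position embedding ----------------------------------------------

# Precompute cos/sin tables for head dimension dh and L positions (0-based
# position angles, half-split convention: channels [1..dh/2 | dh/2+1..dh]).
rope_tables <- function(L, dh, base = 10000) {
  half <- dh %/% 2L
  inv_freq <- base^(-(seq_len(half) - 1) * 2 / dh)
  ang <- outer(seq_len(L) - 1, inv_freq)          # L x half
  list(cos = cbind(cos(ang), cos(ang)), sin = cbind(sin(ang), sin(ang)))
}

rotate_half <- function(X) {
  half <- ncol(X) %/% 2L
  cbind(-X[, (half + 1):(2 * half), drop = FALSE], X[, 1:half, drop = FALSE])
}

rope_apply <- function(X, tab) {
  X * tab$cos + rotate_half(X) * tab$sin
}

# Backward: the rotation is orthogonal per position, so apply the transpose.
rope_backward <- function(dY, tab) {
  half <- ncol(dY) %/% 2L
  rot_t <- cbind(dY[, (half + 1):(2 * half), drop = FALSE],
                 -dY[, 1:half, drop = FALSE])
  dY * tab$cos + rot_t * tab$sin
}
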