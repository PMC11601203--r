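# Hand-derived backward passes for the encoder and both heads, plus the
# per-objective gradient drivers used by the trainers. Gradients are exact
# (verified against central finite differences in the test suite).
# The encoder backward mirrors the stacked forward: all position-wise work is
# done on the concatenated batch; only attention is per sequence.

grad_zero <- function(model) {
  lapply(model$params, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
}

grad_add <- function(g, name, delta) {
  g[[name]] <- g[[name]] + delta
  g
}

grad_sum <- function(g1, g2) {
  for (nm in names(g2)) g1[[nm]] <- g1[[nm]] + g2[[nm]]
  g1
}

grad_scale <- function(g, a) lapply(g, function(x) x * a)

# --- encoder backward --------------------------------------------------------

# dH: gradient wrt stacked encoder output (N x d) for the batch held in
# `cache` (from stack_forward). Accumulates into grad list `g`.
encoder_backward <- function(model, cache, dH, g) {
  p <- model$params
  cfg <- model$config
  d <- cfg$embed_dim; nh <- cfg$n_heads; dh <- d %/% nh
  N <- cache$N
  cosF <- cache$cosF; sinF <- cache$sinF
  permF <- cache$permF; sgn_row <- cache$sgn_row
  # transpose of the rotation: dX = dY*cos + ((dY*sin)[, perm] * (-sgn))
  rope_b <- function(dY) {
    dYs <- dY * sinF
    dY * cosF - dYs[, permF, drop = FALSE] * sgn_row
  }
  lb <- ln_backward(dH, cache$lcf, p$lnf.g)
  g <- grad_add(g, "lnf.g", lb$dg)
  g <- grad_add(g, "lnf.b", lb$db)
  dX <- lb$dX
  inv_sqrt_dh <- 1 / sqrt(dh)

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", l, ".")
    cl <- cache$layers[[l]]
    # feed-forward block: Xout = X1 + Fo, Fo = gelu(B W1 + b1) W2 + b2
    dFo <- dX
    dHg <- tcrossprod(dFo, p[[paste0(pre, "W2")]])
    g <- grad_add(g, paste0(pre, "W2"), crossprod(cl$Hg, dFo))
    g <- grad_add(g, paste0(pre, "b2"), colSums(dFo))
    dA1 <- dHg * cl$Gg
    g <- grad_add(g, paste0(pre, "W1"), crossprod(cl$B, dA1))
    g <- grad_add(g, paste0(pre, "b1"), colSums(dA1))
    dB <- tcrossprod(dA1, p[[paste0(pre, "W1")]])
    lb2 <- ln_backward(dB, cl$lc2, p[[paste0(pre, "ln2.g")]])
    g <- grad_add(g, paste0(pre, "ln2.g"), lb2$dg)
    g <- grad_add(g, paste0(pre, "ln2.b"), lb2$db)
    dX1 <- dX + lb2$dX
    # attention block: X1 = Xin + O Wo + bo
    dattn <- dX1
    g <- grad_add(g, paste0(pre, "bo"), colSums(dattn))
    g <- grad_add(g, paste0(pre, "Wo"), crossprod(cl$O, dattn))
    dO <- tcrossprod(dattn, p[[paste0(pre, "Wo")]])
    dQr <- matrix(0, N, d); dKr <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (s in seq_len(cache$nseq)) {
      rows <- cache$seq_rows[[s]]
      for (h in seq_len(nh)) {
        idx <- ((h - 1L) * dh + 1L):(h * dh)
        P <- cl$Ps[[s]][[h]]
        dOh <- dO[rows, idx, drop = FALSE]
        Vh <- cl$V[rows, idx, drop = FALSE]
        dP <- tcrossprod(dOh, Vh)
        dV[rows, idx] <- crossprod(P, dOh)
        dSc <- softmax_rows_backward(dP, P) * inv_sqrt_dh
        dQr[rows, idx] <- dSc %*% cl$Kr[rows, idx, drop = FALSE]
        dKr[rows, idx] <- crossprod(dSc, cl$Qr[rows, idx, drop = FALSE])
      }
    }
    dQ <- rope_b(dQr); dK <- rope_b(dKr)
    A <- cl$A
    g <- grad_add(g, paste0(pre, "Wq"), crossprod(A, dQ))
    g <- grad_add(g, paste0(pre, "bq"), colSums(dQ))
    g <- grad_add(g, paste0(pre, "Wk"), crossprod(A, dK))
    g <- grad_add(g, paste0(pre, "bk"), colSums(dK))
    g <- grad_add(g, paste0(pre, "Wv"), crossprod(A, dV))
    g <- grad_add(g, paste0(pre, "bv"), colSums(dV))
    dA <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
          tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
          tcrossprod(dV, p[[paste0(pre, "Wv")]])
    lb1 <- ln_backward(dA, cl$lc1, p[[paste0(pre, "ln1.g")]])
    g <- grad_add(g, paste0(pre, "ln1.g"), lb1$dg)
    g <- grad_add(g, paste0(pre, "ln1.b"), lb1$db)
    dX <- dX1 + lb1$dX
  }
  # embedding lookup: scatter-add row gradients, grouped by token
  rs <- rowsum(dX, cache$tokens_all)
  rows <- as.integer(rownames(rs))
  g$emb[rows, ] <- g$emb[rows, , drop = FALSE] + rs
  g
}

# MLM head backward: dZ is gradient wrt residue logits (N x 20).
# Returns list(dH, g).
mlm_head_backward <- function(model, H, dZ, g) {
  tied <- model$config$tie_weights
  nres <- model$vocab$n_residues
  W <- if (tied) model$params$emb[seq_len(nres), , drop = FALSE] else model$params$mlm_W
  dH <- dZ %*% W
  dW <- crossprod(dZ, H)
  if (tied) {
    g$emb[seq_len(nres), ] <- g$emb[seq_len(nres), , drop = FALSE] + dW
  } else {
    g <- grad_add(g, "mlm_W", dW)
  }
  g <- grad_add(g, "mlm_b", colSums(dZ))
  list(dH = dH, g = g)
}

# OGT head backward from cached head forward; dy is scalar dL/dy (raw y).
# Returns list(dH, g).
ogt_head_backward <- function(model, hc, dy, g) {
  p <- model$params
  t3 <- hc$t3
  g <- grad_add(g, "ogt.FC4w", dy * t3)
  g <- grad_add(g, "ogt.FC4b", dy)
  dt3 <- dy * p$ogt.FC4w
  da3 <- dt3 * (1 - t3^2)
  g <- grad_add(g, "ogt.FC3W", outer(hc$r, da3))
  g <- grad_add(g, "ogt.FC3b", da3)
  dr <- drop(p$ogt.FC3W %*% da3)
  # r = a2 + c
  da2 <- dr
  g <- grad_add(g, "ogt.FC2W", outer(hc$h1, da2))
  g <- grad_add(g, "ogt.FC2b", da2)
  dh1 <- drop(p$ogt.FC2W %*% da2)
  da1 <- dh1 * gelu_grad(hc$a1)
  g <- grad_add(g, "ogt.FC1W", outer(hc$cvec, da1))
  g <- grad_add(g, "ogt.FC1b", da1)
  dc <- dr + drop(p$ogt.FC1W %*% da1)
  # c = t(Hn) s
  dHn <- hc$s %o% dc
  ds <- drop(hc$Hn %*% dc)
  dlogit <- (ds - sum(ds * hc$s)) * hc$s
  g <- grad_add(g, "ogt.w", drop(crossprod(hc$Hn, dlogit)))
  g <- grad_add(g, "ogt.b", sum(dlogit))
  dHn <- dHn + dlogit %o% p$ogt.w
  lb <- ln_backward(dHn, hc$lc, p$ogt.lnp.g)
  g <- grad_add(g, "ogt.lnp.g", lb$dg)
  g <- grad_add(g, "ogt.lnp.b", lb$db)
  list(dH = lb$dX, g = g)
}

# --- objective gradient drivers ----------------------------------------------

# MLM reconstruction loss and gradient over a batch of noised sequences
# (one stacked forward/backward). `noised_list` is a list of thermlm_noised
# objects. The loss is the mean of per-sequence losses; reduce picks the
# within-sequence reduction ("mean" per spec default, "sum" the bare sum).
loss_grad_mlm_batch <- function(model, noised_list, reduce = c("mean", "sum"),
                                g = NULL, gscale = 1) {
  reduce <- match.arg(reduce)
  B <- length(noised_list)
  enc <- stack_forward(model, lapply(noised_list, `[[`, "tokens"), cache = TRUE)
  Z <- mlm_logits(model, enc$H)
  P <- softmax_rows(Z)
  logP <- log_softmax_rows(Z)
  dZ <- matrix(0, nrow(Z), ncol(Z))
  loss <- 0
  for (b in seq_len(B)) {
    ns <- noised_list[[b]]
    n <- length(ns$positions)
    if (n < 1L) stop("no noised positions")
    pos <- enc$starts[b] - 1L + ns$positions
    sel <- cbind(pos, ns$originals)
    scale <- if (reduce == "mean") 1 / n else 1
    loss <- loss + (-sum(logP[sel]) * scale) / B
    sc <- scale * gscale / B
    for (k in seq_len(n)) {
      i <- pos[k]
      dZ[i, ] <- dZ[i, ] + P[i, ] * sc
      dZ[i, ns$originals[k]] <- dZ[i, ns$originals[k]] - sc
    }
  }
  if (is.null(g)) g <- grad_zero(model)
  hb <- mlm_head_backward(model, enc$H, dZ, g)
  g <- encoder_backward(model, enc$cache, hb$dH, hb$g)
  list(loss = loss, grads = g)
}

# Single-sequence convenience wrapper (kept for tests and oracles).
loss_grad_mlm <- function(model, noised, reduce = c("mean", "sum"),
                          g = NULL, gscale = 1) {
  loss_grad_mlm_batch(model, list(noised), reduce = reduce, g = g,
                      gscale = gscale)
}

# Mean-squared-error OGT loss and gradient over a batch of sequences
# (stacked encoder pass; pooling head per sequence).
loss_grad_ogt <- function(model, token_list, temps, weight = 1, g = NULL) {
  B <- length(token_list)
  stopifnot(B == length(temps), B >= 1L)
  if (is.null(g)) g <- grad_zero(model)
  token_list <- lapply(token_list, function(tk)
    if (inherits(tk, "thermlm_tokens")) tk$tokens else tk)
  enc <- stack_forward(model, token_list, cache = TRUE)
  dH <- matrix(0, nrow(enc$H), ncol(enc$H))
  loss <- 0
  for (b in seq_len(B)) {
    rows <- enc$cache$seq_rows[[b]]
    hf <- ogt_head_forward(model, enc$H[rows, , drop = FALSE], cache = TRUE)
    err <- hf$y - temps[b]
    loss <- loss + err^2 / B
    hb <- ogt_head_backward(model, hf$cache, weight * 2 * err / B, g)
    g <- hb$g
    dH[rows, ] <- hb$dH
  }
  g <- encoder_backward(model, enc$cache, dH, g)
  list(loss = loss, grads = g)
}

# Gradient of the Pearson correlation-alignment loss L = 1 - cor(S, T) wrt S
# and T (population convention). Returns NULL on zero variance.
pearson_grads <- function(S, T) {
  n <- length(S)
  Sc <- S - mean(S); Tc <- T - mean(T)
  sS <- sqrt(mean(Sc^2)); sT <- sqrt(mean(Tc^2))
  if (sS <= 0 || sT <= 0) return(NULL)
  r <- mean(Sc * Tc) / (sS * sT)
  dr_dS <- Tc / (n * sS * sT) - r * Sc / (n * sS^2)
  dr_dT <- Sc / (n * sS * sT) - r * Tc / (n * sT^2)
  list(loss = 1 - r, dS = -dr_dS, dT = -dr_dT)
}

# Correlation-alignment loss and gradient. `ms` is a mutant sample from
# draw_alignment_mutants() / sample_mutants_for_alignment(); the base
# sequence and all N mutants share one stacked pass. `stop_gradient` picks
# which side of the alignment is treated as a fixed target:
#   "temperatures" (default): T is detached; the alignment feeds back from
#     the predicted OGTs to the MLM scores (the stated direction of the
#     objective), leaving the OGT head to be shaped by its labels alone.
#   "scores": S is detached; alignment moves the OGT predictions.
#   "none": gradients flow through both sides (single shared graph).
loss_grad_corr <- function(model, ms,
                           stop_gradient = c("temperatures", "scores", "none"),
                           g = NULL, gscale = 1) {
  stop_gradient <- match.arg(stop_gradient)
  N <- length(ms$positions)
  enc <- stack_forward(model, c(list(ms$base_tokens), ms$mutant_tokens),
                       cache = TRUE)
  base_rows <- enc$cache$seq_rows[[1]]
  Hbase <- enc$H[base_rows, , drop = FALSE]
  Z <- mlm_logits(model, Hbase)
  logP <- log_softmax_rows(Z)
  S <- logP[cbind(ms$positions, ms$mut_tokens)] -
       logP[cbind(ms$positions, ms$wt_tokens)]
  need_T_grad <- stop_gradient != "temperatures"
  heads <- vector("list", N)
  T <- numeric(N)
  for (i in seq_len(N)) {
    rows <- enc$cache$seq_rows[[i + 1L]]
    heads[[i]] <- ogt_head_forward(model, enc$H[rows, , drop = FALSE],
                                   cache = TRUE)
    T[i] <- heads[[i]]$y
  }
  pg <- pearson_grads(S, T)
  if (is.null(g)) g <- grad_zero(model)
  if (is.null(pg)) {
    warning("zero variance in correlation-alignment sample; returning loss 1 with zero gradient")
    return(list(loss = 1, grads = g, S = S, T = T))
  }
  dH <- matrix(0, nrow(enc$H), ncol(enc$H))
  if (stop_gradient != "scores") {
    # S path: dlogP has +dS at (pos, mut) and -dS at (pos, wt)
    dlogP <- matrix(0, nrow(logP), ncol(logP))
    for (i in seq_len(N)) {
      dlogP[ms$positions[i], ms$mut_tokens[i]] <-
        dlogP[ms$positions[i], ms$mut_tokens[i]] + gscale * pg$dS[i]
      dlogP[ms$positions[i], ms$wt_tokens[i]] <-
        dlogP[ms$positions[i], ms$wt_tokens[i]] - gscale * pg$dS[i]
    }
    # through log-softmax: dZ = dlogP - P * rowSums(dlogP)
    P <- softmax_rows(Z)
    dZ <- dlogP - P * rowSums(dlogP)
    hb <- mlm_head_backward(model, Hbase, dZ, g)
    g <- hb$g
    dH[base_rows, ] <- hb$dH
  }
  if (need_T_grad) {
    for (i in seq_len(N)) {
      rows <- enc$cache$seq_rows[[i + 1L]]
      hb <- ogt_head_backward(model, heads[[i]]$cache, gscale * pg$dT[i], g)
      g <- hb$g
      dH[rows, ] <- hb$dH
    }
  }
  g <- encoder_backward(model, enc$cache, dH, g)
  list(loss = pg$loss, grads = g, S = S, T = T)
}
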