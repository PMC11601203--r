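#' Masked-language-model reconstruction loss
#'
#' Negative log-likelihood of the original residue at each noised position
#' (natural log), averaged over noised positions by default; `reduce = "sum"`
#' gives the bare sum.
#'
#' @param distributions L x 20 matrix of per-position residue probabilities
#'   (from [mlm_distributions()]).
#' @param noised A `thermlm_noised` object supplying the target positions and
#'   original residues.
#' @param reduce `"mean"` (default) or `"sum"`.
#' @return Nonnegative scalar.
#' @export
mlm_loss <- function(distributions, noised, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  n <- length(noised$positions)
  if (n < 1L) stop("no noised positions: MLM loss undefined")
  p <- distributions[cbind(noised$positions, noised$originals)]
  s <- -sum(log(p))
  if (reduce == "mean") s / n else s
}

#' Mean-squared-error OGT loss
#'
#' @param predicted,observed Equal-length numeric temperature vectors (degC).
#' @return Mean of squared differences.
#' @export
ogt_loss <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L)
    stop("predicted and observed must have equal length >= 1")
  mean((predicted - observed)^2)
}

#' Pearson correlation-alignment loss
#'
#' `1 - cov(S, T) / (sigma_S sigma_T)` with population covariance/SDs: 0 for
#' perfect positive correlation, 2 for perfect negative. If either vector has
#' zero variance the correlation is undefined; the loss falls back to 1 (no
#' information) with a warning.
#'
#' @param S,T Equal-length numeric vectors, length >= 3.
#' @return Scalar in [0, 2].
#' @export
correlation_loss <- function(S, T) {
  if (length(S) != length(T)) stop("S and T must have equal length")
  if (length(S) < 3L) stop("correlation loss needs at least 3 samples")
  pg <- pearson_grads(S, T)
  if (is.null(pg)) {
    warning("zero variance in S or T; correlation loss falls back to 1")
    return(1)
  }
  pg$loss
}

#' Combine the three pretraining losses
#'
#' `total = w_mlm * mlm + w_ogt * ogt + w_corr * corr`. The default OGT weight
#' of 0.01 rebalances the raw MSE magnitude (degC^2) against the other two.
#'
#' @param mlm,ogt,corr Finite loss components.
#' @param w_mlm,w_ogt,w_corr Weights (defaults 1, 0.01, 1).
#' @return A `thermlm_loss_breakdown` list: `mlm`, `ogt`, `corr`, `total`,
#'   and the weights used.
#' @export
total_loss <- function(mlm, ogt, corr, w_mlm = 1, w_ogt = 0.01, w_corr = 1) {
  comps <- c(mlm = mlm, ogt = ogt, corr = corr)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0L)
    stop("non-finite loss component(s): ", paste(bad, collapse = ", "))
  structure(list(mlm = mlm, ogt = ogt, corr = corr,
                 total = w_mlm * mlm + w_ogt * ogt + w_corr * corr,
                 weights = c(mlm = w_mlm, ogt = w_ogt, corr = w_corr)),
            class = "thermlm_loss_breakdown")
}

#' Sample single-point mutants for the correlation-alignment objective
#'
#' Draws `N` random single-point mutants of a base sequence (positions
#' uniform over the sequence, substitutions uniform over the 19 non-original
#' residues), scores each by the wild-type-marginal log-odds from one MLM
#' pass on the base sequence, and predicts each mutant's OGT with the raw
#' (unclamped) head output.
#'
#' @param model A `thermlm_model`.
#' @param seq A `thermlm_tokens` base sequence.
#' @param N Number of mutants (>= 3).
#' @param seed Integer seed.
#' @return A `thermlm_mutant_sample`: `base_tokens`, `positions`, `wt_tokens`,
#'   `mut_tokens`, `mutant_tokens` (list of full mutant token vectors),
#'   `S` (log-odds scores), `T` (predicted OGTs).
#' @export
sample_mutants_for_alignment <- function(model, seq, N = 16L, seed = 1L) {
  stopifnot(inherits(seq, "thermlm_tokens"), N >= 3L)
  vocab <- model$vocab
  with_seed(seed, {
    positions <- sample.int(seq$L, N, replace = TRUE)
    wt_tokens <- seq$tokens[positions]
    mut_tokens <- vapply(wt_tokens, function(w) {
      sample(setdiff(seq_len(vocab$n_residues), w), 1L)
    }, integer(1))
    mutant_tokens <- lapply(seq_len(N), function(i) {
      tk <- seq$tokens
      tk[positions[i]] <- mut_tokens[i]
      tk
    })
    logP <- mlm_distributions(model, encode(model, seq)$H, log = TRUE)
    S <- logP[cbind(positions, mut_tokens)] - logP[cbind(positions, wt_tokens)]
    T <- vapply(mutant_tokens, function(tk) {
      ogt_head_forward(model, encode(model, tk)$H)$y
    }, numeric(1))
    structure(list(base_tokens = seq$tokens, positions = positions,
                   wt_tokens = wt_tokens, mut_tokens = mut_tokens,
                   mutant_tokens = mutant_tokens, S = S, T = T),
              class = "thermlm_mutant_sample")
  })
}
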