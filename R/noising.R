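#' Noising configuration
#'
#' The corruption scheme used for masked-language-model training: 20% of
#' positions are selected as reconstruction targets (an exact count,
#' `round(noise_rate * L)`, so the total is deterministic per sequence); each
#' selected position is then independently masked (70%), substituted with a
#' residue drawn from background frequencies (20%), or kept unchanged (10%).
#' Under the defaults this makes the mask token cover ~14% of all tokens and
#' substitutions ~4%.
#'
#' @param noise_rate Fraction of tokens selected as targets (default 0.20).
#' @param mask_share Fraction of selected tokens replaced by `<mask>` (0.70).
#' @param substitute_share Fraction replaced by a background draw (0.20).
#' @param keep_share Fraction left unchanged but still scored (0.10).
#' @return A `thermlm_noise_config` list.
#' @export
noise_config <- function(noise_rate = 0.20, mask_share = 0.70,
                         substitute_share = 0.20, keep_share = 0.10) {
  shares <- c(mask_share, substitute_share, keep_share)
  if (any(shares < 0) || any(shares > 1) || abs(sum(shares) - 1) > 1e-9)
    stop("mask/substitute/keep shares must lie in [0,1] and sum to 1")
  if (noise_rate < 0 || noise_rate > 1) stop("noise_rate must lie in [0,1]")
  structure(list(noise_rate = noise_rate, mask_share = mask_share,
                 substitute_share = substitute_share, keep_share = keep_share),
            class = "thermlm_noise_config")
}

#' Sample a substitution residue from background frequencies
#'
#' Draws a residue token with probability proportional to its background
#' frequency; the draw may coincide with the original residue.
#'
#' @param bg Named numeric vector over the 20 residues (see
#'   [background_frequencies()]).
#' @param n Number of draws.
#' @param vocab A vocabulary.
#' @return Integer token vector of length `n`.
#' @export
sample_substitution <- function(bg, n = 1L, vocab = aa_vocab()) {
  bg <- check_background(bg, vocab)
  sample.int(vocab$n_residues, size = n, replace = TRUE, prob = bg)
}

#' Apply the noising scheme to a sequence
#'
#' @param seq A `thermlm_tokens` object.
#' @param cfg A [noise_config()].
#' @param bg Background frequencies for substitutions.
#' @param seed Integer seed; a given `(seq, cfg, bg, seed)` always yields the
#'   same corruption.
#' @param vocab A vocabulary.
#' @return A `thermlm_noised` object: `tokens` (corrupted), `positions`
#'   (selected target positions), `originals` (original tokens there), and
#'   `category` (`"mask"`, `"substitute"`, or `"keep"` per target).
#' @export
apply_noise <- function(seq, cfg = noise_config(), bg = background_frequencies(),
                        seed = 1L, vocab = aa_vocab()) {
  stopifnot(inherits(seq, "thermlm_tokens"))
  L <- seq$L
  n_sel <- round(cfg$noise_rate * L)
  if (n_sel < 1L)
    stop("noise_rate ", cfg$noise_rate, " selects no positions at L=", L,
         " (no reconstruction targets)")
  bg <- check_background(bg, vocab)
  with_seed(seed, {
    pos <- sort(sample.int(L, n_sel))
    originals <- seq$tokens[pos]
    cat_draw <- sample(c("mask", "substitute", "keep"), n_sel, replace = TRUE,
                       prob = c(cfg$mask_share, cfg$substitute_share, cfg$keep_share))
    tokens <- seq$tokens
    is_mask <- cat_draw == "mask"
    is_sub <- cat_draw == "substitute"
    tokens[pos[is_mask]] <- vocab$mask
    if (any(is_sub))
      tokens[pos[is_sub]] <- sample_substitution(bg, sum(is_sub), vocab)
    structure(list(id = seq$id, tokens = tokens, positions = pos,
                   originals = originals, category = cat_draw, L = L),
              class = "thermlm_noised")
  })
}
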