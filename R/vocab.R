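#' Amino-acid vocabulary
#'
#' The model operates over the 20 canonical amino acids plus two special
#' tokens: `<mask>` (used by the noising scheme) and `<pad>` (reserved for
#' fixed-width storage; the encoder itself works on unpadded sequences).
#' Token indices are 1-based: residues occupy 1..20, mask is 21, pad is 22.
#'
#' @return An object of class `thermlm_vocab` with fields `residues`
#'   (character vector of length 20), `mask`, `pad` (integer indices),
#'   `size` (total vocabulary size) and `index` (named integer map
#'   symbol -> index).
#' @export
#' @examples
#' v <- aa_vocab()
#' v$index[["A"]]
aa_vocab <- function() {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  index <- stats::setNames(seq_along(residues), residues)
  structure(
    list(residues = residues,
         n_residues = 20L,
         mask = 21L,
         pad = 22L,
         size = 22L,
         index = index),
    class = "thermlm_vocab"
  )
}

#' Tokenize a protein sequence
#'
#' Converts a residue string into an integer token vector over [aa_vocab()].
#' Non-canonical symbols (B, J, O, U, X, Z, gaps, ...) are rejected with the
#' offending position, unless `skip_invalid = TRUE`, in which case those
#' positions are dropped.
#'
#' @param sequence A single character string of amino-acid letters.
#' @param vocab A vocabulary from [aa_vocab()].
#' @param id Optional sequence identifier carried along.
#' @param skip_invalid Drop unrecognized residues instead of erroring.
#' @return A `thermlm_tokens` object: list with `id`, `tokens` (integer
#'   vector), `L` (length).
#' @export
tokenize <- function(sequence, vocab = aa_vocab(), id = "seq",
                     skip_invalid = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- unname(vocab$index[chars])
  bad <- which(is.na(idx))
  if (length(bad) > 0L) {
    if (skip_invalid) {
      idx <- idx[-bad]
      if (length(idx) == 0L) stop("sequence '", id, "' has no canonical residues")
    } else {
      stop("non-canonical residue '", chars[bad[1]], "' at position ", bad[1],
           " in sequence '", id, "'")
    }
  }
  structure(list(id = id, tokens = as.integer(idx), L = length(idx)),
            class = "thermlm_tokens")
}

#' Detokenize back to a residue string
#'
#' Inverse of [tokenize()] for canonical residues; the mask token renders as
#' `#` and pad as `-` so corrupted sequences remain printable.
#'
#' @param tokens A `thermlm_tokens` object or integer vector.
#' @param vocab A vocabulary from [aa_vocab()].
#' @return A character string.
#' @export
detokenize <- function(tokens, vocab = aa_vocab()) {
  if (inherits(tokens, "thermlm_tokens")) tokens <- tokens$tokens
  symbols <- c(vocab$residues, "#", "-")
  if (any(tokens < 1L | tokens > vocab$size)) stop("token index out of range")
  paste(symbols[tokens], collapse = "")
}

#' @export
print.thermlm_tokens <- function(x, ...) {
  cat("<thermlm_tokens> id=", x$id, " L=", x$L, "\n", sep = "")
  invisible(x)
}

#' Background amino-acid frequencies
#'
#' Default substitution distribution for the noising scheme, mirroring the
#' natural amino-acid composition reported for the UniProtKB/Swiss-Prot
#' database (release-level averages, rounded; renormalized to sum to 1).
#' Override via [read_background_csv()] or any named simplex.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
background_frequencies <- function() {
  f <- c(A = 0.0826, C = 0.0138, D = 0.0546, E = 0.0672, F = 0.0387,
         G = 0.0708, H = 0.0227, I = 0.0591, K = 0.0580, L = 0.0965,
         M = 0.0241, N = 0.0406, P = 0.0474, Q = 0.0393, R = 0.0553,
         S = 0.0665, T = 0.0536, V = 0.0686, W = 0.0110, Y = 0.0292)
  f / sum(f)
}

#' Read background frequencies from a two-column CSV
#'
#' @param path CSV with columns `residue` and `probability`.
#' @param vocab A vocabulary from [aa_vocab()].
#' @return Named numeric vector over the 20 residues, renormalized.
#' @export
read_background_csv <- function(path, vocab = aa_vocab()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "probability") %in% names(df)))
    stop("background CSV needs columns 'residue' and 'probability'")
  bg <- stats::setNames(rep(0, 20), vocab$residues)
  unknown <- setdiff(df$residue, vocab$residues)
  if (length(unknown) > 0L)
    stop("unknown residues in background CSV: ", paste(unknown, collapse = ", "))
  bg[df$residue] <- df$probability
  if (any(bg < 0) || sum(bg) <= 0) stop("background frequencies must be a nonnegative, non-degenerate vector")
  bg / sum(bg)
}

# Validate a background-frequency vector against the vocabulary order.
check_background <- function(bg, vocab = aa_vocab()) {
  if (is.null(names(bg))) names(bg) <- vocab$residues
  bg <- bg[vocab$residues]
  if (anyNA(bg) || any(bg < 0)) stop("invalid background frequencies")
  s <- sum(bg)
  if (s <= 0) stop("degenerate background frequencies (all zero)")
  bg / s
}
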