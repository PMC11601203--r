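#' Parse a variant notation string
#'
#' Accepts the usual mutant notation (`"Q786L"`, `"Q786L;S430P"`, also with
#' `':'` separators and optional whitespace, as in ProteinGym-style files).
#' Wild-type letters are validated against the supplied wild-type sequence;
#' mutations are sorted by position and duplicate positions rejected.
#'
#' @param text Variant string; one or more `<wt><pos><mut>` tokens.
#' @param wild_type Wild-type sequence: a string or `thermlm_tokens`.
#' @return A `thermlm_variant`: `mutations` data.frame (`pos`, `wt`, `mut`),
#'   `string` (canonical `';'`-joined, position-sorted form), `n` (order).
#' @export
parse_variant <- function(text, wild_type) {
  wt_chars <- wild_type_chars(wild_type)
  stopifnot(is.character(text), length(text) == 1L, nzchar(trimws(text)))
  toks <- strsplit(text, "[;:]")[[1]]
  toks <- trimws(toks)
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) stop("empty variant string")
  m <- regmatches(toks, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", toks))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad) > 0L)
    stop("malformed mutation token '", toks[bad[1]], "'")
  pos <- vapply(m, function(x) as.integer(x[3]), integer(1))
  wt <- toupper(vapply(m, function(x) x[2], character(1)))
  mut <- toupper(vapply(m, function(x) x[4], character(1)))
  if (any(pos < 1L | pos > length(wt_chars)))
    stop("mutation position out of range [1, ", length(wt_chars), "]")
  mismatch <- which(wt != wt_chars[pos])
  if (length(mismatch) > 0L) {
    i <- mismatch[1]
    stop("wild-type mismatch at position ", pos[i], ": variant says '",
         wt[i], "' but wild type has '", wt_chars[pos[i]], "'")
  }
  if (anyDuplicated(pos))
    stop("duplicate mutation position: ", pos[which(duplicated(pos))[1]])
  o <- order(pos)
  new_variant(data.frame(pos = pos[o], wt = wt[o], mut = mut[o],
                         stringsAsFactors = FALSE))
}

new_variant <- function(mutations) {
  string <- if (nrow(mutations) == 0L) "" else
    paste0(mutations$wt, mutations$pos, mutations$mut, collapse = ";")
  structure(list(mutations = mutations, string = string, n = nrow(mutations)),
            class = "thermlm_variant")
}

wild_type_chars <- function(wild_type) {
  if (inherits(wild_type, "thermlm_tokens"))
    return(strsplit(detokenize(wild_type), "")[[1]])
  strsplit(toupper(wild_type), "")[[1]]
}

#' Apply a variant to a wild-type sequence
#'
#' @param wild_type A `thermlm_tokens` wild-type sequence.
#' @param variant A `thermlm_variant` (or notation string).
#' @return A `thermlm_tokens` mutant sequence.
#' @export
apply_variant <- function(wild_type, variant) {
  stopifnot(inherits(wild_type, "thermlm_tokens"))
  if (is.character(variant)) variant <- parse_variant(variant, wild_type)
  vocab <- aa_vocab()
  tk <- wild_type$tokens
  if (variant$n > 0L)
    tk[variant$mutations$pos] <- unname(vocab$index[variant$mutations$mut])
  structure(list(id = paste0(wild_type$id, if (variant$n) paste0(":", variant$string)),
                 tokens = tk, L = wild_type$L),
            class = "thermlm_tokens")
}

#' @export
print.thermlm_variant <- function(x, ...) {
  cat("<thermlm_variant> ", if (nzchar(x$string)) x$string else "(wild type)",
      "\n", sep = "")
  invisible(x)
}

# Treat a single model as an ensemble of one.
as_model_list <- function(model) {
  if (inherits(model, "thermlm_model")) list(model)
  else if (inherits(model, "thermlm_ensemble")) model$members
  else if (is.list(model) && all(vapply(model, inherits, logical(1), "thermlm_model"))) model
  else stop("expected a thermlm_model, thermlm_ensemble, or list of models")
}

# Per-model log-probability matrix at every position of the wild type.
# wt-marginal: one unmasked pass. masked-marginal: L passes, position i masked.
logprob_matrix <- function(model, wild_type,
                           mode = c("wt-marginal", "masked-marginal")) {
  mode <- match.arg(mode)
  if (mode == "wt-marginal") {
    return(mlm_distributions(model, encode(model, wild_type)$H, log = TRUE))
  }
  L <- wild_type$L
  out <- matrix(NA_real_, L, model$vocab$n_residues)
  for (i in seq_len(L)) {
    tk <- wild_type$tokens
    tk[i] <- model$vocab$mask
    out[i, ] <- mlm_distributions(model, encode(model, tk)$H, log = TRUE)[i, ]
  }
  colnames(out) <- model$vocab$residues
  out
}

#' Zero-shot log-odds score of a single mutation
#'
#' `Score(i, m | w) = log P(x_i = m | X) - log P(x_i = w | X)` (natural log),
#' with the probabilities read from the MLM head. The default
#' `"wt-marginal"` mode uses one forward pass on the intact wild type;
#' `"masked-marginal"` masks position `i` first. For an ensemble the member
#' scores are averaged.
#'
#' @param model A `thermlm_model`, ensemble, or list of models.
#' @param wild_type A `thermlm_tokens` wild-type sequence.
#' @param mutation A one-mutation `thermlm_variant`, a notation string
#'   (`"A2C"`), or a list with `pos` and `mut`.
#' @param mode Scoring mode.
#' @return Scalar log-odds score (0 when `m == w`).
#' @export
score_single <- function(model, wild_type, mutation,
                         mode = c("wt-marginal", "masked-marginal")) {
  mode <- match.arg(mode)
  if (is.character(mutation)) mutation <- parse_variant(mutation, wild_type)
  if (inherits(mutation, "thermlm_variant")) {
    if (mutation$n != 1L) stop("score_single expects exactly one mutation")
    pos <- mutation$mutations$pos; mut <- mutation$mutations$mut
  } else {
    pos <- mutation$pos; mut <- mutation$mut
  }
  if (pos < 1L || pos > wild_type$L) stop("position out of range")
  members <- as_model_list(model)
  vocab <- members[[1]]$vocab
  wt_tok <- wild_type$tokens[pos]
  mut_tok <- unname(vocab$index[mut])
  mean(vapply(members, function(m) {
    lp <- logprob_matrix(m, wild_type, mode)
    lp[pos, mut_tok] - lp[pos, wt_tok]
  }, numeric(1)))
}

#' Zero-shot score of a (possibly multisite) variant
#'
#' In zero-shot mode the multisite score is the sum of the constituent
#' single-site log-odds scores (the additive rule); the empty variant scores
#' 0. With `regressor` supplied, the fully mutated sequence is routed through
#' the fitted supervised regressor instead.
#'
#' @param model A model/ensemble (ignored when `regressor` is given).
#' @param wild_type A `thermlm_tokens`.
#' @param variant A `thermlm_variant` or notation string.
#' @param mode Scoring mode for the additive zero-shot path.
#' @param regressor Optional fitted regressor from [fit_regressor()].
#' @return Scalar score.
#' @export
score_variant <- function(model, wild_type, variant,
                          mode = c("wt-marginal", "masked-marginal"),
                          regressor = NULL) {
  mode <- match.arg(mode)
  if (is.character(variant)) variant <- parse_variant(variant, wild_type)
  if (!is.null(regressor))
    return(predict_fitness(regressor, wild_type, list(variant)))
  if (variant$n == 0L) return(0)
  members <- as_model_list(model)
  vocab <- members[[1]]$vocab
  mean(vapply(members, function(m) {
    lp <- logprob_matrix(m, wild_type, mode)
    sum(lp[cbind(variant$mutations$pos, unname(vocab$index[variant$mutations$mut]))] -
        lp[cbind(variant$mutations$pos, unname(vocab$index[variant$mutations$wt]))])
  }, numeric(1)))
}

#' Saturation scan: score all single-site substitutions
#'
#' Scores all `19 * L` substitutions of the wild type. In `"wt-marginal"`
#' mode each ensemble member contributes exactly one encoder pass, reused
#' across all positions; `"masked-marginal"` needs `L` passes per member.
#'
#' @inheritParams score_single
#' @param source Provenance tag recorded in the scorecard.
#' @return A scorecard `data.frame` with columns `variant`, `score`, `rank`,
#'   `n_mutations`, `source`, ordered by descending score (ties broken by the
#'   canonical variant string).
#' @export
score_saturation <- function(model, wild_type,
                             mode = c("wt-marginal", "masked-marginal"),
                             source = "zero-shot") {
  mode <- match.arg(mode)
  members <- as_model_list(model)
  vocab <- members[[1]]$vocab
  L <- wild_type$L
  acc <- matrix(0, L, vocab$n_residues)
  for (m in members) {
    lp <- logprob_matrix(m, wild_type, mode)
    acc <- acc + (lp - lp[cbind(seq_len(L), wild_type$tokens)])
  }
  acc <- acc / length(members)
  wt_chars <- vocab$residues[wild_type$tokens]
  rows <- expand.grid(pos = seq_len(L), mut = vocab$residues,
                      stringsAsFactors = FALSE)
  rows$wt <- wt_chars[rows$pos]
  rows <- rows[rows$wt != rows$mut, ]
  rows$score <- acc[cbind(rows$pos, unname(vocab$index[rows$mut]))]
  sc <- data.frame(variant = paste0(rows$wt, rows$pos, rows$mut),
                   score = rows$score, n_mutations = 1L,
                   source = source, stringsAsFactors = FALSE)
  rank_scorecard(sc)
}

# Order by descending score, ties by canonical string; assign ranks 1..n.
rank_scorecard <- function(sc) {
  o <- order(-sc$score, sc$variant, method = "radix")
  sc <- sc[o, , drop = FALSE]
  sc$rank <- seq_len(nrow(sc))
  rownames(sc) <- NULL
  sc[, c("variant", "score", "rank", "n_mutations", "source")]
}

#' Read a per-residue coordinate table
#'
#' CSV with columns `position, x, y, z` (angstroms), repeated rows per atom.
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_coordinates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("position", "x", "y", "z")
  if (!all(need %in% names(df))) stop("coordinate CSV needs columns position,x,y,z")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  df
}

#' Drop candidates near active sites
#'
#' Removes scorecard rows whose mutations lie within `radius` angstroms
#' (minimum point-to-point distance, closed threshold: exactly `radius` is
#' excluded) of any active-site residue. Candidates whose positions lack
#' coordinates are retained with a warning.
#'
#' @param scorecard A scorecard data.frame (from [score_saturation()] etc.).
#' @param coords Coordinate table (see [read_coordinates_csv()]).
#' @param active_sites Integer vector of active-site positions.
#' @param radius Exclusion radius in angstroms (default 6.0).
#' @return The filtered scorecard, re-ranked.
#' @export
exclude_near_sites <- function(scorecard, coords, active_sites, radius = 6.0) {
  if (length(active_sites) == 0L) return(rank_scorecard(scorecard))
  missing_as <- setdiff(active_sites, coords$position)
  if (length(missing_as) > 0L)
    stop("no coordinates for active-site position(s): ",
         paste(missing_as, collapse = ", "))
  as_pts <- as.matrix(coords[coords$position %in% active_sites,
                             c("x", "y", "z"), drop = FALSE])
  # min distance from each coordinate-bearing position to the active set
  pos_list <- split(seq_len(nrow(coords)), coords$position)
  min_dist <- vapply(pos_list, function(ix) {
    pts <- as.matrix(coords[ix, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(pts^2), rowSums(as_pts^2), `+`) - 2 * pts %*% t(as_pts)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  var_positions <- lapply(scorecard$variant, function(v) {
    as.integer(regmatches(v, gregexpr("[0-9]+", v))[[1]])
  })
  has_coords <- vapply(var_positions, function(ps)
    all(as.character(ps) %in% names(min_dist)), logical(1))
  if (any(!has_coords))
    warning(sum(!has_coords), " candidate(s) lack coordinates and were retained")
  near <- vapply(seq_along(var_positions), function(i) {
    if (!has_coords[i]) return(FALSE)
    any(min_dist[as.character(var_positions[[i]])] <= radius)
  }, logical(1))
  rank_scorecard(scorecard[!near, , drop = FALSE])
}

#' Select the top-K candidates from a scorecard
#'
#' Stable descending-score selection with lexicographic tie-break on the
#' canonical variant string. With `quota` given (named by mutation order,
#' e.g. `c("2" = 10, "3" = 10)`), at most that many variants are taken from
#' each order; `K` then caps the total (default: sum of quotas).
#'
#' @param scorecard A scorecard data.frame.
#' @param K Number of variants to select; if larger than the pool the whole
#'   pool is returned.
#' @param quota Optional named vector of per-order counts.
#' @return The selected rows, re-ranked within the selection.
#' @export
select_top_k <- function(scorecard, K = NULL, quota = NULL) {
  sc <- rank_scorecard(scorecard)
  if (!is.null(quota)) {
    keep <- unlist(lapply(names(quota), function(ord) {
      rows <- which(sc$n_mutations == as.integer(ord))
      utils::head(rows, quota[[ord]])
    }))
    sc <- sc[sort(keep), , drop = FALSE]
  }
  if (is.null(K)) K <- nrow(sc)
  if (K < 1L) stop("K must be >= 1")
  rank_scorecard(utils::head(sc, K))
}

#' Write / read a scorecard CSV
#'
#' @param scorecard A scorecard data.frame.
#' @param path CSV path.
#' @export
write_scorecard_csv <- function(scorecard, path) {
  utils::write.csv(scorecard, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scorecard_csv
#' @export
read_scorecard_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
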