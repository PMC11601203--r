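# Iterative multisite stacking campaign and the in-silico directed-evolution
# harness. Candidate pools are combinations of labeled single mutations
# (mutations at the same position never co-occur); pools beyond the
# enumeration cap are subsampled uniformly with a seeded draw.

#' Enumerate position-compatible combinations of single mutations
#'
#' All variants obtainable by combining the given single mutations at `k`
#' sites for `k` in `orders`, never combining two mutations at the same
#' position. If the pool would exceed `cap`, a seeded uniform subsample of
#' size `cap` is drawn instead (with a message).
#'
#' @param singles data.frame with columns `pos`, `wt`, `mut` (one row per
#'   single mutation), or a character vector of single-mutation strings with
#'   `wild_type` supplied.
#' @param orders Integer vector of combination orders (e.g. `2:4`).
#' @param cap Maximum pool size (default 200000).
#' @param seed Subsampling seed.
#' @param wild_type Needed only when `singles` is a character vector.
#' @return data.frame with `variant` (canonical string) and `n_mutations`.
#' @export
enumerate_combinations <- function(singles, orders, cap = 200000L, seed = 1L,
                                   wild_type = NULL) {
  if (is.character(singles)) {
    stopifnot(!is.null(wild_type))
    ml <- lapply(singles, function(s) parse_variant(s, wild_type)$mutations)
    singles <- do.call(rbind, ml)
  }
  if (nrow(singles) == 0L) stop("empty single-mutation set")
  orders <- sort(unique(as.integer(orders)))
  groups <- split(seq_len(nrow(singles)), singles$pos)
  sizes <- vapply(groups, length, integer(1))
  P <- length(groups)
  # counts per order: elementary symmetric polynomials of the group sizes
  ek <- elementary_symmetric(sizes, max(orders))
  counts <- ek[pmin(orders, P) + 1L]
  counts[orders > P] <- 0
  total <- sum(counts)
  if (total == 0) stop("no combinations possible at the requested orders")
  canon <- function(rows) {
    rows <- rows[order(rows$pos), , drop = FALSE]
    paste0(rows$wt, rows$pos, rows$mut, collapse = ";")
  }
  if (total <= cap) {
    out <- lapply(orders[orders <= P], function(k) {
      subsets <- utils::combn(P, k, simplify = FALSE)
      unlist(lapply(subsets, function(gi) {
        grid <- expand.grid(lapply(groups[gi], identity), stringsAsFactors = FALSE)
        apply(grid, 1, function(ix) canon(singles[as.integer(ix), , drop = FALSE]))
      }))
    })
    variants <- unlist(out)
  } else {
    message("combination pool size ", total, " exceeds cap ", cap,
            "; drawing a seeded uniform subsample")
    variants <- with_seed(derive_seed(seed, "enum"), {
      drawn <- character(0)
      guard <- 0L
      while (length(drawn) < cap && guard < 50L) {
        k <- sample(orders[counts > 0], cap, replace = TRUE,
                    prob = counts[counts > 0])
        new <- vapply(k, function(kk) {
          gi <- sample_subset_weighted(sizes, kk)
          ix <- vapply(gi, function(g) sample(groups[[g]], 1L), integer(1))
          canon(singles[ix, , drop = FALSE])
        }, character(1))
        drawn <- unique(c(drawn, new))
        guard <- guard + 1L
      }
      utils::head(drawn, cap)
    })
  }
  n_mut <- lengths(strsplit(variants, ";", fixed = TRUE))
  data.frame(variant = variants, n_mutations = n_mut, stringsAsFactors = FALSE)
}

# e_0..e_kmax of the sizes vector via the standard DP recurrence.
elementary_symmetric <- function(sizes, kmax) {
  e <- c(1, rep(0, kmax))
  for (s in sizes) {
    for (k in rev(seq_len(kmax))) e[k + 1] <- e[k + 1] + s * e[k]
  }
  e
}

# Draw a uniform k-subset of groups weighted by product of group sizes
# (exact, via the DP table).
sample_subset_weighted <- function(sizes, k) {
  P <- length(sizes)
  E <- matrix(0, P + 1L, k + 1L)
  E[, 1] <- 1
  for (i in seq_len(P)) {
    for (j in seq_len(k)) {
      E[i + 1L, j + 1L] <- E[i, j + 1L] + sizes[i] * E[i, j]
    }
  }
  chosen <- integer(0)
  j <- k
  for (i in rev(seq_len(P))) {
    if (j == 0L) break
    p_take <- sizes[i] * E[i, j] / E[i + 1L, j + 1L]
    if (stats::runif(1) < p_take) {
      chosen <- c(i, chosen)
      j <- j - 1L
    }
  }
  chosen
}

#' Selection metrics for a measured batch
#'
#' @param fitness Measured fitness of the selected variants.
#' @param wt_fitness Wild-type fitness on the same scale.
#' @return List: `n_positive` (strictly above wild type), `max_fitness`,
#'   `median_fitness`.
#' @export
evaluate_selection <- function(fitness, wt_fitness) {
  if (length(fitness) < 1L) stop("empty selection")
  list(n_positive = sum(fitness > wt_fitness),
       max_fitness = max(fitness),
       median_fitness = stats::median(fitness))
}

# --- ridge baseline scorer ---------------------------------------------------

# Binary indicator features: which of the reference singles each variant
# contains (variants are combinations of those singles).
mutation_indicators <- function(variants, singles) {
  keys <- paste0(singles$wt, singles$pos, singles$mut)
  X <- matrix(0, length(variants), length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(variants)) {
    parts <- strsplit(variants[i], ";", fixed = TRUE)[[1]]
    X[i, intersect(parts, keys)] <- 1
  }
  X
}

# Closed-form ridge regression on indicator features (intercept unpenalized).
ridge_scorer <- function(train_variants, train_y, singles, lambda = 1e-2) {
  X <- cbind(1, mutation_indicators(train_variants, singles))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))
  beta <- solve(crossprod(X) + pen, crossprod(X, train_y))
  function(variants) {
    drop(cbind(1, mutation_indicators(variants, singles)) %*% beta)
  }
}

# --- design rounds -----------------------------------------------------------

#' Start a design-campaign state
#'
#' @param wild_type Wild-type sequence string.
#' @return A `thermlm_design_state` with an empty cumulative label set.
#' @export
design_state <- function(wild_type) {
  structure(list(wild_type = wild_type,
                 wt_tokens = tokenize(wild_type, id = "wt"),
                 round = 0L,
                 labels = data.frame(variant = character(0), fitness = numeric(0),
                                     n_mutations = integer(0), round = integer(0),
                                     stringsAsFactors = FALSE),
                 selections = list()),
            class = "thermlm_design_state")
}

#' Record measured labels into the state
#'
#' @param state A `thermlm_design_state`.
#' @param variants Variant strings.
#' @param fitness Measured fitness values.
#' @param round Round tag.
#' @return Updated state (the cumulative training set strictly grows).
#' @export
add_labels <- function(state, variants, fitness, round = state$round) {
  stopifnot(length(variants) == length(fitness))
  dup <- intersect(variants, state$labels$variant)
  if (length(dup) > 0L)
    stop("variant(s) already labeled: ", paste(utils::head(dup, 3), collapse = ", "))
  n_mut <- lengths(strsplit(variants, ";", fixed = TRUE))
  state$labels <- rbind(state$labels,
                        data.frame(variant = variants, fitness = fitness,
                                   n_mutations = n_mut, round = round,
                                   stringsAsFactors = FALSE))
  state
}

#' Run one supervised design round
#'
#' Fits a scorer on the cumulative labels, enumerates the multisite pool from
#' the labeled single mutations, scores it, and selects per quota, excluding
#' variants that already carry labels. The selection (with predicted scores)
#' is appended to the state; measured labels are added afterwards with
#' [add_labels()].
#'
#' @param state A `thermlm_design_state` holding labeled records.
#' @param model Backbone `thermlm_model` (used by the `"regressor"` scorer).
#' @param orders Combination orders for this round's pool.
#' @param quota Named per-order selection counts (see [select_top_k()]).
#' @param scorer `"regressor"` (frozen-backbone FC3/FC4 protocol),
#'   `"ridge"` (indicator-feature baseline), or a function
#'   `f(variant_strings) -> scores` (e.g. a perfect oracle).
#' @param cfg A [regressor_config()] (regressor scorer only).
#' @param seed Round seed.
#' @param cap Enumeration cap.
#' @param cache Optional feature-cache environment shared across rounds.
#' @return List: `state` (updated) and `selection` (data.frame with
#'   `variant`, `score`, `n_mutations`).
#' @export
run_design_round <- function(state, model = NULL, orders, quota,
                             scorer = "regressor", cfg = regressor_config(),
                             seed = 1L, cap = 200000L, cache = NULL) {
  labels <- state$labels
  singles <- labels[labels$n_mutations == 1L, ]
  if (nrow(singles) == 0L) stop("no labeled single mutations to combine")
  smut <- do.call(rbind, lapply(singles$variant, function(v)
    parse_variant(v, state$wild_type)$mutations))
  pool <- enumerate_combinations(smut, orders, cap = cap, seed = seed)
  pool <- pool[!(pool$variant %in% labels$variant), , drop = FALSE]
  if (nrow(pool) == 0L) stop("candidate pool is empty after exclusions")
  score_fun <- if (is.function(scorer)) {
    scorer
  } else if (identical(scorer, "ridge")) {
    if (nrow(labels) < 2L) stop("ridge scorer needs at least 2 labels")
    ridge_scorer(labels$variant, labels$fitness, smut)
  } else if (identical(scorer, "regressor")) {
    if (is.null(model)) stop("regressor scorer needs the backbone model")
    reg <- fit_regressor(model, state$wt_tokens, labels, cfg,
                         seed = derive_seed(seed, "round", state$round + 1L),
                         cache = cache)
    function(vs) predict_fitness(reg, state$wt_tokens, as.list(vs), cache = cache)
  } else stop("unknown scorer")
  sc <- data.frame(variant = pool$variant, score = score_fun(pool$variant),
                   n_mutations = pool$n_mutations, source = "design",
                   stringsAsFactors = FALSE)
  want <- sum(unlist(quota))
  sel <- select_top_k(sc, quota = quota)
  if (nrow(sel) < want)
    warning("quota asked for ", want, " variants but only ", nrow(sel),
            " were available")
  state$round <- state$round + 1L
  state$selections[[length(state$selections) + 1L]] <-
    list(round = state$round, selection = sel)
  list(state = state, selection = sel[, c("variant", "score", "n_mutations")])
}

#' Run a full iterative design campaign against an oracle
#'
#' Round 0 scores all single-site substitutions zero-shot (saturation
#' log-odds), selects the top `round0_k` singles, and "measures" them with
#' the oracle. Each subsequent round fits the scorer on all accumulated
#' labels, enumerates multisite combinations of the labeled singles, selects
#' per quota, and measures the selection. The report tracks the best
#' measured fitness so far after every round.
#'
#' @param model A `thermlm_model` or ensemble (zero-shot round and
#'   `"regressor"` scorer).
#' @param wild_type Wild-type sequence string.
#' @param oracle Function `f(variant_string) -> fitness` (e.g.
#'   `function(v) landscape_fitness(ls, v)`), or a function of a vector.
#' @param rounds List of per-round specs, each `list(orders = , quota = )`.
#' @param round0_k Singles selected in the zero-shot round.
#' @param candidate_singles Optional restriction of the zero-shot round to a
#'   predefined set of candidate single mutations (variant strings or a
#'   data.frame with `pos`, `wt`, `mut`), e.g. a landscape's designated
#'   single set; by default all `19 * L` substitutions compete.
#' @param scorer `"regressor"`, `"ridge"`, or a scoring function.
#' @param cfg A [regressor_config()].
#' @param seed Campaign seed.
#' @return A `thermlm_design_report`: `state`, `per_round` (data.frame with
#'   round, n_selected, best_in_round, best_so_far), `best_variant`.
#' @export
run_design_campaign <- function(model, wild_type, oracle,
                                rounds = list(
                                  list(orders = 2:4,
                                       quota = c("2" = 10, "3" = 10, "4" = 10)),
                                  list(orders = 3:6,
                                       quota = c("3" = 5, "4" = 5, "5" = 5, "6" = 5))),
                                round0_k = 15L, scorer = "regressor",
                                cfg = regressor_config(), seed = 1L,
                                candidate_singles = NULL) {
  oracle_v <- function(vs) vapply(vs, function(v) oracle(v), numeric(1))
  state <- design_state(wild_type)
  wt_tok <- state$wt_tokens
  # round 0: zero-shot singles
  sc0 <- score_saturation(model, wt_tok)
  if (!is.null(candidate_singles)) {
    keys <- if (is.data.frame(candidate_singles)) {
      paste0(candidate_singles$wt, candidate_singles$pos, candidate_singles$mut)
    } else candidate_singles
    sc0 <- sc0[sc0$variant %in% keys, , drop = FALSE]
  }
  sel0 <- select_top_k(sc0, K = round0_k)
  state <- add_labels(state, sel0$variant, oracle_v(sel0$variant), round = 0L)
  state$selections[[1]] <- list(round = 0L, selection = sel0)
  per_round <- data.frame(round = 0L, n_selected = nrow(sel0),
                          best_in_round = max(state$labels$fitness),
                          best_so_far = max(state$labels$fitness))
  cache <- new.env(parent = emptyenv())
  for (r in seq_along(rounds)) {
    rr <- run_design_round(state, model, orders = rounds[[r]]$orders,
                           quota = rounds[[r]]$quota, scorer = scorer,
                           cfg = cfg, seed = derive_seed(seed, "campaign", r),
                           cache = cache)
    state <- rr$state
    fit <- oracle_v(rr$selection$variant)
    state <- add_labels(state, rr$selection$variant, fit, round = state$round)
    per_round <- rbind(per_round,
                       data.frame(round = state$round,
                                  n_selected = nrow(rr$selection),
                                  best_in_round = max(fit),
                                  best_so_far = max(state$labels$fitness)))
  }
  best <- state$labels[which.max(state$labels$fitness), ]
  structure(list(state = state, per_round = per_round,
                 best_variant = best$variant, best_fitness = best$fitness,
                 seed = seed),
            class = "thermlm_design_report")
}

#' In-silico directed evolution harness
#'
#' Compares acquisition strategies on a fully enumerable landscape built
#' from the landscape's designated single mutations. Each replicate runs
#' `rounds` rounds with a per-round budget: round 1 selects by the additive
#' zero-shot proxy (sum of single-mutation effects), later rounds select by
#' a ridge model trained on everything measured so far. Samplers: `"top-k"`
#' (highest scores), `"random"` (uniform), `"stratified"`
#' (score-quantile-stratified: equal draws per quartile).
#'
#' @param landscape A [make_landscape()].
#' @param samplers Character vector among `"top-k"`, `"random"`,
#'   `"stratified"`.
#' @param replicates Number of replicates (default 100).
#' @param rounds Rounds per replicate (default 2).
#' @param budget Variants measured per round (default 50).
#' @param max_order Cap on combination order for the enumerated pool
#'   (default: all orders up to the number of singles).
#' @param seed Harness seed.
#' @return List: `summary` (data.frame sampler x round with mean and max of
#'   cumulative best/mean fitness across replicates) and `config` echo.
#' @export
simulate_directed_evolution <- function(landscape,
                                        samplers = c("top-k", "random", "stratified"),
                                        replicates = 100L, rounds = 2L,
                                        budget = 50L, max_order = NULL,
                                        seed = 1L) {
  singles <- landscape$singles
  N <- nrow(singles)
  max_order <- min(max_order %||% N, N)
  pool <- enumerate_combinations(singles[, c("pos", "wt", "mut")],
                                 orders = seq_len(max_order))
  if (budget > nrow(pool)) stop("budget exceeds the landscape size")
  truth <- vapply(pool$variant, function(v)
    landscape_fitness(landscape, v, noise = FALSE), numeric(1))
  measured <- vapply(pool$variant, function(v)
    landscape_fitness(landscape, v, noise = TRUE), numeric(1))
  additive_proxy <- drop(mutation_indicators(pool$variant, singles) %*% singles$effect)
  pick <- function(scores, avail, k, sampler, rep_seed) {
    av <- which(avail)
    if (length(av) <= k) return(av)
    if (sampler == "random")
      return(with_seed(rep_seed, sample(av, k)))
    if (sampler == "top-k")
      return(av[order(-scores[av])][seq_len(k)])
    # stratified: equal draws per score quartile
    q <- stats::quantile(scores[av], probs = c(0.25, 0.5, 0.75))
    strata <- findInterval(scores[av], q) + 1L
    with_seed(rep_seed, {
      out <- integer(0)
      per <- ceiling(k / 4)
      for (s in 1:4) {
        cand <- av[strata == s]
        out <- c(out, if (length(cand) <= per) cand else sample(cand, per))
      }
      if (length(out) > k) out <- with_seed(rep_seed + 1L, sample(out, k))
      # top up from the best remaining if strata ran short
      if (length(out) < k) {
        rest <- setdiff(av, out)
        out <- c(out, rest[order(-scores[rest])][seq_len(k - length(out))])
      }
      out
    })
  }
  rows <- list()
  for (sampler in samplers) {
    best_mat <- matrix(NA_real_, replicates, rounds)
    mean_mat <- matrix(NA_real_, replicates, rounds)
    for (rep in seq_len(replicates)) {
      avail <- rep(TRUE, nrow(pool))
      labeled <- integer(0)
      for (rd in seq_len(rounds)) {
        scores <- if (rd == 1L) additive_proxy else {
          sf <- ridge_scorer(pool$variant[labeled], measured[labeled], singles)
          sf(pool$variant)
        }
        sel <- pick(scores, avail, budget, sampler,
                    derive_seed(seed, sampler, rep, rd))
        avail[sel] <- FALSE
        labeled <- c(labeled, sel)
        best_mat[rep, rd] <- max(truth[labeled])
        mean_mat[rep, rd] <- mean(truth[sel])
      }
    }
    rows[[sampler]] <- data.frame(sampler = sampler, round = seq_len(rounds),
                                  mean_max_fitness = colMeans(best_mat),
                                  mean_mean_fitness = colMeans(mean_mat),
                                  max_max_fitness = apply(best_mat, 2, max))
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       config = list(replicates = replicates, rounds = rounds, budget = budget,
                     n_singles = N, pool_size = nrow(pool), seed = seed))
}

#' Save / resume a design-campaign state
#'
#' A campaign waiting for wet-lab labels can be persisted and resumed later:
#' write the state after selecting a round, collect measurements, reload,
#' [add_labels()], and run the next round.
#'
#' @param state A `thermlm_design_state`.
#' @param path State file path.
#' @export
save_design_state <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_design_state
#' @export
load_design_state <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "thermlm_design_state")) stop("not a design-state file")
  state
}
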