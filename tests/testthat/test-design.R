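toy_singles <- function(n, L = 40L, seed = 1L) {
  make_landscape(wild_type = random_seq(L, seed = seed), n_singles = n,
                 seed = seed)$singles
}

# Brute-force oracle: count position-compatible k-subsets by enumerating all
# index subsets and filtering duplicated positions.
brute_count <- function(singles, k) {
  if (k > nrow(singles)) return(0L)
  sum(vapply(utils::combn(nrow(singles), k, simplify = FALSE),
             function(ix) !anyDuplicated(singles$pos[ix]), logical(1)))
}

test_that("combination counts match closed forms and the brute-force oracle", {
  s4 <- toy_singles(4, seed = 2)
  pool <- enumerate_combinations(s4[, c("pos", "wt", "mut")], orders = 2:4)
  expect_identical(nrow(pool), 11L)  # C(4,2) + C(4,3) + C(4,4)
  s6 <- toy_singles(6, seed = 3)
  pool6 <- enumerate_combinations(s6[, c("pos", "wt", "mut")], orders = 1:6)
  expect_identical(nrow(pool6), 63L)  # 2^6 - 1
  expect_false(any(duplicated(pool6$variant)))
  # random instances with several mutations per position, N <= 12
  for (rep in 1:4) {
    base <- toy_singles(6, seed = 10 + rep)
    extra <- base[1:3, ]
    v <- aa_vocab()
    extra$mut <- vapply(seq_len(3), function(i)
      setdiff(v$residues, c(base$wt[i], base$mut[i]))[rep], character(1))
    singles <- rbind(base, extra)[, c("pos", "wt", "mut")]
    pool <- enumerate_combinations(singles, orders = 2:3)
    expect_identical(nrow(pool), brute_count(singles, 2L) + brute_count(singles, 3L))
    # no variant carries two mutations at one position
    pos_lists <- lapply(strsplit(pool$variant, ";"), function(x)
      as.integer(gsub("[A-Z]", "", x)))
    expect_false(any(vapply(pos_lists, anyDuplicated, integer(1)) > 0L))
  }
})

test_that("pools beyond the cap are subsampled deterministically", {
  s12 <- toy_singles(12, seed = 4)[, c("pos", "wt", "mut")]
  expect_message(p1 <- enumerate_combinations(s12, orders = 2:6, cap = 200L,
                                              seed = 9), "subsample")
  expect_identical(nrow(p1), 200L)
  expect_false(any(duplicated(p1$variant)))
  p2 <- suppressMessages(enumerate_combinations(s12, orders = 2:6, cap = 200L,
                                                seed = 9))
  expect_identical(p1, p2)
  p3 <- suppressMessages(enumerate_combinations(s12, orders = 2:6, cap = 200L,
                                                seed = 10))
  expect_false(identical(p1$variant, p3$variant))
})

test_that("selection metrics count strict improvements over wild type", {
  met <- evaluate_selection(c(1.2, 0.8, 1.5), wt_fitness = 1.0)
  expect_identical(met$n_positive, 2L)
  expect_identical(met$max_fitness, 1.5)
  expect_identical(met$median_fitness, 1.2)
  expect_identical(evaluate_selection(c(0.1, 0.2), 1)$n_positive, 0L)
  one <- evaluate_selection(3.3, 1)
  expect_identical(one$max_fitness, one$median_fitness)
  expect_error(evaluate_selection(numeric(0), 1), "empty")
})

test_that("a perfect scorer selects the true top of the pool, excluding labeled", {
  ls <- make_landscape(wild_type = random_seq(40, seed = 8), n_singles = 8L,
                       noise_sd = 0, seed = 8)
  singles <- paste0(ls$singles$wt, ls$singles$pos, ls$singles$mut)
  state <- design_state(ls$wild_type)
  state <- add_labels(state, singles,
                      vapply(singles, function(v) landscape_fitness(ls, v),
                             numeric(1)), round = 0L)
  oracle <- function(vs) vapply(vs, function(v)
    landscape_fitness(ls, v, noise = FALSE), numeric(1))
  res <- run_design_round(state, orders = 2:3, quota = c("2" = 4, "3" = 4),
                          scorer = oracle, seed = 1)
  pool <- enumerate_combinations(ls$singles[, c("pos", "wt", "mut")],
                                 orders = 2:3)
  truth <- oracle(pool$variant)
  for (k in c(2L, 3L)) {
    sel_k <- res$selection$variant[res$selection$n_mutations == k]
    top_k <- pool$variant[pool$n_mutations == k][
      order(-truth[pool$n_mutations == k])][1:4]
    expect_setequal(sel_k, top_k)
  }
  # labeled variants are never reselected
  expect_length(intersect(res$selection$variant, state$labels$variant), 0L)
  # relabeling an existing variant is refused
  expect_error(add_labels(res$state, singles[1], 1), "already labeled")
})

test_that("design campaigns are monotone, nested, and reproducible", {
  m <- tiny_model(seed = 9)
  ls <- make_landscape(wild_type = random_seq(35, seed = 13), n_singles = 10L,
                       seed = 13)
  oracle <- function(v) landscape_fitness(ls, v)
  rounds <- list(list(orders = 2:3, quota = c("2" = 5, "3" = 5)),
                 list(orders = 3:4, quota = c("3" = 5, "4" = 5)))
  rep1 <- run_design_campaign(m, ls$wild_type, oracle, rounds = rounds,
                              round0_k = 10L, scorer = "ridge", seed = 5)
  rep2 <- run_design_campaign(m, ls$wild_type, oracle, rounds = rounds,
                              round0_k = 10L, scorer = "ridge", seed = 5)
  expect_identical(rep1$per_round, rep2$per_round)
  expect_identical(rep1$best_variant, rep2$best_variant)
  expect_true(all(diff(rep1$per_round$best_so_far) >= 0))
  expect_gte(rep1$best_fitness, max(rep1$per_round$best_in_round))
  labels <- rep1$state$labels
  # training sets strictly nest: rounds only append
  expect_identical(labels$round, sort(labels$round))
  expect_false(any(duplicated(labels$variant)))
})

test_that("the supervised campaign runs the frozen-backbone regressor end to end", {
  m <- tiny_model(seed = 10)
  ls <- make_landscape(wild_type = random_seq(30, seed = 14), n_singles = 8L,
                       seed = 14)
  rounds <- list(list(orders = 2:3, quota = c("2" = 3, "3" = 3)))
  rep <- run_design_campaign(m, ls$wild_type,
                             function(v) landscape_fitness(ls, v),
                             rounds = rounds, round0_k = 8L,
                             scorer = "regressor",
                             cfg = regressor_config(max_epochs = 30L,
                                                    patience = 10L),
                             seed = 2)
  expect_identical(nrow(rep$per_round), 2L)
  expect_true(all(diff(rep$per_round$best_so_far) >= 0))
  expect_identical(sum(rep$state$labels$round == 1L), 6L)
})

test_that("directed-evolution harness echoes its config and is reproducible", {
  ls <- make_landscape(wild_type = random_seq(30, seed = 17), n_singles = 8L,
                       seed = 17)
  res <- simulate_directed_evolution(ls, samplers = c("top-k", "random"),
                                     replicates = 10L, rounds = 2L,
                                     budget = 20L, seed = 3)
  expect_identical(res$config$replicates, 10L)
  expect_identical(res$config$rounds, 2L)
  expect_identical(res$config$budget, 20L)
  expect_identical(res$config$pool_size, 255L)  # 2^8 - 1
  res2 <- simulate_directed_evolution(ls, samplers = c("top-k", "random"),
                                      replicates = 10L, rounds = 2L,
                                      budget = 20L, seed = 3)
  expect_identical(res$summary, res2$summary)
  expect_error(simulate_directed_evolution(ls, replicates = 2L, budget = 500L),
               "budget")
  # samplers draw exactly the budget without replacement: cumulative labeled
  # counts are implied by mean fitness being finite and max monotone per round
  tk <- res$summary[res$summary$sampler == "top-k", ]
  expect_true(all(diff(tk$mean_max_fitness) >= 0))
})

test_that("design states persist and resume across label deliveries", {
  ls <- make_landscape(wild_type = random_seq(30, seed = 19), n_singles = 6L,
                       seed = 19)
  singles <- paste0(ls$singles$wt, ls$singles$pos, ls$singles$mut)
  state <- design_state(ls$wild_type)
  state <- add_labels(state, singles[1:5],
                      vapply(singles[1:5], function(v) landscape_fitness(ls, v),
                             numeric(1)), round = 0L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_design_state(state, path)
  resumed <- load_design_state(path)
  expect_identical(resumed$labels, state$labels)
  resumed <- add_labels(resumed, singles[6], landscape_fitness(ls, singles[6]))
  expect_identical(nrow(resumed$labels), 6L)
  expect_error(load_design_state(withr::local_tempfile(fileext = ".rds")))
})
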