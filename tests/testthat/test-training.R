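small_corpus <- function(n = 12L, seed = 1L) {
  fam <- family_model(consensus = random_seq(24, seed = seed), sub_rate = 0.2,
                      seed = seed)
  make_ogt_corpus(fam, synthetic_ogt_model(seed = seed), n, seed = seed + 1L)
}

test_that("alternating schedule round-robins the three tasks without starvation", {
  m <- tiny_model()
  corpus <- small_corpus()
  res <- pretrain_alternating(m, corpus,
    pretrain_config(total_steps = 9L, seed = 1, tokens_per_microbatch = 96L))
  counts <- table(res$log$task)
  expect_identical(as.integer(counts[c("mlm", "ogt", "corr")]), c(3L, 3L, 3L))
  # max gap between executions of any one task is the number of tasks
  for (task in c("mlm", "ogt", "corr")) {
    expect_true(all(diff(which(res$log$task == task)) <= 3L))
  }
})

test_that("pretraining is deterministic and skips over-length sequences", {
  m <- tiny_model(seed = 2)
  corpus <- small_corpus(seed = 3)
  cfg <- pretrain_config(total_steps = 6L, seed = 9, tokens_per_microbatch = 96L)
  r1 <- pretrain_alternating(m, corpus, cfg)
  r2 <- pretrain_alternating(m, corpus, cfg)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(r1$log, r2$log)
  corpus2 <- rbind(corpus,
                   data.frame(id = "long", sequence = random_seq(200), ogt = 50))
  expect_message(r3 <- pretrain_alternating(tiny_model(), corpus2, cfg),
                 "skipped")
  expect_identical(r3$skipped, 1L)
  expect_error(pretrain_alternating(m, corpus[0, ], cfg), "empty corpus")
  expect_error(pretrain_alternating(m, corpus[, c("id", "sequence")], cfg), "ogt")
})

test_that("a tiny model memorizes fixed reconstruction targets (loss < 0.1)", {
  # full forward/backward sanity: 10 sequences, fixed noising, 500 Adam steps
  m <- init_model(model_config(seed = 1))
  seqs <- vapply(1:10, function(i) random_seq(48, seed = 100 + i), character(1))
  noised <- lapply(seq_along(seqs),
                   function(i) apply_noise(tokenize(seqs[i]), seed = i))
  opt <- thermlm:::adam_init(m$params)
  first <- NA_real_
  for (step in 1:500) {
    lg <- thermlm:::loss_grad_mlm_batch(m, noised)
    if (step == 1L) first <- lg$loss
    upd <- thermlm:::adam_step(m$params, lg$grads, opt, lr = 1e-3)
    m$params <- upd$params; opt <- upd$state
    if (step >= 200L && lg$loss < 0.1) break
  }
  expect_lt(lg$loss, 0.1)
  expect_lt(lg$loss, 0.5 * first)
})

test_that("homolog fine-tuning freezes the OGT head and caps the input set", {
  m <- tiny_model(seed = 5)
  homs <- generate_family(family_model(consensus = random_seq(20, seed = 2),
                                       sub_rate = 0.1, seed = 2), 35, seed = 3)
  before <- m$params[thermlm:::ogt_param_names(m$params)]
  res <- finetune_homologs(m, homs,
                           pretrain_config(total_steps = 5L, seed = 1,
                                           tokens_per_microbatch = 80L),
                           cap = 30L)
  expect_identical(res$n_used, 30L)
  after <- res$model$params[thermlm:::ogt_param_names(res$model$params)]
  expect_identical(after, before)
  # encoder parameters did change
  expect_false(identical(res$model$params$L1.Wq, m$params$L1.Wq))
  expect_error(finetune_homologs(m, character(0)), "empty homolog")
})

test_that("fine-tuning on near-identical homologs lowers their MLM loss", {
  m <- init_model(model_config(n_layers = 1L, n_heads = 2L, embed_dim = 32L,
                               max_len = 64L, seed = 7))
  fam <- family_model(consensus = random_seq(30, seed = 11), sub_rate = 0.03,
                      seed = 11)
  homs <- generate_family(fam, 20, seed = 12)
  before <- mean_mlm_loss(m, homs, seed = 99)
  res <- finetune_homologs(m, homs,
                           pretrain_config(total_steps = 120L, seed = 1,
                                           learning_rate = 1e-3,
                                           tokens_per_microbatch = 300L))
  after <- mean_mlm_loss(res$model, homs, seed = 99)
  expect_lt(after, before)
})

test_that("dynamic epoch rule averages per-fold stops with round-half-up", {
  expect_identical(thermlm:::round_half_up(mean(c(10, 10, 10, 10, 10))), 10L)
  expect_identical(thermlm:::round_half_up(mean(c(8, 12, 10, 9, 11))), 10L)
  expect_identical(thermlm:::round_half_up(mean(c(1, 1, 1, 1, 2))), 1L)
  expect_identical(thermlm:::round_half_up(2.5), 3L)
})

test_that("determine_epochs runs seeded cross-validation and bounds the answer", {
  m <- tiny_model(seed = 1)
  ls <- make_landscape(wild_type = random_seq(30, seed = 21), n_singles = 10L,
                       noise_sd = 0, seed = 21)
  singles <- paste0(ls$singles$wt, ls$singles$pos, ls$singles$mut)
  assay <- data.frame(variant = singles,
                      fitness = vapply(singles, function(v)
                        landscape_fitness(ls, v), numeric(1)))
  cfg <- regressor_config(max_epochs = 40L, patience = 10L)
  ep <- determine_epochs(m, tokenize(ls$wild_type), assay, cfg, seed = 1)
  expect_gte(ep, 1L)
  expect_lte(ep, 40L)
  expect_identical(determine_epochs(m, tokenize(ls$wild_type), assay, cfg,
                                    seed = 1), ep)
  expect_error(determine_epochs(m, tokenize(ls$wild_type), assay[1:3, ], cfg),
               "smaller fold")
})

test_that("fit_regressor trains only FC3/FC4 and reduces training error", {
  m <- tiny_model(seed = 2)
  ls <- make_landscape(wild_type = random_seq(30, seed = 22), n_singles = 12L,
                       noise_sd = 0, seed = 22)
  singles <- paste0(ls$singles$wt, ls$singles$pos, ls$singles$mut)
  assay <- data.frame(variant = singles,
                      fitness = vapply(singles, function(v)
                        landscape_fitness(ls, v), numeric(1)))
  params_before <- m$params
  cfg <- regressor_config(max_epochs = 60L, patience = 15L)
  reg <- fit_regressor(m, tokenize(ls$wild_type), assay, cfg, seed = 4)
  # backbone untouched, update set is exactly the last two layers
  expect_identical(reg$model$params, params_before)
  expect_identical(sort(reg$updated),
                   sort(c("ogt.FC3W", "ogt.FC3b", "ogt.FC4w", "ogt.FC4b")))
  pred <- predict_fitness(reg, tokenize(ls$wild_type), as.list(assay$variant))
  mse_fit <- mean((pred - assay$fitness)^2)
  # compare against an untrained, freshly randomized head
  reg0 <- reg
  reg0$head <- thermlm:::init_head(m$config$embed_dim, 4L)
  pred0 <- thermlm:::head_predict(reg0$head,
    thermlm:::variant_features(m, tokenize(ls$wild_type), as.list(assay$variant))) *
    reg$y_sd + reg$y_mean
  expect_lt(mse_fit, mean((pred0 - assay$fitness)^2))
})

test_that("regressor generalizes on a noise-free additive landscape", {
  # parameter recovery: the landscape is additive over a fixed set of 15
  # singles; train on 40 variants built from them and predict held-out
  # combinations of the same singles (held-out rank correlation > 0 in at
  # least 9 of 10 seeds). Singles with fresh random effects would be
  # unpredictable in principle; combinations of seen singles are the
  # recoverable structure.
  m <- tiny_model(seed = 3)
  ls <- make_landscape(wild_type = random_seq(40, seed = 30), n_singles = 15L,
                       epistasis_frac = 0, noise_sd = 0, seed = 30)
  pool <- enumerate_combinations(ls$singles[, c("pos", "wt", "mut")],
                                 orders = 1:3)
  sel <- thermlm:::with_seed(77, sample(nrow(pool), 50))
  variants <- pool$variant[sel]
  fitness <- vapply(variants, function(v) landscape_fitness(ls, v), numeric(1))
  train_idx <- 1:40; test_idx <- 41:50
  cache <- new.env(parent = emptyenv())
  wins <- 0L
  for (s in 1:10) {
    reg <- fit_regressor(m, tokenize(ls$wild_type),
                         data.frame(variant = variants[train_idx],
                                    fitness = fitness[train_idx]),
                         regressor_config(learning_rate = 1e-3,
                                          max_epochs = 200L, patience = 20L),
                         seed = s, cache = cache)
    pred <- predict_fitness(reg, tokenize(ls$wild_type),
                            as.list(variants[test_idx]), cache = cache)
    if (cor(pred, fitness[test_idx], method = "spearman") > 0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("ensemble averaging is exact, permutation-invariant, and strict", {
  s1 <- data.frame(variant = c("A1C", "A2C"), score = c(2, 0))
  s2 <- data.frame(variant = c("A2C", "A1C"), score = c(2, 4))
  avg <- ensemble_average(list(s1, s2))
  expect_identical(avg$score[avg$variant == "A1C"], 3)
  expect_identical(avg$score[avg$variant == "A2C"], 1)
  expect_equal(ensemble_average(list(s2, s1))$score[order(ensemble_average(list(s2, s1))$variant)],
               avg$score[order(avg$variant)])
  expect_identical(ensemble_average(list(s1))$score, s1$score)
  s3 <- data.frame(variant = c("A1C"), score = 1)
  expect_error(ensemble_average(list(s1, s3)), "mismatch")
})
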