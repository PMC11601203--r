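# Wild type with known residues at scattered positions for parser tests.
wt60 <- random_seq(60, seed = 77)

test_that("parse_variant handles notation, sorting, and errors", {
  wt_chars <- strsplit(wt60, "")[[1]]
  wt_chars[c(2, 5)] <- c("A", "G")
  wt <- paste(wt_chars, collapse = "")
  v <- parse_variant("G5H;A2C", wt)
  expect_identical(v$mutations$pos, c(2L, 5L))
  expect_identical(v$string, "A2C;G5H")
  expect_identical(parse_variant("A2C:G5H", wt)$string, "A2C;G5H")
  expect_identical(parse_variant(" A2C ; G5H ", wt)$string, "A2C;G5H")
  expect_error(parse_variant("A2C;A2G", wt), "duplicate")
  expect_error(parse_variant("C2A", wt), "wild-type mismatch.*position 2")
  expect_error(parse_variant("A2", wt), "malformed")
  expect_error(parse_variant(sprintf("A%dC", 100), wt), "out of range")
  # canonical string round-trips
  expect_identical(parse_variant(v$string, wt)$string, v$string)
})

test_that("parse_variant accepts deep positions as printed in mutant tables", {
  wt_chars <- strsplit(random_seq(800, seed = 5), "")[[1]]
  wt_chars[786] <- "Q"
  wt <- paste(wt_chars, collapse = "")
  v <- parse_variant("Q786L", wt)
  expect_identical(v$mutations$pos, 786L)
  expect_identical(v$mutations$wt, "Q")
  expect_identical(v$mutations$mut, "L")
})

test_that("score_single is a log-odds from the residue distribution", {
  m <- tiny_model(seed = 6)
  wt <- tokenize(random_seq(25, seed = 6))
  v <- aa_vocab()
  wt_chars <- strsplit(detokenize(wt), "")[[1]]
  # m == w scores zero
  expect_identical(score_single(m, wt, list(pos = 3L, mut = wt_chars[3])), 0)
  # equals the direct difference of log-probabilities (oracle equivalence)
  logP <- mlm_distributions(m, encode(m, wt)$H, log = TRUE)
  for (pos in c(1L, 10L, 25L)) {
    mut <- setdiff(v$residues, wt_chars[pos])[1]
    s <- score_single(m, wt, list(pos = pos, mut = mut))
    expect_equal(s, unname(logP[pos, mut] - logP[pos, wt_chars[pos]]),
                 tolerance = 1e-12)
  }
  expect_error(score_single(m, wt, list(pos = 26L, mut = "A")), "out of range")
})

test_that("score_single is antisymmetric on the same unmasked pass", {
  m <- tiny_model(seed = 8)
  wt <- tokenize(random_seq(15, seed = 9))
  wt_chars <- strsplit(detokenize(wt), "")[[1]]
  mut <- setdiff(aa_vocab()$residues, wt_chars[7])[3]
  fwd <- score_single(m, wt, list(pos = 7L, mut = mut))
  mut_seq <- apply_variant(wt, paste0(wt_chars[7], 7, mut))
  # reverse mutation scored against the mutant's own (unmasked) pass differs;
  # antisymmetry holds when both scores are read from the SAME wild-type pass
  logP <- mlm_distributions(m, encode(m, wt)$H, log = TRUE)
  rev_same_pass <- unname(logP[7, wt_chars[7]] - logP[7, mut])
  expect_equal(fwd, -rev_same_pass, tolerance = 1e-12)
})

test_that("multisite zero-shot scores are additive and order-invariant", {
  m <- tiny_model(seed = 3)
  wt <- tokenize(random_seq(30, seed = 4))
  wt_chars <- strsplit(detokenize(wt), "")[[1]]
  v1 <- paste0(wt_chars[4], 4, "W"); if (wt_chars[4] == "W") v1 <- paste0(wt_chars[4], 4, "Y")
  v2 <- paste0(wt_chars[19], 19, "C"); if (wt_chars[19] == "C") v2 <- paste0(wt_chars[19], 19, "D")
  s1 <- score_single(m, wt, v1)
  s2 <- score_single(m, wt, v2)
  both <- score_variant(m, wt, paste(v1, v2, sep = ";"))
  expect_equal(both, s1 + s2, tolerance = 1e-10)
  expect_equal(score_variant(m, wt, paste(v2, v1, sep = ";")), both,
               tolerance = 1e-12)
  empty <- structure(list(mutations = data.frame(), string = "", n = 0L),
                     class = "thermlm_variant")
  expect_identical(score_variant(m, wt, empty), 0)
})

test_that("saturation scan covers 19L rows, matches score_single, reuses passes", {
  m <- tiny_model(seed = 5)
  wt <- tokenize(random_seq(12, seed = 5))
  reset_pass_counter()
  sc <- score_saturation(m, wt)
  expect_identical(encoder_pass_count(), 1L)
  expect_identical(nrow(sc), 19L * 12L)
  expect_identical(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$score) <= 1e-12))
  # no wt->wt rows
  wt_chars <- strsplit(detokenize(wt), "")[[1]]
  self_rows <- paste0(wt_chars, seq_len(12), wt_chars)
  expect_false(any(sc$variant %in% self_rows))
  # spot-check equality with individual calls
  for (row in c(1L, 57L, 228L)) {
    expect_equal(sc$score[row], score_single(m, wt, sc$variant[row]),
                 tolerance = 1e-10)
  }
  # masked-marginal costs exactly L passes
  reset_pass_counter()
  sc_m <- score_saturation(m, wt, mode = "masked-marginal")
  expect_identical(encoder_pass_count(), 12L)
  expect_identical(nrow(sc_m), 19L * 12L)
})

test_that("ensemble scores are the member mean", {
  members <- list(tiny_model(seed = 1), tiny_model(seed = 2))
  ens <- make_ensemble(members)
  wt <- tokenize(random_seq(10, seed = 1))
  wt_chars <- strsplit(detokenize(wt), "")[[1]]
  mut <- setdiff(aa_vocab()$residues, wt_chars[4])[1]
  mv <- list(pos = 4L, mut = mut)
  s_ens <- score_single(ens, wt, mv)
  s_members <- vapply(members, function(mm) score_single(mm, wt, mv), numeric(1))
  expect_equal(s_ens, mean(s_members), tolerance = 1e-12)
  # matches ensemble_average on scorecards
  cards <- lapply(members, function(mm) score_saturation(mm, wt))
  avg <- ensemble_average(lapply(cards, function(x) x[, c("variant", "score")]))
  sat <- score_saturation(ens, wt)
  key <- match(sat$variant, avg$variant)
  expect_equal(sat$score, avg$score[key], tolerance = 1e-10)
})

test_that("the 6-angstrom exclusion removes near-site candidates (closed bound)", {
  # active site at position 1, candidates strung out along the x axis
  coords <- data.frame(position = 1:4,
                       x = c(0, 5.9, 6.0, 6.1), y = 0, z = 0)
  sc <- data.frame(variant = c("A2C", "A3C", "A4C"), score = c(3, 2, 1),
                   n_mutations = 1L, source = "t", stringsAsFactors = FALSE)
  out <- exclude_near_sites(sc, coords, active_sites = 1L, radius = 6.0)
  expect_identical(out$variant, "A4C")
  # empty active-site set leaves the scorecard unchanged
  out2 <- exclude_near_sites(sc, coords, active_sites = integer(0))
  expect_identical(out2$variant, sc$variant)
  # active site without coordinates is an error
  expect_error(exclude_near_sites(sc, coords, active_sites = 9L),
               "no coordinates")
  # candidates lacking coordinates are retained with a warning
  sc2 <- rbind(sc, data.frame(variant = "A9C", score = 5, n_mutations = 1L,
                              source = "t"))
  expect_warning(out3 <- exclude_near_sites(sc2, coords, active_sites = 1L),
                 "retained")
  expect_true("A9C" %in% out3$variant)
})

test_that("top-K selection is stable with documented tie-break and quotas", {
  sc <- data.frame(variant = c("a", "b", "c"), score = c(3, 1, 2),
                   n_mutations = 1L, source = "t", stringsAsFactors = FALSE)
  expect_identical(select_top_k(sc, K = 2)$variant, c("a", "c"))
  ties <- data.frame(variant = c("B1A", "A1B", "C1A"), score = c(1, 1, 1),
                     n_mutations = 1L, source = "t", stringsAsFactors = FALSE)
  expect_identical(select_top_k(ties, K = 2)$variant, c("A1B", "B1A"))
  mixed <- data.frame(variant = sprintf("V%dA", 1:9),
                      score = 9:1,
                      n_mutations = rep(c(2L, 3L, 4L), each = 3),
                      source = "t", stringsAsFactors = FALSE)
  sel <- select_top_k(mixed, quota = c("2" = 2, "3" = 2, "4" = 2))
  expect_identical(nrow(sel), 6L)
  expect_true(all(table(sel$n_mutations) <= 2))
  # K larger than the pool returns the whole pool
  expect_identical(nrow(select_top_k(sc, K = 50)), 3L)
})
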