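# Synthetic data: toy homologous families, composition-driven OGT labels,
# and epistatic fitness landscapes. Every generator is a pure function of
# (config, seed), so fixtures are reproducible byte for byte.

#' Define a toy homologous protein family
#'
#' A family is parameterized by a consensus sequence, a per-site substitution
#' rate, and per-site residue preferences (a few allowed alternatives per
#' site with seeded weights). This stands in for a natural homolog set: most
#' sites conserved, variable sites drawn from a site-specific distribution.
#'
#' @param consensus Consensus sequence (string). Default: a seeded random
#'   48-mer.
#' @param sub_rate Per-site substitution probability in [0,1] (scalar or
#'   length-L vector).
#' @param n_alternatives Alternative residues allowed per site.
#' @param seed Seed fixing the consensus (if not given) and preferences.
#' @return A `thermlm_family` list.
#' @export
family_model <- function(consensus = NULL, sub_rate = 0.15,
                         n_alternatives = 3L, seed = 1L) {
  vocab <- aa_vocab()
  with_seed(derive_seed(seed, "family"), {
    if (is.null(consensus))
      consensus <- paste(sample(vocab$residues, 48, replace = TRUE), collapse = "")
    L <- nchar(consensus)
    if (any(sub_rate < 0) || any(sub_rate > 1)) stop("sub_rate must lie in [0,1]")
    rate <- rep_len(sub_rate, L)
    cons_chars <- strsplit(consensus, "")[[1]]
    prefs <- lapply(seq_len(L), function(i) {
      alts <- sample(setdiff(vocab$residues, cons_chars[i]), n_alternatives)
      w <- stats::rexp(n_alternatives)
      stats::setNames(w / sum(w), alts)
    })
    structure(list(consensus = consensus, L = L, sub_rate = rate,
                   prefs = prefs, seed = seed),
              class = "thermlm_family")
  })
}

#' Sample sequences from a family model
#'
#' Each site independently mutates away from the consensus with its rate;
#' substitutions are drawn from the site's preference distribution.
#'
#' @param family A [family_model()].
#' @param n Number of sequences.
#' @param seed Draw seed.
#' @return Character vector of `n` sequences of the consensus length.
#' @export
generate_family <- function(family, n, seed = 1L) {
  stopifnot(n >= 1L)
  cons <- strsplit(family$consensus, "")[[1]]
  with_seed(derive_seed(seed, "draw"), {
    vapply(seq_len(n), function(k) {
      chars <- cons
      hit <- which(stats::runif(family$L) < family$sub_rate)
      for (i in hit) {
        pf <- family$prefs[[i]]
        chars[i] <- sample(names(pf), 1L, prob = pf)
      }
      paste(chars, collapse = "")
    }, character(1))
  })
}

#' Synthetic OGT label model
#'
#' OGT is a linear function of amino-acid composition: base temperature plus
#' per-residue weights (degC per unit frequency) times the residue
#' frequencies of the sequence, plus Gaussian noise, clamped to [0, 100].
#' The default weights give realistic mesophile-to-thermophile spreads
#' (roughly 20--80 degC) over a family sample.
#'
#' @param base_temp Baseline temperature (degC).
#' @param weights Named numeric vector over the 20 residues (degC per unit
#'   frequency); default: seeded normals with SD 120.
#' @param noise_sd Gaussian label noise SD (degC).
#' @param seed Seed for the default weights.
#' @return A `thermlm_ogt_model` list.
#' @export
synthetic_ogt_model <- function(base_temp = 50, weights = NULL, noise_sd = 3,
                                seed = 1L) {
  vocab <- aa_vocab()
  if (is.null(weights))
    weights <- with_seed(derive_seed(seed, "ogtw"),
                         stats::setNames(stats::rnorm(20, sd = 120), vocab$residues))
  stopifnot(noise_sd >= 0)
  structure(list(base_temp = base_temp, weights = weights,
                 noise_sd = noise_sd, seed = seed),
            class = "thermlm_ogt_model")
}

#' Assign a synthetic OGT label to a sequence
#'
#' @param sequence A sequence string (or `thermlm_tokens`).
#' @param model A [synthetic_ogt_model()].
#' @param seed Noise seed (per-sequence noise derives from it and the
#'   sequence itself, so labels are reproducible).
#' @return Temperature in degC, clamped to [0, 100].
#' @export
assign_ogt <- function(sequence, model, seed = 1L) {
  if (inherits(sequence, "thermlm_tokens")) sequence <- detokenize(sequence)
  comp <- residue_composition(sequence)
  y <- model$base_temp + sum(model$weights[names(comp)] * comp)
  if (model$noise_sd > 0)
    y <- y + with_seed(derive_seed(seed, "ogt", sequence),
                       stats::rnorm(1, sd = model$noise_sd))
  min(100, max(0, y))
}

#' Residue composition of a sequence
#'
#' @param sequence A sequence string.
#' @return Named numeric vector of residue frequencies (sums to 1) over the
#'   20 residues.
#' @export
residue_composition <- function(sequence) {
  vocab <- aa_vocab()
  chars <- strsplit(toupper(sequence), "")[[1]]
  tab <- table(factor(chars, levels = vocab$residues))
  as.numeric(tab) / length(chars) -> f
  stats::setNames(f, vocab$residues)
}

#' Build a labeled OGT corpus from a family
#'
#' @param family A [family_model()].
#' @param ogt_model A [synthetic_ogt_model()].
#' @param n Number of sequences.
#' @param seed Seed.
#' @return data.frame with `id`, `sequence`, `ogt`.
#' @export
make_ogt_corpus <- function(family, ogt_model, n, seed = 1L) {
  seqs <- generate_family(family, n, seed = seed)
  ogts <- vapply(seq_along(seqs), function(i)
    assign_ogt(seqs[i], ogt_model, seed = derive_seed(seed, "label", i)),
    numeric(1))
  data.frame(id = sprintf("fam%05d", seq_len(n)), sequence = seqs, ogt = ogts,
             stringsAsFactors = FALSE)
}

# --- epistatic fitness landscape ---------------------------------------------

#' Generate an epistatic fitness landscape
#'
#' Ground-truth fitness used as the in-silico wet-lab oracle. Fitness of a
#' variant is the sum of per-mutation additive effects (full L x 20 table,
#' zero at the wild-type residue, negatively biased draws elsewhere -- most
#' random mutations are deleterious), plus pairwise epistasis terms on a
#' sparse set of position pairs (applied when both positions are mutated;
#' a configurable fraction of terms, 0.9 by default, is negative, echoing the
#' strong excess of negative over positive epistasis seen in mutational
#' scans), plus per-variant seeded measurement noise. A designated set of
#' `n_singles` beneficial-leaning single mutations at distinct positions is
#' carried along for combination studies.
#'
#' @param wild_type Wild-type string; default a seeded random 48-mer.
#' @param n_singles Designated single mutations at distinct positions.
#' @param additive_mean,additive_sd Additive-effect draw parameters.
#' @param epistasis_frac Fraction of position pairs carrying an epistasis
#'   term.
#' @param epistasis_sd Magnitude scale of epistasis terms.
#' @param neg_frac Fraction of epistasis terms that are negative.
#' @param noise_sd Assay noise SD (per-variant seeded; repeated queries of a
#'   variant return the same "measurement").
#' @param seed Seed.
#' @return A `thermlm_landscape` list.
#' @export
make_landscape <- function(wild_type = NULL, n_singles = 15L,
                           additive_mean = -0.5, additive_sd = 0.5,
                           epistasis_frac = 0.25, epistasis_sd = 0.3,
                           neg_frac = 0.9, noise_sd = 0.05, seed = 1L) {
  vocab <- aa_vocab()
  with_seed(derive_seed(seed, "landscape"), {
    if (is.null(wild_type))
      wild_type <- paste(sample(vocab$residues, 48, replace = TRUE), collapse = "")
    L <- nchar(wild_type)
    wt_chars <- strsplit(wild_type, "")[[1]]
    wt_idx <- unname(vocab$index[wt_chars])
    additive <- matrix(stats::rnorm(L * 20, mean = additive_mean,
                                    sd = additive_sd), L, 20)
    additive[cbind(seq_len(L), wt_idx)] <- 0
    colnames(additive) <- vocab$residues
    # designated singles: distinct positions, effects drawn positive-leaning
    pos <- sort(sample.int(L, n_singles))
    mut <- vapply(pos, function(i)
      sample(setdiff(vocab$residues, wt_chars[i]), 1L), character(1))
    eff <- abs(stats::rnorm(n_singles, sd = 0.6))
    additive[cbind(pos, unname(vocab$index[mut]))] <- eff
    singles <- data.frame(pos = pos, wt = wt_chars[pos], mut = mut,
                          effect = eff, stringsAsFactors = FALSE)
    # sparse pairwise epistasis over position pairs
    all_pairs <- utils::combn(L, 2)
    take <- which(stats::runif(ncol(all_pairs)) < epistasis_frac)
    e_val <- abs(stats::rnorm(length(take), sd = epistasis_sd)) *
      ifelse(stats::runif(length(take)) < neg_frac, -1, 1)
    pairs <- data.frame(pos_i = all_pairs[1, take], pos_j = all_pairs[2, take],
                        e = e_val)
    structure(list(wild_type = wild_type, L = L, additive = additive,
                   singles = singles, pairs = pairs, neg_frac = neg_frac,
                   noise_sd = noise_sd, seed = seed),
              class = "thermlm_landscape")
  })
}

#' Ground-truth fitness of a variant
#'
#' Sum of additive effects plus pairwise epistasis among mutated positions,
#' plus seeded per-variant measurement noise (so repeated queries behave like
#' repeated assays of the same clone). The wild type has fitness 0 (exactly,
#' at `noise = FALSE` or noise SD 0).
#'
#' @param landscape A [make_landscape()].
#' @param variant A `thermlm_variant` or notation string.
#' @param noise Include the seeded measurement noise (default `TRUE`).
#' @return Scalar fitness.
#' @export
landscape_fitness <- function(landscape, variant, noise = TRUE) {
  vocab <- aa_vocab()
  if (is.character(variant)) variant <- parse_variant(variant, landscape$wild_type)
  mt <- variant$mutations
  f <- 0
  if (nrow(mt) > 0L) {
    f <- sum(landscape$additive[cbind(mt$pos, unname(vocab$index[mt$mut]))])
    if (nrow(mt) > 1L && nrow(landscape$pairs) > 0L) {
      hit <- landscape$pairs$pos_i %in% mt$pos & landscape$pairs$pos_j %in% mt$pos
      f <- f + sum(landscape$pairs$e[hit])
    }
  }
  if (noise && landscape$noise_sd > 0)
    f <- f + with_seed(derive_seed(landscape$seed, "assay", variant$string),
                       stats::rnorm(1, sd = landscape$noise_sd))
  f
}

#' Write / read a landscape as JSON
#'
#' Schema: `wild_type`, `additive` (records of pos, mut, effect for non-wild
#' residues), `singles`, `pairs` (pos_i, pos_j, e), `neg_frac`, `noise_sd`,
#' `seed`.
#'
#' @param landscape A `thermlm_landscape`.
#' @param path JSON file path.
#' @export
write_landscape_json <- function(landscape, path) {
  vocab <- aa_vocab()
  wt_idx <- unname(vocab$index[strsplit(landscape$wild_type, "")[[1]]])
  rec <- expand.grid(pos = seq_len(landscape$L), mut = vocab$residues,
                     stringsAsFactors = FALSE)
  rec$effect <- landscape$additive[cbind(rec$pos, unname(vocab$index[rec$mut]))]
  rec <- rec[unname(vocab$index[rec$mut]) != wt_idx[rec$pos], ]
  rec <- rec[order(rec$pos, rec$mut), ]
  obj <- list(wild_type = landscape$wild_type,
              additive = rec,
              singles = landscape$singles,
              pairs = landscape$pairs,
              neg_frac = landscape$neg_frac,
              noise_sd = landscape$noise_sd,
              seed = landscape$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_landscape_json
#' @export
read_landscape_json <- function(path) {
  vocab <- aa_vocab()
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- nchar(obj$wild_type)
  wt_idx <- unname(vocab$index[strsplit(obj$wild_type, "")[[1]]])
  additive <- matrix(0, L, 20, dimnames = list(NULL, vocab$residues))
  additive[cbind(obj$additive$pos, unname(vocab$index[obj$additive$mut]))] <-
    obj$additive$effect
  additive[cbind(seq_len(L), wt_idx)] <- 0
  structure(list(wild_type = obj$wild_type, L = L, additive = additive,
                 singles = as.data.frame(obj$singles),
                 pairs = as.data.frame(obj$pairs),
                 neg_frac = obj$neg_frac, noise_sd = obj$noise_sd,
                 seed = obj$seed),
            class = "thermlm_landscape")
}

#' Write a complete fixture set
#'
#' Generates, under one seed: a FASTA homolog family, an OGT-labeled corpus
#' CSV, an assay CSV of labeled single mutants of the landscape wild type, a
#' synthetic per-residue coordinate CSV (idealized helix geometry; marked
#' synthetic), and a landscape JSON. Byte-stable for a given seed.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_family Homologs written to the FASTA.
#' @param n_corpus Rows of the labeled OGT corpus.
#' @param n_assay Labeled single mutants in the assay CSV.
#' @return Named character vector of the file paths written.
#' @export
make_fixtures <- function(dir, seed = 1L, n_family = 200L, n_corpus = 2000L,
                          n_assay = 40L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- family_model(seed = seed)
  ogtm <- synthetic_ogt_model(seed = seed)
  ls <- make_landscape(wild_type = fam$consensus, seed = seed)
  paths <- c(
    family = file.path(dir, "family.fasta"),
    corpus = file.path(dir, "ogt_corpus.csv"),
    assay = file.path(dir, "assay_singles.csv"),
    coords = file.path(dir, "coords_synthetic.csv"),
    landscape = file.path(dir, "landscape.json")
  )
  seqs <- generate_family(fam, n_family, seed = derive_seed(seed, "fasta"))
  write_fasta(stats::setNames(seqs, sprintf("hom%04d", seq_len(n_family))),
              paths[["family"]])
  corpus <- make_ogt_corpus(fam, ogtm, n_corpus, seed = derive_seed(seed, "corpus"))
  utils::write.csv(corpus, paths[["corpus"]], row.names = FALSE, quote = FALSE)
  # assay: the designated singles plus seeded random extra singles
  vocab <- aa_vocab()
  wt_chars <- strsplit(ls$wild_type, "")[[1]]
  extra_n <- max(0L, n_assay - nrow(ls$singles))
  extras <- with_seed(derive_seed(seed, "assay-extras"), {
    pos <- sample(setdiff(seq_len(ls$L), ls$singles$pos), extra_n)
    data.frame(pos = pos, wt = wt_chars[pos],
               mut = vapply(pos, function(i)
                 sample(setdiff(vocab$residues, wt_chars[i]), 1L), character(1)),
               stringsAsFactors = FALSE)
  })
  singles <- rbind(ls$singles[, c("pos", "wt", "mut")], extras)
  singles <- utils::head(singles[order(singles$pos), ], n_assay)
  var_str <- paste0(singles$wt, singles$pos, singles$mut)
  assay <- data.frame(
    mutant = var_str,
    score = vapply(var_str, function(v) landscape_fitness(ls, v), numeric(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(assay, paths[["assay"]], row.names = FALSE, quote = FALSE)
  # synthetic coordinates: idealized alpha-helix CA trace (1 point/residue)
  t <- seq_len(ls$L)
  coords <- data.frame(position = t,
                       x = round(2.3 * cos(t * 100 * pi / 180), 3),
                       y = round(2.3 * sin(t * 100 * pi / 180), 3),
                       z = round(1.5 * t, 3))
  utils::write.csv(coords, paths[["coords"]], row.names = FALSE, quote = FALSE)
  write_landscape_json(ls, paths[["landscape"]])
  paths
}
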