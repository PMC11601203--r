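#' Read a FASTA file
#'
#' Wraps Biostrings; ids are taken from headers up to the first whitespace,
#' order is preserved, wrapped records are joined. Duplicate ids and empty
#' records are rejected.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA ids: ", paste(utils::head(dup, 5), collapse = ", "))
  seqs <- as.character(ss)
  if (any(!nzchar(seqs)))
    stop("empty FASTA record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  stats::setNames(toupper(seqs), ids)
}

#' Write a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Destination path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a mutant assay CSV
#'
#' Expects a header with a variant column and a numeric score column
#' (default names `mutant` and `score`, the ProteinGym-style layout); both
#' `':'` and `';'` variant separators are accepted. Variants are parsed and
#' validated against the wild type; parsing failures report the row number.
#'
#' @param path CSV path.
#' @param wild_type Wild-type sequence (string or `thermlm_tokens`).
#' @param variant_col,score_col Column names.
#' @return data.frame with `variant` (canonical strings), `fitness`,
#'   `n_mutations`.
#' @export
read_assay_csv <- function(path, wild_type, variant_col = "mutant",
                           score_col = "score") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c(variant_col, score_col) %in% names(df)))
    stop("assay CSV must have columns '", variant_col, "' and '", score_col, "'")
  scores <- df[[score_col]]
  if (!is.numeric(scores)) stop("non-numeric scores in column '", score_col, "'")
  variants <- character(nrow(df))
  n_mut <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- tryCatch(parse_variant(df[[variant_col]][i], wild_type),
                  error = function(e)
                    stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
    variants[i] <- v$string
    n_mut[i] <- v$n
  }
  dup <- unique(variants[duplicated(variants)])
  if (length(dup) > 0L)
    stop("duplicate variants in assay: ", paste(utils::head(dup, 5), collapse = ", "))
  data.frame(variant = variants, fitness = scores, n_mutations = n_mut,
             stringsAsFactors = FALSE)
}

#' Write a training log as JSONL
#'
#' One JSON object per line: step, task, loss, weighted_loss.
#'
#' @param log Training-log data.frame.
#' @param path Destination path.
#' @export
write_training_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: a stable hash of the
#' configuration, the seed, package version, and checksums of the input
#' files, so every output is re-derivable.
#'
#' @param path Manifest JSON path.
#' @param config Any serializable configuration object.
#' @param seed Run seed.
#' @param inputs Character vector of input file paths (checksummed).
#' @export
write_manifest <- function(path, config, seed, inputs = character(0)) {
  checksums <- vapply(inputs, function(f) {
    if (!file.exists(f)) return(NA_character_)
    as.character(stable_hash(readBin(f, "raw", file.info(f)$size)))
  }, character(1))
  obj <- list(package = "thermlm",
              version = as.character(utils::packageVersion("thermlm")),
              config_hash = stable_hash(config),
              seed = seed,
              inputs = as.list(checksums),
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# FNV-1a hash of a serialized object; stable across sessions for the
# plain-data configs used here.
stable_hash <- function(x) {
  bytes <- if (is.raw(x)) x else serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) h <- ((h * 16777619) %% 4294967296 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read and validate a run configuration
#'
#' YAML run configuration covering the model preset, noise settings, loss
#' weights, training settings, scoring mode, design quotas and seeds.
#' Unknown top-level keys are rejected, so typos fail loudly instead of
#' silently falling back to defaults.
#'
#' @param path YAML file path.
#' @return Named list of settings (only the keys present in the file).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("run config must be a YAML mapping")
  known <- c("preset", "seed", "learning_rate", "total_steps",
             "tokens_per_microbatch", "gradient_accumulation_steps",
             "noise_rate", "mask_share", "substitute_share", "keep_share",
             "w_mlm", "w_ogt", "w_corr", "align_N", "scoring_mode",
             "exclusion_radius", "homolog_cap", "batch_size", "folds",
             "patience", "max_epochs", "ensemble_seeds", "round0_k",
             "quota", "orders", "enumeration_cap")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  cfg
}
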