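# FASTA and TSV readers/writers and the run configuration container.

#' Read sequences from a FASTA file
#'
#' Backed by Biostrings; identifiers are the first whitespace token of the
#' header, sequences are uppercased. Empty records and non-FASTA content
#' are rejected with the offending line number.
#'
#' @param path FASTA path (may hold multiple records).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) stop(sprintf("'%s' is empty", path))
  first <- nonblank[1]
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("not FASTA: line %d of '%s' does not start with '>'",
                 first, path))
  }
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0)) {
    bad <- names(set)[Biostrings::width(set) == 0][1]
    stop(sprintf("record '%s' in '%s' has an empty sequence", bad, path))
  }
  seqs <- toupper(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1)
  stats::setNames(unname(seqs), ids)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' Rows must share one length; the first record is the query.
#'
#' @param path Aligned-FASTA path.
#' @return Character vector of aligned rows (names = record ids).
#' @export
read_msa_fasta <- function(path) {
  rows <- read_fasta(path)
  if (length(unique(nchar(rows))) != 1) {
    stop(sprintf("ragged alignment in '%s': rows differ in length", path))
  }
  rows
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0(">", id), seqs[[id]]), con)
  }
  invisible(path)
}

#' Write per-residue prediction scores as TSV
#'
#' Columns: id, position (1-based), residue, score (4 decimals); one row
#' per residue, deterministic byte output for fixed inputs.
#'
#' @param ids Sequence identifiers.
#' @param seqs Character vector of sequences, same length as `ids`.
#' @param scores List of per-residue score vectors.
#' @param path Output path.
#' @export
write_predictions <- function(ids, seqs, scores, path) {
  stopifnot(length(ids) == length(seqs), length(ids) == length(scores))
  rows <- list()
  for (k in seq_along(ids)) {
    aa <- strsplit(seqs[[k]], "")[[1]]
    if (length(aa) != length(scores[[k]])) {
      stop(sprintf("score length does not match sequence '%s'", ids[[k]]))
    }
    rows[[k]] <- data.frame(id = ids[[k]], position = seq_along(aa),
                            residue = aa,
                            score = sprintf("%.4f", scores[[k]]))
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a predictions TSV back
#'
#' @param path TSV written by [write_predictions()].
#' @return data.frame with `id`, `position`, `residue`, `score`.
#' @export
read_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character",
                                   "numeric"))
}

.default_config <- function() {
  list(
    criteria = list(mode = "strict", trans_lo = -145, trans_hi = -70,
                    regularity_max = 30, min_len = 3,
                    omega_trans_check = FALSE),
    features = list(use_msa = FALSE, use_disorder = FALSE),
    train = list(epochs = 2000, updates_per_epoch = 1920, lr_init = 0.005,
                 lr_halving_patience = 1000, hidden_dim = 11,
                 mlp_hidden = 11),
    evaluation = list(thresholds = c(0.2, 0.5)),
    seed = 1
  )
}

#' Load / save a run configuration
#'
#' A single JSON file covering assignment criteria, feature switches,
#' training schedule and evaluation thresholds. Unknown keys at any level
#' are rejected loudly; the file round-trips losslessly.
#'
#' @param path JSON path.
#' @return Nested configuration list (load); `path` invisibly (save).
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  def <- .default_config()
  check <- function(got, ref, where) {
    bad <- setdiff(names(got), names(ref))
    if (length(bad)) {
      stop(sprintf("unknown config key(s) %s in '%s'",
                   paste0(sQuote(paste0(where, bad)), collapse = ", "), path))
    }
  }
  check(cfg, def, "")
  for (sec in intersect(names(cfg), names(def))) {
    if (is.list(def[[sec]])) check(cfg[[sec]], def[[sec]], paste0(sec, "$"))
  }
  utils::modifyList(def, cfg)
}

#' @rdname load_config
#' @param config Configuration list as returned by [load_config()].
#' @export
save_config <- function(config, path) {
  check <- function(got, ref, where) {
    bad <- setdiff(names(got), names(ref))
    if (length(bad)) {
      stop(sprintf("unknown config key(s): %s",
                   paste0(where, bad, collapse = ", ")))
    }
  }
  def <- .default_config()
  check(config, def, "")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build assignment criteria from a configuration
#'
#' @param config Configuration list (see [load_config()]).
#' @return A [ppii_criteria()].
#' @export
criteria_from_config <- function(config) {
  cc <- config$criteria
  ppii_criteria(mode = cc$mode, trans_lo = cc$trans_lo,
                trans_hi = cc$trans_hi,
                regularity_max = cc$regularity_max, min_len = cc$min_len,
                omega_trans_check = isTRUE(cc$omega_trans_check))
}

#' Build a training configuration from a configuration
#'
#' @param config Configuration list (see [load_config()]).
#' @return A [train_config()].
#' @export
train_config_from_config <- function(config) {
  tc <- config$train
  train_config(epochs = tc$epochs, updates_per_epoch = tc$updates_per_epoch,
               lr_init = tc$lr_init,
               lr_halving_patience = tc$lr_halving_patience,
               hidden_dim = tc$hidden_dim, mlp_hidden = tc$mlp_hidden,
               seed = config$seed)
}
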