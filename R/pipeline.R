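# Dataset splitting, fivefold cross-validation, the proline-window
# baseline, and extraction of high-scoring regions from score tracks.

#' Deterministic test split: every 10th sequence
#'
#' Positions 10, 20, 30, ... (1-based, in the given order) are assigned to
#' the independent test set; the rest are training.
#'
#' @param ids Ordered vector of sequence identifiers.
#' @return List with `train_ids` and `test_ids`.
#' @export
split_every_tenth <- function(ids) {
  idx <- seq_along(ids)
  test <- idx %% 10 == 0
  list(train_ids = ids[!test], test_ids = ids[test])
}

#' Random fold assignment
#'
#' A seeded random permutation dealt round-robin into `k` folds, so fold
#' sizes differ by at most one.
#'
#' @param train_ids Identifiers to partition.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of `k` identifier vectors.
#' @export
make_folds <- function(train_ids, k = 5, seed = 1L) {
  stopifnot(k >= 2)
  n <- length(train_ids)
  if (n < k) stop(sprintf("cannot split %d ids into %d folds", n, k))
  old <- .save_rng_state()
  set.seed(as.integer(seed))
  perm <- sample(train_ids)
  .restore_seed(old)
  split(perm, rep_len(seq_len(k), n))
}

#' Fivefold cross-validation
#'
#' For each fold, trains a network on the other folds and predicts the
#' held-out fold. Returns the `k` trained models (the ensemble) and the
#' pooled held-out (score, label) pairs for evaluation.
#'
#' @param corpus Named list of `list(x = feature matrix, y = labels)`; names
#'   are sequence ids.
#' @param config A [train_config()].
#' @param k Number of folds.
#' @param verbose Forwarded to [train()].
#' @return List with `models` (length `k`), `scores`, `labels` (pooled over
#'   held-out folds) and `folds`.
#' @export
run_crossval <- function(corpus, config = train_config(), k = 5,
                         verbose = FALSE) {
  ids <- names(corpus)
  if (is.null(ids)) stop("corpus must be a named list")
  folds <- make_folds(ids, k = k, seed = config$seed)
  input_dim <- ncol(corpus[[1]]$x)
  models <- vector("list", k)
  scores <- numeric(0); labels <- integer(0)
  for (f in seq_len(k)) {
    held <- folds[[f]]
    train_set <- corpus[setdiff(ids, held)]
    val_set <- corpus[held]
    m0 <- init_model(input_dim, config$hidden_dim, config$mlp_hidden,
                     seed = config$seed + f)
    fit <- train(m0, train_set, config, validation = val_set,
                 verbose = verbose)
    models[[f]] <- fit$model
    for (id in held) {
      scores <- c(scores, forward(fit$model, corpus[[id]]$x))
      labels <- c(labels, corpus[[id]]$y)
    }
  }
  list(models = models, scores = scores, labels = as.integer(labels),
       folds = folds)
}

#' Proline-window baseline score
#'
#' The fraction of prolines in a window of `w` residues to either side of
#' each position; truncated windows at the termini are normalised by the
#' number of positions actually present, so scores stay within the unit interval.
#'
#' @param seq Amino-acid string.
#' @param w Half-width, 0..9 (window sizes 1 to 19).
#' @return Numeric vector, one score per residue.
#' @export
proline_window_score <- function(seq, w = 2) {
  stopifnot(w >= 0)
  aa <- strsplit(toupper(seq), "")[[1]]
  n <- length(aa)
  isP <- as.numeric(aa == "P")
  cs <- c(0, cumsum(isP))
  lo <- pmax(seq_len(n) - w, 1)
  hi <- pmin(seq_len(n) + w, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract high-scoring regions from a score track
#'
#' Maximal runs of residues with score >= `cutoff`; runs of length strictly
#' greater than `min_len_exclusive` are reported with their mean score,
#' sorted by mean score descending.
#'
#' @param scores Per-residue score vector.
#' @param cutoff Score threshold (call at score >= cutoff).
#' @param min_len_exclusive Regions must be strictly longer than this.
#' @param id Identifier copied into the result.
#' @return data.frame with columns `id`, `start`, `end`, `length`,
#'   `mean_score` (1-based inclusive coordinates).
#' @export
high_scoring_regions <- function(scores, cutoff = 0.5, min_len_exclusive = 3,
                                 id = "seq") {
  out <- data.frame(id = character(0), start = integer(0), end = integer(0),
                    length = integer(0), mean_score = numeric(0))
  if (length(scores) == 0) return(out)
  r <- rle(scores >= cutoff)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] <= min_len_exclusive) next
    out <- rbind(out, data.frame(
      id = id, start = starts[k], end = ends[k], length = r$lengths[k],
      mean_score = mean(scores[starts[k]:ends[k]])))
  }
  out[order(-out$mean_score), , drop = FALSE]
}
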