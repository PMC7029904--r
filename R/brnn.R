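# R-facing interface to the recurrent network core: model construction,
# forward/gradient wrappers, the SGD training schedule, ensembling, and
# JSON model serialization.

#' @useDynLib ppiipred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Initialise a bidirectional recurrent network
#'
#' Weights are drawn per layer from a Glorot-style symmetric uniform
#' distribution, ±sqrt(6 / (fan_in + fan_out)) — the standard choice for
#' tanh layers — entirely determined by `seed`; two calls with identical
#' arguments produce identical models.
#'
#' @param input_dim Width of per-residue input vectors (24 or 45 for the
#'   standard encodings; any positive value is accepted).
#' @param hidden_dim Size of the forward/backward hidden-state vectors.
#' @param mlp_hidden Hidden-layer size of the three two-layer perceptrons.
#' @param seed Integer RNG seed.
#' @return An object of class `brnn_model`.
#' @export
init_model <- function(input_dim, hidden_dim = 11, mlp_hidden = 11, seed = 1L) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, mlp_hidden >= 1)
  I <- as.integer(input_dim); H <- as.integer(hidden_dim)
  M <- as.integer(mlp_hidden)
  npar <- .brnn_npar_cpp(I, H, M)
  old <- .save_rng_state()
  set.seed(as.integer(seed))
  sizes <- .brnn_block_sizes(I, H, M)
  params <- numeric(0)
  for (b in sizes) {
    lim <- sqrt(6 / (b$fan_in + b$fan_out))
    params <- c(params, stats::runif(b$n, -lim, lim))
  }
  stopifnot(length(params) == npar)
  .restore_seed(old)
  structure(list(params = params, input_dim = I, hidden_dim = H,
                 mlp_hidden = M, seed = as.integer(seed),
                 alphabet = paste0(aa_alphabet, collapse = "")),
            class = "brnn_model")
}

.brnn_block_sizes <- function(I, H, M) {
  blk <- function(n, fi, fo) list(n = n, fan_in = fi, fan_out = fo)
  list(
    blk(M * (I + H), I + H, M), blk(M, I + H, M),
    blk(H * M, M, H), blk(H, M, H),
    blk(M * (I + H), I + H, M), blk(M, I + H, M),
    blk(H * M, M, H), blk(H, M, H),
    blk(M * (I + 2 * H), I + 2 * H, M), blk(M, I + 2 * H, M),
    blk(M, M, 1), blk(1, M, 1)
  )
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.brnn_model <- function(x, ...) {
  cat(sprintf("<brnn_model: input %d, hidden %d, mlp %d, %d parameters>\n",
              x$input_dim, x$hidden_dim, x$mlp_hidden, length(x$params)))
  invisible(x)
}

.as_feature_matrix <- function(features) {
  m <- unclass(features)
  storage.mode(m) <- "double"
  m
}

#' Forward pass
#'
#' Per-residue scores in (0, 1): the forward hidden chain is filled left to
#' right, the backward chain right to left, then the output net combines
#' both with the local input at each position.
#'
#' @param model A [init_model()] network.
#' @param features Numeric matrix, rows = residues, ncol = `input_dim`.
#' @return Numeric vector of scores, one per residue.
#' @export
forward <- function(model, features) {
  stopifnot(inherits(model, "brnn_model"))
  X <- .as_feature_matrix(features)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("feature width %d does not match model input_dim %d",
                 ncol(X), model$input_dim))
  }
  .brnn_forward_cpp(model$params, model$input_dim, model$hidden_dim,
                    model$mlp_hidden, X)
}

#' Mean binary cross-entropy
#'
#' @param scores Scores in (0, 1).
#' @param labels 0/1 labels, same length.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  eps <- 1e-12
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

#' Loss gradients by backpropagation
#'
#' Exact gradients of the mean binary cross-entropy with respect to every
#' parameter, backpropagated through both hidden chains.
#'
#' @inheritParams forward
#' @param labels 0/1 vector, one per residue.
#' @return List with `loss`, `grad` (flat vector aligned with
#'   `model$params`) and `scores`.
#' @export
gradients <- function(model, features, labels) {
  stopifnot(inherits(model, "brnn_model"))
  X <- .as_feature_matrix(features)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("feature width %d does not match model input_dim %d",
                 ncol(X), model$input_dim))
  }
  .brnn_grad_cpp(model$params, model$input_dim, model$hidden_dim,
                 model$mlp_hidden, X, as.numeric(labels))
}

#' Training configuration
#'
#' Defaults follow the published schedule: 2000 epochs, 1920 weight updates
#' per epoch, initial learning rate 0.005 halved after 1000 epochs without
#' improvement of the validation error. For datasets smaller than
#' `updates_per_epoch` sequences, one update is taken per sequence.
#'
#' @param epochs Passes through the training set.
#' @param updates_per_epoch Weight updates per epoch at full scale.
#' @param lr_init Initial learning rate.
#' @param lr_halving_patience Epochs without validation-error improvement
#'   before the learning rate is halved.
#' @param hidden_dim,mlp_hidden Network sizes passed to [init_model()].
#' @param seed RNG seed controlling initialisation and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 2000, updates_per_epoch = 1920,
                         lr_init = 0.005, lr_halving_patience = 1000,
                         hidden_dim = 11, mlp_hidden = 11, seed = 1L) {
  stopifnot(epochs >= 1, updates_per_epoch >= 1, lr_init > 0,
            lr_halving_patience >= 1)
  structure(list(epochs = as.integer(epochs),
                 updates_per_epoch = as.integer(updates_per_epoch),
                 lr_init = lr_init,
                 lr_halving_patience = as.integer(lr_halving_patience),
                 hidden_dim = as.integer(hidden_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 seed = as.integer(seed)),
            class = "train_config")
}

.val_error <- function(model, validation) {
  # classification error at threshold 0.5, pooled over residues
  wrong <- 0L; total <- 0L
  for (d in validation) {
    s <- forward(model, d$x)
    wrong <- wrong + sum((s >= 0.5) != (d$y == 1))
    total <- total + length(s)
  }
  wrong / total
}

#' Train a network by stochastic gradient descent
#'
#' Each epoch, the training sequences are shuffled (seeded RNG) and dealt
#' into `min(updates_per_epoch, n)` near-equal groups; one gradient step is
#' taken per group on the mean of the group's per-sequence gradients. The
#' learning rate is halved whenever the validation error (classification
#' error at 0.5) has not improved for `lr_halving_patience` epochs.
#'
#' @param model Initial [init_model()] network.
#' @param dataset List of `list(x = feature matrix, y = 0/1 labels)`.
#' @param config A [train_config()].
#' @param validation Optional validation list in the same shape; defaults to
#'   the training set (used only to drive the schedule).
#' @param verbose Print progress every 50 epochs.
#' @return List with `model` (trained) and `history` (data.frame: epoch,
#'   loss, val_error, lr).
#' @export
train <- function(model, dataset, config = train_config(),
                  validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "brnn_model"), inherits(config, "train_config"))
  if (length(dataset) == 0) stop("empty training dataset")
  if (is.null(validation)) validation <- dataset
  n <- length(dataset)
  params <- model$params
  lr <- config$lr_init
  best_val <- Inf
  stall <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_error = numeric(0), lr = numeric(0))
  old <- .save_rng_state()
  set.seed(config$seed)
  on.exit(.restore_seed(old))
  n_groups <- min(config$updates_per_epoch, n)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    groups <- split(ord, rep(seq_len(n_groups), length.out = n))
    ep_loss <- 0
    for (grp in groups) {
      gsum <- NULL; lsum <- 0
      for (i in grp) {
        r <- .brnn_grad_cpp(params, model$input_dim, model$hidden_dim,
                            model$mlp_hidden,
                            .as_feature_matrix(dataset[[i]]$x),
                            as.numeric(dataset[[i]]$y))
        gsum <- if (is.null(gsum)) r$grad else gsum + r$grad
        lsum <- lsum + r$loss
      }
      params <- params - lr * gsum / length(grp)
      ep_loss <- ep_loss + lsum
    }
    model$params <- params
    ve <- .val_error(model, validation)
    if (ve < best_val - 1e-12) {
      best_val <- ve
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$lr_halving_patience) {
        lr <- lr / 2
        stall <- 0L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                   val_error = ve, lr = lr))
    if (verbose && ep %% 50 == 0) {
      message(sprintf("epoch %d: loss %.4f val_error %.4f lr %.5f",
                      ep, ep_loss / n, ve, lr))
    }
  }
  list(model = model, history = hist)
}

#' Ensemble prediction
#'
#' Arithmetic mean of the per-model score tracks; all models must share the
#' input width.
#'
#' @param models Non-empty list of [init_model()] networks.
#' @param features Feature matrix.
#' @return Per-residue mean scores.
#' @export
ensemble_predict <- function(models, features) {
  if (length(models) == 0) stop("empty model list")
  dims <- vapply(models, `[[`, 1L, "input_dim")
  if (length(unique(dims)) != 1) stop("models disagree on input_dim")
  tracks <- vapply(models, forward, numeric(nrow(features)),
                   features = features)
  if (is.null(dim(tracks))) tracks <- matrix(tracks, nrow = 1)
  rowMeans(tracks)
}

#' Save / load a model as JSON
#'
#' The header records dimensions, the amino-acid alphabet and the seed;
#' loading refuses a file whose layout does not match the current encoding.
#'
#' @param model A `brnn_model`.
#' @param path File path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "brnn_model"))
  obj <- list(format = "ppiipred-brnn-1",
              input_dim = model$input_dim, hidden_dim = model$hidden_dim,
              mlp_hidden = model$mlp_hidden, seed = model$seed,
              alphabet = model$alphabet, params = model$params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ppiipred-brnn-1")) {
    stop("not a ppiipred model file (format mismatch)")
  }
  if (!identical(obj$alphabet, paste0(aa_alphabet, collapse = ""))) {
    stop("model alphabet does not match this package's encoding")
  }
  npar <- .brnn_npar_cpp(obj$input_dim, obj$hidden_dim, obj$mlp_hidden)
  if (length(obj$params) != npar) stop("model parameter payload has wrong length")
  structure(list(params = as.numeric(obj$params),
                 input_dim = as.integer(obj$input_dim),
                 hidden_dim = as.integer(obj$hidden_dim),
                 mlp_hidden = as.integer(obj$mlp_hidden),
                 seed = as.integer(obj$seed), alphabet = obj$alphabet),
            class = "brnn_model")
}

#' Write a training history as TSV
#'
#' @param history The `history` data.frame from [train()].
#' @param path Output path.
#' @export
write_history_tsv <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
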