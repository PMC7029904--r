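# Synthetic fixtures: backbone structures with planted conformational
# segments, and labelled sequence corpora with a planted, learnable rule.
# These stand in for curated structure databases so the whole pipeline is
# testable offline.

# canonical backbone dihedrals per conformation (degrees)
.canonical_angles <- list(
  ppii  = c(phi = -75,  psi = 145, omega = 180),
  alpha = c(phi = -60,  psi = -45, omega = 180),
  beta  = c(phi = -120, psi = 130, omega = 180)
)

#' Build a backbone structure with planted conformational segments
#'
#' Concatenates segments of canonical polyproline-II (phi -75, psi 145),
#' alpha-helix (-60, -45), beta-strand (-120, 130) or custom dihedrals,
#' optionally perturbed by Gaussian angle noise, and returns the chain
#' together with the ground-truth per-residue labels (1 inside planted
#' `ppii` segments).
#'
#' @param segments List of `list(conformation = "ppii"|"alpha"|"beta"|
#'   "custom", length = n, phi =, psi =, omega =)`; the explicit angles are
#'   only used for `"custom"`.
#' @param angle_noise_sd Gaussian noise (degrees) added independently to
#'   every phi/psi (omega kept at its segment value).
#' @param seed RNG seed.
#' @param aa Residue letters: by default `P` inside ppii segments, `A`
#'   elsewhere.
#' @return List with `chain` (a [backbone_chain()]), `truth` (0/1 vector)
#'   and `angles` (the requested dihedral table).
#' @export
make_structure <- function(segments, angle_noise_sd = 0, seed = 1L, aa = NULL) {
  stopifnot(length(segments) >= 1, angle_noise_sd >= 0)
  rows <- list(); truth <- integer(0); letters1 <- character(0)
  for (sg in segments) {
    len <- sg$length
    stopifnot(len >= 1)
    ang <- if (identical(sg$conformation, "custom")) {
      c(phi = sg$phi, psi = sg$psi, omega = sg$omega)
    } else {
      .canonical_angles[[sg$conformation]]
    }
    if (is.null(ang)) stop("unknown conformation: ", sg$conformation)
    rows[[length(rows) + 1]] <- data.frame(
      phi = rep(ang[["phi"]], len), psi = rep(ang[["psi"]], len),
      omega = rep(ang[["omega"]], len))
    is_ppii <- identical(sg$conformation, "ppii")
    truth <- c(truth, rep(as.integer(is_ppii), len))
    letters1 <- c(letters1, rep(if (is_ppii) "P" else "A", len))
  }
  angles <- do.call(rbind, rows)
  if (!is.null(aa)) letters1 <- rep_len(aa, nrow(angles))
  old <- .save_rng_state()
  set.seed(as.integer(seed))
  if (angle_noise_sd > 0) {
    angles$phi <- .wrap_angle(angles$phi + stats::rnorm(nrow(angles), 0, angle_noise_sd))
    angles$psi <- .wrap_angle(angles$psi + stats::rnorm(nrow(angles), 0, angle_noise_sd))
  }
  .restore_seed(old)
  chain <- build_backbone(angles, aa = letters1)
  list(chain = chain, truth = truth, angles = angles)
}

# background amino-acid frequencies, approximately natural proteome
# composition (fractions sum to 1 over the ppiipred alphabet order)
.bg_freq <- c(A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039,
              G = 0.071, H = 0.023, I = 0.059, K = 0.058, L = 0.097,
              M = 0.024, N = 0.040, P = 0.047, Q = 0.039, R = 0.055,
              S = 0.066, T = 0.053, V = 0.069, W = 0.011, Y = 0.030)

# composition of the non-proline positions inside planted stretches: the
# side-chain-extending residues favoured by polyproline II helices dominate,
# so the sequence context carries signal beyond proline alone. Stretches
# themselves are an alternating proline anchor (P at odd positions), so
# every stretch is at least half proline but never contains adjacent
# prolines — compact PP/PPP runs in the background are decoys.
.stretch_partner_freq <- local({
  f <- stats::setNames(rep(0, 19), setdiff(names(.bg_freq), "P"))
  ext <- c("A", "L", "M", "K", "R", "E", "Q", "V")
  f[ext] <- 0.80 / length(ext)
  rest <- setdiff(names(f), ext)
  f[rest] <- 0.20 / length(rest)
  f
})

#' Corpus specification for the planted-rule generator
#'
#' @param n_sequences Number of sequences.
#' @param len_range Sequence lengths drawn uniformly from this range.
#' @param target_positive Target fraction of positive (planted) residues;
#'   default 0.024 emulates the class imbalance of the strict structural
#'   training corpus.
#' @param stretch_len_range Planted stretch lengths, uniform over this
#'   range (minimum 3, the shortest admissible helix).
#' @param background Background amino-acid frequencies (named, alphabet
#'   order free).
#' @param partner Frequencies of the non-proline positions inside planted
#'   stretches (stretches alternate P with draws from this distribution).
#' @param decoy_rate Mean number (Poisson) of unlabelled compact PP/PPP
#'   decoy runs planted in the background per sequence.
#' @param seed RNG seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_sequences = 500, len_range = c(60, 140),
                        target_positive = 0.024,
                        stretch_len_range = c(3, 6),
                        background = .bg_freq,
                        partner = .stretch_partner_freq,
                        decoy_rate = 1, seed = 1L) {
  stopifnot(n_sequences >= 1, len_range[1] >= 10,
            stretch_len_range[1] >= 3, target_positive > 0,
            target_positive < 0.5, decoy_rate >= 0)
  structure(list(n_sequences = as.integer(n_sequences),
                 len_range = as.integer(len_range),
                 target_positive = target_positive,
                 stretch_len_range = as.integer(stretch_len_range),
                 background = background / sum(background),
                 partner = partner / sum(partner),
                 decoy_rate = decoy_rate,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a labelled sequence corpus with a planted rule
#'
#' Sequences are drawn from the background composition; proline-anchored
#' stretches (length >= 3, proline at every odd position, side-chain
#' extenders in between) are planted at random non-overlapping positions
#' and their residues labelled positive. The number of stretches per
#' sequence is Poisson with mean chosen so the corpus-wide positive
#' fraction matches `target_positive` in expectation. Unlabelled compact
#' PP/PPP decoy runs are additionally planted in the background (rate
#' `decoy_rate`): proline content alone therefore cannot separate the
#' classes, while the alternating anchor pattern can.
#'
#' @param spec A [corpus_spec()].
#' @return Named list of [labelled_sequence()] objects, deterministic per
#'   seed.
#' @export
make_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  old <- .save_rng_state()
  set.seed(spec$seed)
  on.exit(.restore_seed(old))
  mean_stretch <- mean(spec$stretch_len_range)
  out <- list()
  for (i in seq_len(spec$n_sequences)) {
    len <- sample(spec$len_range[1]:spec$len_range[2], 1)
    aa <- sample(names(spec$background), len, replace = TRUE,
                 prob = spec$background)
    labels <- integer(len)
    lambda <- spec$target_positive * len / mean_stretch
    n_str <- stats::rpois(1, lambda)
    for (s in seq_len(n_str)) {
      slen <- sample(spec$stretch_len_range[1]:spec$stretch_len_range[2], 1)
      # up to 20 attempts to find a non-overlapping slot
      for (try in 1:20) {
        start <- sample.int(len - slen + 1, 1)
        if (all(labels[start:(start + slen - 1)] == 0)) {
          lets <- character(slen)
          for (j in seq_len(slen)) {
            lets[j] <- if (j %% 2 == 1) "P" else {
              sample(names(spec$partner), 1, prob = spec$partner)
            }
          }
          aa[start:(start + slen - 1)] <- lets
          labels[start:(start + slen - 1)] <- 1L
          break
        }
      }
    }
    n_dec <- stats::rpois(1, spec$decoy_rate)
    for (s in seq_len(n_dec)) {
      dlen <- sample(2:3, 1)
      for (try in 1:20) {
        start <- sample.int(len - dlen + 1, 1)
        pad <- max(1, start - 1):min(len, start + dlen)
        if (all(labels[pad] == 0)) {
          aa[start:(start + dlen - 1)] <- "P"
          break
        }
      }
    }
    id <- sprintf("syn%04d", i)
    out[[id]] <- labelled_sequence(id, paste0(aa, collapse = ""), labels)
  }
  out
}

#' Encode a labelled corpus for training
#'
#' @param corpus Named list of [labelled_sequence()] objects.
#' @param msa,disorder Optional per-id lists forwarded to
#'   [encode_sequence()].
#' @return Named list of `list(x = feature matrix, y = labels)`.
#' @export
encode_corpus <- function(corpus, msa = NULL, disorder = NULL) {
  out <- list()
  for (id in names(corpus)) {
    ls <- corpus[[id]]
    out[[id]] <- list(
      x = encode_sequence(ls$seq, msa = msa[[id]],
                          disorder = disorder[[id]], id = id),
      y = ls$labels)
  }
  out
}
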