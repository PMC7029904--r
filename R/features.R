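# Per-residue input encoding for the recurrent network:
# [20 one-hot | length | charge | (20 profile | gap) | iupred | espritz].

#' Amino-acid alphabet used for one-hot and profile encoding
#'
#' Fixed alphabetical order of the 20 standard residues. Any change to this
#' vector is a model-breaking format change: serialized models record it and
#' refuse to load on mismatch.
#' @export
aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# sequence length is normalised by this cap
.length_cap <- 2000

#' One-hot encoding of a residue
#'
#' Unit vector over [aa_alphabet] for standard residues; all-zero for
#' unknown/non-standard letters (B, Z, U, X, ...).
#'
#' @param aa Character vector of one-letter codes.
#' @return Matrix, one row per input letter, 20 columns.
#' @export
one_hot <- function(aa) {
  aa <- toupper(aa)
  m <- matrix(0, length(aa), 20, dimnames = list(NULL, aa_alphabet))
  idx <- match(aa, aa_alphabet)
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

#' Residue charge input
#'
#' +1 for R or K, -1 for D or E, 0 otherwise (histidine counts as neutral).
#'
#' @param aa Character vector of one-letter codes.
#' @return Numeric vector in \{-1, 0, 1\}.
#' @export
charge_input <- function(aa) {
  aa <- toupper(aa)
  ifelse(aa %in% c("R", "K"), 1, ifelse(aa %in% c("D", "E"), -1, 0))
}

#' Sequence length input
#'
#' `min(N, 2000) / 2000`, the same value repeated at every position: a
#' bounded scalar cue about overall chain length.
#'
#' @param N Sequence length (>= 1).
#' @return Value in (0, 1].
#' @export
length_input <- function(N) {
  stopifnot(N >= 1)
  pmin(N, .length_cap) / .length_cap
}

#' Amino-acid frequency profile from a multiple sequence alignment
#'
#' For every query (non-gap) column, the frequency of each of the 20
#' standard residues plus the gap frequency across all rows. Non-standard
#' letters count toward neither a residue nor the gap, and the vector is
#' renormalised over the counted symbols, so each row sums to 1.
#'
#' @param alignment Character vector of aligned sequences, equal lengths,
#'   query first. Gaps are `-` or `.`.
#' @return Matrix with one row per query residue and 21 columns
#'   (`aa_alphabet`, then `gap`).
#' @export
msa_profile <- function(alignment) {
  if (length(alignment) == 0) stop("empty alignment")
  alignment <- toupper(alignment)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) stop("ragged alignment: rows differ in length")
  chars <- do.call(rbind, strsplit(alignment, ""))
  chars[chars == "."] <- "-"
  query_cols <- which(chars[1, ] != "-")
  if (length(query_cols) == 0) stop("query row is all gaps")
  prof <- matrix(0, length(query_cols), 21,
                 dimnames = list(NULL, c(aa_alphabet, "gap")))
  for (k in seq_along(query_cols)) {
    col <- chars[, query_cols[k]]
    counted <- col %in% c(aa_alphabet, "-")
    col <- col[counted]
    if (length(col) == 0) next  # all symbols non-standard: leave zeros
    tab <- table(factor(col, levels = c(aa_alphabet, "-")))
    prof[k, ] <- as.numeric(tab) / length(col)
  }
  prof
}

#' Disorder score track
#'
#' Per-residue intrinsic-disorder scores standing in for external predictor
#' output (a long-disorder score and an NMR-flavoured score). Values are
#' clipped into the unit interval.
#'
#' @param id Sequence identifier.
#' @param iupred_long,espritz_nmr Numeric vectors, one value per residue.
#' @return An object of class `disorder_track`.
#' @export
disorder_track <- function(id, iupred_long, espritz_nmr) {
  stopifnot(length(iupred_long) == length(espritz_nmr))
  clip <- function(x) pmin(pmax(as.numeric(x), 0), 1)
  structure(list(id = id, iupred_long = clip(iupred_long),
                 espritz_nmr = clip(espritz_nmr)),
            class = "disorder_track")
}

#' Read disorder tracks from TSV
#'
#' Expects columns `id`, `position`, `iupred_long`, `espritz_nmr`; one file
#' can hold several sequences.
#'
#' @param path TSV path.
#' @return Named list of [disorder_track()] objects.
#' @export
read_disorder_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("id", "position", "iupred_long", "espritz_nmr")
  if (!all(need %in% names(df))) {
    stop("disorder TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (id in unique(df$id)) {
    sub <- df[df$id == id, ]
    sub <- sub[order(sub$position), ]
    out[[id]] <- disorder_track(id, sub$iupred_long, sub$espritz_nmr)
  }
  out
}

#' Encode a sequence into the network's input matrix
#'
#' Layout: 20 one-hot columns, length, charge, then (with an alignment) the
#' 21 profile columns, then the two disorder columns. Width is 24 without an
#' alignment and 45 with one. Absent disorder scores are encoded as zeros
#' (a documented degraded mode, like running without an alignment).
#'
#' @param seq Amino-acid string.
#' @param msa Optional aligned sequences (query first); the query with gaps
#'   removed must equal `seq`.
#' @param disorder Optional [disorder_track()].
#' @param id Identifier used in error messages.
#' @return A numeric matrix of class `feature_matrix` (rows = residues).
#' @export
encode_sequence <- function(seq, msa = NULL, disorder = NULL, id = "seq") {
  seq <- toupper(seq)
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  stopifnot(n >= 1)
  blocks <- list(one_hot(aa),
                 length = rep(length_input(n), n),
                 charge = charge_input(aa))
  if (!is.null(msa)) {
    prof <- msa_profile(msa)
    q <- gsub("[-.]", "", toupper(msa[1]))
    if (q != seq) stop(sprintf("MSA query does not match sequence '%s'", id))
    blocks$profile <- prof
  }
  dis <- matrix(0, n, 2, dimnames = list(NULL, c("iupred", "espritz")))
  if (!is.null(disorder)) {
    if (length(disorder$iupred_long) != n) {
      stop(sprintf("disorder track length %d does not match sequence '%s' (%d residues)",
                   length(disorder$iupred_long), id, n))
    }
    dis[, 1] <- disorder$iupred_long
    dis[, 2] <- disorder$espritz_nmr
  }
  blocks$disorder <- dis
  m <- do.call(cbind, blocks)
  colnames(m) <- c(aa_alphabet, "length", "charge",
                   if (!is.null(msa)) paste0("p_", c(aa_alphabet, "gap")),
                   "iupred", "espritz")
  class(m) <- c("feature_matrix", class(m))
  attr(m, "id") <- id
  m
}
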