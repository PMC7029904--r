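# PPII helix assignment from backbone dihedrals: trans filtering on the
# C-alpha pseudo-dihedral, dihedral filtering on psi (and phi in strict
# mode), and a regularity filter on candidate segments.

#' PPII assignment criteria
#'
#' The strict definition requires psi in (-180,-160) or (90,180) together
#' with phi in (-105,-45); the less strict definition drops the phi
#' requirement. Both require the C-alpha pseudo-dihedral inside
#' (`trans_lo`, `trans_hi`), a minimum segment length, and a bound on the
#' segment's mean dihedral step (regularity).
#'
#' @param mode `"strict"` or `"non_strict"`.
#' @param trans_lo,trans_hi Bounds (degrees) on the C-alpha pseudo-dihedral.
#' @param psi_band1,psi_band2 Open psi intervals (degrees); psi must fall in
#'   their union. The upper end of `psi_band2` is closed at 180 since angles
#'   live in (-180, 180].
#' @param phi_band Open phi interval, applied in strict mode only.
#' @param regularity_max Maximum mean dihedral step per segment (degrees);
#'   `Inf` disables the regularity filter.
#' @param min_len Minimum segment length in residues.
#' @param omega_trans_check If `TRUE`, additionally require `|omega| > 150`
#'   (a peptide-bond trans test). Off by default: the default trans filter
#'   is the pseudo-dihedral bound.
#' @return An object of class `ppii_criteria`.
#' @export
ppii_criteria <- function(mode = c("strict", "non_strict"),
                          trans_lo = -145, trans_hi = -70,
                          psi_band1 = c(-180, -160), psi_band2 = c(90, 180),
                          phi_band = c(-105, -45),
                          regularity_max = 30, min_len = 3,
                          omega_trans_check = FALSE) {
  mode <- match.arg(mode)
  stopifnot(min_len >= 1, regularity_max >= 0)
  structure(list(mode = mode, trans_lo = trans_lo, trans_hi = trans_hi,
                 psi_band1 = psi_band1, psi_band2 = psi_band2,
                 phi_band = phi_band, regularity_max = regularity_max,
                 min_len = as.integer(min_len),
                 omega_trans_check = isTRUE(omega_trans_check)),
            class = "ppii_criteria")
}

.in_open <- function(x, band, closed_hi = FALSE) {
  !is.na(x) & x > band[1] & (if (closed_hi) x <= band[2] else x < band[2])
}

#' Dihedral filter
#'
#' `TRUE` iff psi is defined and inside one of the two psi bands, and — in
#' strict mode — phi is defined and inside the phi band. Vectorised over the
#' rows of a dihedral table.
#'
#' @param rec A data.frame with columns `phi`, `psi` (from
#'   [chain_dihedrals()]); `NA` = undefined.
#' @param crit A [ppii_criteria()].
#' @return Logical vector.
#' @export
passes_dihedral_filter <- function(rec, crit) {
  psi_ok <- .in_open(rec$psi, crit$psi_band1) |
    .in_open(rec$psi, crit$psi_band2, closed_hi = crit$psi_band2[2] >= 180)
  if (crit$mode == "strict") {
    psi_ok & .in_open(rec$phi, crit$phi_band)
  } else {
    psi_ok
  }
}

#' Trans filter
#'
#' `TRUE` iff the C-alpha pseudo-dihedral is defined and strictly inside
#' (`trans_lo`, `trans_hi`); with `omega_trans_check` also requires a trans
#' peptide bond (`|omega| > 150`, omega defined).
#'
#' @inheritParams passes_dihedral_filter
#' @return Logical vector.
#' @export
passes_trans_filter <- function(rec, crit) {
  ok <- .in_open(rec$ca_pseudo, c(crit$trans_lo, crit$trans_hi))
  if (crit$omega_trans_check) {
    ok <- ok & !is.na(rec$omega) & abs(rec$omega) > 150
  }
  ok
}

.wrap_diff <- function(a, b) {
  # wrapped angular difference a - b in (-180, 180]
  .wrap_angle(a - b)
}

#' Segment regularity
#'
#' Mean dihedral step of a candidate segment: the sum over the n-1
#' consecutive residue pairs of sqrt(dpsi^2 + dphi^2) (wrapped angular
#' differences), divided by n, the number of residues. A perfectly repeating
#' helix scores 0.
#'
#' @param records data.frame with columns `phi`, `psi`, all defined, >= 2 rows.
#' @return Mean step in degrees, or `NA` for fewer than 2 records.
#' @export
segment_regularity <- function(records) {
  n <- nrow(records)
  if (is.null(n) || n < 2) return(NA_real_)
  if (anyNA(records$phi) || anyNA(records$psi)) return(NA_real_)
  dpsi <- .wrap_diff(records$psi[-n], records$psi[-1])
  dphi <- .wrap_diff(records$phi[-n], records$phi[-1])
  sum(sqrt(dpsi^2 + dphi^2)) / n
}

#' Assign PPII helix labels to a chain
#'
#' Marks residues passing both the trans and the dihedral filter, forms
#' maximal runs of marked residues, drops runs shorter than `min_len` or with
#' regularity above `regularity_max`, and labels the residues of the
#' surviving segments.
#'
#' @param chain A [backbone_chain()].
#' @param crit A [ppii_criteria()].
#' @param dihedrals Optional precomputed [chain_dihedrals()] table.
#' @return A `labelled_sequence`: list with `id`, `seq`, `labels` (0/1
#'   integer vector) and `segments` (data.frame `start`, `end`, `length`,
#'   `regularity`).
#' @export
assign_ppii <- function(chain, crit = ppii_criteria(), dihedrals = NULL) {
  stopifnot(inherits(chain, "backbone_chain"), inherits(crit, "ppii_criteria"))
  n <- length(chain)
  seq_str <- paste0(chain$aa, collapse = "")
  if (n == 0) {
    return(labelled_sequence(chain$chain_id, "", integer(0)))
  }
  rec <- if (is.null(dihedrals)) suppressWarnings(chain_dihedrals(chain)) else dihedrals
  pass <- passes_dihedral_filter(rec, crit) & passes_trans_filter(rec, crit)
  segs <- .runs_to_segments(pass, rec, crit)
  labels <- integer(n)
  if (nrow(segs)) {
    for (k in seq_len(nrow(segs))) labels[segs$start[k]:segs$end[k]] <- 1L
  }
  labelled_sequence(chain$chain_id, seq_str, labels, segments = segs)
}

.runs_to_segments <- function(pass, rec, crit) {
  segs <- data.frame(start = integer(0), end = integer(0),
                     length = integer(0), regularity = numeric(0))
  r <- rle(as.logical(pass))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!isTRUE(r$values[k]) || r$lengths[k] < crit$min_len) next
    reg <- segment_regularity(rec[starts[k]:ends[k], , drop = FALSE])
    if (!is.na(reg) && reg > crit$regularity_max) next
    segs <- rbind(segs, data.frame(start = starts[k], end = ends[k],
                                   length = r$lengths[k], regularity = reg))
  }
  segs
}

#' Labelled sequence container
#'
#' @param id Sequence identifier.
#' @param seq One-letter amino-acid string.
#' @param labels Integer 0/1 vector, one per residue.
#' @param segments Optional segment table (`start`, `end`, `length`,
#'   `regularity`); derived from `labels` when omitted.
#' @return An object of class `labelled_sequence`.
#' @export
labelled_sequence <- function(id, seq, labels, segments = NULL) {
  labels <- as.integer(labels)
  stopifnot(nchar(seq) == length(labels), all(labels %in% c(0L, 1L)))
  if (is.null(segments)) {
    segments <- data.frame(start = integer(0), end = integer(0),
                           length = integer(0), regularity = numeric(0))
    if (length(labels)) {
      r <- rle(labels == 1L)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      if (length(keep)) {
        segments <- data.frame(start = starts[keep], end = ends[keep],
                               length = r$lengths[keep],
                               regularity = NA_real_)
      }
    }
  }
  structure(list(id = id, seq = seq, labels = labels, segments = segments),
            class = "labelled_sequence")
}

#' @export
print.labelled_sequence <- function(x, ...) {
  cat(sprintf("<labelled_sequence %s: %d residues, %d PPII, %d segment(s)>\n",
              x$id, length(x$labels), sum(x$labels), nrow(x$segments)))
  invisible(x)
}

#' Write per-residue labels and dihedrals as TSV
#'
#' Columns: id, res_index, aa, phi, psi, omega, ca_pseudo, label.
#'
#' @param chain A [backbone_chain()].
#' @param labelled The matching [labelled_sequence()].
#' @param path Output path.
#' @param dihedrals Optional precomputed dihedral table.
#' @return `path`, invisibly.
#' @export
write_label_tsv <- function(chain, labelled, path, dihedrals = NULL) {
  rec <- if (is.null(dihedrals)) suppressWarnings(chain_dihedrals(chain)) else dihedrals
  df <- data.frame(id = labelled$id, res_index = chain$res_index,
                   aa = chain$aa,
                   phi = round(rec$phi, 3), psi = round(rec$psi, 3),
                   omega = round(rec$omega, 3),
                   ca_pseudo = round(rec$ca_pseudo, 3),
                   label = labelled$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write segments as a BED-like file
#'
#' Half-open 0-based coordinates (BED convention), columns: id, start, end,
#' length, regularity.
#'
#' @param labelled A [labelled_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_bed <- function(labelled, path) {
  s <- labelled$segments
  df <- data.frame(id = rep(labelled$id, nrow(s)),
                   start = s$start - 1L, end = s$end,
                   length = s$length, regularity = round(s$regularity, 3))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
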