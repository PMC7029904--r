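# Backbone geometry: torsion angles, internal-to-Cartesian chain building,
# and PDB ATOM-record I/O restricted to the N/CA/C backbone atoms.

#' Ideal backbone geometry constants
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used by
#' [build_backbone()]. Fixed in one place so reconstructed fixtures are
#' bit-for-bit reproducible.
#'
#' @format A named list: `b_n_ca`, `b_ca_c`, `b_c_n` (lengths, Angstrom);
#'   `a_n_ca_c`, `a_ca_c_n`, `a_c_n_ca` (angles, degrees).
#' @export
ideal_backbone_geometry <- list(
  b_n_ca   = 1.458,
  b_ca_c   = 1.525,
  b_c_n    = 1.329,
  a_n_ca_c = 111.2,
  a_ca_c_n = 116.2,
  a_c_n_ca = 121.7
)

# maximum C(i)-N(i+1) distance for a peptide bond; beyond this is a chain break
.chain_break_dist <- 2.0

#' Construct a backbone chain
#'
#' A `backbone_chain` holds the N, CA and C atom coordinates of an ordered
#' run of residues. Missing atoms are `NA` rows; dihedrals touching them are
#' undefined.
#'
#' @param res_index Integer vector of 1-based residue indices, strictly
#'   increasing.
#' @param aa Character vector of one-letter amino-acid codes.
#' @param N,CA,C Numeric matrices with one xyz row per residue (Angstrom).
#' @param chain_id Single-character chain identifier.
#' @return An object of class `backbone_chain`.
#' @export
backbone_chain <- function(res_index, aa, N, CA, C, chain_id = "A") {
  n <- length(res_index)
  stopifnot(length(aa) == n)
  as_m <- function(m) {
    m <- matrix(as.numeric(m), ncol = 3)
    stopifnot(nrow(m) == n)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  }
  if (n > 1 && any(diff(res_index) <= 0)) {
    stop("res_index must be strictly increasing")
  }
  structure(
    list(chain_id = chain_id, res_index = as.integer(res_index),
         aa = toupper(aa), N = as_m(N), CA = as_m(CA), C = as_m(C)),
    class = "backbone_chain"
  )
}

#' @export
length.backbone_chain <- function(x) length(x$res_index)

#' @export
print.backbone_chain <- function(x, ...) {
  cat(sprintf("<backbone_chain %s: %d residues, %s>\n", x$chain_id,
              length(x), paste0(x$aa[seq_len(min(10, length(x)))], collapse = "")))
  invisible(x)
}

.wrap_angle <- function(a) {
  # map to (-180, 180]
  a <- a - 360 * floor((a + 180) / 360)
  a[a == -180] <- 180
  a
}

#' Signed torsion angle of four points
#'
#' IUPAC sign convention: 0 degrees for a cis (eclipsed) arrangement, 180 for
#' trans. Antisymmetric under reversal of the point order.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors (length 3).
#' @return Angle in degrees in (-180, 180], or `NA` when the construction is
#'   degenerate (zero or collinear difference vectors).
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 == 0 || sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18) return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(cr(n1, n2) * b2) / nb2
  # atan2 gives the angle from the first normal to the second; shift so that
  # cis = 0 under the polymer convention
  .wrap_angle(atan2(y, x) / pi * 180)
}

.row_ok <- function(m, i) i >= 1 && i <= nrow(m) && !anyNA(m[i, ])

#' Backbone dihedral angles of a chain
#'
#' Computes phi, psi, omega and the C-alpha pseudo-dihedral per residue.
#' Conventions: `phi_i` = C(i-1),N(i),CA(i),C(i); `psi_i` =
#' N(i),CA(i),C(i),N(i+1); `omega_i` = CA(i-1),C(i-1),N(i),CA(i) (the peptide
#' bond preceding residue i); `ca_pseudo_i` = CA(i-1),CA(i),CA(i+1),CA(i+2).
#' Angles spanning a chain break (C(i)-N(i+1) distance above 2 Angstrom) or a
#' missing atom are `NA`.
#'
#' @param chain A [backbone_chain()].
#' @return A data.frame with columns `res_index`, `phi`, `psi`, `omega`,
#'   `ca_pseudo` (degrees; `NA` = undefined).
#' @export
chain_dihedrals <- function(chain) {
  stopifnot(inherits(chain, "backbone_chain"))
  n <- length(chain)
  out <- data.frame(res_index = chain$res_index,
                    phi = NA_real_, psi = NA_real_,
                    omega = NA_real_, ca_pseudo = NA_real_)
  if (n == 0) return(out)
  N <- chain$N; CA <- chain$CA; C <- chain$C
  # bonded[i]: residues i and i+1 are covalently continuous
  bonded <- rep(FALSE, max(n - 1, 0))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (.row_ok(C, i) && .row_ok(N, i + 1)) {
        bonded[i] <- sqrt(sum((C[i, ] - N[i + 1, ])^2)) < .chain_break_dist
      }
    }
  }
  miss <- 0L
  for (i in seq_len(n)) {
    if (i > 1 && bonded[i - 1]) {
      if (.row_ok(C, i - 1) && .row_ok(N, i) && .row_ok(CA, i) && .row_ok(C, i)) {
        out$phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
      } else miss <- miss + 1L
      if (.row_ok(CA, i - 1) && .row_ok(C, i - 1) && .row_ok(N, i) && .row_ok(CA, i)) {
        out$omega[i] <- dihedral_angle(CA[i - 1, ], C[i - 1, ], N[i, ], CA[i, ])
      } else miss <- miss + 1L
    }
    if (i < n && bonded[i]) {
      if (.row_ok(N, i) && .row_ok(CA, i) && .row_ok(C, i) && .row_ok(N, i + 1)) {
        out$psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      } else miss <- miss + 1L
    }
    # CA pseudo-dihedral attributed to residue i uses CA(i-1)..CA(i+2); all
    # three consecutive pairs must be continuous
    if (i > 1 && i + 2 <= n && bonded[i - 1] && bonded[i] && bonded[i + 1] &&
        .row_ok(CA, i - 1) && .row_ok(CA, i) && .row_ok(CA, i + 1) && .row_ok(CA, i + 2)) {
      out$ca_pseudo[i] <- dihedral_angle(CA[i - 1, ], CA[i, ], CA[i + 1, ], CA[i + 2, ])
    }
  }
  if (miss > 0) warning(sprintf("%d backbone angle(s) undefined due to missing atoms", miss))
  out
}

# Place atom D given prior atoms A, B, C, the C-D bond length, the B-C-D bond
# angle (degrees) and the A-B-C-D torsion (degrees). Standard chain-extension
# (NeRF) construction.
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  ncr <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  ncr <- ncr / sqrt(sum(ncr^2))
  m2 <- c(ncr[2] * bc[3] - ncr[3] * bc[2],
          ncr[3] * bc[1] - ncr[1] * bc[3],
          ncr[1] * bc[2] - ncr[2] * bc[1])
  C + d_local[1] * bc + d_local[2] * m2 + d_local[3] * ncr
}

#' Build backbone coordinates from requested dihedral angles
#'
#' Chain extension with ideal bond lengths/angles: residue i's phi and the
#' preceding psi/omega determine atom placement, so recomputing dihedrals on
#' the result reproduces the request (the first residue's phi and the last
#' residue's psi have no effect).
#'
#' @param angles A data.frame (or list of rows) with columns `phi`, `psi`,
#'   `omega`, one row per residue, degrees.
#' @param aa One-letter codes, recycled to the number of residues
#'   (default "A").
#' @param geometry Bond lengths/angles, see [ideal_backbone_geometry].
#' @param chain_id Chain identifier.
#' @return A [backbone_chain()].
#' @export
build_backbone <- function(angles, aa = "A", geometry = ideal_backbone_geometry,
                           chain_id = "A") {
  angles <- as.data.frame(angles)
  n <- nrow(angles)
  if (n < 1) stop("angles must contain at least one residue")
  stopifnot(all(c("phi", "psi", "omega") %in% names(angles)))
  aa <- rep_len(toupper(aa), n)
  g <- geometry
  N <- CA <- C <- matrix(NA_real_, n, 3)
  # canonical seed frame for residue 1
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    # N(i): torsion psi(i-1) about N(i-1),CA(i-1),C(i-1)
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          g$b_c_n, g$a_ca_c_n, angles$psi[i - 1])
    # CA(i): torsion omega(i) about CA(i-1),C(i-1),N(i)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           g$b_n_ca, g$a_c_n_ca, angles$omega[i])
    # C(i): torsion phi(i) about C(i-1),N(i),CA(i)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          g$b_ca_c, g$a_n_ca_c, angles$phi[i])
  }
  backbone_chain(seq_len(n), aa, N, CA, C, chain_id = chain_id)
}

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.aa1to3 <- stats::setNames(names(.aa3to1), unname(.aa3to1))

#' Read backbone chains from a PDB file
#'
#' Parses `ATOM` records for the N, CA and C atoms. For alternate locations
#' the first seen is kept; residues are ordered by residue number then
#' insertion code. Missing backbone atoms are kept as `NA` rows.
#'
#' @param path Path to a PDB-format file.
#' @return A list of [backbone_chain()] objects in file order; empty (with a
#'   warning) if the file holds no ATOM record.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom_idx <- which(startsWith(lines, "ATOM"))
  if (length(atom_idx) == 0) {
    warning(sprintf("no ATOM records in '%s'", path))
    return(list())
  }
  recs <- list()
  for (k in atom_idx) {
    ln <- lines[k]
    if (nchar(ln) < 54) {
      warning(sprintf("skipping malformed ATOM record at line %d", k))
      next
    }
    name <- trimws(substr(ln, 13, 16))
    if (!name %in% c("N", "CA", "C")) next
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz)) {
      warning(sprintf("skipping malformed ATOM record at line %d", k))
      next
    }
    recs[[length(recs) + 1]] <- list(
      name = name,
      altloc = substr(ln, 17, 17),
      res3 = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resseq = as.integer(substr(ln, 23, 26)),
      icode = substr(ln, 27, 27),
      xyz = xyz)
  }
  if (length(recs) == 0) {
    warning(sprintf("no backbone N/CA/C ATOM records in '%s'", path))
    return(list())
  }
  chains_seen <- unique(vapply(recs, `[[`, "", "chain"))
  out <- list()
  for (cid in chains_seen) {
    cr <- Filter(function(r) r$chain == cid, recs)
    key <- vapply(cr, function(r) sprintf("%d|%s", r$resseq, r$icode), "")
    ukey <- unique(key)  # file order preserves resseq+icode ordering
    n <- length(ukey)
    N <- CA <- C <- matrix(NA_real_, n, 3)
    aa <- character(n)
    for (j in seq_len(n)) {
      rr <- cr[key == ukey[j]]
      aa[j] <- {
        a3 <- rr[[1]]$res3
        if (a3 %in% names(.aa3to1)) .aa3to1[[a3]] else "X"
      }
      for (r in rr) {
        tgt <- switch(r$name, N = "N", CA = "CA", C = "C")
        m <- get(tgt)
        if (anyNA(m[j, ])) {  # altloc: keep first occurrence
          m[j, ] <- r$xyz
          assign(tgt, m)
        }
      }
    }
    res_index <- vapply(strsplit(ukey, "|", fixed = TRUE), function(p) as.integer(p[1]), 1L)
    # insertion codes: fall back to sequential indexing if duplicates arise
    if (anyDuplicated(res_index) || any(diff(res_index) <= 0)) res_index <- seq_len(n)
    out[[length(out) + 1]] <- backbone_chain(res_index, aa, N, CA, C, chain_id = cid)
  }
  out
}

#' Write backbone chains to a PDB file
#'
#' Emits `ATOM` records for N, CA, C (three per residue, `NA` atoms skipped)
#' that [read_pdb()] round-trips to 1e-3 Angstrom (PDB column precision).
#'
#' @param chains A [backbone_chain()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chains, path) {
  if (inherits(chains, "backbone_chain")) chains <- list(chains)
  lines <- character(0)
  serial <- 0L
  for (ch in chains) {
    for (i in seq_len(length(ch))) {
      res3 <- if (ch$aa[i] %in% names(.aa1to3)) .aa1to3[[ch$aa[i]]] else "UNK"
      for (atom in c("N", "CA", "C")) {
        xyz <- ch[[atom]][i, ]
        if (anyNA(xyz)) next
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, paste0(" ", atom), " ", res3, substr(ch$chain_id, 1, 1),
          ch$res_index[i], " ", xyz[1], xyz[2], xyz[3], 1.00, 0.00))
      }
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
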