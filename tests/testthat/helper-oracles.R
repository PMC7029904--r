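# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# torsion oracle: angle between the two bond-plane normals, signed by the
# determinant convention (independent of dihedral_angle's cross/dot route)
oracle_dihedral <- function(p1, p2, p3, p4) {
  u1 <- p2 - p1; u2 <- p3 - p2; u3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(u1, u2); n2 <- cr(u2, u3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosv <- min(1, max(-1, cosv))
  ang <- acos(cosv) / pi * 180
  if (sum(u1 * n2) < 0) ang <- -ang
  # shift so trans = 180: the normals convention gives cis = 0 already
  ang
}

# brute-force Mann-Whitney AUC with ties counted half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# exhaustive segment scan: all maximal windows of passing residues,
# length >= min_len, regularity <= max
oracle_segments <- function(chain, crit) {
  rec <- suppressWarnings(chain_dihedrals(chain))
  n <- nrow(rec)
  pass <- passes_dihedral_filter(rec, crit) & passes_trans_filter(rec, crit)
  found <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(pass[i:j])) next
      len <- j - i + 1
      if (len < crit$min_len) next
      # maximality: not extendable on either side
      if (i > 1 && pass[i - 1]) next
      if (j < n && pass[j + 1]) next
      reg <- segment_regularity(rec[i:j, , drop = FALSE])
      if (!is.na(reg) && reg > crit$regularity_max) next
      found[[length(found) + 1]] <- c(start = i, end = j)
    }
  }
  if (length(found) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, found))
  df[order(df$start), , drop = FALSE]
}

# random rigid motion applied to all atoms of a chain
apply_rigid_motion <- function(chain, seed = 1) {
  set.seed(seed)
  # random rotation from QR of a Gaussian matrix, det forced positive
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  tvec <- rnorm(3, sd = 10)
  tf <- function(m) sweep(m %*% t(Q), 2, -tvec)
  backbone_chain(chain$res_index, chain$aa, tf(chain$N), tf(chain$CA),
                 tf(chain$C), chain_id = chain$chain_id)
}

# small labelled corpus + encoding, shared by pipeline/brnn tests
tiny_encoded_corpus <- function(n = 30, seed = 9) {
  co <- make_corpus(corpus_spec(n_sequences = n, len_range = c(40, 60),
                                seed = seed))
  encode_corpus(co)
}

# Glorot-style fixture model used where tests need a trainable start
glorot_model <- function(I, H, M, seed) {
  m <- init_model(I, H, M, seed = seed)
  m
}
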