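# PPII assignment: filters, regularity, segment formation.

rec1 <- function(phi = NA, psi = NA, omega = NA, ca = NA) {
  data.frame(phi = phi, psi = psi, omega = omega, ca_pseudo = ca)
}

test_that("dihedral filter follows the printed bands", {
  strict <- ppii_criteria("strict")
  loose <- ppii_criteria("non_strict")
  expect_true(passes_dihedral_filter(rec1(phi = -75, psi = 145), strict))
  # wrap band -180 < psi < -160
  expect_true(passes_dihedral_filter(rec1(phi = -75, psi = -170), strict))
  # phi outside (-105, -45): fails strict, passes non-strict
  expect_false(passes_dihedral_filter(rec1(phi = -120, psi = 145), strict))
  expect_true(passes_dihedral_filter(rec1(phi = -120, psi = 145), loose))
  # psi outside both bands
  expect_false(passes_dihedral_filter(rec1(phi = -75, psi = 0), strict))
  expect_false(passes_dihedral_filter(rec1(phi = -75, psi = 0), loose))
  # undefined required angles never qualify
  expect_false(passes_dihedral_filter(rec1(psi = 145), strict))
  expect_true(passes_dihedral_filter(rec1(psi = 145), loose))
  expect_false(passes_dihedral_filter(rec1(phi = -75), strict))
})

test_that("trans filter bounds the CA pseudo-dihedral", {
  crit <- ppii_criteria("strict")
  expect_true(passes_trans_filter(rec1(ca = -100), crit))
  expect_false(passes_trans_filter(rec1(ca = -150), crit))
  expect_false(passes_trans_filter(rec1(ca = -70), crit))   # open bound
  expect_false(passes_trans_filter(rec1(), crit))           # undefined
  # optional omega trans check
  crit2 <- ppii_criteria("strict", omega_trans_check = TRUE)
  expect_true(passes_trans_filter(rec1(ca = -100, omega = 178), crit2))
  expect_false(passes_trans_filter(rec1(ca = -100, omega = 10), crit2))
  expect_false(passes_trans_filter(rec1(ca = -100), crit2))
})

test_that("segment_regularity implements the printed mean-step formula", {
  same <- data.frame(phi = rep(-75, 5), psi = rep(145, 5))
  expect_equal(segment_regularity(same), 0)
  # one step of length 5 over n = 2 records -> 5/2
  two <- data.frame(phi = c(0, 4), psi = c(0, 3))
  expect_equal(segment_regularity(two), 2.5)
  # wrapped difference: -179 vs 179 is a 2-degree step, not 358
  wrap <- data.frame(phi = c(10, 10), psi = c(-179, 179))
  expect_equal(segment_regularity(wrap), 1.0)
  expect_true(is.na(segment_regularity(data.frame(phi = 1, psi = 1))))
})

test_that("assign_ppii recovers a planted PPII block between helix and sheet", {
  st <- make_structure(list(list(conformation = "alpha", length = 10),
                            list(conformation = "ppii", length = 5),
                            list(conformation = "beta", length = 10)))
  lab <- assign_ppii(st$chain, ppii_criteria("strict"))
  expect_equal(nrow(lab$segments), 1)
  seg <- lab$segments[1, ]
  expect_gte(seg$length, 3)
  # the segment lies inside the planted block (residues 11..15)
  expect_gte(seg$start, 11)
  expect_lte(seg$end, 15)
  # labelled residues are exactly the segment
  expect_equal(which(lab$labels == 1), seq(seg$start, seg$end))
})

test_that("runs below the minimum length yield no segment", {
  st <- make_structure(list(list(conformation = "alpha", length = 8),
                            list(conformation = "ppii", length = 4),
                            list(conformation = "alpha", length = 8)))
  # interior ppii block passes for ~2 residues only once boundary effects
  # are accounted for; use min_len large enough to exclude it
  crit <- ppii_criteria("strict", min_len = 5)
  lab <- assign_ppii(st$chain, crit)
  expect_equal(nrow(lab$segments), 0)
  expect_true(all(lab$labels == 0))
})

test_that("assign_ppii matches the exhaustive window-scan oracle", {
  set.seed(202)
  crit_s <- ppii_criteria("strict")
  crit_n <- ppii_criteria("non_strict")
  for (k in 1:10) {
    segs <- list(list(conformation = "alpha", length = sample(2:5, 1)),
                 list(conformation = "ppii", length = sample(3:7, 1)),
                 list(conformation = "beta", length = sample(2:5, 1)))
    st <- make_structure(segs, angle_noise_sd = 5, seed = 300 + k)
    for (crit in list(crit_s, crit_n)) {
      got <- assign_ppii(st$chain, crit)$segments
      want <- oracle_segments(st$chain, crit)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("strict labels are a subset of non-strict labels", {
  for (k in 1:10) {
    st <- make_structure(list(list(conformation = "ppii", length = 8),
                              list(conformation = "beta", length = 5),
                              list(conformation = "ppii", length = 4)),
                         angle_noise_sd = 8, seed = k)
    s <- assign_ppii(st$chain, ppii_criteria("strict", regularity_max = Inf))
    n <- assign_ppii(st$chain, ppii_criteria("non_strict", regularity_max = Inf))
    expect_true(all(n$labels[s$labels == 1] == 1))
  }
})

test_that("regularity and min_len thresholds act monotonically", {
  st <- make_structure(list(list(conformation = "alpha", length = 5),
                            list(conformation = "ppii", length = 8),
                            list(conformation = "beta", length = 5)),
                       angle_noise_sd = 6, seed = 42)
  n_seg <- function(rmax, mlen) {
    nrow(assign_ppii(st$chain, ppii_criteria("strict", regularity_max = rmax,
                                             min_len = mlen))$segments)
  }
  expect_gte(n_seg(60, 3), n_seg(20, 3))   # raising regularity_max keeps segments
  labelled <- function(mlen) {
    sum(assign_ppii(st$chain, ppii_criteria("strict", min_len = mlen))$labels)
  }
  expect_gte(labelled(3), labelled(5))     # lowering min_len keeps residues
})

test_that("all segment residues individually pass both filters", {
  st <- make_structure(list(list(conformation = "ppii", length = 12)),
                       angle_noise_sd = 4, seed = 5)
  crit <- ppii_criteria("strict")
  lab <- assign_ppii(st$chain, crit)
  rec <- chain_dihedrals(st$chain)
  idx <- which(lab$labels == 1)
  expect_gt(length(idx), 0)
  expect_true(all(passes_dihedral_filter(rec[idx, ], crit)))
  expect_true(all(passes_trans_filter(rec[idx, ], crit)))
})

test_that("label/segment TSV and BED outputs are consistent", {
  st <- make_structure(list(list(conformation = "alpha", length = 6),
                            list(conformation = "ppii", length = 6),
                            list(conformation = "alpha", length = 6)))
  lab <- assign_ppii(st$chain, ppii_criteria("strict"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_label_tsv(st$chain, lab, tsv)
  write_segment_bed(lab, bed)
  t <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(t), 18)
  expect_equal(t$label, lab$labels)
  b <- read.table(bed, sep = "\t")
  expect_equal(nrow(b), nrow(lab$segments))
  # BED is 0-based half-open: length = end - start
  expect_equal(b$V3 - b$V2, b$V4)
  expect_equal(b$V2, lab$segments$start - 1L)
})
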