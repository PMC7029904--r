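---
title: "Assigning and predicting polyproline II helices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning and predicting polyproline II helices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The polyproline II helix (PPIIH) is an extended left-handed secondary
structure with backbone dihedrals near (φ, ψ) ≈ (−75°, 145°) and three
residues per turn. It is rare (a few percent of residues in structure
databases), often proline-rich but not necessarily so, enriched in
disordered regions, and recognised by peptide-binding domains such as SH3
and WW. `ppiipred` provides both halves of the standard workflow:

1. **Assignment from structure** — given backbone coordinates (N, CA, C),
   label each residue PPIIH / non-PPIIH by dihedral-angle filtering. This
   is how training labels are produced from coordinate sets.
2. **Prediction from sequence** — a bidirectional recurrent neural network
   (BRNN) scores every residue in (0, 1) for PPIIH propensity, optionally
   using an alignment profile and per-residue disorder scores, with a
   proline-window baseline and a full per-residue evaluation suite
   (sensitivity, precision, MCC, accuracy, ROC/AUC, TP versus log10 FP).

## Assignment model

A residue is a PPIIH candidate when it passes, simultaneously:

* **trans filter** — the Cα pseudo-dihedral (virtual torsion over four
  consecutive CA atoms, attributed to the second of the four) lies in
  (−145°, −70°). For an ideal PPII helix this value is ≈ −109°; ideal
  α-helix (≈ +51°) and β-strand (≈ −168°) fall outside.
* **dihedral filter** — ψ ∈ (−180°, −160°) ∪ (90°, 180°], and in *strict*
  mode additionally φ ∈ (−105°, −45°). The *less strict* mode drops the φ
  requirement.

Maximal runs of candidates form segments; segments shorter than `min_len`
(default 3 residues, one helix turn) are dropped, as are segments whose
**regularity** — the mean Euclidean step between consecutive residues'
(ψ, φ) pairs, using wrapped angular differences, summed over the n−1
adjacent pairs and divided by n — exceeds `regularity_max`.

Numerical and interpretive choices that were genuinely open:

* *Regularity indexing.* The published step formula mixes two index
  conventions; the only reading under which the sum over n−1 pairs is well
  defined is the step between consecutive residues' (ψ, φ) pairs, which is
  what we implement. The division by n (rather than n−1) is kept exactly
  as printed.
* *Regularity threshold.* No cutoff is published. The default
  `regularity_max = 30°` keeps essentially all near-ideal noisy helices
  (at angle noise σ = 8° the expected step is ≈ 14°) while rejecting
  accidental runs that drift across the broad ψ band; each segment's
  regularity is reported so users can re-threshold without recomputation.
* *The trans filter quantity.* The source text for the trans filter is
  garbled; the printed symbol is the Cα quantity, but the name suggests a
  peptide-bond (ω) test. We bound the Cα pseudo-dihedral by default and
  additionally offer an optional ω trans check (|ω| > 150°), off by
  default — both are exposed, neither asserted as the original intent.
* *Filter scope.* The regularity filter is applied to maximal runs, not to
  sliding sub-windows (unstated in the source; maximal runs are the only
  choice under which "segment" is well defined before filtering).
* *Undefined angles.* φ of the first residue, ψ of the last, anything
  spanning a chain break (C–N distance > 2 Å) or a missing atom is
  undefined, and an undefined required angle never qualifies. Terminal
  residues therefore can never be PPIIH (the Cα pseudo-dihedral needs four
  consecutive CA atoms) — segment boundaries are conservative by one
  residue at chain ends and conformation transitions.
* *DSSP.* The original labels came from DSSP dihedrals. DSSP is not run
  here; angles come from an internal geometry module (IUPAC sign
  convention, cis = 0°). DSSP's exact rounding at edge cases is not
  reproduced and not guessed at.

`build_backbone()` reconstructs Cartesian coordinates from requested
(φ, ψ, ω) by standard chain extension with ideal bond geometry (N–CA
1.458 Å, CA–C 1.525 Å, C–N 1.329 Å), which gives an exact round-trip
through `chain_dihedrals()` — the backbone of the test suite's geometry
oracles, replacing real PDB data.

## Prediction model

Per position j with input vector i_j, the network computes

* forward chain: h_j^F = N^F(i_j, h_{j−1}^F), left to right, h_0^F = 0;
* backward chain: h_j^B = N^B(i_j, h_{j+1}^B), right to left, h_{N+1}^B = 0;
* output: o_j = N^O(i_j, h_j^F, h_j^B) ∈ (0, 1),

where N^F, N^B, N^O are two-layer perceptrons (tanh hidden layers, tanh
hidden-state outputs, sigmoid final output). Every position can therefore
draw on arbitrarily distant context — the property that distinguishes the
architecture from any fixed-window scorer, and which the tests assert
directly by perturbing one end of a sequence and observing the other.

**Inputs** (per residue): 20 one-hot columns over the alphabet
`ACDEFGHIKLMNPQRSTVWY` (non-standard residues are all-zero), a length
input min(N, 2000)/2000, a charge input (+1 for R/K, −1 for D/E, 0
otherwise, histidine neutral), optionally 21 alignment-profile columns
(frequencies of the 20 residues plus the gap frequency per query column,
non-standard symbols excluded and the vector renormalised), and two
disorder columns in [0, 1] (a long-disorder and an NMR-flavoured score,
supplied as files; zeros when absent). Width is 24 without an alignment
and 45 with one.

Open choices, and what we chose:

* *Charge of D/E*: the source is ambiguous ("0 or −1"); −1 makes the
  channel a signed symmetric counterpart to +1 for R/K.
* *Length normalisation*: unspecified; min(N, 2000)/2000 bounds the input.
* *Profile weighting*: raw counts, no sequence weighting or pseudocounts.
* *Loss*: mean binary cross-entropy per residue (the source reports only a
  percentage error; BCE is the standard likelihood loss for a sigmoid
  output).
* *Hidden sizes*: unpublished; defaults hidden_dim = mlp_hidden = 11, kept
  small in the spirit of the architecture's low parameter count, and fully
  configurable.
* *Initialisation*: Glorot-style uniform ±sqrt(6/(fan_in+fan_out)) per
  layer, the standard choice for tanh layers, fully determined by the
  seed. (An earlier ±1/sqrt(fan_in) draw trained visibly slower; the
  switch is an implementation choice, made on the standard result, not a
  tuned constant.)

**Training** follows the published schedule: stochastic gradient descent,
2000 epochs at full scale, 1920 weight updates per epoch, learning rate
0.005 halved whenever the validation error (classification error at 0.5)
has not improved for 1000 epochs. The batching behind "1920 updates per
epoch" is unpublished; we shuffle the sequences each epoch (seeded) into
min(1920, n) near-equal groups and take one step per group on the mean of
the group's per-sequence gradients — this reproduces the update count at
full scale and degrades to one update per sequence on small corpora.
Gradients are exact backpropagation through both chains (C++ core),
verified against central differences to < 1e−5 relative error (with the
usual floored denominator |g|+|num| ∨ 1e−3, since below that magnitude
finite differences are dominated by cancellation noise). Training with a
fixed seed is bit-reproducible on one machine.

**Ensembling.** Five models are trained in fivefold cross-validation
(random, seeded, round-robin fold assignment over the training split;
every 10th sequence of the corpus is held out first as the independent
test split) and their score tracks are averaged.

## The synthetic world

Real training data (a redundancy-reduced, resolution-filtered structure
corpus; PSI-BLAST profiles; disorder predictors) is out of scope, so the
package ships generators that emulate the *shape* of that data:

* `make_structure()` plants segments of canonical PPII (−75, 145, 180),
  α (−60, −45, 180), β (−120, 130, 180) or custom dihedrals, with optional
  Gaussian angle noise (applied in dihedral space so ground truth stays
  defined), and returns the chain plus the planted labels.
* `make_corpus()` draws sequences (default 500, lengths uniform 60–140)
  from near-natural amino-acid frequencies and plants proline-anchored
  stretches (length 3–6) whose residues are labelled positive, at a rate
  calibrated so ≈ 2.4% of residues are positive — the class imbalance of
  the strict structural corpus. Stretches alternate proline (odd
  positions) with side-chain-extending residues (A, L, M, K, R, E, Q, V
  dominate), the residues experimentally favoured in PPII helices. The
  background additionally carries unlabelled compact PP/PPP decoy runs
  (Poisson, one per sequence on average).

The decoys and the alternating anchor are deliberate: they make proline
content alone insufficient to separate the classes — mirroring the
empirical observation that proline composition does not determine the
helix — so the proline-window baseline is competitive but measurably below
the network, which can learn the alternation pattern and its boundaries.
With this world, a single 200-epoch model at hidden_dim 8 reaches held-out
AUC ≈ 0.997 and the best proline window ≈ 0.957 (both recomputed by the
acceptance tests; numbers here are what those tests measure, not claims
beyond them).

What a green test does **not** establish: the synthetic corpus has no
evolutionary conservation signal, no real disorder correlation, no
homology structure between sequences, and its planted rule is far easier
than real PPIIH; passing it validates the machinery (labels, encodings,
gradients, schedule, ensembling, metrics), not biological accuracy. The
published external-data performance (AUC ≈ 0.9 on real structures) is not
reproducible without the original corpus and weights and is explicitly not
asserted by this package.

## Evaluation conventions

* A positive call is `score >= threshold` (the tie side is unpublished; ≥
  is used everywhere and documented).
* The published performance tables label TP/(TP+FP) — precision — as
  "Spec"; the arithmetic of all five published rows confirms this. The
  package reports that quantity as `spec_as_precision` and textbook
  specificity TN/(TN+FP) separately as `specificity`, so the mislabel is
  reproduced numerically but not propagated.
* Metrics with a zero denominator are `NA` (undefined), never 0.
* ROC curves sweep the unique score values with ties grouped; AUC is
  trapezoidal, which equals the Mann–Whitney statistic with ties counted
  half (asserted against a brute-force pairwise loop).
* TP-versus-log10(FP) reports fp = 0 points with a −Inf sentinel rather
  than dropping them.
* High-scoring regions are maximal runs with score ≥ cutoff (default 0.5)
  of length strictly greater than 3, ranked by mean score.

## Limitations

* No mmCIF, no side chains, no hydrogen-bond secondary structure, no DSSP
  parity at edge cases.
* No PSI-BLAST/IUPRED/espritz execution: profiles and disorder arrive as
  files; zeros are a supported degraded mode.
* The regularity threshold and several training hyperparameters are
  configurable stand-ins for unpublished originals; none is asserted as
  the authors' value.
* Training is plain SGD by design (no momentum or adaptive optimisers),
  single-threaded.
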