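# ppiipred

Polyproline II helix (PPIIH) assignment from protein structure and
per-residue prediction from sequence.

The polyproline II helix is an extended left-handed secondary structure
(φ ≈ −75°, ψ ≈ 145°, three residues per turn), rare (~2–4% of residues),
usually but not necessarily proline-rich, enriched in disordered regions,
and central to peptide recognition by SH3, WW, EVH1 and related domains.
This package is for structural bioinformaticians who need (a) reproducible
PPIIH labels from backbone coordinates and (b) a sequence-based propensity
score for large-scale scans where no structure exists.

## What it computes

**Assignment from structure.** Backbone dihedrals (φ, ψ, ω and the Cα
pseudo-dihedral) are computed from N/CA/C coordinates. A residue is a PPIIH
candidate iff its Cα pseudo-dihedral lies in (−145°, −70°) (trans filter)
and ψ ∈ (−180°, −160°) ∪ (90°, 180°] with, in strict mode, φ ∈ (−105°, −45°)
(dihedral filter). Maximal candidate runs of ≥ 3 residues whose regularity
— Σₖ √(Δψₖ² + Δφₖ²) / n over consecutive residue pairs — stays below a
threshold become labelled segments.

**Prediction from sequence.** A bidirectional recurrent neural network:

    h_j^F = N^F(i_j, h_{j−1}^F)      (forward chain,  h_0^F = 0)
    h_j^B = N^B(i_j, h_{j+1}^B)      (backward chain, h_{N+1}^B = 0)
    o_j   = N^O(i_j, h_j^F, h_j^B)   ∈ (0, 1)

with N^F, N^B, N^O two-layer perceptrons (tanh hidden, sigmoid output),
trained by SGD on mean binary cross-entropy (lr 0.005, halved on a
1000-epoch validation stall), five models in fivefold cross-validation,
averaged as an ensemble. Inputs per residue: one-hot (20), sequence length,
charge, optional alignment profile (20 + gap), optional disorder scores —
width 24 or 45. A proline-window baseline (fraction of P in a ±w window)
and per-residue metrics (Sens, precision, MCC, accuracy, ROC/AUC,
TP vs log10 FP) complete the evaluation loop.

Everything is testable offline: `make_structure()` builds backbones from
planted dihedral segments, `make_corpus()` generates labelled sequence
corpora with a planted proline-anchored rule at realistic (~2.4%) class
imbalance.

## Worked example

```r
library(ppiipred)

## 1. Label a structure: plant a PPII helix between an alpha helix and a
##    beta strand, then recover it by dihedral filtering
st <- make_structure(list(list(conformation = "alpha", length = 8),
                          list(conformation = "ppii",  length = 6),
                          list(conformation = "beta",  length = 8)),
                     angle_noise_sd = 3, seed = 42)
lab <- assign_ppii(st$chain, ppii_criteria("strict"))
lab
#> <labelled_sequence A: 22 residues, 5 PPII, 1 segment(s)>
lab$segments
#>   start end length regularity
#> 1     9  13      5   5.555025
```

The planted helix occupies residues 9–14; the recovered segment covers
9–13 (the last residue's Cα pseudo-dihedral spans the following strand, so
boundaries are conservative by one residue). Its regularity, 5.6°, reflects
the 3° angle noise.

```r
## 2. Train a small predictor on a synthetic planted-rule corpus (~30 s)
corpus  <- make_corpus(corpus_spec(n_sequences = 500, seed = 7))
encoded <- encode_corpus(corpus)
split   <- split_every_tenth(names(encoded))
cfg     <- train_config(epochs = 200, hidden_dim = 8, mlp_hidden = 8, seed = 1)
fit     <- train(init_model(24, 8, 8, seed = 1),
                 encoded[split$train_ids], cfg)

## 3. Score the held-out sequences and compare with the proline window
test    <- encoded[split$test_ids]
labels  <- unlist(lapply(test, function(d) d$y))
scores  <- unlist(lapply(test, function(d) forward(fit$model, d$x)))
base    <- unlist(lapply(split$test_ids,
                         function(id) proline_window_score(corpus[[id]]$seq, 2)))
round(c(brnn_auc = roc_curve(scores, labels)$auc,
        proline_window_auc = roc_curve(base, labels)$auc), 3)
#>           brnn_auc proline_window_auc
#>              0.997              0.946
```

The network separates planted helices from background (AUC 0.997) and
beats the proline window (0.946): the corpus deliberately contains
unlabelled compact proline decoys, so proline content alone cannot win.

```r
## 4. Extract high-scoring regions (score >= 0.5, length > 3)
high_scoring_regions(forward(fit$model, encoded[["syn0040"]]$x),
                     cutoff = 0.5, id = "syn0040")
#>        id start end length mean_score
#> 1 syn0040    31  35      5  0.8043134
```

Sequence `syn0040`'s planted stretch spans residues 31–36; the extracted
region (31–35, mean score 0.80) recovers it.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ppiipred.R", package = "ppiipred"))')
Rscript $CLI simulate --n 100 --seed 1 --out corpus.fasta
Rscript $CLI baseline --fasta corpus.fasta --window 2 --out baseline.tsv
Rscript $CLI label    --pdb structure.pdb --mode strict --out labels.tsv
Rscript $CLI regions  --scores baseline.tsv --cutoff 0.5 --out regions.tsv
```

Commands: `label encode train crossval predict baseline regions evaluate
simulate`; every command exits non-zero on error.

## Further reading

`vignettes/ppiipred-methods.Rmd` documents the model, every tunable
parameter with its default and rationale, what the synthetic generators do
and do not emulate, numerical conventions (tie-breaks, undefined angles,
rounding), and known limitations.
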