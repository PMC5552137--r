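---
title: "Position-relative features and statistical moments for N-glycosylation site prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-relative features and statistical moments for N-glycosylation site prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nglyc)
```

## The problem

N-linked glycosylation attaches an oligosaccharide to the side-chain
nitrogen of asparagine, typically inside the N-X-[S/T] sequon (X any
residue but proline).  Whether a given asparagine is actually
glycosylated depends on its sequence neighbourhood, so the prediction
task is: given the 41-residue window centred on a candidate N (twenty
flanking residues per side), decide positive or negative.  `nglyc`
implements a complete window-based predictor: a position- and
composition-variant feature extraction scheme, a back-propagation
multilayer network with adaptive learning rate, and the standard
evaluation protocol (self-consistency, stratified k-fold
cross-validation, jackknife, Sn/Sp/Acc/MCC, ROC/AUC).

## The feature model

Each window is encoded as integers: the twenty standard residues get
codes 1–20 in alphabetical one-letter order, and 0 marks padding or a
non-standard letter.  Any consistent unique assignment carries the same
information; the alphabetical choice is fixed so that feature vectors
are reproducible, and 0 is reserved so terminal padding is
distinguishable from every real residue.  Windows that overhang a
protein terminus are zero-padded rather than dropped — dropping them
would systematically exclude sites near the termini.  Padding is
invisible to the composition extractors but keeps every window's
coordinate system identical (positions are always 1–41).

From the encoded window seven blocks are assembled into one
173-coefficient vector:

| block | length | content |
|---|---|---|
| SVV | 41 | the integer codes themselves (site vicinity vector) |
| FM | 20 | per-residue frequency |
| AAPIV | 20 | per-residue sum of 1-based occurrence positions |
| RAAPIV | 20 | AAPIV of the reversed window |
| grid moments | 24 | raw, central, Hahn moments of the 7×7 window grid |
| PRIM moments | 24 | the same moments of the 20×20 forward incidence matrix |
| RPRIM moments | 24 | the same moments of the reversed-window incidence matrix |

PRIM's entry (i, j) sums the relative positions `p − f_i` of every
occurrence of residue j with respect to the *first* occurrence of
residue i.  "Relative position" is implemented as the signed
difference, keeping negative contributions from occurrences before the
first i — the reading that preserves the most ordering information.
On pad-free windows the extractors obey exact identities that the test
suite asserts: the frequencies sum to 41, and
`aapiv + raapiv = 42 × frequency` for every residue (positions pair up
as `p` with `42 − p`).

### Statistical moments

The 41-mer is placed row-major into the smallest square that holds it
(7×7, eight trailing zeros), and each square matrix (grid, PRIM,
RPRIM) is summarised by eight moments per family at the index pairs
00, 01, 10, 11, 12, 21, 30, 03 — scale-*variant* families on purpose,
because sequence-order information must not be normalised away:

* raw moments `M_ij = Σ p^i q^j β_pq` with 1-based coordinates
  (starting at 0 would delete the first row and column from
  `M10`/`M01`);
* central moments about the centroid `(M10/M00, M01/M00)`, which are
  translation-invariant; a matrix with zero total mass has no centroid,
  and its central block is defined as zeros (this arises for all-zero
  matrices, e.g. features of an empty window);
* discrete Hahn moments: projections onto the classical Hahn
  polynomials `h_n^{(u,v)}(r, N)` on the support `r = 0..N−1`,
  orthogonal under the weight
  `ρ(r) = Γ(N+u−r)Γ(v+1+r)/(Γ(r+1)Γ(N−r))`.

The Hahn shape parameters default to `u = v = 0` (the symmetric,
uniform-weight case — the discrete Chebyshev limit); they are exposed
but there is no reason in this application to move them.  Polynomials
are evaluated through log-gamma-stabilised Pochhammer products so the
20×20 incidence matrices are handled without overflow, and the square
norm `d_n²` is computed by exact summation of `ρ h_n²` over the finite
support rather than from a closed form — the two are mathematically
identical, and the summation form cannot disagree with the
orthogonality it normalises.  Correctness is enforced structurally in
the tests: the scaled basis must be orthonormal to 1e−8, every moment
must match an independent term-by-term double-loop oracle to 1e−9, and
the full-order transform must reconstruct the grid to 1e−6 — the
"reversibility" that motivates using an orthogonal family, since it
shows the moments conserve the window's full positional content.

## The classifier

A feed-forward network with logistic-sigmoid units maps the feature
vector to a score in (0, 1).  Defaults: one hidden layer of 20 units
and a single output, mean-squared-error loss, full-batch gradient
descent.  Weights start uniform in ±1/√fan-in, reproducibly from a
seed; biases start at zero.

The learning rate adapts by the classic accept/reject rule: after each
full-batch step, if the loss did not increase the step is accepted and
the rate is multiplied by 1.05; otherwise the weights are discarded
and the rate is multiplied by 0.7.  The accepted-loss sequence is
therefore non-increasing by construction, which the tests assert on
every run.  Training stops at `max_epochs` (default 500) or when the
loss reaches `tol` (default 1e−6, i.e. effective interpolation of the
training set).  The adaptive constants are conventional values; none
of architecture, epochs or rate constants are claims about any
external reference — they are exposed in `train_config()` with these
documented defaults.  Because the Hahn blocks are orders of magnitude
larger than the residue codes, features are standardised (zero mean,
unit variance, constant features passed through) before training; the
standardiser is always fitted on the training split only, and the
cross-validation harness refits it inside every fold.  The SVV enters
as raw integer codes plus this global standardisation; a one-hot
recoding would change the stated 41-coefficient layout.  Scores are
thresholded at 0.5 with ties called positive.

## Evaluation protocol

* **Self-consistency** (resubstitution): train and test on the full
  dataset — the optimistic bound.
* **Stratified k-fold cross-validation** (default k = 10): indices are
  shuffled within class and dealt round-robin in one stream, so fold
  sizes differ by at most one both overall and per class; the fold
  plans are exact partitions, asserted in the tests.  Mean fold
  accuracy `Ra` is reported together with per-class (positive-site /
  negative-site) accuracies, matching the practice of running the two
  site classes separately.
* **Jackknife**: leave-one-out over a random subsample (default 100;
  set the subsample to the dataset size for exact LOO — full LOO is
  quadratic in training runs).  The estimate `A*` is the mean of the
  0/1 per-iteration outcomes.
* **Metrics**: Sn, Sp, Acc, MCC from the confusion matrix, with
  zero-denominator cases reported as undefined rather than silently
  zeroed.  Printed literature values in this area are four-decimal
  *truncations*, so `truncate_decimal()` reproduces that convention.
  The ROC is a descending threshold sweep with trapezoidal AUC, which
  the tests verify equals the Mann–Whitney rank statistic.

## The synthetic-data generator

Real curated site windows come from annotation databases at a scale
this package does not ship.  `sim_config()`/`generate_dataset()`
instead emulate the one structure the predictor assumes: every window
is a 41-mer with N at position 21; a positive window carries S or T at
position 23 (the sequon position) with probability 0.95 and never has
proline at position 22; a negative window carries the sequon with
probability 0.05.  All other positions are uniform over the twenty
residues.  The 0.95/0.05 defaults are the generator's definition of a
sequon-biased corpus; the uniform background is the deliberately
neutral choice — no flank enrichment is imposed, so the sequon is the
*only* class signal.

What this does and does not show: passing tests demonstrate that the
pipeline extracts, trains, and evaluates correctly, and that the
classifier finds the sequon signal (cross-validated accuracy far above
the exchangeable-null 0.5).  They do not show field performance on
real proteomes, where positives and negatives differ across many
flank positions and training corpora are two orders of magnitude
larger.

## Problem sizes and a known limitation

The shipped study sizes are 200 positive + 200 negative windows for
the end-to-end runs, 10-fold cross-validation, and a 100-sample
jackknife — sizes chosen so a complete evaluation runs in minutes on a
laptop.  At this scale the package's own measurements (the acceptance
script recomputes them on every run) show a real limitation of the
method: training data interpolated by an unregularised
mean-squared-error network generalise at roughly 0.70 cross-validated
accuracy under the 0.95/0.05 sequon conditions, even though the
single informative coordinate supports 0.93 on its own and the
generator's Bayes accuracy is 0.95.  With 360 training rows and 173
coefficients, the ~170 uninformative coordinates are memorised —
regularisation, early stopping and feature selection are all outside
this model's scope.  The gap closes with more data, not with more
epochs or wider layers; resubstitution accuracy (~0.99) and the null
experiment (~0.5) bracket it from both sides.

## Worked example

```{r example, eval = FALSE}
dataset <- generate_dataset(sim_config(n_pos = 200, n_neg = 200, seed = 1))
cfg <- train_config(seed = 2)

sc <- self_consistency(dataset, cfg)
sc$metrics$Acc        # resubstitution accuracy
sc$roc$auc

cv <- cross_validate(dataset, k = 10, cfg)
cv$Ra                 # mean held-out accuracy over the 10 folds
cv$per_fold

model <- sc$model
save_model(model, "model.json")   # bit-exact reload via load_model()
```
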