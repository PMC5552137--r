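# nglyc

Prediction of N-linked glycosylation sites in protein sequences from
position-relative features and statistical moments.

N-linked glycosylation modifies asparagine residues, canonically inside
the N-X-[S/T] sequon (X ≠ proline), and drives protein folding,
trafficking and recognition.  Experimental mapping of sites is slow and
expensive, so sequence-based prediction is the standard first pass.
`nglyc` is for computational biologists who want a transparent,
fully-inspectable window-based predictor: every feature, the network,
and the whole evaluation protocol are plain R, tested against
independent brute-force oracles.

## Method

Each candidate site is represented by its 41-residue **site vicinity
window** (20 flanks per side, integer-encoded A=1..Y=20, 0 = padding).
A window is summarised by 173 coefficients:

- **SVV** (41): the integer codes themselves;
- **FM** (20): residue frequencies τ_i;
- **AAPIV / RAAPIV** (20 + 20): per-residue sums of occurrence
  positions, μ_i = Σ p_k, on the forward and reversed window;
- **moments** (3 × 24): raw `M_ij = Σ p^i q^j β_pq`, central
  `η_ij` (about the centroid `x̄ = M10/M00, ȳ = M01/M00`), and
  discrete orthogonal Hahn moments `H_ij`, each at orders
  {00, 01, 10, 11, 12, 21, 30, 03}, computed on the 7×7 window grid
  and on the 20×20 **PRIM**/**RPRIM** incidence matrices
  (`A_{i→j} = Σ (p_j − f_i)`, positions of j relative to the first
  occurrence of i).

A multilayer feed-forward network (logistic units, default 173–20–1)
is trained by full-batch back-propagation, `θ ← θ − γ∇K(θ)`, with an
adaptive learning rate: steps that increase the loss are discarded and
γ shrinks, accepted steps grow γ, so the accepted-loss sequence
`K(θ_0) ≥ K(θ_1) ≥ …` is non-increasing by construction.  Evaluation:
self-consistency, stratified k-fold cross-validation (`R_a = Σ R_i/k`),
jackknife (`A* = Σ A_i/n`), Sn/Sp/Acc/MCC and ROC/AUC.

## Worked example

```r
library(nglyc)

## metric formulas on a published-scale confusion matrix
m <- classification_metrics(list(TP = 11461, FN = 12, FP = 0, TN = 11988))
lapply(m[1:4], truncate_decimal)
#> $Sn 0.9989   $Sp 1   $Acc 0.9994   $MCC 0.9989

## synthetic sequon-biased study, end to end
dataset <- generate_dataset(sim_config(n_pos = 200, n_neg = 200, seed = 1))
cfg <- train_config(seed = 2)

sc <- self_consistency(dataset, cfg)
sc$model
#> <nglyc_model> layers 173-20-1 | 500 epochs, final loss 0.005 (37 rejected steps)
sc$confusion
#>         predicted+  predicted-
#> actual+        198           2
#> actual-          0         200
sprintf("resubstitution Acc = %.4f, MCC = %.4f, AUC = %.4f",
        sc$metrics$Acc, sc$metrics$MCC, sc$roc$auc)
#> "resubstitution Acc = 0.9950, MCC = 0.9900, AUC = 0.9911"

cv <- cross_validate(dataset, k = 10, cfg)
sprintf("10-fold CV: Ra = %.3f (positive %.3f, negative %.3f)",
        cv$Ra, cv$Ra_pos, cv$Ra_neg)
#> "10-fold CV: Ra = 0.688 (positive 0.705, negative 0.670)"
```

The resubstitution numbers show the network interpolating its training
set; the held-out accuracy is far lower at this desk scale (400
windows, 173 features) — see the methods vignette
(`vignettes/nglyc-methods.Rmd`) for the analysis of that gap and every
modelling choice.

A thin CLI over the same functions ships in `inst/scripts/nglyc`
(`simulate`, `extract`, `featurize`, `train`, `predict`, `evaluate`).

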