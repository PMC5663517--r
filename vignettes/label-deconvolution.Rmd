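---
title: "Deconvolving label-specific sequence features at multi-labeled genomic sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving label-specific sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Collections of regulatory genomic sites — transcription-factor binding
events, DNase hypersensitive sites — are routinely annotated with several
overlapping labels at once: the cell type or timepoint a site was observed
in, whether it is promoter-proximal or distal, whether the surrounding
chromatin was already active. Because the labels co-occur (an "early"
binding site is usually also "ES-active"), a motif found at sites carrying
one label may in truth belong to a confounded companion label. Standard
discriminative motif discovery, which contrasts one label's sites against
everything else, inherits that confounding wholesale.

`motifdeconv` deconvolves the labels instead of contrasting them. Every
distinct observed **combination** of labels is treated as a *subclass*, and
the subclasses become the classes of one multinomial logistic regression on
k-mer content. Per-label models are never fit to data directly: they exist
only inside a fused L1 penalty that ties each subclass's weight vector to
the labels spanning it. A label model therefore ends up holding exactly the
features that are *consistently* enriched across all the subclasses that
label spans — which is what it means for a feature to belong to the label
rather than to a co-occurring companion.

## The model

Sites are reduced to standardized counts of canonical (reverse-complement
collapsed) k-mers; with the default k ∈ {4, 5} there are 136 + 512 = 648
features, z-scored per column over the training set. With subclasses
`n ∈ T`, subclass weight vectors `w_n` (plus an intercept each), label
weight vectors `w_p`, and per-site balancing weights
`b_i = |n_max| / |n_i|`, training minimizes

```
− Σ_i Σ_n b_i y_in log softmax_n(w_n · x_i)
  + λ Σ_n Σ_{p ∈ Π(n)} ‖w_n − w_p‖₁
```

where `Π(n)` is the set of labels spanning subclass `n`. Intercepts are
excluded from the penalty; labels are scored on k-mer content only.

Two coupled updates alternate:

* **Label step** — closed form: each coordinate of `w_p` is the median of
  that coordinate over the subclasses the label spans (for an even number,
  the mean of the two middle values; a label spanning one subclass copies
  it).
* **Subclass step** — the `w_n` sub-problem is solved with scaled,
  over-relaxed ADMM: a quasi-Newton (L-BFGS) minimization of the balanced
  NLL plus the quadratic proximal term, soft-thresholding of the auxiliary
  differences `z_np` at `2λ/ρ`, and the scaled dual update. The
  over-relaxed iterate blends `w_n` toward its consensus value `z + w_p`
  with α = 1.9. Iteration stops when the printed primal and dual residual
  criteria both hold, with the feature count K as the absolute scale
  factor.

### Numerical choices

* **Scaling.** The optimizer works with the NLL per unit of total sequence
  weight, so `lambda` and `rho` are O(1) quantities independent of dataset
  size. The objective reported in fits is the unnormalized form above.
* **Tolerances.** `eps_abs = 1e-5`, `eps_rel = 1e-2`. The stopping rule
  multiplies the absolute tolerance by K = 648; `1e-5 · 648` is numerically
  the tolerance the standard ADMM presentation would give with its
  square-root scale factor at `1e-4`, which is why the smaller default is
  the faithful one.
* **Gauge.** The softmax likelihood and the fused penalty are jointly
  invariant to adding one fixed vector to every subclass weight vector (the
  label medians just shift along). Motif scores would inherit that
  arbitrary drift, so the package fixes the gauge by sum-to-zero contrasts
  over subclasses after each sweep — weights are deviations from a pooled
  model, as in an ANOVA parameterization.
* **Fusion polish.** Finite ADMM leaves "fused" coordinates within a small
  residual of their label consensus rather than exactly on it. After the
  final sweep, coordinates within `snap_frac × 2λ/ρ` (default 15%) of a
  label weight are snapped onto it and the medians and gauge are refreshed
  to a fixed point. This recovers the exact-optimum fusion pattern, the
  same way lasso-ADMM implementations polish their support.
* **λ default 0.005**, with 3-fold cross-validation over
  {0.01, 0.05, 0.1, 0.5, 1} available via `lambda = NULL`. On the
  simulation design, λ ≥ 0.05 drives all but the strongest motif's weights
  to zero, while 0.005 keeps weak AT-rich motifs' per-window scores above
  the hill threshold (below). Users with very large or very diverse site
  collections should prefer the CV route.

## From weights to motifs

The trained k-mer models are scanned across the input sequences: every
15 bp window is scored by summing the model weight of each k-mer occurrence
starting inside it (raw occurrence counts — per-window standardization is
undefined). Maximal runs of windows scoring above the hill threshold
(default 0.1) become **hills**, 10–15 bp regions concentrating the
discriminative signal; each run is represented by its maximal window, and
overlapping candidates are resolved greedily by score. Hills for a label
are called only on sequences carrying the label.

Hills are clustered by K-means on their raw canonical k-mer counts,
restricted to k-mers present in at least 5% of the hills. K is chosen from
2–6 by the highest median silhouette index over 30 bootstrap samples (size
min(500, #hills); the silhouette is evaluated on a 250-point subsample of
each bootstrap, which leaves the median selection unchanged and saves most
of the distance-matrix cost). Clusters below 10% of the largest cluster's
size are merged into their nearest centroid.

Each cluster of hill sequences is summarized as a PWM by an internal ZOOPS
(zero-or-one occurrence per sequence) EM over both strands, with widths
6–12 and 5 random restarts per width. Raw log-likelihood ratio grows
monotonically with width, so widths are compared on a BIC-penalized LLR
(three free parameters per column) and uninformative edge columns
(< 0.25 bits) are trimmed. A fit that cannot clearly beat an EM run on
base-shuffled copies of the same sequences is flagged low-complexity. An
external MEME binary is deliberately *not* required; the MEME minimal
format is used for motif import/export.

Every motif is scored against every label and subclass model as the sum of
the model's weights over the motif's k-mers — all canonical k-mers whose
best gapless log-odds alignment against the PWM reaches at least 70% of the
offset's maximum (`--motif-kmer-frac`). Positive scores mean discriminative
enrichment; non-positive scores indicate depletion relative to other
labels, not necessarily absence.

### Assignment and its robustness

A motif is *assigned* to a label when its score exceeds `assign_thresh`
(default 0) **and** it also scores above the threshold under every subclass
model the label spans. The second condition is the model's own intuition
applied at assignment time: a genuine label feature is consistently
enriched across all the subclasses the label spans, whereas a motif that
merely rides along with a co-occurring label always fails in the spanned
subclass that lacks it. Without the consistency condition, assignment by
sign alone is fragile: under the sum-to-zero gauge the off-target label
scores of a motif come in ± pairs whose signs are pure estimation noise.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a labeled ChIP-seq
compendium at desk scale:

* 150 bp sequences sampled from a 2nd-order Markov background. The default
  background is a synthetic vertebrate-like construction — ~41% GC, strong
  CpG depletion, poly-A/T tract enrichment — built in closed form by the
  package (no real genome is bundled); `fit_markov_background()` fits a
  model of any order to user sequence with add-one smoothing.
* Two label sets (default {A, B} and {X, Y}) with a tunable pairwise
  co-occurrence rate: each sequence takes one label from each set, and the
  set-2 label equals the set-1 label's partner with probability `overlap`.
* One PWM per label, from five bundled synthetic PWMs of widths 7–10
  styled on classic TF families (homeodomain TAATTA, E-box CAGCTG,
  forkhead TGTTTACA, GATA, AP-1). Instances are sampled column-wise from
  the PWM and written over the background at 70% of label-bearing sites,
  placed without overlap; a ground-truth ledger records every insertion.
* `fig_fixture_5label()` is the five-label benchmark: 9,000 sequences,
  {A, B, C} × {X, Y} with strong A–X and B–Y pairing (0.85; C draws its
  set-2 label uniformly — the co-occurrence pattern is the package's
  choice, as only the strong A–X pairing is constrained by design).

What the generator does *not* emulate: read-level noise, peak-calling
artifacts, sequence length heterogeneity, positional bias of motifs within
sites, or motif interdependence. Passing the simulation benchmarks
therefore demonstrates correct deconvolution of cleanly planted signals,
not performance on real ChIP-seq data.

## Evaluation

`match_motifs()` aligns discovered PWMs to ground truth over all offsets
and orientations; a pair matches at mean per-column Pearson correlation
≥ 0.75 over ≥ 6 aligned columns, assigned one-to-one greedily. Discovered
motifs are first deduplicated at a stricter 0.85 correlation (distinct
6-column motifs can correlate moderately by chance) and low-complexity
motifs are dropped. Assignment errors are counted over the truth-motif ×
label grid: a recovered motif assigned its true label is a TP, every wrong
label assigned is an FP, unrecovered truth motifs are FNs; discovered
motifs that match no planted motif have no defined true label and are not
adjudicated. `crossval_auroc()` reports one-vs-rest subclass auROC from
held-out posteriors under stratified k-fold cross-validation.

The naive baseline (`fit_mcc_baseline()`) treats each label as a distinct
class, duplicating multi-labeled sequences, and fits an L1 multinomial
logistic regression (glmnet). Its per-label weight vectors are scored and
assigned with the same machinery (it has no subclass structure, so
assignment reduces to the plain threshold rule).

## Problem sizes

The test-suite and reproduction runs use n = 2000 sequences per simulated
dataset for the overlap sweeps and the full 9,000-sequence five-label
fixture for parameter-recovery checks; EM motif discovery subsamples
clusters to 100 sequences. A full train–scan–cluster–discover–score
pipeline on n = 2000 takes roughly half a minute on one core.

## Known limitations

* Labels spanning only two subclasses make the median update an average,
  which is the least favourable case for deconvolution; three or more
  subclasses per label sharpen it.
* Hills require per-window scores above an absolute threshold; a label
  whose motif is weak relative to the background composition can yield few
  hills (the threshold is exposed as `--hill-thresh`).
* The motif-width search (6–12) cannot represent longer composite
  elements, though hills longer than the largest k-mer partially
  compensate.
* Scores of a motif under unrelated labels are near zero, not exactly
  zero; interpretation should use the consistency rule or the ±0.4
  saturated heat-map convention rather than raw signs.
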