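---
title: "Predicting tyrosine sulfation sites with fused profiles and a discrete firefly optimizer"
author: "sulfire package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tyrosine sulfation sites with fused profiles and a discrete firefly optimizer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tyrosine sulfation marks tyrosines of secreted and transmembrane proteins
and modulates extracellular recognition events. Given a protein sequence
and the per-residue annotation files that standard tools emit — a
PSI-BLAST position-specific scoring matrix (PSSM), a PSIPRED secondary
structure prediction, a DISOPRED disorder prediction — sulfire classifies
each tyrosine as sulfated or not. This vignette explains the model, its
tunable parameters, the numerical conventions, and what the synthetic
benchmark does and does not demonstrate.

## Windows and the fused descriptor

Every tyrosine is the centre of a sliding window of half-width ξ (default
4, window length 9). Windows that overrun a terminus are padded with the
dummy code `X`, so all descriptors have identical dimension; the alphabet
is the 20 standard residues plus `X`. The descriptor concatenates four
blocks, in this fixed order:

* **Evolutionary block (400).** The PSSM rows aligned to the window are
  aggregated into a 20×20 matrix whose cell (i, j) sums the log-odds score
  of substitution column j over all window positions whose native residue
  is type i. The aggregation is taken over the window, not the whole
  protein: a site-level descriptor must differ between two tyrosines of
  the same protein, and window aggregation is what makes the block
  site-specific. Padding rows are all-zero and `X` positions contribute to
  no row, so the block total equals the sum of all sliced scores (a
  conservation identity the tests exploit). Flattening is
  native-residue-major over the canonical PSI-BLAST column order
  `ARNDCQEGHILKMFPSTWYV`; features are named `pssm_<i>_to_<j>`.
* **Secondary-structure block (9).** For each state α ∈ {H, E, C} over the
  non-padded positions: the count `T_num`, the mean run length `Ave_len`
  (count divided by the number of maximal runs; 0 when the state is
  absent), and the composition percentage `Com_per` (0 when every position
  is padded). Padded positions are excluded and break runs — a helix
  interrupted by a terminus is two runs, not one.
* **Disorder block (9).** The per-position disorder probability, 0 at
  padded positions. Probabilities rather than binary calls are used
  because they retain the predictor's confidence; binary calls remain
  available from the parser.
* **Physicochemical block (54).** Six published residue scales —
  hydrophilicity (Hopp–Woods), flexibility (Bhaskaran–Ponnuswamy),
  accessibility (Janin), polarity (Grantham), exposed surface (Chothia
  tripeptide ASA), β-turn propensity (Chou–Fasman) — looked up per
  position, position-major, `X` mapping to 0. The values are pinned in
  `physchem_scales()` and can be overridden.

Widths are forced by arithmetic: 400 + 9 + 9 + 54 = 472, with the
evolutionary block holding 84.75 % of the dimensions and the
secondary-structure block 1.91 %. The intra-block orders are package
conventions, documented in `feature_names()`; nothing downstream depends
on them beyond consistency.

No scaling happens at encoding time. Min–max scaling to [−1, 1] is fitted
on training rows only, inside `svm_train()`, and travels with the model —
the standard SVM practice that also rules out test-fold leakage (a test
asserts that values outside the training range map outside [−1, 1]).

## Relative entropy selection

Each feature is scored by the symmetric Kullback–Leibler divergence
between its class-conditional distributions,
D(P‖Q) + D(Q‖P), estimated on a shared equal-width histogram over the
pooled range with add-one smoothing and natural logarithms (default 20
bins, a config knob). Histograms were preferred over a Gaussian closed
form because several features — counts, run lengths, percentages — are
distinctly non-Gaussian. Scores are comparable only within one run; a
constant feature scores 0 by definition, and ties are broken toward the
smaller feature index so the ranking is deterministic.

## Incremental feature selection

Prefixes of the ranked list are grown one feature at a time; each prefix
is scored by stratified, seeded k-fold cross-validated MCC of an
RBF-kernel SVM, and the smallest prefix attaining the maximum MCC is the
candidate subset. The SVM hyperparameters come from one grid search over
log₂C ∈ [−5, 15] and log₂γ ∈ [−15, 5] on the full feature set and are
held fixed across prefixes: refitting the grid at every prefix would
multiply the cost by the grid size while changing the comparison between
prefixes from "same model, more features" to "different models". The grid
step defaults to 2; the bundled pipeline uses step 4, which on the
synthetic benchmark selects within one step of the fine grid at a ninth of
the cost.

## The discrete firefly algorithm

The second selection round searches the IFS candidate subset jointly with
(C, γ). A firefly is a real vector over n feature dimensions plus two
hyperparameter dimensions (log₂C, log₂γ). Feature bits are sampled through
the sigmoid S(x) = 1/(1+e^(−x)) each time a firefly moves; the
hyperparameter dimensions stay continuous and are clipped to their ranges.
Brightness is the fitness

> fit = w₁ · MCC + w₂ · (1 − n_selected / n),

with w₁ = 0.9, w₂ = 0.1 by default — enough parsimony pressure to strip
redundant features without overriding a genuine MCC gain of 0.1/n per
feature. Each generation, every firefly moves sequentially toward every
brighter one by

> xᵢ ← xᵢ + β₀·exp(−γ_abs·r²)·(xⱼ − xᵢ) + α·(U(0,1) − ½),

with distance r Euclidean over all n + 2 dimensions, α = 0.9 (constant; no
decay schedule), γ_abs = 0.5 and β₀ = 1; the exponent m = 2 in the
attractiveness decay matches the squared distance in the movement rule.
The brightest firefly, having no attractor, takes a pure random-walk step.
Empty masks are repaired by activating one uniformly chosen bit, which
keeps the fitness defined without penalty terms. Evaluations are cached by
mask plus hyperparameters rounded to six significant digits, bounding the
number of cross-validation runs. The default budget is a group of 100 for
1000 generations; the pipeline preset uses group 20 for 30 generations,
which suffices on the synthetic benchmark (the optimizer-correctness tests
show exact agreement with exhaustive search on 8-bit landscapes at group
20, 100 generations).

The optimizer is seeded and bit-reproducible. Any seeded stage that runs
inside another seeded stage (cross-validation inside the firefly
evaluator) saves and restores the RNG state, so nesting cannot silently
shift a stream.

## Cross-validation and metrics

Folds are stratified by class and seeded; metrics are computed per fold
and averaged (not pooled into one confusion matrix). SN, SP, ACC and MCC
follow the usual confusion-matrix definitions with the convention that a
zero denominator yields 0 — including MCC's product term — so degenerate
folds produce defined, pessimistic values rather than NaN. AUC is the
rank-based Mann–Whitney statistic on the SVM decision values (ties counted
half); no probability calibration is applied. The SVM is libsvm through
e1071, matching the behavioural contract of the reference implementation;
class weighting is available but off by default.

## The synthetic benchmark

`simulate_dataset()` writes a complete input tree — FASTA, annotation TSV,
and one PSSM/ss2/diso file per protein in the exact dialects the parsers
read — from a seed. Defaults: 60 proteins of length 90–130, tyrosine
density 0.1, and a 1:4 positive:negative imbalance, yielding roughly 600
candidate windows. Ten features are planted at a class-conditional shift
of 2 pooled SDs: seven PSSM substitution columns of the central tyrosine
row and the three central disorder positions. Signal is planted in
*profile space* (by shifting file contents, not encoded matrices), so the
parsers and encoders are exercised on-path.

Because windows overlap, a planted residue of one site leaks into
neighbouring windows of either class; the generator calibrates the planted
deltas analytically for this crosstalk and for the window-summed variance
of the evolutionary features, and a test verifies the realized shifts stay
within 25 % of the configured value at n ≥ 500 windows. The tyrosine
density is inflated about threefold over natural composition so a small
protein set yields enough windows; the generator emulates file formats,
class imbalance and effect sizes, but not real evolutionary statistics,
homology structure or compositional biases. Passing its tests shows the
machinery recovers known signal of a stated size; it does not certify
performance on curated sulfation data, which additionally requires real
PSI-BLAST/PSIPRED/DISOPRED runs.

## Problem sizes and numerical choices

The bundled pipeline and the reproduction script run at desk scale: ~470
training windows, grid step 4 with 5-fold CV, IFS over the top 30 ranked
features, and the group-20/30-generation firefly budget with 3-fold CV
inside the fitness evaluator — a few minutes on one CPU, with hold-out MCC
around 0.89 on the default benchmark. Other conventions: coordinates are
1-based in all user-facing files; duplicate windows with conflicting
labels are kept with a warning (they are genuine ambiguity, not errors);
every tyrosine not annotated as sulfated is treated as a negative, with
optional seeded down-sampling (off by default, since the imbalance is
information the classifier can use); PSSM column order is read from the
file header rather than assumed, then re-ordered to the canonical
alphabet.

## Known limitations

* Performance claims transfer to real data only qualitatively; the
  benchmark is synthetic by design.
* The fitness weights of the firefly optimizer (0.9/0.1) are a default,
  not a calibrated quantity; applications that value sparsity differently
  should adjust them.
* The IFS hyperparameters are fixed across prefixes; a per-prefix grid
  may shift the peak by a few features.
* Negative sites are inferred from the absence of annotation, so
  incompletely annotated proteins contaminate the negative class — a
  property shared by all predictors trained on positive-only databases.
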