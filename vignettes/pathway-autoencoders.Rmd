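---
title: "Explainable pathway autoencoders: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable pathway autoencoders: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwayAE)
```

## The problem and the representation

The package predicts a binary, pathway-related outcome — say, short-term
mortality after implantation of a cardiac device — from nothing but the
patient's coded medical history, and produces a *global* explanation of
what drives the prediction. Inputs are event logs: per patient, dated
events, each a bag of medical codes from hierarchical classification
systems (ICD-10-like diagnoses, procedure and device nomenclatures,
biology, consultations), a 0/1 outcome, and an index date at which the
prediction is anchored.

Three representation choices matter:

* **Hierarchy enrichment.** Rather than forcing the analyst to pick one
  aggregation level per code system, every occurrence of a code also
  contributes one occurrence of each of its ancestors, so all levels
  coexist as separate activity labels. An ancestor's multiplicity within
  an event is therefore the sum of its descendants' multiplicities there
  (plus its own recorded occurrences). Enrichment never removes
  occurrences. Only single-parent hierarchies (trees) are accepted: the
  cited systems are trees at the levels used, and a poly-hierarchy would
  make the multiplicity semantics ambiguous.
* **Time windows.** Each patient becomes a matrix `x` with `l` activity
  rows and `w` time-window columns; `x[i, j]` counts occurrences of
  activity `i` in window `j`. Windows are contiguous, half-open, and end
  at the index date; window `j = w` is the most recent and the index date
  itself is *excluded* (the history is strictly prior to the prediction
  point). An event `days_before` days before the index falls in window
  `w + 1 - ceiling(days_before / window_days)`; events older than the
  covered period are dropped (counted in `attr(, "n_dropped")`), not
  errors, since claims extracts routinely contain stragglers. Two presets
  are provided — `spec_case_study()` (2 years as 24 windows of 30.44 days)
  and `spec_example()` (2 years as 26 windows of 28 days) — because both
  geometries are in common use; neither is hard-coded anywhere.
* **Rescaling.** Counts are mapped to `[0, 1]` by a single global factor,
  the maximum cell value over the *training* data, persisted and reused at
  test time (values above it clip to 1). A per-activity factor would
  equalise intensities across activities; the global factor keeps relative
  intensity information and is exactly invertible on training data.

Infrequent labels are discarded by total occurrence count (every
occurrence, not distinct patients — the natural reading of an
"occurrences" threshold), after enrichment so roll-up levels are counted
too; the retained label set is sorted so row indexing is reproducible, and
is re-applied as-is to test data.

## Objectives, architectures, scores

With class function `C(x) ∈ {0, 1}`, the autoencoder (encoder `f_θ`,
decoder `g_θ`, output `x' = g_θ(f_θ(x))`) is trained to minimise

`J^α = Σ_x L(δ^α(x), x')`,

where `L` is binary cross entropy summed over the `p = l·w` cells and the
target transform `δ^α` treats the classes asymmetrically:

* **filter** (`α = F`): negatives map to the all-zero target, positives to
  themselves. The trained model passes positive-class information through
  the bottleneck and suppresses the rest; the score is the decoded mass
  `y^F(x) = Σ_{i,j} x'[i,j] ∈ [0, p]`.
* **inverse** (`α = I`): negatives map to their complement `1 − x`,
  positives to themselves. The model acts as a classifier with a
  matrix-valued output; the score is the inverse reconstruction error
  `y^I(x) = 1 − (1/p) Σ (x[i,j] − x'[i,j])² ∈ [0, 1]`.

The squared elementwise deviation in `y^I` is a deliberate reading of the
`|·|²` notation (absolute difference would also normalise, but the square
matches the stated normalisation by `p` and standard error usage); it is
the package's documented choice.

Three architectures share one symmetric dense skeleton —
`flatten(p) → dense(32, tanh) → latent(8) → dense(32, tanh) →
dense(p, sigmoid)`:

* **AE**: the plain model above.
* **DAE**: identical, but each epoch the *inputs* are corrupted by
  flipping exactly `round(noise_ratio · p)` uniformly chosen cells to
  their complement (default ratio 0.1%); targets stay clean. Corruption is
  resampled every epoch from the seeded stream.
* **VAE**: the latent head emits means and log-variances (`2 × 8`
  values); training draws one reparameterised sample per element and adds
  the analytic KL divergence of the diagonal Gaussian posterior from
  `N(0, I)`. Maximising the ELBO is expressed as minimising `J^α + KL`.
  At inference the posterior *mean* is decoded, never a sample, so
  predictions and explanations are deterministic.

Training uses Adam (learning rate `1e-4`), batch size 64, at most 5,000
epochs with early stopping after 25 epochs without validation improvement,
returning the best-validation weights. The monitored loss is computed on a
held-out stratified 10% of the training patients (the source method does
not say what was monitored; a held-out split is the conservative choice,
and an explicit validation dataset can be supplied instead). The loss is
summed over cells and averaged over the batch — a scaling that keeps
gradients independent of batch size and equals the formal per-element sum
up to a constant. Outputs are clipped to `[1e-7, 1 − 1e-7]` inside the
cross entropy. Everything — initialisation (Glorot), shuffling, DAE
corruption, VAE sampling, validation split — derives from one integer
seed, and refits are bit-identical. Dropout and batch-normalisation are
deliberately absent: they are described only for the baseline deep
classifiers, not the autoencoders, and omitting them keeps fits exactly
reproducible. The hand-rolled backpropagation is verified against finite
differences in the test suite.

## Thresholding and metrics

Scores are thresholded where the size-weighted Gini impurity of the
two-group split is minimal, scanning midpoints of consecutive sorted
unique scores (the CART split criterion; ties resolve to the smallest
threshold, and `predicted = score >= threshold`). Reported metrics are
AUC-ROC (Mann–Whitney rank form, average ranks for ties), AUC-PR (step
integration over descending unique thresholds) and MCC at the threshold; a
zero confusion margin yields MCC 0 with a warning rather than `NaN`.

## Explanation and validation

The explanation element is `E = x̄₁ − x̄₀`, the cell-wise difference of
mean decoded positives and negatives, computed on training data in the
pipeline (any population can be passed explicitly). Cells that push
predictions towards the positive class carry the largest values of `E`;
under the inverse objective the whole map is shifted downwards (negatives
decode towards complements, inflating `x̄₀`), so rankings read the
*ordering*, not the absolute level. Two scopes are ranked separately:
row sums over windows `1..w−1` (recurrent, long-term factors) and the last
window's column alone (punctual, just-before-index events). Ties break
lexicographically by label so reports are reproducible. A minimal
representation zeroes all but the selected rows of `E` for display.

Ranked activities are then validated epidemiologically. For each activity
and scope, patients are split at the population mean of the scope
statistic (`>=` is exposed; with identical patients everyone is exposed —
the degenerate case is accepted, but a single-group exposure makes the
relative risk undefined and errors). The relative risk of the outcome is
computed from the 2×2 table with the 95% Katz log-normal interval
`exp(log RR ± 1.96·SE)`, adding 0.5 to all four cells only when a cell is
zero (flagged). "Most significant" is implemented as *CI excludes 1 and
RR > 1, ordered by RR descending* — the source names no test, and this
rule matches how forest plots of such factors are read; the top 15 are
kept by default. The validation population is train ∪ test by default
(configurable), since association, unlike prediction, need not be
evaluated out-of-sample.

## The synthetic generator: what a green test establishes

No claims extract can ship with the package, so every pipeline property is
exercised on simulated logs. The generator's stated world is:

* 2,000 patients, 40% outcome prevalence (the case study's observed
  prevalence), index dates spread across a year;
* 20 background activities (leaves of a generated 2-system, depth-2
  hierarchy), each active per (patient, window) as an independent
  Bernoulli draw at rate 0.02 — a sparse null resembling claims density of
  roughly ten coded events per patient-year per retained label family;
* 26 windows of 28 days (two years);
* a 6-activity temporal motif planted in 90% of positives
  (`pattern_penetrance`), its last step in the final pre-index window so
  both ranking scopes have a recoverable target; 5% of negatives carry the
  first half of the motif as confusable noise.

Window offsets, not absolute dates, define the motif, so it transfers to
any geometry. Event dates sit mid-window, making tensorization recover
planted cells exactly. With penetrance 1 and no noise the classes are
perfectly separable (a motif detector attains AUC-ROC 1), bounding what a
trained model can achieve; at penetrance 0.9 the ceiling is ≈ 0.95
because non-carrier positives are statistically identical to negatives.

What the generator does **not** emulate: realistic marginal code
frequencies, co-morbidity correlation structure, bursty hospitalisation
episodes, or any source-database table structure. A green test therefore
establishes that the machinery — representation, objectives, optimisation,
scoring, explanation, validation — recovers planted structure under an
idealised null, not that any particular clinical performance level will be
reached on real data.

## Numerical and design notes

* The filter objective has a long loss plateau on sparse data: targets
  are near-zero for *both* classes except at the few active cells of
  positives, so the class-gating signal is weak and, at learning rate
  `1e-4`, patience-25 early stopping can halt inside the plateau before
  the filtering behaviour emerges. The acceptance check for the filtering
  property therefore trains a fixed 1,600-epoch budget with the patience
  rule disabled (still ~2.5 minutes on one CPU). The inverse objective has
  no such plateau — every cell of every patient carries class signal —
  which is consistent with it outperforming the filter strategy.
* Matrix datasets persist as plain CSV values plus a JSON side-car
  (labels, classes, geometry, rescale factor); no HDF5 library for R is
  assumed. Model checkpoints are single-file RDS archives whose loader
  verifies shape compatibility. Pipeline configurations are JSON merged
  over documented defaults.
* The pipeline stages (`cmd_simulate` … `cmd_validate`) each persist
  their outputs plus a `run_<stage>.json` recording config, seed, package
  version and input checksums, so runs are resumable and auditable; with
  equal inputs, all numeric outputs are bit-identical.
* Raw recordings at several hierarchy levels are all kept as-is before
  enrichment (no deduplication): the data are trusted to mean what they
  record.
* Events are keyed by (patient, calendar date); intra-day ordering is not
  modelled — claims carry dates, and same-day activities form one event.

## Limitations

Only dense encoders are provided (recurrent or convolutional variants are
plausible extensions); no hyper-parameter search is built in; the
explanation is global, not per-patient; relative risks are unadjusted
2×2 associations, not causal estimates; and the window length remains a
user choice driven by clinical knowledge of the studied pathway.
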