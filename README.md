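# pathwayAE

Explainable prediction of binary pathway outcomes from coded medical event
logs, using autoencoders trained with class-asymmetric objectives.

The package is aimed at researchers working with claims-style data — per
patient, a sequence of dated events, each carrying medical codes
(diagnoses, procedures, devices, biology, consultations) organised in
hierarchies — who want to predict an outcome fixed at an index date (e.g.
short-term mortality after device implantation) *and* identify which
activities, at which point in the history, drive the prediction, without a
black-box post-hoc explainer.

## Method

Each patient's two-year history is represented as a matrix
`x ∈ [0,1]^(l×w)`: rows are activity labels (raw codes plus every ancestor
in the code hierarchy), columns are `w` time windows ending at the index
date, and `x[i,j]` is the rescaled occurrence count of activity `i` in
window `j`. An encoder `f_θ` and decoder `g_θ` (dense, tanh hidden layers,
sigmoid output, bottleneck `d_latent = 8`) are trained by minimising, over
patients `x` with class `C(x) ∈ {0,1}`,

    J^α = Σ_x L(δ^α(x), g_θ(f_θ(x)))      α ∈ {F, I}

where `L` is summed binary cross entropy and the target transform is

    δ^F(x) = 0      if C(x) = 0      δ^I(x) = 1 − x   if C(x) = 0
           = x      if C(x) = 1             = x       if C(x) = 1

("filter": negatives must decode to zeros; "inverse": negatives must
decode to their complement). Plain (AE), denoising (DAE, random bit-flip
corruption) and variational (VAE, ELBO with the likelihood term replaced
by `J^α`) variants are available. Prediction scores are the decoded mass
`y^F = Σ x'` or the inverse reconstruction error
`y^I = 1 − (1/p) Σ (x − x')²`; a decision threshold minimises the Gini
impurity of the score split, and performance is reported as AUC-ROC,
AUC-PR and MCC. A global explanation element `E = x̄₁ − x̄₀` (difference of
mean decoded positives and negatives) ranks predictive (activity, window)
cells; top activities are validated epidemiologically via relative risks
with 95% Katz confidence intervals after mean-threshold exposure grouping.

A synthetic event-log generator with plantable temporal motifs (and full
ground truth) makes the entire pipeline testable without access to claims
data.

## Worked example

Simulate the built-in 2,000-patient benchmark (40% prevalence, a 6-step
motif planted in 90% of positives), train the inverse-objective VAE, and
evaluate on held-out patients:

```r
library(pathwayAE)

gen   <- generate_event_log(benchmark_config(seed = 1))
split <- split_train_test(gen$log, test_fraction = 0.2, seed = 1)
spec  <- window_spec(n_windows = 26, window_days = 28)
train <- tensorize(split$train, spec)
test  <- tensorize(split$test, spec, rescale_factor = train$rescale_factor)

fit <- pathway_autoencoder(train, strategy = "inverse", architecture = "vae",
                           max_epochs = 200, seed = 1)
fit
#> Pathway autoencoder (VAE, inverse objective)
#>   input: l = 20 activities x w = 26 windows (p = 520)
#>   widths: hidden 32, latent 8 (mean + log-variance heads)
#>   trained 89 epochs; best validation loss 79.8757 at epoch 64

evaluate_scores(predict(fit, test, type = "score"), test$classes)
#> Evaluation report
#>   AUC-ROC: 0.9482   AUC-PR: 0.9622   MCC: 0.9235
#>   threshold: 0.984697   confusion (tp fp fn tn): 145 0 15 240
```

The held-out AUC-ROC of 0.95 sits at the ceiling this generator admits:
the 10% of positives that do not carry the motif are indistinguishable
from negatives. Explanation and validation recover the planted structure:

```r
E <- explanation_element(fit, train)
head(rank_frequent(E, k = 10), 4)
#>   rank    label     score    scope
#> 1    1 DIAG.2.1 -20.46531 frequent
#> 2    2 DIAG.1.2 -20.48770 frequent
#> 3    3 DIAG.1.1 -20.49067 frequent
#> 4    4 DIAG.2.2 -20.52297 frequent

relative_risk(exposure_frequent(train, "DIAG.2.1"), train$classes)
#>      label    scope   a   b  c   d       rr  ci_low ci_high significant
#> 1 DIAG.2.1 frequent 607 408 33 552 10.60143 7.58175 14.8238        TRUE
```

The top-ranked activities are exactly the motif activities planted by the
generator (`gen$truth$pattern`), and the top one is a strongly significant
risk factor. Only the *ordering* of the ranking scores matters; under the
inverse objective their absolute level is shifted by the complement
decoding of negatives.

The same pipeline is scriptable end-to-end through `cmd_simulate()`,
`cmd_prepare()`, `cmd_train()`, `cmd_evaluate()`, `cmd_explain()` and
`cmd_validate()` with a JSON configuration, or from a shell via
`inst/scripts/xae.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — simulating the benchmark event log, preparing matrices, training
the inverse-objective VAE, evaluating held-out patients, computing the
explanation element and validating risk factors — and writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
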