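---
title: "Rater-adaptive ensembles for crowdsourced developmental screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rater-adaptive ensembles for crowdsourced developmental screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raterstack)
library(dplyr)
```

## The model

`raterstack` aggregates multiple-choice behavioral annotations of children's
videos, produced by non-clinician raters, into a screening decision for
developmental delay. The data are tabular: one row per (child, rater), with
ordinal answer codes for each of 31 instrument questions and a per-child
diagnosis in {TD, SLC, ASD} (typical development, speech-and-language
condition, autism spectrum disorder).

### Per-rater models and softmax weighting

Raters differ in which behaviors they score reliably. The pipeline therefore
trains one random-forest classifier per rater, on that rater's own
annotations, and combines the models rather than the raw answers. For rater
$j$, let $z_j$ be the accuracy of its model on held-out validation children
minus the accuracy of the majority-vote baseline on the same children. The
rater weights are

$$w_j = \frac{e^{z_j}}{\sum_k e^{z_k}},$$

and the ensemble probability of the target class for child $i$ is
$p^{(i)} = \sum_j w_j\, p_j^{(i)}$. The softmax guarantees positive weights
summing to one (so the ensemble is a convex combination), is invariant to
adding a constant to all deltas, and preserves their ordering. Because $z$ is
measured in accuracy fractions (range $[-1, 1]$), the weights are
intentionally soft: a rater must be far worse than consensus to be strongly
down-weighted, which keeps the ensemble robust when all raters are adequate.
The softmax temperature is fixed at 1, matching the weight formula as
written; deltas can be rescaled before weighting if sharper separation is
wanted.

Two interpretations of "majority-vote baseline" are plausible and both are
implemented (`baseline` argument of `fit_rater_ensemble()`): the default
scores each rater's model against the plurality of all rater models' predicted
labels on the validation children, making $z_j$ a measure of marginal skill
over the consensus; the alternative (`"majority_class"`) scores against a
constant most-frequent-class predictor.

The validation split is a stratified 25% of the labeled children, held out
once and shared by all raters, so the majority-vote baseline is coherent
across raters and no rater's nested model sees another rater's validation
children. After the deltas are computed the per-rater models are refit on all
their labeled children, with the weights frozen; this uses the full training
fold for the deployed models while keeping weight estimation out-of-sample.
A child not rated by every rater is still predictable: the weights are
renormalized over the covering raters, so partial annotation coverage needs
no imputation.

### The stacked two-layer pipeline

Screening and differential classification are different decisions, so they
are stacked: layer 1 classifies TD vs atypical ({ASD, SLC}); children whose
layer-1 ensemble probability reaches the decision threshold are gated into
layer 2, which classifies ASD vs other delay. The threshold defaults to 0.5
and is configurable; with the atypical class in the majority, the default
already yields the high-sensitivity behavior wanted of a first-stage screen,
and lowering the threshold can only increase sensitivity further (gating is
monotone).

Layer 2 is trained on the truly atypical training children (the only ones
with an ASD-vs-SLC label) but evaluated on the *predicted*-atypical test
children, because that is the population the second stage sees in
deployment. Gated TD false positives are counted as layer-2 negatives. On
small cohorts this contamination makes layer-2 specificity volatile across
folds — an honest property of the design, visible in the reported SDs. A
fold whose gated set is single-class gets undefined layer-2 metrics; these
are excluded from the mean/SD rather than imputed, with a warning.

Metrics per fold: sensitivity, specificity, their mean (unweighted average
recall), accuracy, and AUC computed from the Mann–Whitney rank statistic
with midrank tie correction (constant scores give exactly 0.5). Aggregates
are the mean and sample SD over folds. Cross-validation folds partition
*children* (never annotation rows) and are stratified by the three-way
diagnosis even though a plain random split would do; on 150–300 children
stratification visibly stabilizes the per-fold class mix.

### Shapley attribution through the ensemble

Interventional Shapley values attribute each video's predicted probability
to its feature values: $\Phi_k(F_j, x^{(i)})$ is feature $k$'s contribution
for video $i$ under model $F_j$, relative to a base value defined as the
model's mean prediction over a reference set. Local accuracy —
$\text{base} + \sum_k \Phi_k = F_j(x^{(i)})$ — is the property that makes
attributions comparable across videos and models.

Because the ensemble is linear in the rater models, ensemble attributions
need no separate explanation pass:
$\Phi^{ens}_k = \sum_j w_j \Phi_k(F_j, x^{(i)})$ with base value
$\sum_j w_j \cdot \text{base}_j$, and ensemble local accuracy follows by
linearity. Global importance is the per-feature sum of absolute ensemble
Shapley values over videos, ranked with ties broken by feature order.

Two computation paths are provided. Up to 12 features, `model_shapley()`
enumerates all $2^p$ feature subsets and returns exact interventional values.
Beyond that it switches to paired permutation sampling (default 2048 draws,
seeded): each draw couples a random feature ordering with a single reference
row, and because marginal contributions telescope from the reference
prediction to the video's prediction, local accuracy holds *exactly* even at
small sample counts — only the allocation across features is approximate. In
the sampling path the base value is the mean prediction over the sampled
reference rows. A separate brute-force oracle (`exact_shapley_oracle()`)
implements the factorial-weighted subset formula directly and independently,
for verification. The reference set defaults to the training-fold matrix,
keeping test children out of the base value. Missing-answer sentinel codes
are attributed like any other code: "unratable" is an observation in its own
right and trees may legitimately route on it.

### Cross-site transfer

To ask whether one cohort's feature–diagnosis relationships generalize to
another, the package fits elastic-net logistic regression on child-level
features and evaluates across sites. The objective is

$$\frac{1}{n}\sum_i w_i\,\ell_i(\beta, \beta_0) +
  \alpha\left(\rho\|\beta\|_1 + \tfrac{1-\rho}{2}\|\beta\|_2^2\right),$$

with the intercept unpenalized and balanced class weights
$w_i = n/(2 n_{c(i)})$. This parameterization maps exactly onto glmnet
(`alpha` there is $\rho$, `lambda` is $\alpha$, `standardize = FALSE`), which
is used as the solver with a warm-start path ending at the requested
strength. Features are *not* standardized: they share the ordinal answer
scale already, and keeping raw codes makes coefficients and selection counts
directly comparable across sites.

Hyperparameters are grid-searched (defaults $\alpha \in \{1, 0.1, 0.01,
0.001\}$, $\rho \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$) by stratified
cross-validation on 80% of the training site, selecting the pair with
maximal mean AUC; ties resolve toward larger $\alpha$ then larger $\rho$,
preferring the more parsimonious model. The final model is evaluated on the
same-site 20% held-out split (stratified — the split protocol should
preserve the class mix at these sample sizes) and on the full other site.
Feature-selection frequency tables count, per feature and per $\alpha$, the
cross-validation folds in which its coefficient exceeds $10^{-8}$ in
magnitude — numerical zero under coordinate-descent tolerance.

Multi-rater rows are collapsed to one consensus vector per child for this
module (plurality over raters per question, ties toward the lower code,
questions nobody could rate mapped to the sentinel); missing answers do not
vote. The per-rater ensemble machinery is deliberately not reused here: the
transfer question is about site-level feature relationships, not rater
skill.

## The synthetic-data generator

No public accession exists for crowdsourced video-annotation cohorts of this
kind, so the package generates its own test beds with the statistical
structure the method assumes:

* **Cohorts.** Class counts default to 55 ASD / 50 SLC / 54 TD — a
  159-child screening cohort. Each class has an archetype: per question, a
  probability vector over answer codes. Children draw latent "true" answers
  independently per question. Default archetypes place triangular mass
  around a class-specific position on the severity-ordered codes (TD low,
  SLC middle, ASD high), flattened toward uniform by the `separation`
  parameter.
* **Raters.** A rater reports each latent answer with per-question
  reliability $r$, otherwise one of the remaining codes uniformly at random,
  and marks items unratable with a per-question missingness probability
  (default 0.02). The default panel is one expert ($r = 0.95$ throughout),
  one feature-complementary rater (mean 0.75: 0.95 on even-indexed
  questions, 0.55 on odd-indexed), and one near-chance rater ($r = 0.40$) —
  the heterogeneous-expertise structure the weighting is designed to
  exploit.
* **Separation default.** `separation = 0.2` was chosen so that the default
  scenario lands in a realistic screening regime (layer-1 AUC ≈ 0.75–0.85,
  layer-2 AUC ≈ 0.65–0.85 across seeds) rather than the saturated regime
  where every classifier is perfect and rater weighting has nothing to do.
  With 31 conditionally independent informative questions, even modest
  per-question signal compounds quickly; 0.2 keeps individual questions
  weak (single-question AUC near chance) while the aggregate remains
  learnable.
* **Site shift.** `generate_two_sites()` perturbs a chosen subset of
  questions by mixing each class archetype toward the class-pooled mean
  with weight `magnitude`: 0 leaves the sites exchangeable, 1 removes all
  class signal from the shifted questions at site B. This gives the
  transfer module both a null (exchangeable sites) and a targeted
  alternative (site-specific feature relevance) to test against.

What the simulator does *not* model: rater drift over time, correlated
errors between raters, question dependence within child beyond class
membership, demographic covariates, and systematic (non-uniform) error
patterns such as severity-adjacent confusions. Passing simulation tests
therefore demonstrates the pipeline's internal correctness and its behavior
under the assumed noise structure — not performance on real clinical data.

## Numerical choices and degenerate inputs

* All sampling and fitting is seeded; independent sub-streams are derived
  from the user seed by hashing a stream label, so adding a stage never
  shifts another stage's draws.
* Softmax is computed with max-subtraction; weights sum to 1 within `1e-9`.
* Mann–Whitney AUC uses midranks, so tied scores are handled without
  randomization; single-class truth raises an error rather than returning a
  vacuous value.
* Majority votes break ties by training-class prevalence, then fixed class
  order (TD, SLC, ASD) — deterministic across platforms.
* Stratified splits guarantee each fold's per-class count is within one
  child of proportional, by dealing the class-blocked shuffled sequence
  cyclically.
* Coordinate descent runs at `thresh = 1e-12` with a 30-point warm-start
  path; the $\alpha = 0$ path ends at exactly 0 and reproduces the
  unpenalized weighted fit to `1e-4`.
* Sizes used in the shipped checks: the 159-child default cohort for the
  stacked pipeline, 300 children for weight-recovery replicates, 400 per
  site for transfer, 8-question vocabularies for exact-Shapley
  verification. These keep full runs to a few minutes on one core while
  leaving each check adequately powered.

## Known limitations

* Rater models are random forests only; the design would admit any
  probabilistic classifier, but no alternative learners are wired in.
* Hyperparameters of the per-rater forests are fixed (500 trees, default
  `mtry`) rather than tuned per rater.
* The number of raters is configurable but the shipped scenario uses three;
  behavior with dozens of sparse raters is supported through weight
  renormalization but not profiled.
* Layer-1 specificity at the default threshold is low on imbalanced
  cohorts; applications needing balanced screening should sweep the
  threshold (`evaluate_stack_cv(threshold = ...)`).
* Ensemble Shapley values inherit each rater model's feature view: a child's
  attribution for rater $j$ is computed on rater $j$'s annotations, so
  per-feature values mix annotation disagreement with model behavior.
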