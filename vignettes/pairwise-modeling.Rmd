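---
title: "Pairwise naive Bayes modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise naive Bayes modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairNB)
```

## The model

`pairNB` predicts a binary clinical outcome (coded 1 = event, e.g.
locoregional recurrence; 0 = no event) from a numeric feature table by
classifying *template–sample pairs* rather than samples.

Let $M_I \in \mathbb{R}^d$, $I = 1,\dots,T$ be the feature vectors of $T$
representative labeled templates and $N_i$ the vector of sample $i$, all in
the processed (normalized, reduced, screened) feature space. The pair
vector is the signed difference

$$V_{I,i} = M_I - N_i,$$

and the pair is *positive* when template and sample share the outcome
class, *negative* otherwise. A binary pair classifier — Gaussian naive
Bayes by default — is fitted on the training pairs and outputs the
positive-pair probability $P_{PP}(V)$.

At prediction time each template votes. A subtlety: a naive average of
$P_{PP} + (1 - P_{NP})$ over templates is degenerate for a binary pair
classifier, because $P_{NP} = 1 - P_{PP}$ makes both terms identical and
the average loses all dependence on the template labels — yet the decision
rule explicitly depends on them. The only reading under which the
aggregated score behaves as the probability that the sample is an event is
the one implemented here: template $I$ contributes

$$s_I = \begin{cases} P_{PP,I} & \text{if } M_I \text{ is an event
template}\\ 1 - P_{PP,I} & \text{otherwise,} \end{cases}$$

the aggregate is $P_i = \tfrac1T \sum_I s_I$, and the predicted class is
$1$ when $P_i \ge 0.5$. The decision rule is stated with strict
inequalities on either side of $0.5$, which leaves the boundary undefined;
we resolve the tie toward class 1 (operator $\ge$), and the threshold is a
configurable model field. The continuous score $P_i$ — never the
thresholded class — feeds ROC, calibration and decision-curve analyses.

Self-pairs (a template paired with its own row) are zero vectors and
perfect positives by construction; they are excluded from training by
default because they bias the pair classifier's positive class toward the
origin. An absolute-difference mode ($|M_I - N_i|$) is available for the
strict "distance" reading of the pairing, but the signed difference is the
default since the construction is written as a subtraction.

### Template selection

Expert choice of "representative cases" is supported via
`strategy = "manual"`, but the default is deterministic: per-class template
counts proportional to class frequencies (largest-remainder rounding, at
least one per class — 45/46 training classes with 7 templates give 3
event / 4 non-event), and within each class the *medoids*, i.e. the samples
minimizing summed Euclidean distance to their classmates, with ties broken
by sample id after canonicalizing to sorted-id order so the choice cannot
depend on row order. Templates are drawn from the training partition only
and stay in it; they are never test-set members — the only leakage-safe
arrangement.

## The surrounding pipeline

`fit_pipeline()` chains, fitted strictly on the training partition:

1. **Normalization** (`unit`, `zero_center`, `unit_zero_center`). "Unit"
   here means division by the per-feature Euclidean norm over training
   samples, not min–max scaling; the combined scheme is
   $(x - \bar x)/\lVert x - \bar x\rVert$. This is the FAE-style
   convention for radiomics tables; the min–max reading of "unit" is the
   main plausible alternative and is deliberately not implemented twice.
   A feature with zero scale maps to all zeros (scale fallback 1) and is
   flagged.
2. **Reduction.** `pcc`: a greedy first-kept-wins scan over features in
   table order (or by screening score when a hint is supplied) dropping any
   feature whose absolute Pearson correlation with an already-kept feature
   exceeds the threshold (default 0.99 — radiomics families are nearly
   collinear, and the aim is only to remove near-duplicates before
   screening; no threshold is prescribed by the source methodology). The
   scan is idempotent and sample-order independent. `pca` is the
   alternative, with components ordered by explained variance and a fixed
   sign convention (largest-magnitude loading positive) for
   reproducibility.
3. **Screening.** `anova`: per-feature one-way F between the outcome
   groups — the standard select-K-best construction; a true multivariate
   ANOVA would not yield the required per-feature ranking. `relief`:
   classic binary Kira–Rendell Relief, one nearest hit and miss by
   Euclidean distance over all features, every training sample visited
   once in seeded random order, range-normalized differences. `rfe`:
   recursive elimination of the smallest-|coefficient| feature from a
   ridge logistic model (the naive Bayes classifier exposes no coefficient
   magnitudes to drive elimination), one feature per step. All rankings
   break ties lexicographically by feature name.
4. **Top-`n_features` selection** (default 12), then template selection,
   pair construction, and the pair classifier fit.

Clinical ordinal covariates (T stage, N stage and the like) are expected
pre-encoded as numerics and screened jointly with the radiomics features;
no published encoding or exemption rule exists, and joint screening is the
assumption-free default.

### Cross-validation and the grid optimizer

`crossvalidate()` uses stratified folds (91 samples in 5 folds split
19/18/18/18/18) and refits *every* data-dependent step — normalizer,
reduction, screening, templates, classifier — inside each fold. Refitting
only the classifier would leak screening information from the validation
folds and bias validation AUC upward; the per-fold audit trail
(`return_details = TRUE`) exposes the fitted normalizer statistics and
template ids so tests can verify the contract directly.

`grid_optimize()` crosses {3 normalizations} × {pcc, pca} × {3 screeners}
× `n_features` 1..20 × classifier families, scores each cell by mean CV
validation AUC, breaks ties by fewer features then lexicographic
configuration, records failed cells rather than aborting, and refits the
winner on the full training set.

### The classifier menu

Ten families: `gaussian_nb`, `logistic`, `lda`, `svm_linear`, `svm_rbf`,
`knn`, `decision_tree`, `random_forest`, `adaboost`, `gaussian_process`.
Standard families delegate to the stock implementations (`MASS`, `e1071`,
`class`, `rpart`, `randomForest`, `kernlab`, `stats::glm`). Two are
implemented in-package: Gaussian naive Bayes, because pair vectors
routinely produce near-duplicate or zero-variance dimensions and the fit
needs an explicit variance floor ($10^{-9}$ times the largest per-feature
variance, never below $10^{-12}$, the usual smoothing convention), and
because the default model should serialize transparently to JSON; and a
depth-1-stump AdaBoost.M1 (50 rounds, logistic link on the ensemble margin
for probabilities), since no AdaBoost implementation is available among
the package's dependencies. Beyond naive Bayes, SVM, LDA and logistic
regression, the menu's composition is an implementation choice.

## Evaluation statistics

- **AUC** via `pROC` (Mann–Whitney concordance with tie credit); the test
  suite checks it against brute-force concordant-pair counting.
- **AUC interval**: stratified percentile bootstrap, 1000 resamples of
  events and non-events separately, seed recorded. No interval method is
  prescribed by the source methodology; the percentile bootstrap is the
  assumption-lightest choice.
- **Hosmer–Lemeshow**: deciles of predicted risk with tied quantile bins
  merged (degrees of freedom shrink accordingly),
  $\chi^2 = \sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$, $df = g - 2$.
- **Decision curves**: net benefit
  $TP/n - (FP/n)\,p_t/(1-p_t)$ on the grid $p_t = 0.01..0.99$ step 0.01,
  against treat-all and treat-none; no smoothing. For label-independent
  scores the expected excess over the better default strategy is zero —
  individual draws exceed it by $O(n^{-1/2})$, which is why the property
  test runs at large $n$.
- **Cohort comparisons**: Pearson chi-squared *without* continuity
  correction for categorical variables — this is the variant that
  reproduces the published training/testing comparison p-values to three
  decimals, including rows with expected cell counts below 5, where the
  small-count condition is surfaced as a warning rather than an automatic
  switch to Fisher's exact test (available by flag). Continuous variables
  use the two-sided Mann–Whitney U with normal approximation and tie
  correction.

## Segmentation agreement

Dice is the plain overlap ratio $2|A\cap B|/(|A|+|B|)$ on same-grid binary
masks (raw arrays or NIfTI via `RNifti`; no resampling); two empty masks
return 1 with a warning. ICC is fixed to the two-way random-effects,
absolute-agreement, single-rater form ICC(2,1) with $F = MSR/MSE$ on
$(n-1, (n-1)(k-1))$ degrees of freedom and the Shrout–Fleiss
F-distribution confidence bounds — the F statistics reported alongside
published radiomics reproducibility tables are consistent with this
two-way decomposition, whereas one-way or consistency variants are not.
Absolute agreement is invariant to a *shared* affine rescaling of both
readers but not to a single-reader shift, and both directions are asserted
in the tests.

## The synthetic cohort generator

`cohort_spec()` defaults encode the study conditions the pipeline is
designed for: $n = 130$ with the event count fixed at
$\mathrm{round}(0.4923 \cdot n) = 64$ (fixed by count, not Bernoulli
draws, so small-cohort tests are stable), 200 radiomics features in
equicorrelated Gaussian blocks of 10 with within-block correlation 0.8
(emulating the near-collinear feature families that motivate the PCC
filter), 5 informative features with standardized mean difference 1.0, and
two clinical covariates — a continuous wall-thickness-like Gaussian and a
4-level ordinal T-stage-like variable obtained by cutting a shifted latent
Gaussian at its null quantiles, each with half the radiomics effect by
default (the source material identifies wall thickness and T stage as
informative but quantifies neither; half the radiomics effect is a
deliberately modest choice).

What the generator does *not* emulate: non-Gaussian radiomics marginals,
scanner batch effects, heavy-tailed measurement noise, label noise, and
feature-feature interactions. Passing tests on these cohorts demonstrate
the pipeline's statistical mechanics (calibration under the null, recovery
of planted signal, leakage-freedom, determinism) — not clinical
performance on real CT radiomics, which requires external data.

`generate_mask_pair()` produces an ellipsoid mask and a boundary-jittered
copy (center and radii perturbed by seeded Gaussian noise) whose expected
Dice decreases with the jitter magnitude, as fixtures for the agreement
metrics.

## Numerical and serialization choices

- All randomness funnels through explicit integer seeds
  (`withr::with_seed`), so whole-pipeline outputs are pure functions of
  (data, config, seed); two fits with the same seed serialize
  byte-identically.
- Model and config JSON are written with 17 significant digits, the
  minimum that round-trips IEEE doubles exactly; the round-trip equality
  of predictions is asserted in tests. Model files carry an explicit
  `format_version` and refuse to load under a mismatch.
- The default pair classifier serializes as its explicit parameters
  (priors, per-class means and variances); other families embed a
  serialized payload.
- Degenerate inputs: constant features normalize to zero and are flagged;
  a constant feature has Relief weight 0 and ANOVA F of 0 (or infinity if
  it separates the classes exactly, ranking it first); correlation with a
  constant feature is treated as 0 in the PCC filter; PPV/NPV are reported
  missing (not 0) when no positive/negative calls exist.

## Problem sizes in the test suite

The stochastic properties are checked at sizes chosen to make the checks
sharp but quick: null calibration and planted-signal recovery over 20
seeds at the default cohort ($130 \times 202$), effect-size validation at
$n = 2000$, DCA null behavior at $n = 20000$, ICC noise behavior at
$n = 200$. The voting rule is verified exhaustively against a brute-force
implementation over all template-label patterns with 2–4 templates and
probability grids of step 0.25.

## Known limitations

- Binary outcomes only; no survival-time modeling of recurrence.
- Features are treated as continuous; categorical clinical variables must
  be pre-encoded, and the encoding affects screening.
- The pairwise construction multiplies training rows by $T$, so pair rows
  are not independent; internal CV metrics are honest at the sample level
  (folds are split by sample before pairing) but pair-level classifier
  diagnostics would be optimistic.
- `knn` and kernel-based families scale quadratically in pairs; they are
  practical at these cohort sizes but not for $n$ in the thousands.
- Dice requires same-grid masks; no resampling or surface-distance metrics.
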