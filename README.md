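# pairNB

Pairwise naive-Bayes classification for small-sample radiomics cohorts.

## The problem

Predicting a binary clinical outcome — here, locoregional recurrence (LR)
after radical radiotherapy in elderly esophageal squamous cell carcinoma
patients — from a feature table of CT radiomics features plus a handful of
clinical covariates is hard at typical cohort sizes (n ≈ 130): the feature
space is large and highly collinear, the classes are nearly balanced but
small, and plain classifiers trained directly on sample vectors generalize
poorly.

`pairNB` implements a template-based *pairwise* (metric-learning) approach
for this regime. Instead of classifying samples directly, a small set of
representative labeled **templates** is chosen, every sample is paired with
every template, and a classifier operates on the pair difference vectors:

- **Pair vectors.** For template *I* with feature vector *M<sub>I</sub>* and
  sample *i* with feature vector *N<sub>i</sub>*, the pair vector is the
  signed difference *V<sub>I,i</sub> = M<sub>I</sub> − N<sub>i</sub>*. A
  pair is **positive** when template and sample share the outcome class,
  **negative** otherwise.
- **Pair classifier.** A Gaussian naive Bayes model (by default; nine other
  standard families are available) is trained to output the positive-pair
  probability *P<sub>PP</sub>* for each pair vector.
- **Voting.** For a new sample, each template contributes the evidence
  *s<sub>I</sub> = P<sub>PP,I</sub>* if its label is 1 and
  *s<sub>I</sub> = 1 − P<sub>PP,I</sub>* if its label is 0; the sample-level
  probability is the average *P = (1/T) Σ<sub>I</sub> s<sub>I</sub>*, and the
  predicted class is 1 when *P ≥ 0.5*.

With T templates and n training samples this turns n labeled cases into
roughly T·n training pairs, which is what makes the approach attractive for
small cohorts.

Around this core the package provides the full model-selection pipeline
such a study needs: three normalization schemes (unit norm, zero-centering,
and their combination), Pearson-correlation and PCA dimensionality
reduction, ANOVA-F / Relief / RFE feature screening, stratified 7:3
splitting, stratified five-fold cross-validation with *everything* refitted
per fold, and a grid optimizer over all scheme combinations. Evaluation
covers ROC AUC with stratified bootstrap intervals, confusion metrics,
Hosmer–Lemeshow calibration, decision curve analysis, and Table-1-style
cohort baseline comparisons (chi-squared / Fisher / Mann–Whitney).
Inter-observer segmentation agreement is covered by Dice overlap on binary
masks (arrays or NIfTI) and ICC(2,1) on paired shape measures. A seeded
synthetic-cohort generator emulates the block-correlated radiomics
structure so every stage is testable without patient data.

## Worked example

```r
library(pairNB)

# a synthetic 130-patient cohort: 200 block-correlated radiomics features
# (5 informative), wall thickness and T stage as clinical covariates,
# 64 events (49.23% prevalence)
tab   <- generate_cohort(cohort_spec(seed = 42L))
split <- split_cohort(tab, ratio = 0.7, seed = 42L)   # 91 train / 39 test

model <- fit_pipeline(split$train, config = pipeline_config(seed = 42L))
model
#> trained_pairwise_model: gaussian_nb pair classifier, 12 features, 7 templates
#> features: rad_003, rad_004, rad_005, rad_001, rad_002, wall_thickness, ...

pred <- predict(model, split$test)
head(pred, 3)
#>   sample_id      prob class
#> 1      s001 0.5073837     1
#> 2      s003 0.5925139     1
#> 3      s008 0.6404651     1

evaluate_predictions(pred$prob, split$test$labels, seed = 42L)
#> n = 39, threshold = 0.5
#> AUC 0.661 (0.482-0.826)
#> accuracy 0.615  sensitivity 0.684  specificity 0.550
#> PPV 0.591  NPV 0.647
#> TP 13  FP 9  TN 11  FN 6

cv <- crossvalidate(split$train, config = pipeline_config(seed = 42L))
cv$mean_validation_auc
#> [1] 0.720
```

The fitted pipeline found all five planted informative radiomics features
plus the wall-thickness covariate among its twelve inputs; the test AUC of
0.66 on 39 held-out samples is one seed's draw from the distribution the
acceptance script characterizes (mean ≈ 0.77 across 20 seeds at these
settings).

A command-line interface wraps the same operations:

```sh
./exec/pairnb simulate --out run/sim --seed 42
./exec/pairnb split    --input run/sim/cohort.csv --out run/split --seed 42
./exec/pairnb train    --input run/split/train.csv --out run/model --seed 42
./exec/pairnb predict  --input run/split/test.csv --model run/model/model.json --out run/pred
./exec/pairnb evaluate --pred run/pred/predictions.csv --out run/eval
```

Every subcommand writes a `manifest.json` (config snapshot, seed, input
hashes) sufficient to re-execute the run exactly.

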