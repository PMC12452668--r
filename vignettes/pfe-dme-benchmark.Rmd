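---
title: "Paraconsistent feature engineering for DME screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paraconsistent feature engineering for DME screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfedme)
```

## The problem

Diabetic macular edema (DME) — retinal thickening with intraretinal fluid at
the macula — is a leading cause of vision loss in working-age adults.
Optical coherence tomography (OCT) reduces each examination to a small panel
of quantitative features: the nine ETDRS macular-grid sector thicknesses
(µm) and sector volumes (mm³), the fovea minima, the total macular volume,
visual acuity, plus age, sex and eye laterality.  `pfedme` implements a
screening pipeline over this 24-feature tabular panel: a paraconsistent
filter ranks the features by diagnostic evidence, and a benchmark harness
compares four classifier families on the full panel versus the selected
subset, in a binary (DME yes/no) and a six-phenotype scenario (Y, Y-Mer,
Y-Perifoveal, N, N-Anomalies, N-Mer, where "Mer" marks an epiretinal
membrane).

## Paraconsistent feature scoring

Each feature receives two bounded degrees of evidence:

* **α (intraclass similarity)** — how concentrated the feature's values are
  within each diagnostic class;
* **β (interclass overlap)** — how much the classes' value ranges overlap
  one another.

These combine into the **degree of certainty** $G_1 = \alpha - \beta$ and
the **degree of contradiction** $G_2 = \alpha + \beta - 1$, placing each
feature on the paraconsistent plane.  The ideal discriminative feature sits
at $(G_1, G_2) = (1, 0)$: perfectly homogeneous within each class
($\alpha = 1$) and with disjoint class ranges ($\beta = 0$).  A constant
feature sits at $(0, 1)$ — full intraclass agreement *and* full interclass
overlap, i.e. pure contradiction.  Features are ranked by Euclidean distance
to $(1, 0)$ and the top-$k$ (default $k = 4$) form the reduced panel.

### The α/β estimator

Verbal definitions of α and β admit many estimators; the package fixes one
and documents the choice:

1. each feature is min–max normalized to $[0, 1]$ over *all* samples, so
   widths and overlaps are comparable across µm, mm³ and years
   (`normalize_feature()`; a constant feature maps to 0.5 so that its
   degrees are defined, not dropped);
2. each class is summarized by its 10th–90th percentile interval
   (`class_interval()`, type-7 linear interpolation).  The trimmed interval
   — rather than the range — keeps both degrees robust to the outliers
   routine in clinical measurements; percentile bounds are tunable
   (`p_lo`, `p_hi`);
3. $\alpha = 1 - \text{mean interval width}$ across classes; $\alpha = 1$
   exactly when every class interval has zero width;
4. $\beta$ = mean Jaccard overlap $|I \cap I'| / |I \cup I'|$ over unordered
   class pairs; zero-width intervals overlap fully at the same point and
   not at all at distinct points, and $\beta = 0$ exactly when all pairs
   are disjoint.

One wording ambiguity deserves a flag: β is sometimes described as
interclass *dissimilarity*, yet maximizing $G_1 = \alpha - \beta$ requires
**small** β at the ideal point, which is described as "perfectly distinct
between classes".  The two statements conflict; the package resolves it by
implementing β as *overlap* (small when classes are distinct), which is the
only direction consistent with the ideal point $(1, 0)$.  An alternative
coefficient-of-variation α (`alpha_method = "cv"`,
$\alpha = 1 - \min(1, \text{mean within-class CV})$) is provided for
sensitivity analysis.

Ties in the distance ranking are broken lexicographically by feature name,
so rankings are deterministic.  Empty classes are an error, never silently
skipped.

## The benchmark harness

Sixteen tests — {LR, SVM, KNN, DTREE} × {all 24 features, top-4 PFE} ×
{binary, multiclass} — run under one split specification.  Model families
use their ecosystem defaults, recorded verbatim in every report:
unpenalized logistic regression (`stats::glm`; `nnet::multinom` for six
classes), RBF-kernel SVM at cost 1 (`e1071::svm`), $k = 5$ nearest
neighbours on train-standardized features (`caret::knn3`, which returns the
per-class probability matrix the ROC analysis needs), and an unpruned
decision tree (`rpart`, `cp = 0`, unlimited effective depth).  No
hyperparameter search and no class reweighting are performed: the point of
the harness is comparison under like-for-like defaults, not leaderboard
accuracy.

**Splits.**  The default is a stratified 20% holdout with seed 42: on the
700-exam study composition this yields exactly the 26 positive / 114
negative test exams that a published 140-case test split implies.  K-fold
cross-validation (`split_spec("kfold")`) is also provided — published
descriptions mention both a train/test split and cross-validation without
reconciling them, so both modes exist; k-fold reports pool out-of-fold
predictions so each exam is tested exactly once.

**Selection leakage.**  With the PFE feature set, ranking is recomputed on
the training rows of each split (`pfe_mode = "train_only"`, the default),
so selection never sees test labels.  A `"full"` mode scores the whole
table once — the apparent workflow of whole-dataset filter selection —
and exists for descriptive replication only.  A canary test plants signal
confined to the test rows and verifies that train-only selection cannot
find it while full-table selection does.

## Metrics

All reported metrics are implemented from first principles in the package
(`confusion_matrix()`, `binary_metrics()`, `multiclass_metrics()`,
`roc_auc()`, `micro_average_auc()`): sensitivity TP/(TP+FN), specificity
TN/(TN+FP), PPV, NPV, per-class F1, accuracy, and the classification score
(count of correct test cases, the confusion-matrix trace).  The AUC uses
the rank-sum (Mann–Whitney) identity with midranks, so ties count half;
the multiclass AUC pools all (sample, class) one-vs-rest decisions into one
binary problem (micro-average).  Percentages are rounded half-up to
integers (one decimal for AUC), the precision diagnostic tables are
printed at.  Ratios with empty denominators are returned as `NA` and
listed in an `undefined` field — they are never coerced to 0 or 1.
Published binary tables in this domain sometimes interchange
sensitivity/PPV and specificity/NPV relative to these standard definitions;
the package always uses the standard ones, so compare against the
internally consistent cells (accuracy, classification score, F1) when
cross-reading such tables.  For six-class reports both macro one-vs-rest
averages and per-class values are emitted, since a single printed
sensitivity for six classes is ambiguous.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` emulates
the study conditions instead:

* 700 examinations, six phenotypes, 131 positive / 569 negative in binary
  collapse (`multiclass_class_counts()`; per-phenotype counts are
  documented conventions, as published cohorts rarely print them);
* ages 23–91 (truncated normal, mean 62.5, SD 13), 55.3% male, balanced
  eye laterality;
* numeric features from truncated normal distributions (truncated at 0 —
  thicknesses and volumes are strictly positive) around physiologic
  baselines: central subfield ≈250 µm, inner ring ≈320 µm, outer ring
  ≈280 µm, total volume ≈8.7 mm³;
* positive phenotypes carry the edema signature — central thickening
  (+150 µm central subfield), volume gain, reduced visual acuity — with a
  3× wider spread on thickness/volume features, because edema severity is
  heterogeneous between eyes; Y-Mer adds diffuse traction thickening,
  Y-Perifoveal concentrates edema in the inner ring, N-Mer is a uniform
  thickness offset without the fluid signature, N-Anomalies a mild
  outer-ring irregularity;
* visual acuity lives on the decimal scale in (0, 1.2] and is negatively
  correlated (default ρ = 0.5, configurable) with central thickness in
  positive phenotypes;
* exams are independent rows by default; `patient_ids = TRUE` optionally
  pairs eyes under a shared patient id.

Alternatively, `effect_sizes` plants pure standardized contrasts: each
named feature is shifted by Cohen's $d \times$ SD in the positive classes
and **all other features carry no class contrast**.  This is the mode for
controlled experiments — planted-effect recovery, permutation nulls — and
its parameters (d = 2, n = 700, the study composition) are the conditions
the selection-recovery and null-calibration guarantees are stated under.

What the generator does **not** emulate: measurement error correlated
across ETDRS sectors (real sector thicknesses are strongly spatially
correlated), device- and operator-level batch effects, repeated exams of
the same eye over time, and the label noise of clinical adjudication.
Passing tests on synthetic cohorts therefore certify the *machinery* —
selection recovers planted signal, the harness is leakage-free and
calibrated under the null, metrics match their definitions — not clinical
performance on any real population, and synthetic cohorts are more
separable than the clinical cohorts that motivated the pipeline.

## Numerical and design choices

* Percentile defaults 10/90; type-7 interpolation (the `quantile` default).
* Constant features score (α, β) = (1, 1), i.e. maximal contradiction,
  rather than being undefined or silently dropped.
* Degenerate splits (a class absent from training) are an error, not a
  warning.
* Stratified holdout keeps at least one exam of every class on each side
  of the split.
* Model-internal randomness (the SVM's probability-calibration folds) is
  seeded per fold from the split seed, so every report is a deterministic
  function of (data, split specification).
* Preprocessing mirrors tabular clinical practice: rows with any null are
  removed and counted, and categorical columns are integer-encoded by
  sorted category order (F→0, M→1; L→0, R→1).

## Problem sizes

The test suite and acceptance checks run at the study scale they make
claims about: selection recovery uses 100 cohorts of n = 700, the
permutation-null calibration 20 cohorts of n = 700, the AUC/oracle
equivalence 50 instances up to n = 500, and the 16-test grid a 280-exam
six-phenotype cohort.  The full suite completes in well under a minute on
a laptop-class single core.

## Known limitations

* α/β are interval summaries; features discriminative only in their tails
  or via interactions can rank poorly (an inherent property of univariate
  filter methods).
* The four selected features on any given cohort are data-dependent; the
  package makes no claim of reproducing a particular published selection,
  which requires the private cohort that produced it.
* Multiclass performance on small phenotypes (n ≈ 25) is noisy at a 20%
  holdout; prefer k-fold pooling there.
* Micro-average AUC weights every (sample, class) decision equally and so
  is dominated by prevalent classes; per-class AUCs are emitted alongside
  for that reason.
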