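# pfedme

Paraconsistent feature engineering (PFE) and a classifier benchmark for
tabular pre-diagnosis of **diabetic macular edema (DME)** from quantitative
OCT features.

DME screening from OCT reduces each examination to a 24-feature panel: the
nine ETDRS macular-grid sector thicknesses (µm) and nine sector volumes
(mm³), fovea minima, total macular volume, visual acuity, age, sex and eye
laterality. `pfedme` is for methodologists and clinical data scientists who
want a transparent, fully tested implementation of:

- **PFE feature ranking.** Every feature gets an intraclass-similarity
  degree α and an interclass-overlap degree β, mapped to the paraconsistent
  plane via the degree of certainty *G1 = α − β* and the degree of
  contradiction *G2 = α + β − 1*, and ranked by Euclidean distance to the
  ideal point (1, 0) — a feature homogeneous within classes and disjoint
  between them. The top-*k* (default 4) form the reduced panel.
- **A 16-test benchmark.** {logistic regression, SVM (RBF), KNN, decision
  tree} × {all 24 features, top-4 PFE} × {binary DME yes/no, six DME
  phenotypes}, under a stratified holdout (default) or k-fold
  cross-validation, with train-only feature selection so the ranking never
  sees test labels.
- **A first-principles metric suite.** Confusion matrix, accuracy,
  classification score, sensitivity, specificity, PPV, NPV, per-class F1,
  rank-sum (Mann–Whitney) ROC AUC with ties counted half, and micro-average
  one-vs-rest multiclass AUC. Undefined ratios are flagged `NA`, never
  coerced to 0.
- **A synthetic cohort generator** emulating the study conditions (700
  exams, 131 DME-positive / 569 negative, six phenotypes, ages 23–91) with
  configurable per-feature standardized effect sizes, so the whole pipeline
  is testable without patient data.

## Worked example

```r
library(pfedme)

cohort <- generate_cohort(cohort_config(seed = 1))   # 700 exams, 6 phenotypes
clean  <- preprocess(cohort)                         # null-row removal, encoding
scores <- pfe_scores(clean$table)                    # rank all 24 features
head(as.data.frame(scores), 5)
#>     feature alpha  beta    g1       g2 distance rank
#> 1  foveamin 0.774 0.221 0.554 -0.00467    0.446    1
#> 2  etdrs9_1 0.743 0.197 0.546 -0.05967    0.458    2
#> 3  etdrs9_4 0.718 0.215 0.503 -0.06770    0.502    3
#> 4 etdrs9v_1 0.704 0.211 0.493 -0.08517    0.515    4
#> 5  etdrs9_3 0.700 0.250 0.450 -0.05039    0.552    5

select_top_k(scores, 4)
#> [1] "foveamin"  "etdrs9_1"  "etdrs9_4"  "etdrs9v_1"
```

The central-macula features rank first: on this cohort the fovea minima has
the highest degree of certainty (G1 = 0.55) with near-zero contradiction —
its class intervals are tight and barely overlap — which is exactly the
edema signature the generator plants (central thickening with heterogeneous
severity).

```r
reports <- run_matrix(clean$table, split_spec(seed = 42))  # 16 tests
results_table(reports)[1:4, c("model", "features", "scenario",
                              "classification_score", "accuracy",
                              "f1_Y", "f1_N", "auc")]
#>   model  features scenario classification_score accuracy f1_Y f1_N   auc
#> 1    LR normal_24   binary                  135       96   90   98  93.6
#> 2   SVM normal_24   binary                  140      100  100  100 100.0
#> 3   KNN normal_24   binary                  129       92   73   95  92.3
#> 4 DTREE normal_24   binary                  137       98   94   99  97.2
```

Each row is one test evaluated on the stratified 140-exam holdout (26
positive, 114 negative): the classification score counts correct test
exams (the confusion-matrix trace), accuracy/F1 are percentages rounded
half-up, and `auc` is the positive-class ROC AUC (micro-average one-vs-rest
for the multiclass rows). Synthetic cohorts are cleaner than clinical data,
so absolute accuracies run high; the informative comparisons are *between*
rows — e.g. the four PFE-selected features retain most of the 24-feature
performance.

`full_run()` ties everything together and writes the artifact bundle
(PFE scores CSV, results table, per-test confusion matrices, paraconsistent
plane and ROC figures, JSON manifest), with the seed and a configuration
hash embedded in every filename:

```r
full_run(cohort_config(seed = 1), out_dir = "dme_run")
```

## Package layout

- `R/synthetic.R` — cohort configuration and generation, missingness
  injection
- `R/pfe.R` — normalization, class intervals, α/β, plane coordinates,
  ranking and selection
- `R/pipeline.R`, `R/models.R`, `R/run.R` — scenarios, splits,
  preprocessing, the four model families, the 16-test harness
- `R/metrics.R` — the diagnostic metric suite
- `R/io.R` — schema-validated CSV I/O, plots, `full_run()`
- `vignettes/pfe-dme-benchmark.Rmd` — methods, estimator choices, generator
  design, limitations
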