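# Fixtures are built in code; nothing is stored on disk.

# Pooled-SD Cohen's d between the binary collapse of the phenotype labels.
empirical_d <- function(table, feature) {
  pos <- startsWith(as.character(table$Diagnosis), "Y")
  y <- table[[feature]][pos]
  n <- table[[feature]][!pos]
  sp <- sqrt(((length(y) - 1) * var(y) + (length(n) - 1) * var(n)) /
               (length(y) + length(n) - 2))
  (mean(y) - mean(n)) / sp
}

# Cohort with a single planted standardized effect and no other contrast.
planted_cohort <- function(seed, d = 2, feature = "etdrs9_1", n = 700,
                           counts = binary_class_counts()) {
  generate_cohort(cohort_config(
    n_exams = n, class_counts = counts,
    effect_sizes = stats::setNames(d, feature), seed = seed))
}

# Small six-phenotype cohort (study composition scaled to 280 exams; classes
# stay large enough for stratified holdout and SVM probability fitting).
small_multiclass_cohort <- function(seed = 5) {
  generate_cohort(cohort_config(
    n_exams = 280,
    class_counts = c("Y" = 32L, "Y-Mer" = 12L, "Y-Perifoveal" = 10L,
                     "N" = 172L, "N-Anomalies" = 26L, "N-Mer" = 28L),
    seed = seed))
}

# O(n^2) pairwise AUC oracle: P(score_pos > score_neg), ties half.
pairwise_auc_oracle <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
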