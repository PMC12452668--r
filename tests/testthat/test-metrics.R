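fig2_cm <- function() {
  # 26 true positives: 17 called Y, 9 called N; 114 true negatives:
  # 112 called N, 2 called Y.
  truth <- c(rep("Y", 26), rep("N", 114))
  pred <- c(rep("Y", 17), rep("N", 9), rep("N", 112), rep("Y", 2))
  confusion_matrix(truth, pred, c("Y", "N"))
}

test_that("confusion matrix counts true-by-predicted cells", {
  cm <- fig2_cm()
  expect_identical(unname(cm), matrix(c(17L, 2L, 9L, 112L), 2))
  expect_equal(sum(cm), 140)

  perfect <- confusion_matrix(c("A", "B", "B"), c("A", "B", "B"), c("A", "B"))
  expect_identical(unname(perfect), matrix(c(1L, 0L, 0L, 2L), 2))

  expect_error(confusion_matrix(character(0), character(0), "A"), "empty")
  expect_error(confusion_matrix("A", "Z", c("A", "B")), "outside the class set")
  expect_error(confusion_matrix(c("A", "A"), "A", c("A")), "equal length")
})

test_that("binary metrics use standard definitions at table precision", {
  m <- binary_metrics(fig2_cm(), positive = "Y")
  expect_identical(m$classification_score, 129L)
  expect_equal(m$accuracy, 129 / 140)
  expect_equal(m$percent$accuracy, 92)
  expect_equal(m$f1[["Y"]], 34 / 45)
  expect_equal(m$f1[["N"]], 224 / 235)
  expect_equal(unname(m$percent$f1), c(76, 95))
  # standard definitions (sensitivity = TP / (TP + FN), etc.)
  expect_equal(m$sensitivity, 17 / 26)
  expect_equal(m$specificity, 112 / 114)
  expect_equal(m$ppv, 17 / 19)
  expect_equal(m$npv, 112 / 121)
  expect_length(m$undefined, 0)
})

test_that("zero-denominator ratios are NA-flagged, never coerced to 0", {
  cm <- matrix(c(0L, 0L, 0L, 5L), 2, byrow = TRUE,
               dimnames = list(c("Y", "N"), c("Y", "N")))
  m <- binary_metrics(cm)
  expect_true(is.na(m$sensitivity))
  expect_true("sensitivity" %in% m$undefined)
  expect_true("ppv" %in% m$undefined)   # no positive calls either
  expect_equal(m$specificity, 1)
  expect_error(binary_metrics(diag(3L)), "2x2")
})

test_that("multiclass one-vs-rest metrics are exact on a diagonal matrix", {
  cm <- diag(c(5L, 3L, 2L))
  dimnames(cm) <- list(c("A", "B", "C"), c("A", "B", "C"))
  m <- multiclass_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_identical(m$classification_score, 10L)
  expect_true(all(as.matrix(m$per_class[, -1]) == 1))
  expect_equal(unname(m$macro), rep(1, 5))
})

test_that("single-class truth flags specificity as undefined", {
  truth <- rep("Y", 8)
  pred <- c(rep("Y", 6), rep("N", 2))
  cm <- confusion_matrix(truth, pred, c("Y", "N"))
  m <- multiclass_metrics(cm)
  expect_true("Y:specificity" %in% m$undefined)
})

test_that("collapsing a multiclass matrix commutes with collapsing labels", {
  bin <- binary_scenario()
  set.seed(31)
  for (i in 1:10) {
    truth <- sample(phenotype_labels(), 120, replace = TRUE)
    pred <- sample(phenotype_labels(), 120, replace = TRUE)
    cm6 <- confusion_matrix(truth, pred, phenotype_labels())
    via_matrix <- collapse_confusion(cm6, bin$label_map, bin$class_set)
    via_labels <- confusion_matrix(bin$label_map[truth], bin$label_map[pred],
                                   bin$class_set)
    expect_identical(via_matrix, via_labels)
    expect_equal(binary_metrics(via_matrix)$f1, binary_metrics(via_labels)$f1)
  }
})

test_that("per-class F1 is invariant to class-order permutation", {
  set.seed(17)
  truth <- sample(c("A", "B", "C"), 90, replace = TRUE)
  pred <- sample(c("A", "B", "C"), 90, replace = TRUE)
  m1 <- multiclass_metrics(confusion_matrix(truth, pred, c("A", "B", "C")))
  m2 <- multiclass_metrics(confusion_matrix(truth, pred, c("C", "A", "B")))
  f1_1 <- setNames(m1$per_class$f1, m1$per_class$class)
  f1_2 <- setNames(m2$per_class$f1, m2$per_class$class)
  expect_equal(f1_1[c("A", "B", "C")], f1_2[c("A", "B", "C")])
})

test_that("rank-sum AUC honours perfect separation, ties and complement", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(4)
  for (i in 1:10) {
    s <- rnorm(60)
    y <- runif(60) < 0.4
    if (!any(y) || all(y)) next
    expect_equal(roc_auc(s, y) + roc_auc(s, !y), 1, tolerance = 1e-12)
  }
})

test_that("rank-sum AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- round(rnorm(200), 1)  # rounding forces ties
  y <- runif(200) < 0.3
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("the ROC curve integrates to the rank-sum AUC", {
  set.seed(13)
  s <- round(rnorm(150), 1)
  y <- runif(150) < 0.35
  cur <- roc_curve(s, y)
  trap <- sum(diff(cur$fpr) * (head(cur$tpr, -1) + tail(cur$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(s, y), tolerance = 1e-12)
  expect_equal(cur$fpr[1], 0)
  expect_equal(tail(cur$tpr, 1), 1)
})

test_that("micro-average AUC pools one-vs-rest decisions", {
  classes <- c("A", "B", "C")
  truth <- c("A", "B", "C", "A")
  onehot <- outer(truth, classes, `==`) * 1
  colnames(onehot) <- classes
  expect_equal(micro_average_auc(onehot, truth), 1)

  uniform <- matrix(1 / 3, 4, 3, dimnames = list(NULL, classes))
  expect_equal(micro_average_auc(uniform, truth), 0.5)

  # k = 2 with complementary scores is consistent with the binary AUC
  set.seed(2)
  p <- runif(40)
  y <- ifelse(runif(40) < 0.4, "Y", "N")
  if (length(unique(y)) == 2) {
    sm <- cbind(Y = p, N = 1 - p)
    expect_equal(micro_average_auc(sm, y), roc_auc(p, y, positive = "Y"),
                 tolerance = 0.1)
  }
})

test_that("percentage rounding is half-up at printed precision", {
  expect_equal(pfedme:::round_half_up(75.5), 76)
  expect_equal(pfedme:::round_half_up(76.5), 77)
  expect_equal(pfedme:::round_half_up(92.143), 92)
  expect_equal(pfedme:::round_half_up(81.75, 1), 81.8)
  expect_true(is.na(pfedme:::round_half_up(NA_real_)))
})
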