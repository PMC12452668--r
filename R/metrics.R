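#' Confusion matrix
#'
#' Counts `counts[i, j] = #(true == classes[i] & predicted == classes[j])`.
#' Rows are true classes, columns predicted classes, in the order given.
#'
#' @param truth,predicted Equal-length label vectors; every value must appear
#'   in `classes`.
#' @param classes Ordered class labels.
#' @return An integer matrix with `classes` as dimnames.
#' @export
confusion_matrix <- function(truth, predicted, classes) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0L) {
    stop(sprintf("label(s) outside the class set: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  tt <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  cm <- matrix(as.integer(tt), nrow = length(classes),
               dimnames = list(true = classes, predicted = classes))
  cm
}

# NA (flagged), never 0, when a metric's denominator is empty.
safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Diagnostic metrics for a binary confusion matrix
#'
#' Standard definitions with the DME-positive class as reference:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)`, per-class F1 `2TP_c/(2TP_c+FP_c+FN_c)`, accuracy
#' `(TP+TN)/n`.  The classification score is the count of correctly
#' classified test cases (the matrix trace).  Ratios with a zero denominator
#' are returned as `NA` and listed in `undefined` -- they are never coerced
#' to 0.  `percent` holds the same quantities rounded half-up to integer
#' percentages, the precision diagnostic tables are printed at.
#'
#' @param cm A 2x2 matrix from [confusion_matrix()].
#' @param positive Label of the positive (disease) class; must be one of the
#'   matrix classes.
#' @return A list of class `dme_binary_metrics`.
#' @examples
#' cm <- confusion_matrix(c("Y", "Y", "N"), c("Y", "N", "N"), c("Y", "N"))
#' binary_metrics(cm)$accuracy
#' @export
binary_metrics <- function(cm, positive = "Y") {
  if (!is.matrix(cm) || nrow(cm) != 2L || ncol(cm) != 2L) {
    stop("`cm` must be a 2x2 confusion matrix", call. = FALSE)
  }
  classes <- rownames(cm)
  if (!positive %in% classes) {
    stop(sprintf("positive class %s not in matrix classes", dQuote(positive)),
         call. = FALSE)
  }
  negative <- setdiff(classes, positive)
  tp <- cm[positive, positive]; fn <- cm[positive, negative]
  fp <- cm[negative, positive]; tn <- cm[negative, negative]
  n <- sum(cm)

  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  ppv  <- safe_ratio(tp, tp + fp)
  npv  <- safe_ratio(tn, tn + fn)
  f1 <- c(safe_ratio(2 * tp, 2 * tp + fp + fn),
          safe_ratio(2 * tn, 2 * tn + fn + fp))
  names(f1) <- c(positive, negative)
  acc <- (tp + tn) / n

  vals <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
            f1)
  undefined <- names(vals)[is.na(vals)]

  structure(list(
    classes = classes, positive = positive,
    tp = tp, fn = fn, fp = fp, tn = tn,
    classification_score = as.integer(tp + tn),
    n_test = as.integer(n),
    accuracy = acc,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1,
    undefined = undefined,
    percent = list(
      accuracy = round_half_up(100 * acc),
      sensitivity = round_half_up(100 * sens),
      specificity = round_half_up(100 * spec),
      ppv = round_half_up(100 * ppv),
      npv = round_half_up(100 * npv),
      f1 = round_half_up(100 * f1)
    )
  ), class = "dme_binary_metrics")
}

#' One-vs-rest metrics for a multiclass confusion matrix
#'
#' Each class is scored against the rest (its TP is the diagonal cell; FP,
#' FN, TN follow from the margins), giving per-class sensitivity,
#' specificity, PPV, NPV and F1 plus their macro (unweighted) averages.
#' Undefined per-class ratios are `NA`-flagged and excluded from the macro
#' mean, with the affected class/metric pairs listed in `undefined`.
#'
#' @param cm A k x k matrix from [confusion_matrix()], k >= 2.
#' @return A list of class `dme_multiclass_metrics` with a `per_class` data
#'   frame and `macro` named vector.
#' @export
multiclass_metrics <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || nrow(cm) < 2L) {
    stop("`cm` must be a square confusion matrix with k >= 2", call. = FALSE)
  }
  classes <- rownames(cm)
  n <- sum(cm)
  per <- do.call(rbind, lapply(classes, function(cls) {
    tp <- cm[cls, cls]
    fn <- sum(cm[cls, ]) - tp
    fp <- sum(cm[, cls]) - tp
    tn <- n - tp - fn - fp
    data.frame(
      class = cls,
      sensitivity = safe_ratio(tp, tp + fn),
      specificity = safe_ratio(tn, tn + fp),
      ppv = safe_ratio(tp, tp + fp),
      npv = safe_ratio(tn, tn + fn),
      f1 = safe_ratio(2 * tp, 2 * tp + fp + fn)
    )
  }))
  rownames(per) <- NULL
  metric_cols <- c("sensitivity", "specificity", "ppv", "npv", "f1")
  undef <- which(is.na(as.matrix(per[metric_cols])), arr.ind = TRUE)
  undefined <- if (nrow(undef) > 0L) {
    paste(per$class[undef[, 1]], metric_cols[undef[, 2]], sep = ":")
  } else character(0)
  macro <- vapply(per[metric_cols], mean, numeric(1), na.rm = TRUE)
  structure(list(
    classes = classes,
    classification_score = as.integer(sum(diag(cm))),
    n_test = as.integer(n),
    accuracy = sum(diag(cm)) / n,
    per_class = per,
    macro = macro,
    undefined = undefined,
    percent = list(
      accuracy = round_half_up(100 * sum(diag(cm)) / n, 1),
      macro = round_half_up(100 * macro),
      f1 = stats::setNames(round_half_up(100 * per$f1), per$class)
    )
  ), class = "dme_multiclass_metrics")
}

#' Collapse a multiclass confusion matrix by a label map
#'
#' Sums rows and columns of `cm` over groups of source classes that map to
#' the same target class.  Collapsing the matrix commutes with collapsing
#' the label vectors themselves.
#'
#' @param cm A confusion matrix whose classes are all named in `label_map`.
#' @param label_map Named character vector, source class -> target class.
#' @param class_set Ordered target classes (default: unique map values).
#' @return The collapsed confusion matrix.
#' @export
collapse_confusion <- function(cm, label_map, class_set = unique(label_map)) {
  src <- rownames(cm)
  if (any(!src %in% names(label_map))) {
    stop("every matrix class must appear in `label_map`", call. = FALSE)
  }
  grp <- factor(label_map[src], levels = class_set)
  out <- matrix(0L, length(class_set), length(class_set),
                dimnames = list(true = class_set, predicted = class_set))
  for (i in seq_along(src)) {
    for (j in seq_along(src)) {
      out[grp[i], grp[j]] <- out[grp[i], grp[j]] + cm[i, j]
    }
  }
  out
}

#' Rank-sum ROC AUC
#'
#' The area under the ROC curve computed by the rank-sum (Mann-Whitney)
#' identity: the probability that a random positive case outscores a random
#' negative one, with ties counted half.  Equivalent to the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param truth Binary truth: logical, or a vector with `positive` naming
#'   the positive label.
#' @param positive Positive label when `truth` is not logical.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_auc <- function(scores, truth, positive = "Y") {
  if (length(scores) != length(truth)) {
    stop("`scores` and `truth` must have equal length", call. = FALSE)
  }
  pos <- if (is.logical(truth)) truth else as.character(truth) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)  # midranks: ties counted half
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Points of the empirical ROC curve (FPR, TPR) at every distinct score
#' threshold, descending, with the (0,0) and (1,1) endpoints.  The
#' trapezoidal area under this curve equals [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return A data frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, truth, positive = "Y") {
  pos <- if (is.logical(truth)) truth else as.character(truth) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Micro-average one-vs-rest multiclass AUC
#'
#' Pools every (sample, class) one-vs-rest decision -- `n * k` score/label
#' pairs, where the label is whether the sample truly belongs to that class
#' -- into a single binary problem and applies the rank-sum AUC.
#'
#' @param score_matrix `n x k` numeric matrix of per-class scores; columns
#'   must be named (or `classes` supplied) and cover the class set.
#' @param truth Length-`n` vector of true class labels.
#' @param classes Ordered class labels; defaults to the score columns.
#' @return AUC in \[0, 1\].
#' @export
micro_average_auc <- function(score_matrix, truth, classes = colnames(score_matrix)) {
  score_matrix <- as.matrix(score_matrix)
  if (is.null(classes) || length(classes) < 2L) {
    stop("need a score column per class, k >= 2", call. = FALSE)
  }
  if (nrow(score_matrix) != length(truth)) {
    stop("`score_matrix` rows must match `truth` length", call. = FALSE)
  }
  score_matrix <- score_matrix[, classes, drop = FALSE]
  truth <- as.character(truth)
  onehot <- outer(truth, classes, `==`)
  roc_auc(as.vector(score_matrix), as.vector(onehot))
}
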