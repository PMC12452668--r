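#' Run one benchmark test
#'
#' Trains the specified model family on the training rows and evaluates it on
#' the held-out rows (holdout) or on pooled out-of-fold predictions (k-fold).
#' With `feature_set = "pfe_4"`, the paraconsistent ranking is by default
#' recomputed on the training portion only (`pfe_mode = "train_only"`), so
#' feature selection never sees test labels; `pfe_mode = "full"` scores the
#' whole table once, the apparent workflow of whole-dataset filter selection
#' (use for descriptive replication only -- it leaks selection information).
#'
#' @param spec A [test_spec()].
#' @param table A preprocessed feature table (see [preprocess()]): complete
#'   rows, categorical predictors encoded.
#' @param split A [split_spec()].
#' @param pfe_mode `"train_only"` (default) or `"full"`.
#' @return An `evaluation_report` list: confusion matrix, metric suite, AUC
#'   (binary: positive-class ROC; multiclass: micro-average one-vs-rest),
#'   selected features, hyperparameters, and the pooled test scores/truth for
#'   ROC plotting.
#' @examples
#' \donttest{
#' tab <- preprocess(generate_cohort(cohort_config(seed = 1)))$table
#' rep <- run_test(test_spec("LR", "normal_24"), tab)
#' rep$metrics$percent$accuracy
#' }
#' @export
run_test <- function(spec, table, split = split_spec(),
                     pfe_mode = c("train_only", "full")) {
  pfe_mode <- match.arg(pfe_mode)
  if (!inherits(spec, "test_spec")) {
    stop("`spec` must come from test_spec()", call. = FALSE)
  }
  targets <- make_targets(table, spec$scenario)
  predictors <- feature_columns()
  not_num <- predictors[!vapply(table[predictors], is.numeric, logical(1))]
  if (length(not_num) > 0L) {
    stop(sprintf("non-numeric predictor(s) %s: run preprocess() first",
                 paste(not_num, collapse = ", ")), call. = FALSE)
  }
  classes <- spec$scenario$class_set
  folds <- make_split(targets, split)

  full_selection <- NULL
  if (spec$feature_set == "pfe_4" && pfe_mode == "full") {
    sc <- pfe_scores(cbind(table[predictors], .target = targets),
                     label_col = ".target", exclude = character(0))
    full_selection <- select_top_k(sc, spec$k)
  }

  n <- nrow(table)
  pred_pool <- rep(NA_character_, n)
  score_pool <- matrix(NA_real_, n, length(classes),
                       dimnames = list(NULL, classes))
  selected <- vector("list", length(folds))

  for (i in seq_along(folds)) {
    tr <- folds[[i]]$train
    te <- folds[[i]]$test
    absent <- setdiff(classes, unique(as.character(targets[tr])))
    if (length(absent) > 0L) {
      stop(sprintf("degenerate split: class(es) %s absent from training",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    feats <- if (spec$feature_set == "normal_24") {
      predictors
    } else if (!is.null(full_selection)) {
      full_selection
    } else {
      sc <- pfe_scores(cbind(table[tr, predictors, drop = FALSE],
                             .target = targets[tr]),
                       label_col = ".target", exclude = character(0))
      select_top_k(sc, spec$k)
    }
    selected[[i]] <- feats
    set.seed(split$seed + i)  # model-internal randomness (e.g. SVM prob. CV)
    fp <- fit_predict(spec$model,
                      table[tr, feats, drop = FALSE], targets[tr],
                      table[te, feats, drop = FALSE], classes,
                      spec$hyperparameters)
    pred_pool[te] <- as.character(fp$pred)
    score_pool[te, ] <- fp$scores
  }

  tested <- !is.na(pred_pool)
  truth <- targets[tested]
  pred <- pred_pool[tested]
  scores <- score_pool[tested, , drop = FALSE]

  cm <- confusion_matrix(truth, pred, classes)
  metrics <- if (length(classes) == 2L) {
    binary_metrics(cm, positive = classes[1])
  } else {
    multiclass_metrics(cm)
  }
  auc <- if (length(classes) == 2L) {
    roc_auc(scores[, classes[1]], truth, positive = classes[1])
  } else {
    micro_average_auc(scores, truth, classes)
  }

  structure(list(
    id = paste(spec$model, spec$feature_set, spec$scenario$name, sep = "/"),
    model = spec$model,
    feature_set = spec$feature_set,
    scenario = spec$scenario$name,
    hyperparameters = spec$hyperparameters,
    split = split,
    pfe_mode = pfe_mode,
    selected_features = selected[[1]],
    n_predictors = length(selected[[1]]),
    n_test = length(truth),
    confusion = cm,
    metrics = metrics,
    auc = auc,
    auc_pct = round_half_up(100 * auc, 1),
    scores = scores,
    truth = as.character(truth)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s\n", x$id))
  cat(sprintf("  n_test = %d, predictors = %d (%s)\n", x$n_test,
              x$n_predictors, paste(x$selected_features, collapse = ", ")))
  cat(sprintf("  classification score = %d, accuracy = %.1f%%, AUC = %.1f%%\n",
              x$metrics$classification_score, 100 * x$metrics$accuracy,
              x$auc_pct))
  invisible(x)
}

#' Run the full 16-test benchmark matrix
#'
#' Enumerates the 4 model families x 2 feature sets x 2 scenarios grid (or a
#' subset) and runs every cell with the same split specification.
#'
#' @param table A preprocessed feature table.
#' @param split A [split_spec()].
#' @param models Model families to include.
#' @param feature_sets Feature sets to include.
#' @param scenarios List of [scenario_spec()] objects.
#' @param k PFE subset size.
#' @param pfe_mode Passed to [run_test()].
#' @return A named list of `evaluation_report`s keyed
#'   `model/feature_set/scenario`.
#' @seealso [results_table()]
#' @export
run_matrix <- function(table, split = split_spec(),
                       models = c("LR", "SVM", "KNN", "DTREE"),
                       feature_sets = c("normal_24", "pfe_4"),
                       scenarios = list(binary_scenario(),
                                        multiclass_scenario()),
                       k = 4, pfe_mode = "train_only") {
  reports <- list()
  for (scn in scenarios) {
    for (fs in feature_sets) {
      for (m in models) {
        rep <- run_test(test_spec(m, fs, scn, k = k), table, split,
                        pfe_mode = pfe_mode)
        reports[[rep$id]] <- rep
      }
    }
  }
  reports
}

#' Tidy benchmark results table
#'
#' One row per test in the layout of the printed benchmark tables:
#' classification score (correct test cases), accuracy, sensitivity,
#' specificity, PPV, NPV, per-class F1 for the headline Y and N classes, and
#' AUC.  Binary rows report positive-class metrics; multiclass rows report
#' macro one-vs-rest averages with Y/N F1 from the per-class table and the
#' micro-average AUC.
#'
#' @param reports A list of `evaluation_report`s from [run_matrix()].
#' @return A data frame with one row per report.
#' @export
results_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    m <- r$metrics
    if (inherits(m, "dme_binary_metrics")) {
      data.frame(
        model = r$model, features = r$feature_set, scenario = r$scenario,
        classification_score = m$classification_score,
        accuracy = m$percent$accuracy,
        sensitivity = m$percent$sensitivity,
        specificity = m$percent$specificity,
        ppv = m$percent$ppv, npv = m$percent$npv,
        f1_Y = unname(m$percent$f1["Y"]), f1_N = unname(m$percent$f1["N"]),
        auc = r$auc_pct, n_test = r$n_test
      )
    } else {
      data.frame(
        model = r$model, features = r$feature_set, scenario = r$scenario,
        classification_score = m$classification_score,
        accuracy = m$percent$accuracy,
        sensitivity = unname(m$percent$macro["sensitivity"]),
        specificity = unname(m$percent$macro["specificity"]),
        ppv = unname(m$percent$macro["ppv"]),
        npv = unname(m$percent$macro["npv"]),
        f1_Y = unname(m$percent$f1["Y"]), f1_N = unname(m$percent$f1["N"]),
        auc = r$auc_pct, n_test = r$n_test
      )
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
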