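#' Read and write the feature-table CSV
#'
#' The on-disk format is UTF-8, comma-separated, "." decimal CSV with a
#' header whose column names are exactly the schema abbreviations
#' ([table1_columns()]), including `R/L eye` and `whole/total`.
#'
#' `read_feature_csv()` validates the header and column types: a missing or
#' renamed column is an error naming it; a non-numeric value in a numeric
#' column is an error giving the row index; extra columns are rejected
#' unless `allow_extra = TRUE`; a header-only file is an empty-table error.
#'
#' @param path File path.
#' @param allow_extra Tolerate (and drop) columns beyond the schema.
#' @return A feature table `data.frame` in schema column order.
#' @export
read_feature_csv <- function(path, allow_extra = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  missing <- setdiff(table1_columns(), names(raw))
  if (length(missing) > 0L) {
    stop(sprintf("input is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(raw), table1_columns())
  if (length(extra) > 0L && !allow_extra) {
    stop(sprintf("unexpected column(s): %s (use allow_extra = TRUE to drop)",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  raw <- raw[, table1_columns(), drop = FALSE]
  if (nrow(raw) == 0L) stop("input file has a header but no rows", call. = FALSE)
  for (col in numeric_feature_columns()) {
    v <- raw[[col]]
    blank <- is.na(v) | v == ""
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!blank & is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric value %s in numeric column %s at row %d",
                   dQuote(v[bad[1]]), dQuote(col), bad[1]), call. = FALSE)
    }
    raw[[col]] <- num
  }
  for (col in c("ID", "R/L eye", "Sex", "Diagnosis")) {
    raw[[col]][!is.na(raw[[col]]) & raw[[col]] == ""] <- NA
  }
  raw
}

#' @rdname read_feature_csv
#' @param table A feature table to write.
#' @export
write_feature_csv <- function(table, path) {
  assert_schema(table)
  utils::write.csv(table[, table1_columns(), drop = FALSE], path,
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Paraconsistent plane plot
#'
#' Scatter of features at (G1, G2) -- degree of certainty on the horizontal
#' axis, degree of contradiction on the vertical -- with the unit square and
#' the ideal point (1, 0) annotated.  Features near (1, 0) are homogeneous
#' within classes and distinct between them.
#'
#' @param scores A [pfe_scores()] result.
#' @param label_top Annotate the `label_top` best-ranked features by name.
#' @return A ggplot object.
#' @export
plot_paraconsistent_plane <- function(scores, label_top = 4) {
  if (!inherits(scores, "pfe_scores")) {
    stop("`scores` must come from pfe_scores()", call. = FALSE)
  }
  top <- scores[scores$rank <= label_top, , drop = FALSE]
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$g1, y = .data$g2)) +
    ggplot2::annotate("rect", xmin = -1, xmax = 1, ymin = -1, ymax = 1,
                      fill = NA, colour = "grey60", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::annotate("point", x = 1, y = 0, shape = 4, size = 3,
                      colour = "red") +
    ggplot2::annotate("text", x = 1, y = -0.08, label = "ideal (1, 0)",
                      colour = "red", size = 3) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$feature),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_equal(xlim = c(-1.05, 1.15), ylim = c(-1.05, 1.05)) +
    ggplot2::labs(x = "G1 (degree of certainty)",
                  y = "G2 (degree of contradiction)",
                  title = "Paraconsistent plane") +
    ggplot2::theme_minimal()
}

#' ROC curve plot for an evaluation report
#'
#' Binary reports get the positive-class ROC trace; multiclass reports get
#' one one-vs-rest trace per class plus the pooled micro-average trace, each
#' labelled with its AUC.
#'
#' @param report An `evaluation_report` from [run_test()].
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(report) {
  if (!inherits(report, "evaluation_report")) {
    stop("`report` must come from run_test()", call. = FALSE)
  }
  classes <- colnames(report$scores)
  curves <- list()
  if (length(classes) == 2L) {
    pos <- classes[1]
    cur <- roc_curve(report$scores[, pos], report$truth, positive = pos)
    cur$trace <- sprintf("%s (AUC %.1f%%)", pos, report$auc_pct)
    curves[[1]] <- cur
  } else {
    for (cls in classes) {
      truth_c <- report$truth == cls
      if (!any(truth_c) || all(truth_c)) next
      auc_c <- roc_auc(report$scores[, cls], truth_c)
      cur <- roc_curve(report$scores[, cls], truth_c)
      cur$trace <- sprintf("%s (AUC %.2f)", cls, auc_c)
      curves[[length(curves) + 1L]] <- cur
    }
    onehot <- as.vector(outer(report$truth, classes, `==`))
    cur <- roc_curve(as.vector(report$scores), onehot)
    cur$trace <- sprintf("micro-average (AUC %.1f%%)", report$auc_pct)
    curves[[length(curves) + 1L]] <- cur
  }
  dat <- do.call(rbind, curves)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$trace)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  colour = NULL, title = report$id) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' End-to-end pipeline run
#'
#' Ties the stages together: obtain a feature table (from a CSV path or by
#' generating a synthetic cohort), preprocess, score all candidate features
#' on the paraconsistent plane, run the benchmark matrix, and write the
#' artifact bundle to `out_dir`: the PFE scores CSV, the tidy results table,
#' per-test confusion matrices, plane and ROC figures (optional), and a
#' machine-readable JSON manifest (configuration, seed, config hash, package
#' version, null-drop count, test ids).  Output filenames embed the seed and
#' an 8-character configuration hash.
#'
#' @param input A CSV path, a [cohort_config()], or a feature-table data
#'   frame.
#' @param out_dir Output directory (created if needed).
#' @param split A [split_spec()]; its seed governs split and model
#'   randomness.
#' @param models,feature_sets,scenarios,k,pfe_mode Passed to [run_matrix()].
#' @param make_plots Write PNG figures (plane + one ROC per scenario's
#'   best-AUC test).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `reports`, `results`, `scores`, `manifest`,
#'   and the written `paths`.
#' @export
full_run <- function(input = cohort_config(), out_dir,
                     split = split_spec(),
                     models = c("LR", "SVM", "KNN", "DTREE"),
                     feature_sets = c("normal_24", "pfe_4"),
                     scenarios = list(binary_scenario(),
                                      multiclass_scenario()),
                     k = 4, pfe_mode = "train_only",
                     make_plots = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  table <- stage("input", {
    if (is.character(input)) {
      say("reading %s", input)
      read_feature_csv(input)
    } else if (inherits(input, "cohort_config")) {
      say("generating synthetic cohort (n = %d, seed = %d)",
          input$n_exams, input$seed)
      generate_cohort(input)
    } else if (is.data.frame(input)) {
      assert_schema(input)
    } else {
      stop("`input` must be a path, cohort_config, or data frame")
    }
  })
  cfg_hash <- substr(rlang::hash(list(input = if (is.data.frame(input))
    "data" else input, split = split, models = models,
    feature_sets = feature_sets, k = k, pfe_mode = pfe_mode)), 1, 8)
  tag <- sprintf("seed%d_%s", split$seed, cfg_hash)

  pre <- stage("preprocess", preprocess(table))
  say("preprocess: dropped %d null row(s), %d remain", pre$dropped,
      nrow(pre$table))

  scores <- stage("pfe", pfe_scores(pre$table))
  reports <- stage("benchmark",
                   run_matrix(pre$table, split, models, feature_sets,
                              scenarios, k, pfe_mode))
  results <- results_table(reports)

  paths <- list()
  paths$scores <- file.path(out_dir, sprintf("pfe_scores_%s.csv", tag))
  utils::write.csv(scores, paths$scores, row.names = FALSE)
  paths$results <- file.path(out_dir, sprintf("results_%s.csv", tag))
  utils::write.csv(results, paths$results, row.names = FALSE)
  for (id in names(reports)) {
    fn <- file.path(out_dir, sprintf("confusion_%s_%s.csv",
                                     gsub("/", "-", id), tag))
    utils::write.csv(as.data.frame(reports[[id]]$confusion), fn)
    paths$confusion <- c(paths$confusion, fn)
  }
  if (make_plots) {
    paths$plane <- file.path(out_dir, sprintf("paraconsistent_plane_%s.png", tag))
    ggplot2::ggsave(paths$plane, plot_paraconsistent_plane(scores),
                    width = 6, height = 5, dpi = 150)
    for (scn in unique(results$scenario)) {
      sub <- results[results$scenario == scn, ]
      best <- reports[[with(sub, paste(model[which.max(auc)],
                                       features[which.max(auc)], scn,
                                       sep = "/"))]]
      fn <- file.path(out_dir, sprintf("roc_%s_%s.png", scn, tag))
      ggplot2::ggsave(fn, plot_roc_curves(best), width = 6, height = 6,
                      dpi = 150)
      paths$roc <- c(paths$roc, fn)
    }
  }

  manifest <- list(
    seed = split$seed,
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("pfedme")),
    n_input_rows = nrow(table),
    dropped_null_rows = pre$dropped,
    n_rows_used = nrow(pre$table),
    encodings = pre$encodings,
    split = split[c("mode", "test_fraction", "n_folds", "stratified", "seed")],
    k = k,
    pfe_mode = pfe_mode,
    selected_top_k = select_top_k(scores, k),
    tests = names(reports),
    n_tests = length(reports),
    artifacts = unname(unlist(paths))
  )
  paths$manifest <- file.path(out_dir, sprintf("manifest_%s.json", tag))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  say("wrote %d artifact(s) to %s", length(unlist(paths)), out_dir)
  invisible(list(reports = reports, results = results, scores = scores,
                 manifest = manifest, paths = paths))
}
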