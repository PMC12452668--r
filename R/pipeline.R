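#' Diagnostic scenarios
#'
#' A scenario maps the raw phenotype label to the classification target.
#' `binary_scenario()` collapses the six phenotypes to DME presence
#' (`Y`, `Y-Mer`, `Y-Perifoveal` -> `Y`; `N`, `N-Anomalies`, `N-Mer` -> `N`).
#' `multiclass_scenario()` keeps all six phenotypes.
#'
#' @param label_map Named character vector, raw diagnosis -> target class.
#' @param class_set Ordered target classes (2 for binary, 6 for multiclass).
#' @param name Scenario name.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(name, label_map, class_set) {
  if (!all(label_map %in% class_set)) {
    stop("`label_map` values must lie in `class_set`", call. = FALSE)
  }
  structure(list(name = name, label_map = label_map, class_set = class_set),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @export
binary_scenario <- function() {
  labs <- phenotype_labels()
  scenario_spec("binary",
                stats::setNames(ifelse(is_positive_label(labs), "Y", "N"),
                                labs),
                c("Y", "N"))
}

#' @rdname scenario_spec
#' @export
multiclass_scenario <- function() {
  labs <- phenotype_labels()
  scenario_spec("multiclass", stats::setNames(labs, labs), labs)
}

#' Train/test split specification
#'
#' @param mode `"holdout"` (default: stratified 20% test split, mirroring the
#'   140-exam test set implied by the benchmark's classification scores) or
#'   `"kfold"` cross-validation with pooled out-of-fold predictions.
#' @param test_fraction Holdout test fraction in (0, 1).
#' @param n_folds Number of folds, >= 2.
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed controlling the split and model fits.
#' @return A `split_spec` list.
#' @export
split_spec <- function(mode = c("holdout", "kfold"), test_fraction = 0.2,
                       n_folds = 5, stratified = TRUE, seed = 42L) {
  mode <- match.arg(mode)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (n_folds < 2) stop("`n_folds` must be at least 2", call. = FALSE)
  structure(list(mode = mode, test_fraction = test_fraction,
                 n_folds = as.integer(n_folds), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Compute split indices
#'
#' Deterministic given `split$seed`.  For holdout, returns one
#' `list(train, test)` pair; for k-fold, a list of such pairs (each sample in
#' exactly one test fold).  Stratified splits sample within each class.
#'
#' @param labels Target label vector.
#' @param split A [split_spec()].
#' @return A list of `list(train, test)` index pairs.
#' @export
make_split <- function(labels, split = split_spec()) {
  n <- length(labels)
  set.seed(split$seed)
  strata <- if (split$stratified) as.character(labels) else rep("all", n)
  # sample() treats a length-1 integer as 1:n; index explicitly
  resample <- function(x) x[sample.int(length(x))]
  if (split$mode == "holdout") {
    test_idx <- unlist(lapply(split(seq_len(n), strata), function(idx) {
      n_test <- round(split$test_fraction * length(idx))
      n_test <- max(1L, min(length(idx) - 1L, n_test))
      resample(idx)[seq_len(n_test)]
    }), use.names = FALSE)
    list(list(train = sort(setdiff(seq_len(n), test_idx)),
              test = sort(test_idx)))
  } else {
    fold_of <- integer(n)
    for (idx in split(seq_len(n), strata)) {
      fold_of[resample(idx)] <- rep_len(seq_len(split$n_folds), length(idx))
    }
    lapply(seq_len(split$n_folds), function(f) {
      list(train = which(fold_of != f), test = which(fold_of == f))
    })
  }
}

#' Preprocess a feature table
#'
#' Mirrors the study's preprocessing: rows containing any null are removed
#' and counted, and the categorical columns (eye laterality, sex) are
#' integer-encoded by sorted category order (label-encoder convention, codes
#' from 0: `F -> 0, M -> 1`; `L -> 0, R -> 1`).  The diagnosis column is kept
#' as the raw label -- scenarios encode it -- but its code map is included in
#' the encoding report for completeness.
#'
#' @param table A feature table with the [table1_columns()] schema.
#' @return A list with `table` (encoded, complete rows), `encodings` (named
#'   list of code maps, for inversion), and `dropped` (count of removed
#'   rows).
#' @export
preprocess <- function(table) {
  assert_schema(table)
  complete <- stats::complete.cases(table)
  dropped <- sum(!complete)
  table <- table[complete, , drop = FALSE]
  if (nrow(table) == 0L) {
    stop("no complete rows remain after null removal", call. = FALSE)
  }
  rownames(table) <- NULL
  encodings <- list()
  for (col in c("R/L eye", "Sex")) {
    lv <- sort(unique(as.character(table[[col]])))
    code <- stats::setNames(seq_along(lv) - 1L, lv)
    encodings[[col]] <- code
    table[[col]] <- unname(code[as.character(table[[col]])])
  }
  diag_lv <- sort(unique(as.character(table[["Diagnosis"]])))
  encodings[["Diagnosis"]] <- stats::setNames(seq_along(diag_lv) - 1L, diag_lv)
  list(table = table, encodings = encodings, dropped = dropped)
}

#' Map raw diagnoses to scenario targets
#'
#' @param table A feature table (raw or preprocessed).
#' @param scenario A [scenario_spec()].
#' @return A factor over `scenario$class_set`.  Warns if only a single class
#'   is present (class-contrast statistics are then undefined).
#' @export
make_targets <- function(table, scenario) {
  diag <- as.character(table[["Diagnosis"]])
  unmapped <- setdiff(unique(diag), names(scenario$label_map))
  if (length(unmapped) > 0L) {
    stop(sprintf("diagnosis label(s) not covered by the scenario map: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  out <- factor(scenario$label_map[diag], levels = scenario$class_set)
  if (length(unique(out)) < 2L) {
    warning("targets contain a single class; class-contrast statistics are undefined")
  }
  out
}

#' Specify one benchmark test
#'
#' One cell of the 4 models x 2 feature sets x 2 scenarios grid.
#' Hyperparameters default to the families' ecosystem defaults (SVM: RBF
#' kernel, cost 1; KNN: k = 5; decision tree: unpruned, unlimited depth;
#' logistic regression: unpenalized) and are recorded verbatim in every
#' report for audit.
#'
#' @param model One of `"LR"`, `"SVM"`, `"KNN"`, `"DTREE"`.
#' @param feature_set `"normal_24"` (all 24 candidates) or `"pfe_4"` (top-k
#'   PFE selection).
#' @param scenario A [scenario_spec()].
#' @param k Number of PFE-selected features when `feature_set = "pfe_4"`.
#' @param hyperparameters Named list overriding family defaults.
#' @return A `test_spec` list.
#' @export
test_spec <- function(model = c("LR", "SVM", "KNN", "DTREE"),
                      feature_set = c("normal_24", "pfe_4"),
                      scenario = binary_scenario(), k = 4,
                      hyperparameters = list()) {
  model <- match.arg(model)
  feature_set <- match.arg(feature_set)
  defaults <- switch(model,
    LR = list(penalty = "none", maxit = 200),
    SVM = list(kernel = "radial", cost = 1, probability = TRUE),
    KNN = list(k = 5, scale = TRUE),
    DTREE = list(cp = 0, minsplit = 2, minbucket = 1, maxdepth = 30)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(model = model, feature_set = feature_set,
                 scenario = scenario, k = as.integer(k),
                 hyperparameters = hp),
            class = "test_spec")
}
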