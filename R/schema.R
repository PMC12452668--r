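#' Feature-table schema
#'
#' The per-examination feature table carries 26 columns: an opaque exam `ID`,
#' eye laterality, visual acuity on the decimal scale, the nine ETDRS macular
#' grid sector thicknesses (micrometres) and nine sector volumes (cubic
#' millimetres), the fovea minima, the total macular volume, patient sex and
#' age, and the diagnostic phenotype label.  `table1_columns()` returns the
#' canonical column order used for CSV input/output; `feature_columns()`
#' returns the 24 candidate predictors (everything except `ID` and
#' `Diagnosis`).
#'
#' @return A character vector of column names.
#' @export
table1_columns <- function() {
  c("ID", "R/L eye", "VisualAcuity",
    paste0("etdrs9_", 1:9), "foveamin",
    paste0("etdrs9v_", 1:9), "whole/total",
    "Diagnosis", "Sex", "Age")
}

#' @rdname table1_columns
#' @export
feature_columns <- function() {
  setdiff(table1_columns(), c("ID", "Diagnosis"))
}

# Numeric subset of the schema; eye and sex are categorical until encoded.
numeric_feature_columns <- function() {
  setdiff(feature_columns(), c("R/L eye", "Sex"))
}

categorical_columns <- function() c("R/L eye", "Sex", "Diagnosis")

# The six diagnostic phenotypes, positives first.
phenotype_labels <- function() {
  c("Y", "Y-Mer", "Y-Perifoveal", "N", "N-Anomalies", "N-Mer")
}

assert_schema <- function(table, context = "feature table") {
  missing <- setdiff(table1_columns(), names(table))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 context, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(table)
}
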