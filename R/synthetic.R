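#' Default class compositions
#'
#' `binary_class_counts()` is the printed study composition (131 exams with
#' DME, 569 without).  `multiclass_class_counts()` splits the same totals over
#' the six phenotypes; the per-phenotype counts are documented conventions
#' (the source tables never print them) chosen so that the positive phenotypes
#' sum to 131 and the negative ones to 569.
#'
#' @return Named integer vector of exam counts per phenotype.
#' @export
binary_class_counts <- function() c(Y = 131L, N = 569L)

#' @rdname binary_class_counts
#' @export
multiclass_class_counts <- function() {
  c("Y" = 80L, "Y-Mer" = 26L, "Y-Perifoveal" = 25L,
    "N" = 430L, "N-Anomalies" = 69L, "N-Mer" = 70L)
}

# Physiologic baselines (healthy macula) on native units: thickness in um,
# volume in mm^3, visual acuity decimal.  Means follow ETDRS normative
# conventions (central subfield ~250 um, inner ring ~320, outer ring ~280).
baseline_profile <- function() {
  means <- c(
    "VisualAcuity" = 0.80,
    "etdrs9_1" = 250, "etdrs9_2" = 320, "etdrs9_3" = 320, "etdrs9_4" = 318,
    "etdrs9_5" = 315, "etdrs9_6" = 282, "etdrs9_7" = 285, "etdrs9_8" = 278,
    "etdrs9_9" = 272,
    "foveamin" = 225,
    "etdrs9v_1" = 0.20, "etdrs9v_2" = 0.50, "etdrs9v_3" = 0.50,
    "etdrs9v_4" = 0.50, "etdrs9v_5" = 0.49,
    "etdrs9v_6" = 1.40, "etdrs9v_7" = 1.42, "etdrs9v_8" = 1.38,
    "etdrs9v_9" = 1.33,
    "whole/total" = 8.7,
    "Age" = 62.5
  )
  sds <- c(
    "VisualAcuity" = 0.18,
    "etdrs9_1" = 20, "etdrs9_2" = 18, "etdrs9_3" = 18, "etdrs9_4" = 18,
    "etdrs9_5" = 18, "etdrs9_6" = 16, "etdrs9_7" = 16, "etdrs9_8" = 16,
    "etdrs9_9" = 16,
    "foveamin" = 20,
    "etdrs9v_1" = 0.02, "etdrs9v_2" = 0.04, "etdrs9v_3" = 0.04,
    "etdrs9v_4" = 0.04, "etdrs9v_5" = 0.04,
    "etdrs9v_6" = 0.10, "etdrs9v_7" = 0.10, "etdrs9v_8" = 0.10,
    "etdrs9v_9" = 0.10,
    "whole/total" = 0.60,
    "Age" = 13
  )
  list(means = means, sds = sds)
}

# Per-phenotype mean shifts on native units, relative to the healthy baseline.
# Positive phenotypes additionally draw thickness/volume features at 3x the
# baseline spread (edema severity is heterogeneous between eyes).
# Y carries the edema signature (central thickening + volume gain, lower VA);
# Y-Mer adds diffuse membrane-traction thickening on top of Y; Y-Perifoveal
# concentrates the edema in the inner (perifoveal) ring; N-Mer is a uniform
# thickness offset without the central fluid signature; N-Anomalies is a mild
# outer-ring irregularity.
phenotype_shifts <- function() {
  zero <- stats::setNames(numeric(length(numeric_feature_columns())),
                          numeric_feature_columns())
  shift <- function(...) {
    s <- zero
    v <- c(...)
    s[names(v)] <- v
    s
  }
  inner_t <- paste0("etdrs9_", 2:5); outer_t <- paste0("etdrs9_", 6:9)
  inner_v <- paste0("etdrs9v_", 2:5); outer_v <- paste0("etdrs9v_", 6:9)
  y <- shift(
    "etdrs9_1" = 150, "foveamin" = 130,
    stats::setNames(rep(80, 4), inner_t), stats::setNames(rep(35, 4), outer_t),
    "etdrs9v_1" = 0.12,
    stats::setNames(rep(0.10, 4), inner_v),
    stats::setNames(rep(0.15, 4), outer_v),
    "whole/total" = 1.0, "VisualAcuity" = -0.35
  )
  list(
    "Y" = y,
    "Y-Mer" = y + shift(
      "etdrs9_1" = 25, "foveamin" = 20,
      stats::setNames(rep(25, 4), inner_t), stats::setNames(rep(25, 4), outer_t),
      stats::setNames(rep(0.03, 4), inner_v),
      stats::setNames(rep(0.03, 4), outer_v),
      "whole/total" = 0.2
    ),
    "Y-Perifoveal" = shift(
      "etdrs9_1" = 40, "foveamin" = 30,
      stats::setNames(rep(110, 4), inner_t), stats::setNames(rep(25, 4), outer_t),
      "etdrs9v_1" = 0.03,
      stats::setNames(rep(0.14, 4), inner_v),
      stats::setNames(rep(0.10, 4), outer_v),
      "whole/total" = 0.9, "VisualAcuity" = -0.25
    ),
    "N" = zero,
    "N-Anomalies" = shift(
      stats::setNames(rep(20, 4), outer_t),
      stats::setNames(rep(0.05, 4), outer_v),
      "whole/total" = 0.2, "VisualAcuity" = -0.10
    ),
    "N-Mer" = shift(
      "etdrs9_1" = 40, "foveamin" = 35,
      stats::setNames(rep(40, 4), inner_t), stats::setNames(rep(40, 4), outer_t),
      "etdrs9v_1" = 0.04,
      stats::setNames(rep(0.05, 4), inner_v),
      stats::setNames(rep(0.05, 4), outer_v),
      "whole/total" = 0.3, "VisualAcuity" = -0.10
    )
  )
}

#' Configure a synthetic OCT cohort
#'
#' Builds the configuration object consumed by [generate_cohort()].  The
#' defaults reproduce the study conditions the pipeline is benchmarked under:
#' 700 examinations split over six diagnostic phenotypes (131 DME-positive,
#' 569 negative in the binary collapse), ages 23--91 years, roughly balanced
#' eye laterality, and a class-conditional edema signature on the ETDRS
#' thickness/volume features.
#'
#' Two signal modes exist.  With `effect_sizes = NULL` (default) each
#' phenotype receives its documented native-unit mean-shift profile (central
#' thickening, volume gain, reduced visual acuity for positive phenotypes).
#' When `effect_sizes` is a named numeric vector of Cohen's d values, those
#' standardized shifts *replace* the phenotype profiles: each named feature is
#' shifted by `d * sd` in every DME-positive phenotype and all other features
#' carry no class contrast.  This is the mode used to plant controlled signal
#' for recovery experiments.
#'
#' @param n_exams Number of examinations (rows).
#' @param class_counts Named integer vector, phenotype label -> count.  Must
#'   sum to `n_exams`.
#' @param effect_sizes `NULL`, or named numeric vector of standardized mean
#'   shifts (Cohen's d) between positive and negative classes; names must be
#'   numeric feature columns.
#' @param noise_sd Optional named numeric vector overriding per-feature
#'   standard deviations on native units; values must be positive.
#' @param age_range Two-element numeric vector, inclusive age bounds in years.
#' @param eye_balance Fraction of right-eye exams, in \[0, 1\].
#' @param male_fraction Fraction of male patients, in \[0, 1\].
#' @param va_cor Strength of the negative correlation between visual acuity
#'   and central subfield thickness in DME-positive phenotypes, in \[0, 1).
#'   Ignored in `effect_sizes` mode.
#' @param patient_ids If `TRUE`, consecutive same-phenotype exams are paired
#'   as right/left eyes of a shared patient id.  Off by default: exams are
#'   treated as independent rows.
#' @param seed Integer RNG seed; the generated table is a deterministic
#'   function of the full configuration.
#' @return A `cohort_config` list.
#' @seealso [generate_cohort()], [inject_missingness()]
#' @examples
#' cfg <- cohort_config(n_exams = 100,
#'                      class_counts = c(Y = 20, N = 80), seed = 1)
#' table(generate_cohort(cfg)$Diagnosis)
#' @export
cohort_config <- function(n_exams = 700,
                          class_counts = multiclass_class_counts(),
                          effect_sizes = NULL,
                          noise_sd = NULL,
                          age_range = c(23, 91),
                          eye_balance = 0.5,
                          male_fraction = 0.553,
                          va_cor = 0.5,
                          patient_ids = FALSE,
                          seed = 1L) {
  if (length(n_exams) != 1L || n_exams < 1 || n_exams != round(n_exams)) {
    stop("`n_exams` must be a single positive integer", call. = FALSE)
  }
  if (is.null(names(class_counts)) || any(!nzchar(names(class_counts)))) {
    stop("`class_counts` must be a named vector of phenotype counts",
         call. = FALSE)
  }
  if (any(class_counts < 0) || any(class_counts != round(class_counts))) {
    stop("class counts must be non-negative integers", call. = FALSE)
  }
  if (sum(class_counts) != n_exams) {
    stop(sprintf("class counts sum to %d but `n_exams` is %d",
                 sum(class_counts), n_exams), call. = FALSE)
  }
  if (!is.null(effect_sizes)) {
    if (length(effect_sizes) > 0 &&
        (is.null(names(effect_sizes)) ||
         !all(names(effect_sizes) %in% numeric_feature_columns()))) {
      stop("`effect_sizes` names must be numeric feature columns",
           call. = FALSE)
    }
  }
  if (!is.null(noise_sd)) {
    if (is.null(names(noise_sd)) ||
        !all(names(noise_sd) %in% numeric_feature_columns())) {
      stop("`noise_sd` names must be numeric feature columns", call. = FALSE)
    }
    if (any(noise_sd <= 0)) stop("`noise_sd` must be positive", call. = FALSE)
  }
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    stop("`age_range` must be an increasing pair of ages", call. = FALSE)
  }
  if (eye_balance < 0 || eye_balance > 1) {
    stop("`eye_balance` must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_exams = as.integer(n_exams),
    class_counts = stats::setNames(as.integer(class_counts),
                                   names(class_counts)),
    effect_sizes = effect_sizes,
    noise_sd = noise_sd,
    age_range = as.numeric(age_range),
    eye_balance = eye_balance,
    male_fraction = male_fraction,
    va_cor = va_cor,
    patient_ids = isTRUE(patient_ids),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic cohort feature table
#'
#' Draws a feature table with the 26-column schema of [table1_columns()].
#' Numeric features come from truncated normal distributions (truncated at 0:
#' thicknesses and volumes are strictly positive); visual acuity is clamped to
#' (0, 1.2\] and, for DME-positive phenotypes in the default signal mode,
#' negatively correlated with central subfield thickness.  The label histogram
#' equals `config$class_counts` exactly and the output is a deterministic
#' function of `config` (including its seed).
#'
#' @param config A [cohort_config()] object.
#' @return A `data.frame` with `config$n_exams` rows and the 26 schema
#'   columns, rows shuffled across phenotypes.
#' @examples
#' cfg <- cohort_config(n_exams = 50, class_counts = c(Y = 10, N = 40),
#'                      effect_sizes = c(etdrs9_1 = 2), seed = 7)
#' head(generate_cohort(cfg))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be created by cohort_config()", call. = FALSE)
  }
  set.seed(config$seed)
  prof <- baseline_profile()
  if (!is.null(config$noise_sd)) {
    prof$sds[names(config$noise_sd)] <- config$noise_sd
  }
  shifts <- phenotype_shifts()
  num_cols <- numeric_feature_columns()

  blocks <- lapply(names(config$class_counts), function(cls) {
    n_c <- config$class_counts[[cls]]
    if (n_c == 0L) return(NULL)
    means <- prof$means
    if (is.null(config$effect_sizes)) {
      sh <- shifts[[cls]]
      if (!is.null(sh)) {  # unknown phenotype: baseline profile
        means[num_cols] <- means[num_cols] + sh[num_cols]
      }
    } else if (is_positive_label(cls) && length(config$effect_sizes) > 0) {
      f <- names(config$effect_sizes)
      means[f] <- means[f] + config$effect_sizes * prof$sds[f]
    }
    df <- data.frame(check.names = FALSE, row.names = NULL,
                     matrix(nrow = n_c, ncol = 0))
    df[["R/L eye"]] <- ifelse(stats::runif(n_c) < config$eye_balance, "R", "L")
    df[["Sex"]] <- ifelse(stats::runif(n_c) < config$male_fraction, "M", "F")
    df[["Age"]] <- round(rtrunc_norm(n_c, means[["Age"]], prof$sds[["Age"]],
                                     config$age_range[1], config$age_range[2]))
    # Edema severity varies widely between eyes: in the default signal mode
    # the positive phenotypes draw thickness/volume features with a 3x wider
    # spread than the healthy baseline.
    sd_scale <- if (is.null(config$effect_sizes) && is_positive_label(cls)) 3 else 1
    thick_vol <- setdiff(num_cols, c("VisualAcuity", "Age"))
    for (f in thick_vol) {
      df[[f]] <- rtrunc_norm(n_c, means[[f]], sd_scale * prof$sds[[f]],
                             lower = 0)
    }
    # Visual acuity: correlate negatively with central thickness for the
    # positive phenotypes (fluid degrades acuity); independent otherwise.
    rho <- if (is.null(config$effect_sizes) && is_positive_label(cls)) {
      config$va_cor
    } else 0
    z_central <- (df[["etdrs9_1"]] - means[["etdrs9_1"]]) / prof$sds[["etdrs9_1"]]
    z_noise <- stats::rnorm(n_c)
    z_va <- -rho * z_central + sqrt(1 - rho^2) * z_noise
    df[["VisualAcuity"]] <-
      pmin(1.2, pmax(0.05, means[["VisualAcuity"]] +
                             prof$sds[["VisualAcuity"]] * z_va))
    df[["Diagnosis"]] <- cls
    if (config$patient_ids) {
      df[[".patient"]] <- paste0(substr(cls, 1, 1), ceiling(seq_len(n_c) / 2))
      pair_pos <- seq_len(n_c) %% 2L
      df[["R/L eye"]] <- ifelse(pair_pos == 1L, "R", "L")
    }
    df
  })
  tab <- do.call(rbind, blocks)
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  rownames(tab) <- NULL
  tab[["ID"]] <- if (config$patient_ids) {
    paste0(tab[[".patient"]], "-", stats::ave(seq_len(nrow(tab)), tab[[".patient"]],
                                       FUN = seq_along))
  } else {
    sprintf("EX%04d", seq_len(nrow(tab)))
  }
  tab[[".patient"]] <- NULL
  tab[, table1_columns(), drop = FALSE]
}

#' Blank cells at random to exercise null-row handling
#'
#' Independently replaces each non-label cell (the 24 feature columns; `ID`
#' and `Diagnosis` are never touched) with `NA` with probability `rate`.
#' Deterministic given `seed`.
#'
#' @param table A feature table with the schema of [table1_columns()].
#' @param rate Per-cell blanking probability in \[0, 1).  Rates above 0.5 are
#'   allowed but trigger a warning: downstream null-row removal would discard
#'   almost every exam.
#' @param seed Integer RNG seed.
#' @return The table with blanked cells.
#' @export
inject_missingness <- function(table, rate, seed = 1L) {
  assert_schema(table)
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate >= 1) {
    stop("`rate` must be a single probability in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(table)
  if (rate > 0.5) {
    warning(sprintf(
      "blanking rate %.2f will leave almost no complete rows", rate))
  }
  set.seed(seed)
  cols <- feature_columns()
  mask <- matrix(stats::runif(nrow(table) * length(cols)) < rate,
                 nrow = nrow(table))
  for (j in seq_along(cols)) {
    table[[cols[j]]][mask[, j]] <- NA
  }
  table
}
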