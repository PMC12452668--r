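test_that("generated cohorts match the configured composition and schema", {
  cfg <- cohort_config(seed = 11)
  tab <- generate_cohort(cfg)

  expect_identical(names(tab), table1_columns())
  expect_equal(nrow(tab), 700)
  counts <- table(tab$Diagnosis)
  expect_equal(unname(counts[names(cfg$class_counts)]),
               unname(cfg$class_counts), ignore_attr = TRUE)
  # binary collapse reproduces the 131/569 composition
  expect_equal(sum(startsWith(tab$Diagnosis, "Y")), 131)
  expect_equal(sum(startsWith(tab$Diagnosis, "N")), 569)
})

test_that("numeric features respect physiologic bounds", {
  tab <- generate_cohort(cohort_config(seed = 3))
  thick_vol <- c(paste0("etdrs9_", 1:9), "foveamin",
                 paste0("etdrs9v_", 1:9), "whole/total")
  for (f in thick_vol) expect_true(all(tab[[f]] > 0), label = f)
  expect_true(all(tab$Age >= 23 & tab$Age <= 91))
  expect_true(all(tab$VisualAcuity > 0 & tab$VisualAcuity <= 1.2))
  expect_true(all(tab$`R/L eye` %in% c("R", "L")))
  expect_true(all(tab$Sex %in% c("M", "F")))
  # healthy central subfield thickness sits near its physiologic baseline
  expect_equal(mean(tab$etdrs9_1[tab$Diagnosis == "N"]), 250, tolerance = 0.02)
})

test_that("identical config and seed give identical tables", {
  cfg <- cohort_config(seed = 99)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_feature_csv(t1, f1); write_feature_csv(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(t1, generate_cohort(cohort_config(seed = 100))))
})

test_that("planted standardized effects are recovered from the table", {
  tab <- planted_cohort(seed = 7, d = 2, n = 2000,
                        counts = c(Y = 1000, N = 1000))
  expect_gt(empirical_d(tab, "etdrs9_1"), 1.8)
  expect_lt(empirical_d(tab, "etdrs9_1"), 2.2)
  others <- setdiff(c(paste0("etdrs9_", 1:9), "foveamin",
                      paste0("etdrs9v_", 1:9), "whole/total",
                      "VisualAcuity", "Age"), "etdrs9_1")
  for (f in others) {
    expect_lt(abs(empirical_d(tab, f)), 0.15, label = f)
  }
})

test_that("single-class cohorts generate but flag degenerate targets", {
  tab <- generate_cohort(cohort_config(n_exams = 10,
                                       class_counts = c(Y = 0, N = 10)))
  expect_true(all(tab$Diagnosis == "N"))
  expect_warning(make_targets(tab, binary_scenario()), "single class")
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_exams = 10, class_counts = c(Y = 3, N = 3)),
               "sum to 6")
  expect_error(cohort_config(n_exams = 2, class_counts = c(Y = -1, N = 3)),
               "non-negative")
  expect_error(cohort_config(class_counts = c(131, 569)), "named")
  expect_error(cohort_config(noise_sd = c(etdrs9_1 = -1)), "positive")
  expect_error(cohort_config(effect_sizes = c(bogus = 1)), "feature columns")
  expect_error(cohort_config(age_range = c(91, 23)), "increasing")
})

test_that("paired-eye mode shares a patient id across eyes", {
  tab <- generate_cohort(cohort_config(n_exams = 40,
                                       class_counts = c(Y = 20, N = 20),
                                       patient_ids = TRUE, seed = 2))
  pid <- sub("-[0-9]+$", "", tab$ID)
  sizes <- table(pid)
  expect_true(all(sizes <= 2))
  paired <- names(sizes)[sizes == 2]
  for (p in paired) {
    expect_setequal(tab$`R/L eye`[pid == p], c("R", "L"))
  }
})

test_that("missingness injection blanks cells at the requested rate", {
  tab <- generate_cohort(cohort_config(seed = 21))
  expect_identical(inject_missingness(tab, 0), tab)

  out <- inject_missingness(tab, 0.1, seed = 3)
  # ID and Diagnosis are never blanked
  expect_false(anyNA(out$ID))
  expect_false(anyNA(out$Diagnosis))
  n_cells <- nrow(tab) * length(feature_columns())
  n_blank <- sum(is.na(out[, feature_columns()]))
  se <- sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(n_blank / n_cells - 0.1), 3 * se)
  # deterministic given seed
  expect_identical(out, inject_missingness(tab, 0.1, seed = 3))

  expect_error(inject_missingness(tab, 1), "\\[0, 1\\)")
  expect_error(inject_missingness(tab, -0.1), "\\[0, 1\\)")
  expect_warning(inject_missingness(tab, 0.99), "almost no complete rows")
})
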