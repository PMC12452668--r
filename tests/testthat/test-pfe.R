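test_that("min-max normalization maps to [0,1] and is affine invariant", {
  expect_equal(normalize_feature(c(100, 200, 300)), c(0, 0.5, 1))
  expect_equal(normalize_feature(c(7, 7, 7)), c(0.5, 0.5, 0.5))
  expect_error(normalize_feature(numeric(0)), "non-empty")
  expect_error(normalize_feature(c(1, NA)), "finite")
  expect_error(normalize_feature(c(1, Inf)), "finite")

  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(normalize_feature(a * v + b), normalize_feature(v),
                 tolerance = 1e-12)
  }
})

test_that("class intervals follow the percentile contract", {
  grid11 <- seq(0, 1, by = 0.1)
  expect_equal(class_interval(grid11), c(0.1, 0.9))
  expect_equal(class_interval(grid11, 0, 100), c(0, 1))
  expect_equal(class_interval(rep(0.5, 4)), c(0.5, 0.5))
  expect_error(class_interval(numeric(0), class = "Y"),
               "class .Y. has no observations")
  expect_error(class_interval(grid11, 90, 10), "p_lo < p_hi")
  expect_error(class_interval(grid11, -5, 50), "p_lo < p_hi|0 <=")
})

test_that("alpha and beta degrees match hand-computed interval arithmetic", {
  expect_equal(pfe_alpha(list(c(0.3, 0.3), c(0.8, 0.8))), 1)
  expect_equal(pfe_alpha(list(c(0, 1), c(0, 1))), 0)
  expect_equal(pfe_alpha(list(c(0.1, 0.3), c(0.6, 1.0))), 0.7)

  expect_equal(pfe_beta(list(c(0.1, 0.3), c(0.6, 1.0))), 0)
  expect_equal(pfe_beta(list(c(0.2, 0.7), c(0.2, 0.7))), 1)
  expect_equal(pfe_beta(list(c(0.0, 0.5), c(0.25, 0.75))), 1 / 3)
  # zero-width intervals: same point overlap fully, distinct points none
  expect_equal(pfe_beta(list(c(0.4, 0.4), c(0.4, 0.4))), 1)
  expect_equal(pfe_beta(list(c(0.2, 0.2), c(0.8, 0.8))), 0)
  expect_error(pfe_beta(list(c(0, 1))), "two classes")
})

test_that("degenerate features land at known plane points", {
  n <- 40
  tab <- data.frame(
    check.names = FALSE,
    perfect = rep(c(10, 20), each = n / 2),   # constant per class, distinct
    constant = rep(7, n),                     # constant everywhere
    noise = c(rnorm(n / 2, 0, 1), rnorm(n / 2, 0, 1)),
    Diagnosis = rep(c("Y", "N"), each = n / 2)
  )
  sc <- pfe_scores(tab, exclude = "Diagnosis")
  perfect <- sc[sc$feature == "perfect", ]
  expect_equal(perfect$alpha, 1)
  expect_equal(perfect$beta, 0)
  expect_equal(perfect$g1, 1)
  expect_equal(perfect$g2, 0)
  expect_equal(perfect$distance, 0)
  expect_equal(perfect$rank, 1L)

  const <- sc[sc$feature == "constant", ]
  expect_equal(const$alpha, 1)
  expect_equal(const$beta, 1)
  expect_equal(const$g1, 0)
  expect_equal(const$g2, 1)
  expect_equal(const$distance, sqrt(2))
})

test_that("scores are invariant to sample order, affine rescaling and label swap", {
  set.seed(8)
  tab <- preprocess(planted_cohort(seed = 8))$table
  sc <- pfe_scores(tab)

  perm <- sample(nrow(tab))
  expect_equal(as.data.frame(pfe_scores(tab[perm, ])), as.data.frame(sc),
               tolerance = 1e-12)

  tab2 <- tab
  tab2$etdrs9_1 <- 3.7 * tab2$etdrs9_1 + 55
  expect_equal(as.data.frame(pfe_scores(tab2)), as.data.frame(sc),
               tolerance = 1e-10)

  tab3 <- tab
  tab3$Diagnosis <- ifelse(tab3$Diagnosis == "Y", "N", "Y")
  sc3 <- pfe_scores(tab3)
  expect_equal(sc3$alpha, sc$alpha, tolerance = 1e-12)
  expect_equal(sc3$beta, sc$beta, tolerance = 1e-12)
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  tab <- data.frame(
    b_feat = rep(c(1, 2), each = 10),
    a_feat = rep(c(1, 2), each = 10),   # identical scores, earlier name
    Diagnosis = rep(c("Y", "N"), each = 10)
  )
  sc <- pfe_scores(tab, exclude = "Diagnosis")
  expect_identical(sc$feature[sc$rank == 1L], "a_feat")
  expect_identical(sc$feature[sc$rank == 2L], "b_feat")
  expect_setequal(sc$rank, seq_len(nrow(sc)))
})

test_that("a strongly planted feature is ranked first and selected", {
  tab <- preprocess(planted_cohort(seed = 7, d = 2))$table
  sc <- pfe_scores(tab)
  expect_equal(nrow(sc), 24)
  expect_identical(sc$feature[sc$rank == 1L], "etdrs9_1")
  expect_identical(select_top_k(sc, 1), "etdrs9_1")
  top4 <- select_top_k(sc, 4)
  expect_length(top4, 4)
  expect_identical(top4[1], "etdrs9_1")
  expect_identical(select_top_k(sc, nrow(sc)), sc$feature[order(sc$rank)])
  expect_error(select_top_k(sc, 0), "\\[1, 24\\]")
  expect_error(select_top_k(sc, 25), "\\[1, 24\\]")
})

test_that("scoring rejects malformed inputs", {
  tab <- data.frame(x = 1:6, Diagnosis = rep(c("Y", "N"), 3))
  expect_error(pfe_scores(tab, features = "nope"), "unknown feature")
  expect_error(pfe_scores(tab, label_col = "lbl"), "label column")
  tab$cat <- rep(c("a", "b"), 3)
  expect_error(pfe_scores(tab, features = "cat"), "not numeric")
  one <- data.frame(x = 1:4, Diagnosis = "Y")
  expect_error(pfe_scores(one), "two classes")
})

test_that("the CV-based alpha variant stays in bounds and rewards tight classes", {
  tab <- preprocess(planted_cohort(seed = 12))$table
  sc <- pfe_scores(tab, alpha_method = "cv")
  expect_true(all(sc$alpha >= 0 & sc$alpha <= 1))
  expect_true(all(sc$g1 == sc$alpha - sc$beta))
  expect_setequal(sc$rank, seq_len(nrow(sc)))
})
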