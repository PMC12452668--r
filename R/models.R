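# Classifier back-ends for the benchmark harness.  Each family is fitted
# through its established implementation; the harness only standardizes the
# interface: fit on (x_train, y_train), return predicted labels and an
# n x k per-class score matrix with columns in `classes` order.

fit_predict <- function(model, x_train, y_train, x_test, classes, hp) {
  # syntactic column names for formula interfaces ("R/L eye", "whole/total")
  nm <- make.names(colnames(x_train), unique = TRUE)
  colnames(x_train) <- nm
  colnames(x_test) <- nm
  y_train <- factor(as.character(y_train), levels = classes)

  scores <- switch(model,
    LR = {
      if (length(classes) == 2L) {
        df <- data.frame(x_train, check.names = FALSE)
        df$.y <- y_train
        fit <- suppressWarnings(stats::glm(
          .y ~ ., data = df, family = stats::binomial(),
          control = stats::glm.control(maxit = hp$maxit)))
        p2 <- suppressWarnings(stats::predict(
          fit, newdata = data.frame(x_test, check.names = FALSE),
          type = "response"))
        matrix(c(1 - p2, p2), ncol = 2,
               dimnames = list(NULL, classes))  # glm models P(second level)
      } else {
        df <- data.frame(x_train, check.names = FALSE)
        df$.y <- y_train
        fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
                              maxit = hp$maxit, MaxNWts = 10000)
        p <- stats::predict(fit, newdata = data.frame(x_test, check.names = FALSE),
                            type = "probs")
        if (is.null(dim(p))) p <- matrix(p, ncol = length(classes))
        p
      }
    },
    SVM = {
      fit <- suppressWarnings(e1071::svm(
        x = as.matrix(x_train), y = y_train, kernel = hp$kernel,
        cost = hp$cost, probability = TRUE, scale = TRUE))
      pr <- stats::predict(fit, as.matrix(x_test), probability = TRUE)
      attr(pr, "probabilities")[, classes, drop = FALSE]
    },
    KNN = {
      xtr <- as.matrix(x_train)
      xte <- as.matrix(x_test)
      if (isTRUE(hp$scale)) {
        mu <- colMeans(xtr)
        sdev <- apply(xtr, 2, stats::sd)
        sdev[sdev == 0] <- 1
        xtr <- scale(xtr, mu, sdev)
        xte <- scale(xte, mu, sdev)
      }
      fit <- caret::knn3(xtr, y_train, k = hp$k)
      stats::predict(fit, xte, type = "prob")
    },
    DTREE = {
      df <- data.frame(x_train, check.names = FALSE)
      df$.y <- y_train
      fit <- rpart::rpart(
        .y ~ ., data = df, method = "class",
        control = rpart::rpart.control(cp = hp$cp, minsplit = hp$minsplit,
                                       minbucket = hp$minbucket,
                                       maxdepth = hp$maxdepth, xval = 0))
      stats::predict(fit, data.frame(x_test, check.names = FALSE),
                     type = "prob")
    },
    stop(sprintf("unknown model family %s", dQuote(model)), call. = FALSE)
  )
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- classes
  scores <- scores[, classes, drop = FALSE]
  pred <- classes[max.col(scores, ties.method = "first")]
  list(pred = factor(pred, levels = classes), scores = scores)
}
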