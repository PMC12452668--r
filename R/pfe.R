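#' Min-max normalize a feature vector
#'
#' Scales a numeric vector to \[0, 1\] over all samples so that interval
#' widths and overlaps are comparable across features measured on different
#' native units (micrometres, cubic millimetres, years, ...).  A constant
#' vector maps to all 0.5: its per-class intervals then have zero width at a
#' shared point, which scores as maximal intraclass similarity *and* maximal
#' interclass overlap (pure contradiction) rather than being undefined.
#'
#' @param values Non-empty numeric vector with finite entries.
#' @return Numeric vector in \[0, 1\] of the same length.
#' @examples
#' normalize_feature(c(100, 200, 300))
#' @export
normalize_feature <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("`values` must be numeric and finite", call. = FALSE)
  }
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0.5, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Percentile interval of one class
#'
#' Summarizes a class's normalized feature values as the interval between two
#' percentiles (default 10th and 90th, linear interpolation).  The trimmed
#' interval, rather than the range, keeps the alpha/beta degrees robust to
#' outlying clinical measurements.
#'
#' @param values Normalized values of a single class.
#' @param p_lo,p_hi Percentile bounds, `0 <= p_lo < p_hi <= 100`.
#' @param class Optional class label used in error messages.
#' @return Numeric vector `c(lo, hi)` with `lo <= hi`.
#' @export
class_interval <- function(values, p_lo = 10, p_hi = 90, class = NULL) {
  if (length(values) == 0L) {
    stop(sprintf("class %s has no observations",
                 if (is.null(class)) "<unnamed>" else dQuote(class)),
         call. = FALSE)
  }
  if (p_lo < 0 || p_hi > 100 || p_lo >= p_hi) {
    stop("percentiles must satisfy 0 <= p_lo < p_hi <= 100", call. = FALSE)
  }
  stats::quantile(values, c(p_lo, p_hi) / 100, names = FALSE, type = 7)
}

#' Intraclass similarity degree (alpha)
#'
#' `alpha = 1 - mean(interval widths)`: 1 exactly when every class interval
#' has zero width (perfect within-class homogeneity), 0 when every class
#' spans the whole normalized range.
#'
#' @param intervals List of `c(lo, hi)` intervals, one per class.
#' @return Degree in \[0, 1\].
#' @export
pfe_alpha <- function(intervals) {
  if (length(intervals) < 1L) stop("need at least one class", call. = FALSE)
  widths <- vapply(intervals, function(i) i[2] - i[1], numeric(1))
  1 - mean(widths)
}

#' Interclass overlap degree (beta)
#'
#' Mean Jaccard overlap `|I ∩ I'| / |I ∪ I'|` over all unordered class
#' pairs.  Two zero-width intervals overlap fully (1) at the same point and
#' not at all (0) at different points; beta is 0 exactly when every pair of
#' class intervals is disjoint.  Small beta therefore means the classes
#' occupy distinct value ranges -- the discriminative direction.
#'
#' @inheritParams pfe_alpha
#' @return Degree in \[0, 1\].
#' @export
pfe_beta <- function(intervals) {
  k <- length(intervals)
  if (k < 2L) stop("beta needs at least two classes", call. = FALSE)
  jac <- function(a, b) {
    uni <- max(a[2], b[2]) - min(a[1], b[1])
    if (uni == 0) return(1)  # both zero-width at the same point
    max(0, min(a[2], b[2]) - max(a[1], b[1])) / uni
  }
  pairs <- utils::combn(k, 2)
  mean(apply(pairs, 2, function(p) jac(intervals[[p[1]]], intervals[[p[2]]])))
}

#' Paraconsistent plane coordinates
#'
#' Maps the paraconsistent degrees to the plane: degree of certainty
#' `G1 = alpha - beta`, degree of contradiction `G2 = alpha + beta - 1`, and
#' the Euclidean distance to the ideal point (1, 0) -- a feature perfectly
#' homogeneous within each class and perfectly distinct between classes.
#'
#' @param alpha,beta Degrees in \[0, 1\] (vectorized).
#' @return A `data.frame` with columns `g1`, `g2`, `distance`.
#' @examples
#' paraconsistent_coords(1, 0)    # ideal feature
#' paraconsistent_coords(1, 1)    # constant feature: pure contradiction
#' @export
paraconsistent_coords <- function(alpha, beta) {
  if (any(alpha < 0 | alpha > 1 | beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("alpha and beta must lie in [0, 1]", call. = FALSE)
  }
  g1 <- alpha - beta
  g2 <- alpha + beta - 1
  data.frame(g1 = g1, g2 = g2, distance = sqrt((g1 - 1)^2 + g2^2))
}

#' Score features on the paraconsistent plane
#'
#' For each candidate feature: min-max normalize over all samples, summarize
#' each class by its percentile interval, compute the intraclass-similarity
#' degree alpha and interclass-overlap degree beta, map to the plane
#' (G1, G2), and rank features by ascending distance to the ideal point
#' (1, 0).  Ties are broken lexicographically by feature name so the ranking
#' is deterministic.
#'
#' @param table A data frame; candidate features must be numeric (encode
#'   categorical columns first, see [preprocess()]).
#' @param label_col Name of the class-label column.
#' @param features Character vector of candidate feature names; defaults to
#'   every column except `label_col` and `exclude`.
#' @param exclude Columns never scored (identifier and label by default).
#' @param p_lo,p_hi Percentile bounds for the class intervals.
#' @param alpha_method `"interval"` (default; 1 - mean interval width) or
#'   `"cv"` (1 - min(1, mean within-class coefficient of variation)).
#' @return A `pfe_scores` data frame with one row per feature and columns
#'   `feature`, `alpha`, `beta`, `g1`, `g2`, `distance`, `rank`, ordered by
#'   rank.
#' @seealso [select_top_k()], [plot_paraconsistent_plane()]
#' @export
pfe_scores <- function(table, label_col = "Diagnosis", features = NULL,
                       exclude = c("ID", "Diagnosis"),
                       p_lo = 10, p_hi = 90,
                       alpha_method = c("interval", "cv")) {
  alpha_method <- match.arg(alpha_method)
  if (!label_col %in% names(table)) {
    stop(sprintf("label column %s not found", dQuote(label_col)),
         call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(names(table), union(label_col, exclude))
  }
  unknown <- setdiff(features, names(table))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  labels <- as.character(table[[label_col]])
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("scoring needs at least two classes in the label column",
         call. = FALSE)
  }
  rows <- lapply(features, function(f) {
    v <- table[[f]]
    if (!is.numeric(v)) {
      stop(sprintf("feature %s is not numeric; encode it first", dQuote(f)),
           call. = FALSE)
    }
    v <- normalize_feature(v)
    ints <- lapply(classes, function(cls) {
      class_interval(v[labels == cls], p_lo, p_hi, class = cls)
    })
    a <- if (alpha_method == "interval") {
      pfe_alpha(ints)
    } else {
      cvs <- vapply(classes, function(cls) {
        x <- v[labels == cls]
        if (stats::sd(x) == 0) return(0)
        if (mean(x) == 0) return(1)
        min(1, stats::sd(x) / mean(x))
      }, numeric(1))
      1 - min(1, mean(cvs))
    }
    b <- pfe_beta(ints)
    cbind(data.frame(feature = f, alpha = a, beta = b),
          paraconsistent_coords(a, b))
  })
  out <- do.call(rbind, rows)
  ord <- order(out$distance, out$feature)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pfe_scores", "data.frame")
  out
}

#' Select the top-ranked features
#'
#' @param scores A [pfe_scores()] result.
#' @param k Number of features to keep, `1 <= k <= nrow(scores)`.
#' @return Character vector of the `k` smallest-distance features in rank
#'   order.
#' @export
select_top_k <- function(scores, k) {
  if (!inherits(scores, "pfe_scores")) {
    stop("`scores` must come from pfe_scores()", call. = FALSE)
  }
  if (length(k) != 1L || k < 1 || k > nrow(scores) || k != round(k)) {
    stop(sprintf("`k` must be an integer in [1, %d]", nrow(scores)),
         call. = FALSE)
  }
  scores$feature[order(scores$rank)][seq_len(k)]
}
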