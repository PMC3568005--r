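#' Evaluation metrics
#'
#' Regression endpoints are scored with the squared Pearson correlation
#' coefficient `r2_pearson()`, the root mean squared error `rmse()`, and the
#' cross-validated determination coefficient `q2()`,
#' `Q2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, computed over pooled
#' out-of-fold predictions with the mean taken from the same pooled truth.
#' Binary classification endpoints are scored with `recall_per_class()`
#' (fraction of each true class predicted correctly) and
#' `balanced_accuracy()` (mean of the two class recalls).
#'
#' Degenerate inputs (constant truth or predictions where a correlation is
#' required, an absent class) raise a classed undefined-metric error rather
#' than returning 0, so that fold aggregation can report the metric as
#' missing.
#'
#' @param y_true,y_pred numeric vectors of equal length (regression) or label
#'   vectors (classification).
#' @return a single number; `recall_per_class()` returns a named numeric
#'   vector with one recall per class.
#' @examples
#' r2_pearson(c(0, 1, 2, 3), c(0, 1, 2, 0))
#' rmse(c(0, 0, 2, 2), c(1, 1, 1, 1))
#' balanced_accuracy(rep(c("a", "z"), each = 5), rep("z", 10))
#' @export
r2_pearson <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  if (length(y_true) < 3) {
    stop_mixqspr("r2_pearson needs at least 3 observations", "mixqspr_undefined_metric")
  }
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop_mixqspr("correlation undefined for constant input", "mixqspr_undefined_metric")
  }
  stats::cor(y_true, y_pred)^2
}

#' @rdname r2_pearson
#' @export
rmse <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  sqrt(mean((y_true - y_pred)^2))
}

#' @rdname r2_pearson
#' @param y_true_cv,y_pred_cv pooled out-of-fold truths and predictions.
#' @export
q2 <- function(y_true_cv, y_pred_cv) {
  check_lengths(y_true_cv, y_pred_cv)
  if (length(y_true_cv) < 3) {
    stop_mixqspr("q2 needs at least 3 observations", "mixqspr_undefined_metric")
  }
  tss <- sum((y_true_cv - mean(y_true_cv))^2)
  if (tss == 0) {
    stop_mixqspr("q2 undefined for zero-variance truth", "mixqspr_undefined_metric")
  }
  1 - sum((y_true_cv - y_pred_cv)^2) / tss
}

#' @rdname r2_pearson
#' @export
recall_per_class <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(y_true))
  out <- vapply(classes, function(cl) {
    in_class <- y_true == cl
    sum(y_pred[in_class] == cl) / sum(in_class)
  }, numeric(1))
  stats::setNames(out, classes)
}

#' @rdname r2_pearson
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  check_lengths(y_true, y_pred)
  classes <- sort(unique(as.character(y_true)))
  if (length(classes) != 2) {
    stop_mixqspr("balanced accuracy is defined for two classes both present in y_true",
                 "mixqspr_undefined_metric")
  }
  mean(recall_per_class(y_true, y_pred))
}

check_lengths <- function(a, b) {
  if (length(a) != length(b)) {
    stop_mixqspr("y_true and y_pred differ in length", "mixqspr_dimension_error")
  }
  if (length(a) == 0) {
    stop_mixqspr("empty input", "mixqspr_undefined_metric")
  }
  invisible(TRUE)
}
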