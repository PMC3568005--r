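#' Fit a mixture-property model
#'
#' Central fitting function: featurizes a canonical mixture dataset under one
#' of the four mixture-descriptor schemes, scales the features, and trains an
#' estimator on the result. The returned object bundles everything needed to
#' predict new mixtures (descriptor matrix, scheme, fitted scaler, fitted
#' estimator) and supports the usual methods: `print()`, `summary()`,
#' `coef()` (linear estimators), `predict()`, `fitted()`, `residuals()`, and
#' `plot()` (observed versus fitted).
#'
#' @param dataset a [mixture_dataset()].
#' @param descriptors a `descriptor_matrix` covering every compound in
#'   `dataset` (see [compute_descriptor_matrix()]).
#' @param scheme mixture-descriptor scheme, one of [mixture_schemes()].
#' @param estimator a [mix_estimator()]; its kind must match the dataset's
#'   endpoint kind.
#' @param scale feature scaling method (`"zscore"`, `"minmax"`, `"none"`),
#'   fitted on the training features.
#' @param seed integer seed passed to the estimator.
#' @return object of class `mixqspr`.
#' @examples
#' spec <- synthetic_spec(n_compounds = 15, n_pairs = 25,
#'                        compositions_per_mixture = 3,
#'                        interaction_strength = 0, compound_effect_sd = 0,
#'                        noise_sd = 0.01, endpoint = "bubble_like", seed = 7)
#' d <- generate_mixture_dataset(spec)
#' fit <- mixqspr(d, attr(d, "truth")$descriptors, scheme = "weighted_sum")
#' fit
#' head(residuals(fit))
#' @export
mixqspr <- function(dataset, descriptors, scheme = "weighted_sum",
                    estimator = NULL, scale = "zscore", seed = 1) {
  kind <- attr(dataset, "endpoint_kind")
  if (is.null(estimator)) {
    estimator <- if (kind == "classification") mix_estimator("rf", kind = "classification")
                 else mix_estimator("ridge")
  }
  if (estimator$kind != kind) {
    stop_mixqspr(sprintf("estimator kind '%s' does not match endpoint kind '%s'",
                         estimator$kind, kind), "mixqspr_config_error")
  }
  feats <- suppressWarnings(featurize_dataset(dataset, descriptors, scheme))
  scaler <- fit_scaler(feats$X, match.arg(scale, c("zscore", "minmax", "none")))
  Xs <- apply_scaler(scaler, feats$X)
  model <- estimator$fit(Xs, feats$y, seed = seed)

  obj <- structure(list(
    estimator = estimator, model = model, scaler = scaler,
    scheme = scheme, descriptors = descriptors,
    feature_names = feats$feature_names,
    property = attr(dataset, "property"), endpoint_kind = kind,
    n = nrow(dataset), seed = seed,
    y = feats$y, call = match.call()
  ), class = "mixqspr")
  obj$fitted <- predict_features(obj, feats$X)
  obj
}

predict_features <- function(object, X) {
  object$estimator$predict(object$model, apply_scaler(object$scaler, X))
}

#' Predict mixture properties for new data
#'
#' @param object a fitted [mixqspr()] model.
#' @param newdata a [mixture_dataset()] of mixtures to predict.
#' @param descriptors descriptor matrix covering the new compounds; defaults
#'   to the matrix stored in the model.
#' @param ... unused.
#' @return numeric vector (regression) or character label vector
#'   (classification), one prediction per record.
#' @export
predict.mixqspr <- function(object, newdata, descriptors = NULL, ...) {
  if (missing(newdata)) return(object$fitted)
  descriptors <- descriptors %||% object$descriptors
  feats <- suppressWarnings(featurize_dataset(newdata, descriptors, object$scheme))
  predict_features(object, feats$X)
}

#' @export
print.mixqspr <- function(x, ...) {
  cat(sprintf("<mixqspr> %s model for '%s'\n", x$endpoint_kind, x$property))
  cat(sprintf("  scheme: %s (%d features), estimator: %s, n = %d records\n",
              x$scheme, length(x$feature_names), x$estimator$id, x$n))
  if (x$endpoint_kind == "regression") {
    cat(sprintf("  training RMSE: %.4g\n", rmse(x$y, x$fitted)))
  } else {
    cat(sprintf("  training balanced accuracy: %.3f\n", balanced_accuracy(x$y, x$fitted)))
  }
  invisible(x)
}

#' @export
summary.mixqspr <- function(object, ...) {
  out <- list(model = object)
  if (object$endpoint_kind == "regression") {
    out$metrics <- c(
      r2 = tryCatch(r2_pearson(object$y, object$fitted), mixqspr_error = function(e) NA_real_),
      rmse = rmse(object$y, object$fitted)
    )
  } else {
    out$metrics <- c(balanced_accuracy = balanced_accuracy(object$y, object$fitted),
                     recall_per_class(object$y, object$fitted))
  }
  class(out) <- "summary.mixqspr"
  out
}

#' @export
print.summary.mixqspr <- function(x, ...) {
  print(x$model)
  cat("  training-set metrics:\n")
  for (nm in names(x$metrics)) cat(sprintf("    %s: %.4g\n", nm, x$metrics[[nm]]))
  invisible(x)
}

#' @export
coef.mixqspr <- function(object, ...) {
  if (!is.null(object$model$coef)) return(object$model$coef)
  stop_mixqspr(sprintf("estimator '%s' has no linear coefficients", object$estimator$id),
               "mixqspr_config_error")
}

#' @export
fitted.mixqspr <- function(object, ...) object$fitted

#' @export
residuals.mixqspr <- function(object, ...) {
  if (object$endpoint_kind != "regression") {
    stop_mixqspr("residuals are defined for regression models", "mixqspr_config_error")
  }
  object$y - object$fitted
}

#' @export
plot.mixqspr <- function(x, ...) {
  if (x$endpoint_kind != "regression") {
    stop_mixqspr("plot is defined for regression models", "mixqspr_config_error")
  }
  graphics::plot(x$y, x$fitted, xlab = "observed", ylab = "fitted",
                 main = sprintf("%s / %s", x$scheme, x$estimator$id), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
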