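#' Protocol-aware cross-validation
#'
#' Runs external cross-validation over a [fold_plan()]: for every fold, the
#' feature scaler and estimator are fitted on the fold's training records only
#' (for compounds-out plans the training set additionally excludes records
#' sharing a compound with the external fold's compound group; see
#' [fold_training_records()]), and metrics are computed on the fold's
#' records. Per-fold metrics are aggregated as mean and standard deviation
#' across folds; for regression, pooled out-of-fold statistics (`q2`, pooled
#' R2 and RMSE) are also reported because fold-averaged and pooled
#' correlation conventions differ. A fold whose metric is undefined (fewer
#' than 3 test records, constant truth or predictions) is reported as missing
#' for that fold, not as 0.
#'
#' @param dataset a [mixture_dataset()].
#' @param descriptors a `descriptor_matrix` covering all compounds.
#' @param scheme mixture-descriptor scheme, one of [mixture_schemes()].
#' @param plan a [fold_plan()] for `dataset`; its audit must report 0
#'   violations.
#' @param estimator a [mix_estimator()] matching the endpoint kind; default
#'   ridge regression / random-forest classification.
#' @param scale feature scaling method, fitted per fold on training rows.
#' @param seed integer; fold-level seeds are derived from it.
#' @param keep_fold_models keep each fold's fitted scaler and estimator in
#'   the report (for leakage inspection).
#' @return object of class `mixqspr_cv`: list with `per_fold` (data frame of
#'   per-fold metrics), `aggregate` (mean and sd per metric), `pooled`
#'   (regression only), `predictions` (out-of-fold prediction per record),
#'   `protocol`, `scheme`, `estimator_id`, `seed`.
#' @export
crossvalidate <- function(dataset, descriptors, scheme, plan, estimator = NULL,
                          scale = "zscore", seed = 1, keep_fold_models = FALSE) {
  kind <- attr(dataset, "endpoint_kind")
  if (is.null(estimator)) {
    estimator <- if (kind == "classification") mix_estimator("rf", kind = "classification")
                 else mix_estimator("ridge")
  }
  if (estimator$kind != kind) {
    stop_mixqspr(sprintf("estimator kind '%s' does not match endpoint kind '%s'",
                         estimator$kind, kind), "mixqspr_config_error")
  }
  if (plan$audit$violations > 0) {
    stop_mixqspr("fold plan fails its leakage audit; refusing to cross-validate",
                 "mixqspr_leakage_error")
  }
  scale <- match.arg(scale, c("zscore", "minmax", "none"))
  feats <- suppressWarnings(featurize_dataset(dataset, descriptors, scheme))
  n <- nrow(dataset)
  pooled_pred <- if (kind == "regression") rep(NA_real_, n) else rep(NA_character_, n)

  classes <- if (kind == "classification") sort(unique(as.character(feats$y))) else NULL
  per_fold <- list()
  fold_models <- list()

  for (f in seq_len(plan$k)) {
    train <- fold_training_records(plan, dataset, f)
    test <- which(plan$assignment == f)
    scaler <- fit_scaler(feats$X[train, , drop = FALSE], scale)
    Xtr <- apply_scaler(scaler, feats$X[train, , drop = FALSE])
    Xte <- apply_scaler(scaler, feats$X[test, , drop = FALSE])
    model <- estimator$fit(Xtr, feats$y[train], seed = seed + f)
    pred <- estimator$predict(model, Xte)
    pooled_pred[test] <- pred
    truth <- feats$y[test]

    safe <- function(expr) tryCatch(expr, mixqspr_undefined_metric = function(e) NA_real_)
    row <- if (kind == "regression") {
      data.frame(fold = f, n_test = length(test), n_train = length(train),
                 r2 = if (length(test) >= 3) safe(r2_pearson(truth, pred)) else NA_real_,
                 rmse = rmse(truth, pred))
    } else {
      rec <- recall_per_class(truth, pred)
      row <- data.frame(fold = f, n_test = length(test), n_train = length(train),
                        balanced_accuracy = safe(balanced_accuracy(truth, pred)))
      for (cl in classes) {
        row[[paste0("recall_", cl)]] <- if (cl %in% names(rec)) rec[[cl]] else NA_real_
      }
      row
    }
    per_fold[[f]] <- row
    if (keep_fold_models) fold_models[[f]] <- list(scaler = scaler, model = model)
  }

  per_fold <- do.call(rbind, per_fold)
  rownames(per_fold) <- NULL
  metric_cols <- setdiff(names(per_fold), c("fold", "n_test", "n_train"))
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metric_cols, function(m) stats::sd(per_fold[[m]], na.rm = TRUE), numeric(1)),
    row.names = NULL
  )

  pooled <- NULL
  if (kind == "regression") {
    pooled <- c(
      q2 = tryCatch(q2(feats$y, pooled_pred), mixqspr_undefined_metric = function(e) NA_real_),
      r2_pooled = tryCatch(r2_pearson(feats$y, pooled_pred),
                           mixqspr_undefined_metric = function(e) NA_real_),
      rmse_pooled = rmse(feats$y, pooled_pred)
    )
  }

  structure(list(per_fold = per_fold, aggregate = aggregate, pooled = pooled,
                 predictions = pooled_pred, protocol = plan$protocol, k = plan$k,
                 scheme = scheme, estimator_id = estimator$id, seed = seed,
                 fold_models = if (keep_fold_models) fold_models else NULL),
            class = "mixqspr_cv")
}

#' @export
print.mixqspr_cv <- function(x, ...) {
  cat(sprintf("<mixqspr_cv> %d-fold '%s' cross-validation, scheme '%s', estimator '%s'\n",
              x$k, x$protocol, x$scheme, x$estimator_id))
  for (i in seq_len(nrow(x$aggregate))) {
    cat(sprintf("  %s: %.3f ± %.3f\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  }
  if (!is.null(x$pooled)) {
    cat(sprintf("  pooled: Q2 = %.3f, R2 = %.3f, RMSE = %.4g\n",
                x$pooled[["q2"]], x$pooled[["r2_pooled"]], x$pooled[["rmse_pooled"]]))
  }
  invisible(x)
}

#' @export
summary.mixqspr_cv <- function(object, ...) {
  print(object)
  cat("  per-fold:\n")
  print(object$per_fold, row.names = FALSE)
  invisible(object)
}

#' Evaluate a model on a held-out dataset
#'
#' Trains on `train_dataset`, predicts `test_dataset`, and reports metrics
#' together with an overlap report between the two sets: shared mixtures
#' (unordered component pairs) and shared compounds. The overlap classifies
#' the holdout relative to training — `"points-out-like"` when mixtures are
#' shared, `"mixtures-out-like"` when only compounds are shared,
#' `"compounds-out-like"` when every test record has at least one compound
#' unseen in training, and `"mixed"` otherwise — mirroring how silently
#' duplicated mixtures between training and test sets bias reported accuracy.
#'
#' @param train_dataset,test_dataset [mixture_dataset()] objects sharing a
#'   property.
#' @inheritParams crossvalidate
#' @return object of class `mixqspr_holdout`: list with `metrics`, `overlap`
#'   (shared pairs/compounds and the holdout classification), `predictions`,
#'   and the fitted `model`.
#' @export
evaluate_holdout <- function(train_dataset, test_dataset, descriptors, scheme,
                             estimator = NULL, scale = "zscore", seed = 1) {
  if (nrow(test_dataset) == 0) {
    stop_mixqspr("empty test set", "mixqspr_config_error")
  }
  fit <- mixqspr(train_dataset, descriptors, scheme = scheme, estimator = estimator,
                 scale = scale, seed = seed)
  pred <- predict(fit, test_dataset)
  truth <- test_dataset$value

  train_pairs <- unique(pair_key(train_dataset$comp1, train_dataset$comp2)[!train_dataset$is_pure])
  test_pairs <- unique(pair_key(test_dataset$comp1, test_dataset$comp2)[!test_dataset$is_pure])
  shared_pairs <- intersect(train_pairs, test_pairs)
  train_cmp <- dataset_compounds(train_dataset)
  test_cmp <- dataset_compounds(test_dataset)
  shared_cmp <- intersect(train_cmp, test_cmp)

  novel_per_record <- vapply(seq_len(nrow(test_dataset)), function(i) {
    cmps <- c(test_dataset$comp1[i],
              if (!is.na(test_dataset$comp2[i])) test_dataset$comp2[i])
    any(!cmps %in% train_cmp)
  }, logical(1))

  classification <- if (length(shared_pairs)) "points-out-like"
    else if (all(novel_per_record)) "compounds-out-like"
    else if (all(test_cmp %in% train_cmp)) "mixtures-out-like"
    else "mixed"

  kind <- attr(train_dataset, "endpoint_kind")
  metrics <- if (kind == "regression") {
    c(r2 = tryCatch(r2_pearson(truth, pred), mixqspr_undefined_metric = function(e) NA_real_),
      rmse = rmse(truth, pred))
  } else {
    c(balanced_accuracy = tryCatch(balanced_accuracy(truth, pred),
                                   mixqspr_undefined_metric = function(e) NA_real_),
      recall_per_class(truth, pred))
  }

  structure(list(
    metrics = metrics,
    overlap = list(shared_mixtures = shared_pairs, n_shared_mixtures = length(shared_pairs),
                   shared_compounds = shared_cmp, n_shared_compounds = length(shared_cmp),
                   n_test_records_with_novel_compound = sum(novel_per_record),
                   classification = classification),
    predictions = pred, model = fit
  ), class = "mixqspr_holdout")
}

#' @export
print.mixqspr_holdout <- function(x, ...) {
  cat("<mixqspr_holdout>\n")
  cat(sprintf("  holdout classified as: %s (%d shared mixture(s), %d shared compound(s))\n",
              x$overlap$classification, x$overlap$n_shared_mixtures,
              x$overlap$n_shared_compounds))
  for (nm in names(x$metrics)) cat(sprintf("  %s: %.4g\n", nm, x$metrics[[nm]]))
  invisible(x)
}
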