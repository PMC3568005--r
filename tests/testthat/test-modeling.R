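test_that("a linear model recovers a perfectly learnable additive endpoint", {
  d <- generate_mixture_dataset(synthetic_spec(
    n_compounds = 30, n_pairs = 60, compositions_per_mixture = 5,
    interaction_strength = 0, compound_effect_sd = 0, noise_sd = 1e-6,
    endpoint = "bubble_like", seed = 14))
  desc <- attr(d, "truth")$descriptors
  plan <- suppressWarnings(points_out_folds(d, k = 10, seed = 3))
  cv <- crossvalidate(d, desc, "weighted_sum", plan, mix_estimator("ridge"), seed = 1)
  expect_gte(cv$aggregate$mean[cv$aggregate$metric == "r2"], 0.99)
  expect_gte(cv$pooled[["q2"]], 0.99)
})

test_that("the training-mean baseline scores Q2 near zero", {
  q2s <- vapply(1:10, function(s) {
    d <- generate_mixture_dataset(synthetic_spec(
      n_compounds = 20, n_pairs = 40, compositions_per_mixture = 4,
      endpoint = "bubble_like", seed = s))
    plan <- suppressWarnings(points_out_folds(d, k = 5, seed = s))
    cv <- crossvalidate(d, attr(d, "truth")$descriptors, "weighted_sum", plan,
                        mix_estimator("mean"), seed = s)
    cv$pooled[["q2"]]
  }, numeric(1))
  expect_true(all(abs(q2s) < 0.1))
})

test_that("cross-validation reports are byte-identical under identical inputs and seeds", {
  d <- toy_regression_dataset(seed = 4, n_compounds = 20, n_pairs = 35)
  desc <- attr(d, "truth")$descriptors
  run <- function() {
    plan <- fold_plan(d, "mixtures_out", k = 5, seed = 8)
    crossvalidate(d, desc, "weighted_sum_absdiff", plan, mix_estimator("rf"), seed = 6)
  }
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("test-fold targets never influence training-fold artifacts", {
  d <- toy_regression_dataset(seed = 12, n_compounds = 20, n_pairs = 35)
  desc <- attr(d, "truth")$descriptors
  plan <- fold_plan(d, "mixtures_out", k = 5, seed = 2)
  cv1 <- crossvalidate(d, desc, "weighted_sum", plan, mix_estimator("ridge"),
                       seed = 5, keep_fold_models = TRUE)

  noisy <- d
  test_rows <- which(plan$assignment == 1)
  noisy$value[test_rows] <- withr::with_seed(1, rnorm(length(test_rows), sd = 50))
  cv2 <- crossvalidate(noisy, desc, "weighted_sum", plan, mix_estimator("ridge"),
                       seed = 5, keep_fold_models = TRUE)

  # fold 1 trains without its own records: scaler and model unchanged
  expect_identical(serialize(cv1$fold_models[[1]], NULL),
                   serialize(cv2$fold_models[[1]], NULL))
  # sanity: other folds DO train on those records, so they must change
  expect_false(identical(serialize(cv1$fold_models[[2]], NULL),
                         serialize(cv2$fold_models[[2]], NULL)))
})

test_that("cross-validation refuses plans that fail their audit and mismatched estimators", {
  d <- toy_regression_dataset(seed = 3)
  desc <- attr(d, "truth")$descriptors
  po <- suppressWarnings(points_out_folds(d, k = 5, seed = 1))
  po$protocol <- "mixtures_out"
  po$audit <- audit_plan(po, d)
  expect_error(crossvalidate(d, desc, "weighted_sum", po, mix_estimator("ridge")),
               class = "mixqspr_leakage_error")

  plan <- fold_plan(d, "mixtures_out", k = 5, seed = 1)
  expect_error(crossvalidate(d, desc, "weighted_sum", plan,
                             mix_estimator("rf", kind = "classification")),
               class = "mixqspr_config_error")
})

test_that("classification cross-validation reports balanced accuracy and per-class recalls", {
  az <- generate_mixture_dataset(synthetic_spec(n_compounds = 30, n_pairs = 120,
                                                endpoint = "azeotrope_label", seed = 5))
  az <- augment_with_pure_compounds(az, policy = "zeotrope")
  plan <- fold_plan(az, "mixtures_out", k = 5, seed = 4)
  cv <- suppressWarnings(crossvalidate(az, attr(az, "truth")$descriptors, "sum_absdiff",
                                       plan, mix_estimator("rf", kind = "classification"),
                                       seed = 2))
  expect_setequal(cv$aggregate$metric,
                  c("balanced_accuracy", "recall_azeotrope", "recall_zeotrope"))
  ba <- cv$aggregate$mean[cv$aggregate$metric == "balanced_accuracy"]
  expect_gt(ba, 0.5)  # should beat chance on its own generating signal
  expect_equal(cv$aggregate$mean[1],
               mean(cv$per_fold[[cv$aggregate$metric[1]]], na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("the fitted-model object supports the standard methods", {
  d <- generate_mixture_dataset(synthetic_spec(
    n_compounds = 20, n_pairs = 40, compositions_per_mixture = 4,
    interaction_strength = 0, compound_effect_sd = 0, noise_sd = 0.01,
    endpoint = "bubble_like", seed = 21))
  desc <- attr(d, "truth")$descriptors
  fit <- mixqspr(d, desc, scheme = "weighted_sum", estimator = mix_estimator("ridge"),
                 scale = "none", seed = 1)
  expect_s3_class(fit, "mixqspr")
  expect_output(print(fit), "ridge")
  expect_output(print(summary(fit)), "training-set metrics")

  cf <- coef(fit)
  expect_true("(Intercept)" %in% names(cf))
  expect_length(residuals(fit), nrow(d))
  expect_lt(rmse(d$value, fitted(fit)), 0.05)

  preds <- predict(fit, d)
  expect_equal(preds, fitted(fit))

  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))

  # coefficients approximate the generating weights (additive, tiny noise)
  w <- attr(d, "truth")$weights
  beta <- cf[paste0(colnames(desc), "_wsum")]
  cosine <- sum(beta * w) / sqrt(sum(beta^2) * sum(w^2))
  expect_gt(cosine, 0.999)
})

test_that("holdout evaluation reports overlap and classifies the split", {
  train <- toy_regression_dataset(seed = 31, n_compounds = 20, n_pairs = 30)
  desc <- attr(train, "truth")$descriptors

  # mixtures-out-like: new pairs of known compounds
  all_keys <- pair_key(train$comp1, train$comp2)
  held_key <- unique(all_keys[!train$is_pure])[1]
  test_d <- mixture_dataset(as.data.frame(train)[all_keys == held_key, ],
                            property = attr(train, "property"))
  train_d <- mixture_dataset(as.data.frame(train)[all_keys != held_key, ],
                             property = attr(train, "property"))
  hold <- evaluate_holdout(train_d, test_d, desc, "weighted_sum",
                           mix_estimator("ridge"))
  expect_equal(hold$overlap$classification, "mixtures-out-like")
  expect_equal(hold$overlap$n_shared_mixtures, 0)

  # a deliberately duplicated mixture flips the classification and is flagged
  leaky_test <- mixture_dataset(rbind(as.data.frame(test_d),
                                      as.data.frame(train_d)[1, ]),
                                property = attr(train, "property"))
  hold2 <- evaluate_holdout(train_d, leaky_test, desc, "weighted_sum",
                            mix_estimator("ridge"))
  expect_equal(hold2$overlap$n_shared_mixtures, 1)
  expect_equal(hold2$overlap$classification, "points-out-like")

  expect_error(evaluate_holdout(train_d, train_d[0, ], desc, "weighted_sum"),
               class = "mixqspr_config_error")
})

test_that("compounds-out holdouts are harder than mixtures-out holdouts of equal size", {
  diffs <- vapply(1:10, function(s) {
    d <- generate_mixture_dataset(synthetic_spec(n_compounds = 24, n_pairs = 60,
                                                 compositions_per_mixture = 5,
                                                 endpoint = "bubble_like", seed = 100 + s))
    desc <- attr(d, "truth")$descriptors
    df <- as.data.frame(d)
    keys <- pair_key(d$comp1, d$comp2)

    # compounds-out holdout: every record touching 4 held-out compounds
    held_cmp <- withr::with_seed(s, sample(dataset_compounds(d), 4))
    co_rows <- which(df$comp1 %in% held_cmp |
                       (!is.na(df$comp2) & df$comp2 %in% held_cmp))
    co_test <- mixture_dataset(df[co_rows, ], property = attr(d, "property"))
    co_train <- mixture_dataset(df[-co_rows, ], property = attr(d, "property"))

    # mixtures-out holdout of comparable size from the remaining data
    pool <- unique(keys[!df$is_pure & !(seq_len(nrow(df)) %in% co_rows)])
    mo_keys <- withr::with_seed(s, sample(pool, ceiling(length(co_rows) / 5)))
    mo_rows <- which(keys %in% mo_keys)
    mo_test <- mixture_dataset(df[mo_rows, ], property = attr(d, "property"))
    mo_train <- mixture_dataset(df[-mo_rows, ], property = attr(d, "property"))

    co <- evaluate_holdout(co_train, co_test, desc, "weighted_sum", mix_estimator("knn"))
    mo <- evaluate_holdout(mo_train, mo_test, desc, "weighted_sum", mix_estimator("knn"))
    co$metrics[["rmse"]] - mo$metrics[["rmse"]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("consensus averaging blends regression predictions", {
  d <- toy_regression_dataset(seed = 17, n_compounds = 15, n_pairs = 25)
  desc <- attr(d, "truth")$descriptors
  ft <- featurize_dataset(d, desc, "weighted_sum")
  cons <- consensus_estimator(list(mix_estimator("ridge"), mix_estimator("knn")))
  model <- cons$fit(ft$X, ft$y, seed = 1)
  pred <- cons$predict(model, ft$X)
  r <- mix_estimator("ridge"); k <- mix_estimator("knn")
  pr <- r$predict(r$fit(ft$X, ft$y, seed = 2), ft$X)
  pk <- k$predict(k$fit(ft$X, ft$y, seed = 3), ft$X)
  expect_equal(pred, (pr + pk) / 2, tolerance = 1e-10)
  expect_error(consensus_estimator(list(mix_estimator("rf", kind = "classification"))),
               class = "mixqspr_config_error")
})
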