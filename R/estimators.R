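#' Pluggable estimator specifications
#'
#' Any learner satisfying a `fit(X, y, seed)` / `predict(model, X)` contract
#' can be used for model building; predictions must be deterministic given
#' the seed. Shipped estimators:
#'
#' * `"ridge"` — regularized linear regression (closed-form solve of the
#'   centered normal equations); with the default small `lambda` it is
#'   essentially ordinary least squares.
#' * `"svr"` / `"svc"` — support-vector regression / classification with an
#'   RBF kernel (\pkg{e1071}).
#' * `"rf"` — random forest regression or classification
#'   (\pkg{randomForest}).
#' * `"knn"` — k-nearest-neighbour regression or classification (\pkg{FNN}).
#' * `"mean"` — predicts the training mean (regression) or majority class; a
#'   null baseline (its pooled Q2 is about 0 by construction).
#'
#' `consensus_estimator()` averages the predictions of several regression
#' estimators (simple mean), mirroring consensus modeling; it is optional and
#' never applied implicitly.
#'
#' @param id one of `"ridge"`, `"svr"`, `"svc"`, `"rf"`, `"knn"`, `"mean"`.
#' @param kind `"regression"` or `"classification"`; defaults to the natural
#'   kind of `id`.
#' @param ... hyperparameters: `lambda` (ridge, default `1e-6`), `cost`,
#'   `gamma`, `epsilon` (SVM), `ntree`, `mtry` (random forest), `k`
#'   (neighbours, default 5).
#' @return object of class `mix_estimator` with elements `id`, `kind`,
#'   `hyperparameters`, `fit`, `predict`.
#' @examples
#' est <- mix_estimator("ridge")
#' fit <- est$fit(cbind(x = 1:10), y = 2 * (1:10) + 1, seed = 1)
#' est$predict(fit, cbind(x = c(2.5, 7.5)))
#' @export
mix_estimator <- function(id = c("ridge", "svr", "svc", "rf", "knn", "mean"),
                          kind = NULL, ...) {
  id <- match.arg(id)
  hyper <- list(...)
  default_kind <- switch(id, ridge = "regression", svr = "regression",
                         svc = "classification", rf = "regression",
                         knn = "regression", mean = "regression")
  kind <- kind %||% default_kind
  kind <- match.arg(kind, c("regression", "classification"))
  if (id %in% c("ridge", "svr") && kind == "classification") {
    stop_mixqspr(sprintf("estimator '%s' is regression-only", id), "mixqspr_config_error")
  }
  if (id == "svc" && kind == "regression") {
    stop_mixqspr("estimator 'svc' is classification-only", "mixqspr_config_error")
  }

  fit <- switch(id,
    ridge = function(X, y, seed = 1) {
      # closed-form ridge on centered data; lambda > 0 keeps the normal
      # equations well-posed under collinearity
      lambda <- hyper$lambda %||% 1e-6
      keep <- apply(X, 2, function(col) max(col) > min(col))
      if (!any(keep)) {
        return(list(coef = stats::setNames(mean(y), "(Intercept)"),
                    features = character(0)))
      }
      Xk <- X[, keep, drop = FALSE]
      mu <- colMeans(Xk)
      Xc <- sweep(Xk, 2, mu, "-")
      yc <- y - mean(y)
      beta <- drop(solve(crossprod(Xc) + diag(lambda, ncol(Xc)), crossprod(Xc, yc)))
      cf <- c("(Intercept)" = mean(y) - sum(mu * beta),
              stats::setNames(beta, colnames(Xk)))
      list(coef = cf, features = colnames(X)[keep])
    },
    svr = function(X, y, seed = 1) {
      with_seed(seed, do.call(e1071::svm, c(list(x = X, y = y, type = "eps-regression",
                                                 kernel = "radial"),
                                            hyper[names(hyper) %in% c("cost", "gamma", "epsilon")])))
    },
    svc = function(X, y, seed = 1) {
      with_seed(seed, do.call(e1071::svm, c(list(x = X, y = factor(y),
                                                 type = "C-classification",
                                                 kernel = "radial"),
                                            hyper[names(hyper) %in% c("cost", "gamma")])))
    },
    rf = function(X, y, seed = 1) {
      yy <- if (kind == "classification") factor(y) else y
      with_seed(seed, do.call(randomForest::randomForest,
                              c(list(x = X, y = yy,
                                     ntree = hyper$ntree %||% 200),
                                hyper[names(hyper) %in% "mtry"])))
    },
    knn = function(X, y, seed = 1) {
      list(X = X, y = y, k = hyper$k %||% 5, seed = seed)
    },
    mean = function(X, y, seed = 1) {
      if (kind == "classification") {
        tab <- sort(table(y), decreasing = TRUE)
        list(value = names(tab)[1])
      } else {
        list(value = mean(y))
      }
    })

  predict_fn <- switch(id,
    ridge = function(model, X) {
      drop(cbind(1, X[, model$features, drop = FALSE]) %*% model$coef)
    },
    svr = ,
    svc = function(model, X) {
      p <- stats::predict(model, X)
      if (is.factor(p)) as.character(p) else as.numeric(p)
    },
    rf = function(model, X) {
      p <- stats::predict(model, X)
      if (is.factor(p)) as.character(p) else as.numeric(p)
    },
    knn = function(model, X) {
      if (kind == "classification") {
        with_seed(model$seed,
                  as.character(FNN::knn(model$X, X, factor(model$y), k = model$k)))
      } else {
        FNN::knn.reg(model$X, X, model$y, k = model$k)$pred
      }
    },
    mean = function(model, X) {
      rep(if (is.character(model$value)) model$value else model$value, nrow(X))
    })

  structure(list(id = id, kind = kind, hyperparameters = hyper,
                 fit = fit, predict = predict_fn),
            class = "mix_estimator")
}

#' @rdname mix_estimator
#' @param estimators list of regression `mix_estimator` objects.
#' @export
consensus_estimator <- function(estimators) {
  if (!length(estimators) || !all(vapply(estimators, inherits, logical(1), "mix_estimator"))) {
    stop_mixqspr("consensus_estimator takes a list of mix_estimator objects",
                 "mixqspr_config_error")
  }
  if (any(vapply(estimators, function(e) e$kind, character(1)) != "regression")) {
    stop_mixqspr("consensus averaging is defined for regression estimators",
                 "mixqspr_config_error")
  }
  structure(list(
    id = paste0("consensus(", paste(vapply(estimators, `[[`, character(1), "id"),
                                    collapse = "+"), ")"),
    kind = "regression",
    hyperparameters = list(),
    fit = function(X, y, seed = 1) {
      lapply(seq_along(estimators), function(i) estimators[[i]]$fit(X, y, seed + i))
    },
    predict = function(model, X) {
      preds <- vapply(seq_along(estimators),
                      function(i) estimators[[i]]$predict(model[[i]], X),
                      numeric(nrow(X)))
      rowMeans(preds)
    }),
    class = "mix_estimator")
}

#' @export
print.mix_estimator <- function(x, ...) {
  cat(sprintf("<mix_estimator> %s (%s)\n", x$id, x$kind))
  invisible(x)
}
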