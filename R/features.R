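#' Mixture-descriptor construction schemes
#'
#' Builds the descriptor vector of a binary mixture from the descriptor
#' vectors `D1`, `D2` of its two components. Four schemes are available, in
#' two families:
#'
#' * Concentration-independent family (one property value per mixture):
#'   `mix_average()` is the unweighted elementwise mean `(D1 + D2) / 2`;
#'   `mix_sum_absdiff()` concatenates the elementwise sum and absolute
#'   difference `[D1 + D2, |D1 - D2|]` (2m features).
#' * Concentration-dependent family (property varies with composition):
#'   `mix_weighted_sum()` is the mole-fraction-weighted sum
#'   `x1*D1 + (1 - x1)*D2`; `mix_weighted_sum_absdiff()` concatenates the
#'   weighted sum with the weighted absolute difference
#'   `|x1*D1 - (1 - x1)*D2|` (2m features).
#'
#' All four forms are invariant under relabeling the components
#' (`(D1, D2, x1)` vs `(D2, D1, 1 - x1)`), which together with
#' majority-component-first storage makes featurization independent of how a
#' mixture was entered.
#'
#' @param D1,D2 numeric descriptor vectors of equal length (component 1 is
#'   the majority component).
#' @param x1 molar fraction of component 1, in `[0.5, 1]`.
#' @return numeric feature vector (length m, or 2m for the `_absdiff` forms).
#' @examples
#' mix_average(c(2, 4), c(0, 8))
#' mix_weighted_sum(c(2, 4), c(0, 8), x1 = 0.75)
#' @export
mix_average <- function(D1, D2) {
  check_dims(D1, D2)
  (D1 + D2) / 2
}

#' @rdname mix_average
#' @export
mix_sum_absdiff <- function(D1, D2) {
  check_dims(D1, D2)
  c(D1 + D2, abs(D1 - D2))
}

#' @rdname mix_average
#' @export
mix_weighted_sum <- function(D1, D2, x1) {
  check_dims(D1, D2)
  check_x1(x1)
  x1 * D1 + (1 - x1) * D2
}

#' @rdname mix_average
#' @export
mix_weighted_sum_absdiff <- function(D1, D2, x1) {
  check_dims(D1, D2)
  check_x1(x1)
  c(x1 * D1 + (1 - x1) * D2, abs(x1 * D1 - (1 - x1) * D2))
}

check_dims <- function(D1, D2) {
  if (length(D1) != length(D2)) {
    stop_mixqspr(sprintf("descriptor vectors differ in length (%d vs %d)",
                         length(D1), length(D2)), "mixqspr_dimension_error")
  }
  invisible(TRUE)
}

check_x1 <- function(x1) {
  if (!is_scalar_number(x1) || x1 < 0.5 || x1 > 1) {
    stop_mixqspr("x1 must be a single number in [0.5, 1]", "mixqspr_domain_error")
  }
  invisible(TRUE)
}

#' Available scheme names
#' @return character vector of the four scheme identifiers.
#' @export
mixture_schemes <- function() {
  c("average", "sum_absdiff", "weighted_sum", "weighted_sum_absdiff")
}

scheme_feature_names <- function(scheme, descriptor_names) {
  switch(scheme,
    average = paste0(descriptor_names, "_avg"),
    sum_absdiff = c(paste0(descriptor_names, "_sum"), paste0(descriptor_names, "_absdiff")),
    weighted_sum = paste0(descriptor_names, "_wsum"),
    weighted_sum_absdiff = c(paste0(descriptor_names, "_wsum"),
                             paste0(descriptor_names, "_wabsdiff")))
}

#' Featurize a mixture dataset under a scheme
#'
#' Computes one mixture feature row per record from the per-compound
#' descriptor matrix. Pure-compound records (`x1 = 1`, no second component)
#' are featurized consistently with their degenerate-mixture reading: under
#' the weighted schemes the second component contributes nothing
#' (`D2 = 0, x1 = 1`), so the row reduces to the compound's own descriptor
#' vector (with a zero weighted-difference block); under the unweighted
#' schemes the pure compound is treated as a mixture of itself
#' (`D1 = D2`), so the absolute-difference block is zero.
#'
#' The unweighted family is meant for concentration-independent endpoints and
#' the weighted family for concentration-dependent ones; a mismatch is
#' allowed but warned about.
#'
#' @param dataset a [mixture_dataset()].
#' @param matrix a `descriptor_matrix` covering every compound in `dataset`.
#' @param scheme one of [mixture_schemes()].
#' @return object of class `mixture_features`: list with numeric matrix `X`
#'   (one row per record), `y` (target values), `feature_names`, `scheme`,
#'   and `record_keys` (row indices into `dataset`).
#' @export
featurize_dataset <- function(dataset, matrix, scheme = mixture_schemes()) {
  scheme <- match.arg(scheme)
  compounds <- dataset_compounds(dataset)
  uncovered <- setdiff(compounds, rownames(matrix))
  if (length(uncovered)) {
    stop_mixqspr(paste0("descriptor matrix does not cover compound(s): ",
                        paste(uncovered, collapse = ", ")),
                 "mixqspr_coverage_error")
  }
  weighted <- scheme %in% c("weighted_sum", "weighted_sum_absdiff")
  if (weighted && !attr(dataset, "concentration_dependent")) {
    warning("weighted schemes are intended for concentration-dependent endpoints")
  }
  if (!weighted && attr(dataset, "concentration_dependent")) {
    warning("unweighted schemes are intended for one-value-per-mixture endpoints")
  }

  m <- ncol(matrix)
  n <- nrow(dataset)
  D1 <- unclass(matrix)[dataset$comp1, , drop = FALSE]
  zero <- matrix(0, n, m)
  comp2 <- ifelse(is.na(dataset$comp2), dataset$comp1, dataset$comp2)
  D2 <- unclass(matrix)[comp2, , drop = FALSE]
  if (weighted) {
    # pure records: absent second component contributes nothing
    D2[dataset$is_pure, ] <- 0
  }
  x1 <- dataset$x1
  X <- switch(scheme,
    average = (D1 + D2) / 2,
    sum_absdiff = cbind(D1 + D2, abs(D1 - D2)),
    weighted_sum = x1 * D1 + (1 - x1) * D2,
    weighted_sum_absdiff = cbind(x1 * D1 + (1 - x1) * D2,
                                 abs(x1 * D1 - (1 - x1) * D2)))
  feature_names <- scheme_feature_names(scheme, colnames(matrix))
  dimnames(X) <- list(NULL, feature_names)

  structure(list(X = X, y = dataset$value, feature_names = feature_names,
                 scheme = scheme, record_keys = seq_len(n),
                 backend_id = attr(matrix, "backend_id")),
            class = "mixture_features")
}

#' @export
print.mixture_features <- function(x, ...) {
  cat(sprintf("<mixture_features> %d record(s) x %d feature(s), scheme '%s'\n",
              nrow(x$X), ncol(x$X), x$scheme))
  invisible(x)
}
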