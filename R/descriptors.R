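#' Per-compound descriptor backends
#'
#' A descriptor backend is a deterministic function mapping a character vector
#' of canonical structures to a numeric matrix (one row per structure, named
#' columns). Any external descriptor engine can be plugged in through this
#' contract or through a precomputed cache table ([read_descriptor_cache()]).
#'
#' `descriptor_backend_openbabel()` computes the Open Babel physicochemical
#' set (molecular weight, logP, TPSA, molar refractivity, H-bond donors and
#' acceptors, ...) from SMILES via \pkg{ChemmineOB}.
#' `descriptor_backend_toy()` derives a small deterministic numeric profile
#' from the structure string itself (length, character counts); it has no
#' chemical meaning and exists so that pipelines and tests run without a
#' chemistry toolkit.
#'
#' @return a function of class `mix_descriptor_backend` with a `backend_id`
#'   attribute.
#' @export
descriptor_backend_toy <- function() {
  f <- function(structures) {
    structures <- as.character(structures)
    feats <- function(s) {
      chars <- strsplit(s, "")[[1]]
      c(length = nchar(s),
        n_c = sum(chars %in% c("C", "c")),
        n_o = sum(chars %in% c("O", "o")),
        n_n = sum(chars %in% c("N", "n")),
        n_digit = sum(grepl("[0-9]", chars)),
        n_branch = sum(chars == "("),
        n_upper = sum(grepl("[A-Z]", chars)),
        checksum = sum(utf8ToInt(s)) %% 97)
    }
    m <- t(vapply(structures, feats, numeric(8)))
    rownames(m) <- structures
    m
  }
  structure(f, class = c("mix_descriptor_backend", "function"), backend_id = "toy")
}

#' @rdname descriptor_backend_toy
#' @export
descriptor_backend_openbabel <- function() {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop_mixqspr("ChemmineR/ChemmineOB are required for the Open Babel backend",
                 "mixqspr_config_error")
  }
  f <- function(structures) {
    structures <- as.character(structures)
    sdf <- ChemmineR::smiles2sdf(stats::setNames(structures, structures))
    p <- ChemmineR::propOB(sdf)
    num <- p[, vapply(p, is.numeric, logical(1)), drop = FALSE]
    m <- as.matrix(num)
    rownames(m) <- structures
    m
  }
  structure(f, class = c("mix_descriptor_backend", "function"),
            backend_id = "openbabel_prop")
}

#' Compute a per-compound descriptor matrix
#'
#' Runs a descriptor backend over a set of compounds and assembles a
#' `descriptor_matrix`: a numeric matrix with one row per canonical structure
#' and unique descriptor names as columns. Columns that are constant across
#' all compounds carry no information and are dropped; columns containing any
#' non-finite value are dropped with a warning (column drop, not imputation,
#' so cross-validation folds stay comparable). Row content is independent of
#' the order in which compounds are supplied.
#'
#' @param compounds character vector of canonical structures (duplicates
#'   ignored).
#' @param backend a descriptor backend; see [descriptor_backend_toy()].
#' @param select optional character vector restricting the columns (applied
#'   after computation); unknown names are an error.
#' @return numeric matrix of class `descriptor_matrix` with attribute
#'   `backend_id`.
#' @export
compute_descriptor_matrix <- function(compounds, backend = descriptor_backend_toy(),
                                      select = NULL) {
  compounds <- sort(unique(as.character(compounds)))
  rows <- vector("list", length(compounds))
  failed <- character(0)
  for (i in seq_along(compounds)) {
    rows[[i]] <- tryCatch(backend(compounds[i]), error = function(e) e)
    if (inherits(rows[[i]], "condition")) failed <- c(failed, compounds[i])
  }
  if (length(failed)) {
    stop_mixqspr(paste0("descriptor backend failed for compound(s): ",
                        paste(failed, collapse = ", ")),
                 "mixqspr_backend_error")
  }
  m <- do.call(rbind, rows)
  rownames(m) <- compounds
  if (anyDuplicated(colnames(m))) {
    stop_mixqspr("backend returned duplicated descriptor names", "mixqspr_backend_error")
  }
  m <- drop_uninformative_columns(m)
  if (!is.null(select)) {
    unknown <- setdiff(select, colnames(m))
    if (length(unknown)) {
      stop_mixqspr(paste0("requested descriptor(s) not available: ",
                          paste(unknown, collapse = ", ")),
                   "mixqspr_selection_error")
    }
    m <- m[, select, drop = FALSE]
  }
  as_descriptor_matrix(m, backend_id = attr(backend, "backend_id") %||% "custom")
}

# constant columns and columns with non-finite entries are removed; the two
# rules commute, so application order does not matter
drop_uninformative_columns <- function(m, warn = TRUE) {
  bad <- colSums(!is.finite(m)) > 0
  if (any(bad) && warn) {
    warning(sprintf("dropping %d descriptor column(s) with non-finite values: %s",
                    sum(bad), paste(colnames(m)[bad], collapse = ", ")))
  }
  m <- m[, !bad, drop = FALSE]
  if (nrow(m) > 1) {
    const <- apply(m, 2, function(col) max(col) == min(col))
    m <- m[, !const, drop = FALSE]
  }
  m
}

#' @rdname compute_descriptor_matrix
#' @param x numeric matrix (rownames = canonical structures).
#' @param backend_id identifier of the producing backend.
#' @export
as_descriptor_matrix <- function(x, backend_id = "custom") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) {
    stop_mixqspr("descriptor matrix needs structure rownames", "mixqspr_schema_error")
  }
  if (anyDuplicated(colnames(x))) {
    stop_mixqspr("descriptor names must be unique", "mixqspr_schema_error")
  }
  structure(x, class = c("descriptor_matrix", "matrix", "array"),
            backend_id = backend_id)
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compound(s) x %d descriptor(s), backend '%s'\n",
              nrow(x), ncol(x), attr(x, "backend_id")))
  print(utils::head(unclass(x), 4))
  invisible(x)
}

#' Read a precomputed descriptor cache
#'
#' Accepts the output of any external descriptor engine as a tabular file:
#' first column the canonical structure, remaining columns numeric descriptor
#' values with a header row.
#'
#' @param path csv file path.
#' @param backend_id identifier recorded on the matrix.
#' @return a `descriptor_matrix`.
#' @export
read_descriptor_cache <- function(path, backend_id = "cache") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  as_descriptor_matrix(drop_uninformative_columns(m), backend_id = backend_id)
}

#' Column scaling with train-only fitting
#'
#' Fits per-column scaling statistics on a subset of compounds only, so that
#' cross-validation can scale descriptors without information from test folds.
#' `zscore` centers and scales to unit variance; columns degenerate (zero
#' variance) on the fit set map to 0. `minmax` maps the fit-set range to
#' `[0, 1]`. `none` is the identity.
#'
#' @param matrix a `descriptor_matrix` (or any numeric matrix with rownames).
#' @param method `"none"`, `"zscore"`, or `"minmax"`.
#' @param fit_on rownames (compounds) used to fit the statistics; defaults to
#'   all rows.
#' @return list with `matrix` (all rows transformed) and `scaler` (an object
#'   usable with [apply_scaler()] and [invert_scaler()]).
#' @export
scale_columns <- function(matrix, method = c("none", "zscore", "minmax"),
                          fit_on = rownames(matrix)) {
  method <- tryCatch(match.arg(method),
                     error = function(e) stop_mixqspr(
                       paste("unknown scaling method:", method[1]), "mixqspr_config_error"))
  if (!length(fit_on)) stop_mixqspr("fit_on must be non-empty", "mixqspr_config_error")
  missing <- setdiff(fit_on, rownames(matrix))
  if (length(missing)) {
    stop_mixqspr(paste0("fit_on rows absent from matrix: ", paste(missing, collapse = ", ")),
                 "mixqspr_config_error")
  }
  scaler <- fit_scaler(matrix[fit_on, , drop = FALSE], method)
  out <- apply_scaler(scaler, matrix)
  attributes(out) <- attributes(matrix)
  dimnames(out) <- dimnames(matrix)
  list(matrix = out, scaler = scaler)
}

fit_scaler <- function(X, method) {
  X <- as.matrix(X)
  sc <- switch(method,
    none = list(method = "none"),
    zscore = {
      mu <- colMeans(X)
      sd <- apply(X, 2, stats::sd)
      if (nrow(X) == 1L) sd[] <- 0
      list(method = "zscore", center = mu, scale = sd)
    },
    minmax = {
      lo <- apply(X, 2, min)
      hi <- apply(X, 2, max)
      list(method = "minmax", lo = lo, range = hi - lo)
    })
  structure(sc, class = "mix_scaler", feature_names = colnames(X))
}

#' @rdname scale_columns
#' @param scaler a fitted scaler from [scale_columns()].
#' @param newdata numeric matrix with the same columns.
#' @export
apply_scaler <- function(scaler, newdata) {
  X <- as.matrix(newdata)
  switch(scaler$method,
    none = X,
    zscore = {
      s <- ifelse(scaler$scale > 0, scaler$scale, Inf)  # degenerate columns -> 0
      sweep(sweep(X, 2, scaler$center, "-"), 2, s, "/")
    },
    minmax = {
      r <- ifelse(scaler$range > 0, scaler$range, Inf)
      sweep(sweep(X, 2, scaler$lo, "-"), 2, r, "/")
    })
}

#' @rdname scale_columns
#' @param scaled numeric matrix of scaled values.
#' @export
invert_scaler <- function(scaler, scaled) {
  X <- as.matrix(scaled)
  switch(scaler$method,
    none = X,
    zscore = {
      s <- ifelse(scaler$scale > 0, scaler$scale, 0)
      sweep(sweep(X, 2, s, "*"), 2, scaler$center, "+")
    },
    minmax = {
      r <- ifelse(scaler$range > 0, scaler$range, 0)
      sweep(sweep(X, 2, r, "*"), 2, scaler$lo, "+")
    })
}
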