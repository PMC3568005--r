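#' Canonicalize one raw mixture data point
#'
#' Turns one row of the upload dialect into a canonical mixture record. The
#' majority component is always stored first, so the stored molar fraction
#' `x1` lies in `[0.5, 1]`: when the reported fraction of the first compound is
#' below 0.5 the two components are interchanged and the complement to 1 is
#' used as the molar fraction. At the equimolar point (`x1 = 0.5`) components
#' are ordered by lexicographic canonical structure so every mixture has one
#' storage form. A fraction of exactly 1 denotes a pure compound and the
#' second component is absent. The fraction of the second component is never
#' stored; it is always `1 - x1`.
#'
#' @param raw_row named list or one-row data frame with elements `SMILES1`
#'   (or `MOL1`, a path to an SDF/MOL file), `MOLAR_FRACTION`, `SMILES2` (or
#'   `MOLID2`/`MOL2`), `VALUE`, and optionally `PROPERTY`, `UNIT`, `SOURCE`,
#'   `NAME2`.
#' @param canonicalizer structure canonicalization backend; see
#'   [canonicalizer_identity()].
#' @return object of class `mixture_record`: a named list with fields
#'   `comp1`, `comp2` (`NA` for a pure compound), `x1`, `property`, `value`,
#'   `unit`, `source`, `is_pure`.
#' @examples
#' canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = 0.3,
#'                          SMILES2 = "B", VALUE = 1.2))
#' @export
canonicalize_record <- function(raw_row, canonicalizer = canonicalizer_identity()) {
  raw_row <- as.list(raw_row)
  get_chr <- function(nm) {
    v <- raw_row[[nm]]
    if (is.null(v) || length(v) == 0L) return(NA_character_)
    v <- as.character(v)[1]
    if (is.na(v) || trimws(v) == "") NA_character_ else trimws(v)
  }

  s1 <- get_chr("SMILES1")
  if (is.na(s1) && !is.na(get_chr("MOL1"))) {
    s1 <- read_structure_file(get_chr("MOL1"), canonicalizer)
  }
  if (is.na(s1)) {
    stop_mixqspr("row has no parsable structure for component 1", "mixqspr_structure_error")
  }

  f <- suppressWarnings(as.numeric(raw_row[["MOLAR_FRACTION"]]))
  if (length(f) != 1L || is.na(f)) {
    stop_mixqspr("molar fraction is missing or not numeric", "mixqspr_domain_error")
  }
  if (f <= 0 || f > 1) {
    stop_mixqspr(sprintf("molar fraction %g outside (0, 1]", f), "mixqspr_domain_error")
  }

  s2 <- get_chr("SMILES2")
  if (is.na(s2)) s2 <- get_chr("MOLID2")
  if (is.na(s2) && !is.na(get_chr("MOL2"))) {
    s2 <- read_structure_file(get_chr("MOL2"), canonicalizer)
  }
  if (f < 1 && is.na(s2)) {
    stop_mixqspr("mixture row (fraction < 1) lacks a second component",
                 "mixqspr_incomplete_record_error")
  }

  value <- suppressWarnings(as.numeric(raw_row[["VALUE"]]))
  if (length(value) != 1L || is.na(value)) {
    # classification labels are kept verbatim
    value <- get_chr("VALUE")
    if (is.na(value)) {
      stop_mixqspr("VALUE is missing", "mixqspr_domain_error")
    }
  }

  comp1 <- canonicalizer(s1)
  if (f == 1) {
    comp2 <- NA_character_
    x1 <- 1
  } else {
    comp2 <- canonicalizer(s2)
    x1 <- f
    if (x1 < 0.5 || (x1 == 0.5 && comp1 > comp2)) {
      tmp <- comp1; comp1 <- comp2; comp2 <- tmp
      x1 <- 1 - x1
    }
  }

  structure(list(
    comp1 = comp1, comp2 = comp2, x1 = x1,
    property = get_chr("PROPERTY") %||% NA_character_,
    value = value,
    unit = get_chr("UNIT"), source = get_chr("SOURCE"),
    is_pure = x1 == 1
  ), class = "mixture_record")
}

#' @export
print.mixture_record <- function(x, ...) {
  if (x$is_pure) {
    cat(sprintf("<mixture_record> pure %s  value=%s\n", x$comp1, format(x$value)))
  } else {
    cat(sprintf("<mixture_record> %s (x1=%.4g) + %s  value=%s\n",
                x$comp1, x$x1, x$comp2, format(x$value)))
  }
  invisible(x)
}

#' Assemble a binary-mixture dataset
#'
#' A `mixture_dataset` is a data frame of canonical mixture records (columns
#' `comp1`, `comp2`, `x1`, `property`, `value`, `unit`, `source`, `is_pure`)
#' carrying the endpoint metadata as attributes. All records must share one
#' property and one unit; mismatched units in a single dataset are an error
#' (no unit conversion is attempted).
#'
#' @param records data frame of canonical records, e.g. rows built with
#'   [canonicalize_record()].
#' @param property common property name; defaults to the (unique) value found
#'   in `records`.
#' @param endpoint_kind `"regression"` or `"classification"`.
#' @param concentration_dependent logical; `TRUE` when a mixture is measured
#'   at several compositions (many records per component pair), `FALSE` when
#'   each mixture has a single property value.
#' @return object of class `mixture_dataset` (a data frame).
#' @export
mixture_dataset <- function(records, property = NULL,
                            endpoint_kind = c("regression", "classification"),
                            concentration_dependent = TRUE) {
  endpoint_kind <- match.arg(endpoint_kind)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("comp1", "x1", "value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop_mixqspr(paste("records lack column(s):", paste(missing_cols, collapse = ", ")),
                 "mixqspr_schema_error")
  }
  if (!"comp2" %in% names(records)) records$comp2 <- NA_character_
  for (nm in c("property", "unit", "source")) {
    if (!nm %in% names(records)) records[[nm]] <- NA_character_
  }
  records$is_pure <- records$x1 == 1

  if (any(records$x1 < 0.5 | records$x1 > 1)) {
    stop_mixqspr("records contain x1 outside [0.5, 1]; canonicalize first",
                 "mixqspr_domain_error")
  }
  if (any(records$is_pure & !is.na(records$comp2)) ||
      any(!records$is_pure & is.na(records$comp2))) {
    stop_mixqspr("is_pure must coincide with x1 == 1 and an absent second component",
                 "mixqspr_domain_error")
  }

  prop <- unique(records$property[!is.na(records$property)])
  if (is.null(property)) property <- if (length(prop)) prop[1] else "property"
  if (length(prop) > 1) {
    stop_mixqspr("all records must share one property", "mixqspr_schema_error")
  }
  records$property <- property

  units <- unique(records$unit[!is.na(records$unit)])
  if (length(units) > 1) {
    stop_mixqspr(paste("mismatched units in one dataset:", paste(units, collapse = ", ")),
                 "mixqspr_unit_error")
  }

  if (endpoint_kind == "regression") records$value <- as.numeric(records$value)

  if (!concentration_dependent) {
    mix <- records[!records$is_pure, , drop = FALSE]
    keys <- pair_key(mix$comp1, mix$comp2)
    if (anyDuplicated(keys)) {
      stop_mixqspr("concentration-independent dataset has several records for one mixture",
                   "mixqspr_schema_error")
    }
  }

  rownames(records) <- NULL
  structure(records,
            class = c("mixture_dataset", "data.frame"),
            property = property,
            endpoint_kind = endpoint_kind,
            concentration_dependent = concentration_dependent)
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf("<mixture_dataset> %d records  property: %s (%s, %s)\n",
              nrow(x), attr(x, "property"), attr(x, "endpoint_kind"),
              if (attr(x, "concentration_dependent")) "concentration-dependent"
              else "one value per mixture"))
  mix <- x[!x$is_pure, , drop = FALSE]
  cat(sprintf("  %d mixtures, %d pure-compound records, %d distinct compounds\n",
              length(unique(pair_key(mix$comp1, mix$comp2))), sum(x$is_pure),
              length(dataset_compounds(x))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more record(s)\n", nrow(x) - 6L))
  invisible(x)
}

#' Compounds occurring in a dataset
#'
#' @param dataset a [mixture_dataset()].
#' @return sorted character vector of canonical structures appearing as either
#'   component.
#' @export
dataset_compounds <- function(dataset) {
  sort(unique(c(dataset$comp1, dataset$comp2[!is.na(dataset$comp2)])))
}

#' Canonicalize a raw table of mixture rows
#'
#' Vectorized [canonicalize_record()] over a raw data frame in the upload
#' dialect. Row-level failures are collected and reported together with their
#' row numbers rather than aborting at the first bad row.
#'
#' @inheritParams canonicalize_record
#' @param raw data frame with the dialect columns.
#' @inheritParams mixture_dataset
#' @return a [mixture_dataset()].
#' @export
canonicalize_rows <- function(raw, canonicalizer = canonicalizer_identity(),
                              endpoint_kind = c("regression", "classification"),
                              concentration_dependent = TRUE) {
  endpoint_kind <- match.arg(endpoint_kind)
  recs <- vector("list", nrow(raw))
  errs <- character(0)
  for (i in seq_len(nrow(raw))) {
    recs[[i]] <- tryCatch(canonicalize_record(raw[i, , drop = FALSE], canonicalizer),
                          mixqspr_error = function(e) e)
    if (inherits(recs[[i]], "condition")) {
      errs <- c(errs, sprintf("row %d: %s", i, conditionMessage(recs[[i]])))
    }
  }
  if (length(errs)) {
    stop_mixqspr(paste0("failed to canonicalize ", length(errs), " row(s):\n  ",
                        paste(errs, collapse = "\n  ")),
                 "mixqspr_structure_error")
  }
  df <- do.call(rbind, lapply(recs, function(r) {
    data.frame(comp1 = r$comp1, comp2 = r$comp2, x1 = r$x1, property = r$property,
               value = I(r$value), unit = r$unit, source = r$source,
               is_pure = r$is_pure, stringsAsFactors = FALSE)
  }))
  df$value <- unlist(df$value)
  mixture_dataset(df, endpoint_kind = endpoint_kind,
                  concentration_dependent = concentration_dependent)
}

#' Detect duplicated mixture records
#'
#' Two records are duplicates when they concern the same unordered component
#' pair and property, their stored molar fractions agree within
#' `fraction_tolerance`, and their values agree within `value_tolerance`
#' (after a unit check). Because storage is majority-component-first, the rows
#' `(A, f, B)` and `(B, 1 - f, A)` collapse to the same key before comparison.
#' Record-level duplicate clusters are merged per mixture: the returned
#' `groups` list one entry per duplicated mixture (component pair), covering
#' all of its duplicated records — the granularity at which duplicated
#' composition series are usually reported.
#'
#' @param dataset a canonical [mixture_dataset()].
#' @param value_tolerance absolute tolerance on the measured value; `0`
#'   restricts duplicates to records with identical values.
#' @param fraction_tolerance absolute tolerance on `x1` (default `1e-6`).
#' @return object of class `duplicate_report`: list with `groups`
#'   (mixture-level, list of integer record-index vectors), `clusters`
#'   (record-level maximal clusters of size >= 2), and `n_records_flagged`.
#' @export
detect_duplicates <- function(dataset, value_tolerance = 0, fraction_tolerance = 1e-6) {
  n <- nrow(dataset)
  keys <- paste(pair_key(dataset$comp1, dataset$comp2), dataset$property, sep = " @ ")
  clusters <- list()
  groups <- list()
  numeric_values <- is.numeric(dataset$value)

  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) < 2L) next
    # single-linkage transitive closure over the tolerance relation
    parent <- seq_along(idx)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(idx)[-1]) {
      for (b in seq_len(a - 1L)) {
        ia <- idx[a]; ib <- idx[b]
        same_x <- abs(dataset$x1[ia] - dataset$x1[ib]) <= fraction_tolerance
        same_v <- if (numeric_values) {
          abs(dataset$value[ia] - dataset$value[ib]) <= value_tolerance
        } else {
          dataset$value[ia] == dataset$value[ib]
        }
        if (same_x && same_v) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      if (length(members) >= 2L) clusters[[length(clusters) + 1L]] <- sort(members)
    }
    flagged <- idx[roots %in% unique(roots)[tabulate(match(roots, unique(roots))) >= 2L]]
    if (length(flagged)) groups[[length(groups) + 1L]] <- sort(flagged)
  }

  structure(list(groups = groups, clusters = clusters,
                 n_records_flagged = length(unique(unlist(groups)))),
            class = "duplicate_report")
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf("<duplicate_report> %d duplicated mixture(s), %d record-level cluster(s), %d record(s) involved\n",
              length(x$groups), length(x$clusters), x$n_records_flagged))
  invisible(x)
}

#' Add pure-compound records for every mixture component
#'
#' Descriptor calculation for a mixture needs both components, so every
#' compound occurring in the dataset must be present at least once as a pure
#' record (`x1 = 1`). For classification endpoints with
#' `policy = "zeotrope"`, added pure records carry the zeotrope label (a pure
#' compound cannot form an azeotrope with itself). For regression endpoints,
#' pure property values must be supplied via `pure_values`; compounds without
#' a value are reported by name rather than silently invented. The operation
#' is idempotent: compounds already present as pure records are left alone.
#'
#' @param dataset a canonical [mixture_dataset()].
#' @param pure_values named numeric vector (names = canonical structures) of
#'   pure-compound property values, for regression endpoints.
#' @param policy `"zeotrope"` to label added pure records as zeotropes
#'   (classification), or `NULL`.
#' @param zeotrope_label label used under the zeotrope policy.
#' @return the augmented [mixture_dataset()].
#' @export
augment_with_pure_compounds <- function(dataset, pure_values = NULL, policy = NULL,
                                        zeotrope_label = "zeotrope") {
  compounds <- dataset_compounds(dataset)
  have_pure <- unique(dataset$comp1[dataset$is_pure])
  todo <- setdiff(compounds, have_pure)
  if (!length(todo)) return(dataset)

  if (identical(policy, "zeotrope")) {
    values <- rep(zeotrope_label, length(todo))
  } else {
    if (is.null(pure_values)) {
      stop_mixqspr(paste0("no pure values supplied for compound(s): ",
                          paste(todo, collapse = ", ")),
                   "mixqspr_augmentation_error")
    }
    missing <- setdiff(todo, names(pure_values))
    if (length(missing)) {
      stop_mixqspr(paste0("missing pure value(s) for compound(s): ",
                          paste(missing, collapse = ", ")),
                   "mixqspr_augmentation_error")
    }
    values <- as.numeric(pure_values[todo])
  }

  unit <- dataset$unit[1]
  add <- data.frame(comp1 = todo, comp2 = NA_character_, x1 = 1,
                    property = attr(dataset, "property"),
                    value = values, unit = unit,
                    source = "pure-compound augmentation",
                    is_pure = TRUE, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(dataset), add)
  mixture_dataset(out, property = attr(dataset, "property"),
                  endpoint_kind = attr(dataset, "endpoint_kind"),
                  concentration_dependent = attr(dataset, "concentration_dependent"))
}
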