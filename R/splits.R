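#' External-validation fold plans for mixture data
#'
#' Random cross-validation of mixture datasets leaks information: the same
#' mixture measured at several compositions, or the same compound in many
#' mixtures, ends up on both sides of the split. Three protocols of
#' increasing rigor control this:
#'
#' * `"points_out"` — data points are placed in folds at random. The same
#'   mixture is typically present in both training and external sets; the
#'   protocol estimates the ability to interpolate new compositions of known
#'   mixtures and is the weakest (creating such a plan emits a warning).
#' * `"mixtures_out"` — all data points of a mixture (the same unordered
#'   component pair at different ratios) are placed in the same external
#'   fold, so every mixture is in either the training or the external set,
#'   never both.
#' * `"compounds_out"` — compounds are partitioned into k groups and every
#'   record is placed in the fold of one of its own components' group; when
#'   a fold is external, training additionally excludes all records sharing a
#'   compound with that fold's group, so every external mixture contains at
#'   least one compound absent from the training set. This is the most
#'   rigorous protocol and the default.
#'
#' Fold balancing targets record counts: mixtures (and compound groups) are
#' packed greedily, largest first, onto the currently smallest fold. Plans
#' are fully reproducible from `(dataset, k, seed)`.
#'
#' @param dataset a [mixture_dataset()].
#' @param k number of external folds (default 10 for regression endpoints,
#'   5 for classification).
#' @param seed integer seed controlling the random partition.
#' @param protocol one of `"compounds_out"`, `"mixtures_out"`,
#'   `"points_out"`.
#' @return object of class `fold_plan`: list with `protocol`, `k`,
#'   `assignment` (integer fold index in `1..k` per record), `seed`,
#'   `compound_groups` (compounds-out only), and `audit` (see
#'   [audit_plan()]).
#' @examples
#' d <- generate_mixture_dataset(synthetic_spec(n_compounds = 12, n_pairs = 18,
#'                                              compositions_per_mixture = 3, seed = 1))
#' plan <- fold_plan(d, protocol = "mixtures_out", k = 5, seed = 42)
#' plan$audit$violations
#' @export
fold_plan <- function(dataset, protocol = c("compounds_out", "mixtures_out", "points_out"),
                      k = NULL, seed = 1) {
  protocol <- match.arg(protocol)
  if (is.null(k)) {
    k <- if (attr(dataset, "endpoint_kind") == "classification") 5L else 10L
  }
  switch(protocol,
    points_out = points_out_folds(dataset, k, seed),
    mixtures_out = mixtures_out_folds(dataset, k, seed),
    compounds_out = compounds_out_folds(dataset, k, seed))
}

new_fold_plan <- function(protocol, k, assignment, seed, dataset, compound_groups = NULL) {
  plan <- structure(list(protocol = protocol, k = as.integer(k),
                         assignment = as.integer(assignment), seed = as.integer(seed),
                         compound_groups = compound_groups, audit = NULL),
                    class = "fold_plan")
  plan$audit <- audit_plan(plan, dataset)
  plan
}

#' @rdname fold_plan
#' @export
points_out_folds <- function(dataset, k, seed = 1) {
  n <- nrow(dataset)
  check_k(k, n, "records")
  warning("'points out' is the weakest validation protocol: the same mixture is ",
          "present in both the training and the external sets", call. = FALSE)
  assignment <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  new_fold_plan("points_out", k, assignment, seed, dataset)
}

#' @rdname fold_plan
#' @export
mixtures_out_folds <- function(dataset, k, seed = 1) {
  keys <- pair_key(dataset$comp1, dataset$comp2)
  mix_keys <- unique(keys[!dataset$is_pure])
  check_k(k, length(mix_keys), "distinct mixtures")
  groups <- with_seed(seed, pack_groups(keys, k))
  assignment <- groups[keys]
  new_fold_plan("mixtures_out", k, assignment, seed, dataset)
}

# greedy largest-first bin packing of grouped records onto k folds,
# balancing record counts; ties broken by the pre-shuffled order
pack_groups <- function(keys, k) {
  sizes <- table(keys)
  ids <- sample(names(sizes))              # random tie order
  ids <- ids[order(-as.integer(sizes[ids]))]
  fold_load <- numeric(k)
  fold_of <- integer(length(ids))
  names(fold_of) <- ids
  for (id in ids) {
    f <- which.min(fold_load)
    fold_of[id] <- f
    fold_load[f] <- fold_load[f] + sizes[[id]]
  }
  fold_of
}

#' @rdname fold_plan
#' @param max_repair maximum repair iterations for compounds-out plans.
#' @export
compounds_out_folds <- function(dataset, k, seed = 1, max_repair = 5L) {
  compounds <- dataset_compounds(dataset)
  check_k(k, length(compounds), "distinct compounds")
  keys <- pair_key(dataset$comp1, dataset$comp2)

  # one anchor pair of compounds per distinct mixture key, kept pair-consistent
  # so that compounds-out plans are also valid mixtures-out plans
  anchors <- pair_anchors(dataset, keys)

  # compounds are packed onto k groups balancing the record count they anchor
  # (greedy largest-first), so external folds end up of comparable size
  key_sizes <- table(keys)
  anchored <- stats::setNames(numeric(length(compounds)), compounds)
  for (i in seq_along(anchors$key)) {
    anchored[[anchors$anchor1[i]]] <- anchored[[anchors$anchor1[i]]] +
      key_sizes[[anchors$key[i]]]
  }
  group_of <- with_seed(seed, {
    ids <- sample(compounds)
    ids <- ids[order(-anchored[ids])]
    load <- numeric(k)
    count <- integer(k)
    g <- stats::setNames(integer(length(ids)), ids)
    for (id in ids[anchored[ids] > 0]) {
      f <- which.min(load)
      g[[id]] <- f
      load[f] <- load[f] + anchored[[id]]
      count[f] <- count[f] + 1L
    }
    for (id in ids[anchored[ids] == 0]) {  # spread non-anchoring compounds evenly
      f <- which.min(count)
      g[[id]] <- f
      count[f] <- count[f] + 1L
    }
    g
  })

  fold_of_key <- group_of[anchors$anchor1]
  names(fold_of_key) <- anchors$key

  presence <- function(fold_of_key) {
    # folds in which each compound occurs in any record
    f1 <- fold_of_key[keys]
    pres <- list()
    for (cmp in compounds) {
      rows <- dataset$comp1 == cmp | (!is.na(dataset$comp2) & dataset$comp2 == cmp)
      pres[[cmp]] <- unique(f1[rows])
    }
    pres
  }

  for (iter in seq_len(max_repair)) {
    pres <- presence(fold_of_key)
    moved <- FALSE
    for (i in seq_along(anchors$key)) {
      key <- anchors$key[i]
      a1 <- anchors$anchor1[i]; a2 <- anchors$anchor2[i]
      f <- fold_of_key[[key]]
      if (is.na(a2)) next
      a1_confined <- identical(pres[[a1]], f) || all(pres[[a1]] == f)
      f2 <- group_of[[a2]]
      a2_confined <- all(pres[[a2]] == f2)
      if (!a1_confined && a2_confined && f != f2) {
        fold_of_key[[key]] <- f2
        moved <- TRUE
      }
    }
    if (!moved) break
  }

  # remaining cross-group mixtures: place with the anchor whose compound has
  # fewer occurrences in foreign folds (least-violation fold)
  pres <- presence(fold_of_key)
  for (i in seq_along(anchors$key)) {
    key <- anchors$key[i]
    a1 <- anchors$anchor1[i]; a2 <- anchors$anchor2[i]
    if (is.na(a2)) next
    cand <- c(group_of[[a1]], group_of[[a2]])
    cost <- vapply(c(a1, a2), function(cmp) {
      rows <- dataset$comp1 == cmp | (!is.na(dataset$comp2) & dataset$comp2 == cmp)
      sum(fold_of_key[keys[rows]] != group_of[[cmp]])
    }, numeric(1))
    fold_of_key[[key]] <- cand[which.min(cost)]
  }

  assignment <- unname(fold_of_key[keys])
  new_fold_plan("compounds_out", k, assignment, seed, dataset,
                compound_groups = group_of)
}

# anchor1 = the compound acting as majority component in most of the pair's
# records (lexicographic tie-break); pure keys anchor on their compound
pair_anchors <- function(dataset, keys) {
  uk <- unique(keys)
  a1 <- character(length(uk)); a2 <- character(length(uk))
  for (i in seq_along(uk)) {
    rows <- which(keys == uk[i])
    c1 <- dataset$comp1[rows]; c2 <- dataset$comp2[rows]
    if (all(is.na(c2))) { a1[i] <- c1[1]; a2[i] <- NA_character_; next }
    tab <- sort(table(c1), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    a1[i] <- min(top)
    both <- unique(c(c1, c2[!is.na(c2)]))
    a2[i] <- setdiff(both, a1[i])[1] %||% NA_character_
  }
  list(key = uk, anchor1 = a1, anchor2 = a2)
}

check_k <- function(k, n_units, what) {
  if (!is_scalar_number(k) || k < 2 || k != round(k)) {
    stop_mixqspr("k must be an integer >= 2", "mixqspr_config_error")
  }
  if (k > n_units) {
    stop_mixqspr(sprintf("k = %d exceeds the number of %s (%d)", k, what, n_units),
                 "mixqspr_config_error")
  }
  invisible(TRUE)
}

#' Brute-force audit of a fold plan
#'
#' Re-derives the protocol's leakage guarantee from scratch and counts
#' violating records. For `"mixtures_out"`, a record violates when its
#' unordered component pair occurs in more than one fold. For
#' `"compounds_out"` plans carrying their compound partition, a record in
#' fold `f` violates when it has no component in fold `f`'s compound group —
#' i.e. no compound guaranteed absent from the effective training set (which
#' excludes all records sharing a compound with group `f`); the audit also
#' reports, per fold, how many outside records that exclusion removes, and
#' how many records have both compounds occurring in other folds
#' (`strict_leaks`, a diagnostic). A plan relabeled as `"compounds_out"`
#' without a compound partition is audited under the strict reading (some
#' component absent from every other fold). `"points_out"` offers no grouping
#' guarantee, so only partition validity is checked.
#'
#' @param plan a [fold_plan()].
#' @param dataset the dataset the plan indexes.
#' @return list with `protocol`, `violations` (must be 0 for a valid plan),
#'   `strict_leaks`, and a `per_fold` data frame (records, mixtures,
#'   compounds, excluded training records per fold).
#' @export
audit_plan <- function(plan, dataset) {
  n <- nrow(dataset)
  if (length(plan$assignment) != n) {
    stop_mixqspr("plan does not cover the dataset", "mixqspr_config_error")
  }
  assignment <- plan$assignment
  k <- plan$k
  keys <- pair_key(dataset$comp1, dataset$comp2)
  comp2 <- dataset$comp2

  record_compounds <- function(i) {
    c(dataset$comp1[i], if (!is.na(comp2[i])) comp2[i])
  }

  violations <- 0L
  strict_leaks <- 0L
  excluded <- integer(k)

  if (plan$protocol == "mixtures_out" || plan$protocol == "compounds_out") {
    fold_of_key <- tapply(assignment, keys, function(f) length(unique(f)))
    straddle_keys <- names(fold_of_key)[fold_of_key > 1]
  }

  if (plan$protocol == "mixtures_out") {
    violations <- sum(keys %in% straddle_keys)
  } else if (plan$protocol == "compounds_out") {
    if (!is.null(plan$compound_groups)) {
      group_of <- plan$compound_groups
      for (f in seq_len(k)) {
        in_f <- which(assignment == f)
        group_f <- names(group_of)[group_of == f]
        # effective training set: outside records sharing no group-f compound
        out_f <- which(assignment != f)
        shares <- vapply(out_f, function(i) any(record_compounds(i) %in% group_f),
                         logical(1))
        excluded[f] <- sum(shares)
        train_compounds <- unique(unlist(lapply(out_f[!shares], record_compounds)))
        bad <- vapply(in_f, function(i) all(record_compounds(i) %in% train_compounds),
                      logical(1))
        violations <- violations + sum(bad)
      }
      # diagnostic: strict-partition reading (compound absent from ALL other folds)
      fold_sets <- lapply(seq_len(k), function(f) {
        unique(unlist(lapply(which(assignment == f), record_compounds)))
      })
      for (i in seq_len(n)) {
        f <- assignment[i]
        elsewhere <- unique(unlist(fold_sets[-f]))
        if (all(record_compounds(i) %in% elsewhere)) strict_leaks <- strict_leaks + 1L
      }
    } else {
      # strict reading when no compound partition is recorded
      fold_sets <- lapply(seq_len(k), function(f) {
        unique(unlist(lapply(which(assignment == f), record_compounds)))
      })
      for (i in seq_len(n)) {
        f <- assignment[i]
        elsewhere <- unique(unlist(fold_sets[-f]))
        if (all(record_compounds(i) %in% elsewhere)) violations <- violations + 1L
      }
    }
  }

  per_fold <- data.frame(
    fold = seq_len(k),
    n_records = vapply(seq_len(k), function(f) sum(assignment == f), integer(1)),
    n_mixtures = vapply(seq_len(k), function(f)
      length(unique(keys[assignment == f & !dataset$is_pure])), integer(1)),
    n_compounds = vapply(seq_len(k), function(f)
      length(unique(unlist(lapply(which(assignment == f), record_compounds)))),
      integer(1)),
    n_excluded_train = excluded
  )

  list(protocol = plan$protocol, k = k, violations = violations,
       strict_leaks = strict_leaks, per_fold = per_fold)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> protocol '%s', k = %d, seed = %d\n",
              x$protocol, x$k, x$seed))
  cat(sprintf("  fold sizes: %s\n", paste(x$audit$per_fold$n_records, collapse = ", ")))
  cat(sprintf("  audit violations: %d\n", x$audit$violations))
  if (x$protocol == "compounds_out") {
    cat(sprintf("  training records excluded per external fold: %s\n",
                paste(x$audit$per_fold$n_excluded_train, collapse = ", ")))
  }
  invisible(x)
}

#' Training records for one external fold
#'
#' Returns the record indices an estimator may train on when fold `fold` is
#' external: all records outside the fold, and for `"compounds_out"` plans
#' additionally excluding records sharing a compound with the fold's
#' compound group (so the guarantee "at least one compound absent from
#' training" holds for every external record).
#'
#' @inheritParams audit_plan
#' @param fold external fold index in `1..k`.
#' @return integer vector of training record indices.
#' @export
fold_training_records <- function(plan, dataset, fold) {
  out <- which(plan$assignment != fold)
  if (plan$protocol == "compounds_out" && !is.null(plan$compound_groups)) {
    group_f <- names(plan$compound_groups)[plan$compound_groups == fold]
    shares <- dataset$comp1[out] %in% group_f |
      (!is.na(dataset$comp2[out]) & dataset$comp2[out] %in% group_f)
    out <- out[!shares]
  }
  out
}
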