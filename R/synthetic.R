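#' Specification of a synthetic binary-mixture study
#'
#' Defines the generating process for synthetic datasets with known ground
#' truth that emulate the shapes of typical mixture-property studies:
#' concentration-dependent regression endpoints measured at several
#' compositions per mixture (a density-deviation-like and a bubble-point-like
#' case) and a concentration-independent binary azeotrope/zeotrope label
#' (one record per mixture).
#'
#' Generating model: each compound `i` gets an m-dimensional descriptor
#' vector `d_i ~ N(0, I)` and a latent pure property
#' `p_i = w . d_i + c_i`, where `w` are the additive weights and
#' `c_i ~ N(0, compound_effect_sd^2)` is a compound-specific effect NOT
#' carried by the descriptors (it makes unseen compounds genuinely hard).
#' A mixture of `i` and `j` at majority fraction `x1` has ideal value
#' `x1 * p_i + (1 - x1) * p_j` and observed value
#' `ideal + gamma * x1 * (1 - x1) * g_ij + noise`, with pair interaction
#' `g_ij = u . (d_i * d_j) + b * v . |d_i - d_j|` (`u`, `v`, `b` drawn once
#' per seed). Endpoints: `density_deviation` stores observation minus ideal
#' (zero for ideal mixtures and for pure compounds), `bubble_like` stores the
#' observation, `azeotrope_label` stores `"azeotrope"` when
#' `gamma * g_ij` exceeds a threshold bisected on the realized sample so the
#' class balance is 50/50.
#'
#' @param n_compounds number of compounds.
#' @param m_descriptors descriptors per compound.
#' @param compositions_per_mixture composition points per mixture, on an even
#'   grid strictly inside `(0.5, 1)` (forced to 1 for the azeotrope
#'   endpoint, recorded at the equimolar point).
#' @param n_pairs number of mixtures (component pairs); alternative to
#'   `pair_density`.
#' @param pair_density fraction of all possible pairs realized, in `(0, 1]`.
#' @param additive_weights weight vector `w` (length `m_descriptors`);
#'   default drawn `N(0, 1/m)` under the seed.
#' @param interaction_strength non-additivity strength `gamma >= 0`.
#' @param compound_effect_sd sd of the descriptor-orthogonal compound effect.
#' @param noise_sd measurement noise sd.
#' @param endpoint `"density_deviation"`, `"bubble_like"`, or
#'   `"azeotrope_label"`.
#' @param include_pure include one pure record per compound (default TRUE for
#'   regression endpoints; FALSE for the azeotrope endpoint, where pures are
#'   added by [augment_with_pure_compounds()] as a separate step).
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 60, m_descriptors = 8,
                           compositions_per_mixture = 9,
                           n_pairs = 150, pair_density = NULL,
                           additive_weights = NULL,
                           interaction_strength = 1, compound_effect_sd = 0.5,
                           noise_sd = 0.1,
                           endpoint = c("density_deviation", "bubble_like",
                                        "azeotrope_label"),
                           include_pure = NULL, seed = 1) {
  endpoint <- match.arg(endpoint)
  max_pairs <- choose(n_compounds, 2)
  if (!is.null(pair_density)) {
    if (pair_density <= 0 || pair_density > 1) {
      stop_mixqspr("pair_density must be in (0, 1]", "mixqspr_config_error")
    }
    n_pairs <- round(pair_density * max_pairs)
  }
  if (n_pairs < 1) {
    stop_mixqspr("pair_density/n_pairs realize no mixture pair", "mixqspr_config_error")
  }
  if (n_pairs > max_pairs) {
    stop_mixqspr("more pairs requested than exist", "mixqspr_config_error")
  }
  if (interaction_strength < 0 || compound_effect_sd < 0 || noise_sd < 0) {
    stop_mixqspr("strengths and sds must be >= 0", "mixqspr_config_error")
  }
  if (endpoint == "azeotrope_label") compositions_per_mixture <- 1L
  if (compositions_per_mixture < 1) {
    stop_mixqspr("compositions_per_mixture must be >= 1", "mixqspr_config_error")
  }
  if (!is.null(additive_weights) && length(additive_weights) != m_descriptors) {
    stop_mixqspr("additive_weights must have length m_descriptors", "mixqspr_config_error")
  }
  if (is.null(include_pure)) include_pure <- endpoint != "azeotrope_label"

  structure(list(n_compounds = as.integer(n_compounds),
                 m_descriptors = as.integer(m_descriptors),
                 compositions_per_mixture = as.integer(compositions_per_mixture),
                 n_pairs = as.integer(n_pairs),
                 pair_density = n_pairs / max_pairs,
                 additive_weights = additive_weights,
                 interaction_strength = interaction_strength,
                 compound_effect_sd = compound_effect_sd,
                 noise_sd = noise_sd, endpoint = endpoint,
                 include_pure = include_pure, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# single deterministic draw shared by generate_compounds() and
# generate_mixture_dataset(): fixed order w, d, c, u, v, b, pairs, noise
synth_draw_compounds <- function(spec) {
  m <- spec$m_descriptors
  n <- spec$n_compounds
  ids <- sprintf("CPD%03d", seq_len(n))
  w <- spec$additive_weights %||% stats::rnorm(m, sd = 1 / sqrt(m))
  if (!is.null(spec$additive_weights)) invisible(stats::rnorm(m, sd = 1 / sqrt(m)))
  d <- matrix(stats::rnorm(n * m), n, m,
              dimnames = list(ids, sprintf("d%02d", seq_len(m))))
  c_eff <- stats::rnorm(n, sd = spec$compound_effect_sd)
  p <- drop(d %*% w) + c_eff
  list(ids = ids, w = w, d = d, compound_effects = c_eff, pure = p)
}

#' Generate compounds with descriptors and latent pure properties
#'
#' @param spec a [synthetic_spec()].
#' @return list with `descriptors` (a `descriptor_matrix`), `pure_values`
#'   (named latent pure properties), `compound_effects`, and `weights`.
#' @export
generate_compounds <- function(spec) {
  cmp <- with_seed(spec$seed, synth_draw_compounds(spec))
  list(descriptors = as_descriptor_matrix(cmp$d, backend_id = "synthetic"),
       pure_values = stats::setNames(cmp$pure, cmp$ids),
       compound_effects = stats::setNames(cmp$compound_effects, cmp$ids),
       weights = cmp$w)
}

# sample n_pairs unordered pairs without replacement, guaranteeing that every
# compound appears in at least one pair (uncovered compounds replace pairs
# between high-degree compounds)
sample_covering_pairs <- function(n, n_pairs) {
  all_pairs <- t(utils::combn(n, 2))
  if (n_pairs < ceiling(n / 2)) {
    # too few pairs to cover every compound; plain random sample
    return(all_pairs[sample(nrow(all_pairs), n_pairs), , drop = FALSE])
  }
  # random perfect matching first (guarantees coverage), then fill with
  # uniformly sampled pairs from the complement
  perm <- sample(n)
  base <- matrix(perm[seq_len(2 * floor(n / 2))], ncol = 2, byrow = TRUE)
  if (n %% 2 == 1) {
    last <- perm[n]
    base <- rbind(base, c(last, sample(perm[-n], 1)))
  }
  base <- t(apply(base, 1, sort))
  key <- function(p) paste(p[, 1], p[, 2])
  pool <- all_pairs[!(key(all_pairs) %in% key(base)), , drop = FALSE]
  extra <- n_pairs - nrow(base)
  if (extra > 0) {
    base <- rbind(base, pool[sample(nrow(pool), extra), , drop = FALSE])
  }
  base
}

#' Generate a synthetic mixture dataset with known ground truth
#'
#' Draws compounds, realizes component pairs (every compound is guaranteed to
#' appear in at least one pair), lays out composition grids, and computes
#' endpoint values under the generating model described in
#' [synthetic_spec()]. The generating truth (weights, descriptors, latent
#' pure values, pair interactions, threshold) is attached as
#' `attr(dataset, "truth")`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [mixture_dataset()] with a `truth` attribute.
#' @examples
#' d <- generate_mixture_dataset(synthetic_spec(n_compounds = 10, n_pairs = 12,
#'                                              compositions_per_mixture = 3, seed = 1))
#' d
#' @export
generate_mixture_dataset <- function(spec) {
  out <- with_seed(spec$seed, {
    cmp <- synth_draw_compounds(spec)
    m <- spec$m_descriptors
    u <- stats::rnorm(m)
    v <- stats::rnorm(m)
    b <- stats::rnorm(1)
    pairs <- sample_covering_pairs(spec$n_compounds, spec$n_pairs)

    g <- apply(pairs, 1, function(pr) {
      di <- cmp$d[pr[1], ]; dj <- cmp$d[pr[2], ]
      sum(u * di * dj) + b * sum(v * abs(di - dj))
    })

    cpm <- spec$compositions_per_mixture
    gamma <- spec$interaction_strength

    if (spec$endpoint == "azeotrope_label") {
      s <- gamma * g
      thr <- balance_threshold(s)
      comp1 <- pmin(cmp$ids[pairs[, 1]], cmp$ids[pairs[, 2]])
      comp2 <- pmax(cmp$ids[pairs[, 1]], cmp$ids[pairs[, 2]])
      df <- data.frame(comp1 = comp1, comp2 = comp2, x1 = 0.5,
                       value = ifelse(s > thr, "azeotrope", "zeotrope"),
                       stringsAsFactors = FALSE)
      truth_extra <- list(threshold = thr, score = stats::setNames(s, pair_key(comp1, comp2)))
    } else {
      xs <- 0.5 + 0.5 * seq_len(cpm) / (cpm + 1)
      idx <- rep(seq_len(nrow(pairs)), each = cpm)
      x1 <- rep(xs, nrow(pairs))
      p_i <- cmp$pure[pairs[idx, 1]]
      p_j <- cmp$pure[pairs[idx, 2]]
      ideal <- x1 * p_i + (1 - x1) * p_j
      eps <- stats::rnorm(length(idx), sd = spec$noise_sd)
      obs <- ideal + gamma * x1 * (1 - x1) * g[idx] + eps
      value <- if (spec$endpoint == "density_deviation") obs - ideal else obs
      df <- data.frame(comp1 = cmp$ids[pairs[idx, 1]], comp2 = cmp$ids[pairs[idx, 2]],
                       x1 = x1, value = value, stringsAsFactors = FALSE)
      truth_extra <- list(ideal = ideal)
    }

    if (spec$include_pure) {
      pure_value <- if (spec$endpoint == "density_deviation") {
        rep(0, spec$n_compounds)
      } else if (spec$endpoint == "bubble_like") {
        unname(cmp$pure)
      } else {
        rep("zeotrope", spec$n_compounds)
      }
      df <- rbind(df, data.frame(comp1 = cmp$ids, comp2 = NA_character_, x1 = 1,
                                 value = pure_value, stringsAsFactors = FALSE))
    }

    df$property <- spec$endpoint
    df$unit <- "a.u."
    df$source <- sprintf("synthetic generator (seed %d)", spec$seed)
    df$is_pure <- df$x1 == 1

    list(df = df, cmp = cmp, u = u, v = v, b = b, g = g, pairs = pairs,
         truth_extra = truth_extra)
  })

  kind <- if (spec$endpoint == "azeotrope_label") "classification" else "regression"
  ds <- mixture_dataset(out$df, property = spec$endpoint, endpoint_kind = kind,
                        concentration_dependent = spec$endpoint != "azeotrope_label")
  truth <- c(list(
    weights = out$cmp$w,
    descriptors = as_descriptor_matrix(out$cmp$d, backend_id = "synthetic"),
    pure_values = stats::setNames(out$cmp$pure, out$cmp$ids),
    compound_effects = stats::setNames(out$cmp$compound_effects, out$cmp$ids),
    u = out$u, v = out$v, b = out$b,
    g = stats::setNames(out$g, pair_key(out$cmp$ids[out$pairs[, 1]],
                                        out$cmp$ids[out$pairs[, 2]])),
    spec = spec
  ), out$truth_extra)
  attr(ds, "truth") <- truth
  ds
}

# threshold at which the fraction of scores strictly above it is closest to
# one half, found by bisection on the realized sample
balance_threshold <- function(s, tol = 1e-12, max_iter = 200) {
  if (max(s) == min(s)) {
    stop_mixqspr("interaction scores are constant; class balance is impossible",
                 "mixqspr_config_error")
  }
  lo <- min(s) - 1
  hi <- max(s) + 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    frac <- mean(s > mid)
    if (frac > 0.5) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  # the upper bound is the side with fraction <= 1/2, exactly 1/2 for an even
  # count of distinct scores
  hi
}

#' Ideal mixture value from pure-component values
#'
#' Baseline value of a binary mixture obtained by combining the
#' pure-component property values linearly according to the mole ratio:
#' `x1 * p_i + (1 - x1) * p_j`. The modeled non-additive endpoint is the
#' deviation of the measured value from this baseline. (For density the
#' physically exact ideal mixes via molar volumes; the linear mole-fraction
#' form is the conventional descriptor-level baseline, and any alternative
#' can be supplied through `combine`.)
#'
#' @param p_i,p_j pure-component property values (majority component first).
#' @param x1 molar fraction of component `i`, in `[0.5, 1]`.
#' @param combine optional function `(p_i, p_j, x1) -> value` replacing the
#'   linear rule, e.g. a volume-based variant.
#' @return numeric value.
#' @examples
#' ideal_mixture_value(2, 4, 0.75)
#' @export
ideal_mixture_value <- function(p_i, p_j, x1, combine = NULL) {
  if (any(x1 < 0.5 | x1 > 1)) {
    stop_mixqspr("x1 must lie in [0.5, 1]", "mixqspr_domain_error")
  }
  if (!is.null(combine)) return(combine(p_i, p_j, x1))
  x1 * p_i + (1 - x1) * p_j
}
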