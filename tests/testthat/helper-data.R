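# Shared fixture builders; everything is generated in code.

bare_matrix <- function(m) {
  m <- unclass(m)
  attr(m, "backend_id") <- NULL
  m
}

random_raw_rows <- function(n, seed = 1, compounds = sprintf("CPD%02d", 1:12)) {
  withr::with_seed(seed, {
    c1 <- sample(compounds, n, replace = TRUE)
    c2 <- vapply(c1, function(a) sample(setdiff(compounds, a), 1), character(1))
    data.frame(SMILES1 = c1, MOLAR_FRACTION = round(runif(n, 0.01, 0.99), 4),
               SMILES2 = c2, PROPERTY = "prop", VALUE = round(rnorm(n), 4),
               UNIT = "g/cm3", SOURCE = "sim", stringsAsFactors = FALSE)
  })
}

record_as_raw <- function(rec) {
  list(SMILES1 = rec$comp1, MOLAR_FRACTION = rec$x1,
       SMILES2 = if (is.na(rec$comp2)) NULL else rec$comp2,
       PROPERTY = rec$property, VALUE = rec$value,
       UNIT = rec$unit, SOURCE = rec$source)
}

toy_regression_dataset <- function(seed = 1, n_compounds = 15, n_pairs = 25,
                                   compositions = 3, ...) {
  generate_mixture_dataset(synthetic_spec(
    n_compounds = n_compounds, n_pairs = n_pairs,
    compositions_per_mixture = compositions, seed = seed, ...))
}
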