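test_that("canonicalization stores the majority component first with the complement fraction", {
  rec <- canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = 0.3,
                                  SMILES2 = "B", VALUE = 1.2))
  expect_equal(rec$comp1, "B")
  expect_equal(rec$comp2, "A")
  expect_equal(rec$x1, 0.7)
  expect_equal(rec$value, 1.2)
  expect_false(rec$is_pure)

  pure <- canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = 1, VALUE = 0.997))
  expect_true(pure$is_pure)
  expect_equal(pure$x1, 1)
  expect_true(is.na(pure$comp2))

  # equimolar tie-break: lexicographically smaller structure first
  eq <- canonicalize_record(list(SMILES1 = "ZZ", MOLAR_FRACTION = 0.5,
                                 SMILES2 = "AA", VALUE = 1))
  expect_equal(eq$comp1, "AA")
  expect_equal(eq$x1, 0.5)
})

test_that("canonicalization rejects malformed rows with informative errors", {
  expect_error(canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = 0,
                                        SMILES2 = "B", VALUE = 1)),
               class = "mixqspr_domain_error")
  expect_error(canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = 1.2,
                                        SMILES2 = "B", VALUE = 1)),
               class = "mixqspr_domain_error")
  expect_error(canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = -0.3,
                                        SMILES2 = "B", VALUE = 1)),
               class = "mixqspr_domain_error")
  expect_error(canonicalize_record(list(SMILES1 = "A", MOLAR_FRACTION = 0.7, VALUE = 1)),
               class = "mixqspr_incomplete_record_error")
  expect_error(canonicalize_record(list(MOLAR_FRACTION = 0.7, SMILES2 = "B", VALUE = 1)),
               class = "mixqspr_structure_error")
})

test_that("canonicalization is idempotent and order-normalizing", {
  raw <- random_raw_rows(200, seed = 42)
  for (i in seq_len(nrow(raw))) {
    once <- canonicalize_record(raw[i, ])
    twice <- canonicalize_record(record_as_raw(once))
    expect_identical(once, twice)

    # entering the same mixture from the other component's perspective
    swapped <- raw[i, ]
    tmp <- swapped$SMILES1; swapped$SMILES1 <- swapped$SMILES2; swapped$SMILES2 <- tmp
    swapped$MOLAR_FRACTION <- 1 - swapped$MOLAR_FRACTION
    expect_identical(canonicalize_record(swapped), once)
  }
})

test_that("x1 + derived x2 is exactly 1 and x1 stays in [0.5, 1]", {
  d <- toy_regression_dataset(seed = 5)
  expect_true(all(d$x1 >= 0.5 & d$x1 <= 1))
  x2 <- 1 - d$x1
  expect_true(all(d$x1 + x2 == 1))
})

test_that("dataset constructor enforces unit and shape invariants", {
  base <- data.frame(comp1 = c("B", "C"), comp2 = c("A", "A"), x1 = c(0.7, 0.6),
                     value = c(1, 2), unit = c("K", "C"), stringsAsFactors = FALSE)
  expect_error(mixture_dataset(base), class = "mixqspr_unit_error")

  bad_x <- data.frame(comp1 = "B", comp2 = "A", x1 = 0.3, value = 1)
  expect_error(mixture_dataset(bad_x), class = "mixqspr_domain_error")

  dup_pair <- data.frame(comp1 = c("B", "A"), comp2 = c("A", "B"), x1 = c(0.6, 0.7),
                         value = c(1, 2), stringsAsFactors = FALSE)
  expect_error(mixture_dataset(dup_pair, concentration_dependent = FALSE),
               class = "mixqspr_schema_error")
})

test_that("mirror-entered rows collapse to one duplicate group", {
  df <- data.frame(comp1 = c("B", "B"), comp2 = c("A", "A"), x1 = c(0.7, 0.7),
                   value = c(1.5, 1.5), stringsAsFactors = FALSE)
  d <- mixture_dataset(df, property = "p")
  rep <- detect_duplicates(d, value_tolerance = 0)
  expect_length(rep$groups, 1)
  expect_equal(rep$groups[[1]], c(1L, 2L))
})

test_that("a dataset with cloned composition series reports one duplicate group per cloned mixture", {
  # 8 duplicated mixtures spanning 144 data points (18 compositions each),
  # cloned into fresh rows -> 8 mixture-level groups over 288 records
  withr::with_seed(7, {
    pairs <- data.frame(c1 = sprintf("X%02d", 1:8), c2 = sprintf("Y%02d", 1:8))
    xs <- seq(0.52, 0.95, length.out = 18)
    series <- do.call(rbind, lapply(1:8, function(i) {
      data.frame(comp1 = pairs$c1[i], comp2 = pairs$c2[i], x1 = xs,
                 value = round(rnorm(18), 6), stringsAsFactors = FALSE)
    }))
    extra <- data.frame(comp1 = sprintf("Z%02d", 1:20), comp2 = sprintf("W%02d", 1:20),
                        x1 = 0.75, value = rnorm(20), stringsAsFactors = FALSE)
  })
  d <- mixture_dataset(rbind(series, series, extra), property = "p")
  expect_equal(nrow(d), 144 + 144 + 20)
  rep <- detect_duplicates(d, value_tolerance = 0)
  expect_length(rep$groups, 8)
  expect_equal(rep$n_records_flagged, 288)
  expect_true(all(lengths(rep$clusters) == 2))
})

test_that("all-distinct datasets yield no duplicates and tolerance 0 equals exact-key grouping", {
  d <- toy_regression_dataset(seed = 11, noise_sd = 0.5)
  expect_length(detect_duplicates(d, 0)$groups, 0)

  # brute-force check: clusters at tolerance 0 == grouping by exact key
  df <- as.data.frame(d)[sample(nrow(d), 60), ]
  df <- rbind(df, df[1:10, ])  # force exact duplicates
  dd <- mixture_dataset(df, property = attr(d, "property"))
  rep <- detect_duplicates(dd, 0)
  key <- paste(pair_key(dd$comp1, dd$comp2), dd$x1, dd$property, dd$value)
  expected <- unname(Filter(function(g) length(g) >= 2,
                            split(seq_len(nrow(dd)), key)))
  got <- rep$clusters
  sort_groups <- function(gs) gs[order(vapply(gs, min, numeric(1)))]
  expect_equal(sort_groups(got), sort_groups(lapply(expected, as.integer)))
})

test_that("pure-compound augmentation adds each component once and is idempotent", {
  az <- generate_mixture_dataset(synthetic_spec(n_compounds = 65, n_pairs = 400,
                                                endpoint = "azeotrope_label", seed = 2))
  expect_equal(nrow(az), 400)
  aug <- augment_with_pure_compounds(az, policy = "zeotrope")
  expect_equal(nrow(aug), 465)
  expect_true(all(aug$value[aug$is_pure] == "zeotrope"))
  expect_identical(nrow(augment_with_pure_compounds(aug, policy = "zeotrope")), 465L)

  # regression: missing pure values are reported, not invented
  d <- mixture_dataset(data.frame(
    comp1 = c("B", "C"), comp2 = c("A", "A"), x1 = 0.7, value = c(1, 2),
    stringsAsFactors = FALSE), property = "p")
  err <- tryCatch(augment_with_pure_compounds(d, pure_values = c(A = 1, B = 2)),
                  mixqspr_augmentation_error = function(e) conditionMessage(e))
  expect_match(err, "C")
  full <- augment_with_pure_compounds(d, pure_values = c(A = 1, B = 2, C = 3))
  expect_equal(nrow(full), 5)
})

test_that("csv round trip reproduces the dataset", {
  d <- generate_mixture_dataset(synthetic_spec(n_compounds = 30, n_pairs = 100,
                                               compositions_per_mixture = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_mixture_dataset(d, path)
  d2 <- read_mixture_dataset(path)
  expect_equal(as.data.frame(d2)[c("comp1", "comp2", "x1", "value")],
               as.data.frame(d)[c("comp1", "comp2", "x1", "value")],
               tolerance = 1e-12)
  expect_equal(attr(d2, "property"), attr(d, "property"))
})

test_that("file rows are canonicalized on read and schema errors are caught", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES1,MOLAR_FRACTION,SMILES2,PROPERTY,VALUE,UNIT,SOURCE",
               "A,0.30,B,p,1.2,K,src",
               "C,1.0,,p,0.9,K,src",
               "D,0.80,E,p,2.0,K,src"), path)
  d <- read_mixture_dataset(path)
  expect_equal(nrow(d), 3)
  expect_equal(d$comp1[1], "B")
  expect_equal(d$x1[1], 0.7)
  expect_true(d$is_pure[2])

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES1,SMILES2,VALUE", "A,B,1"), bad)
  expect_error(read_mixture_dataset(bad), class = "mixqspr_schema_error")

  # row-level failures are collected with row numbers
  rows <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES1,MOLAR_FRACTION,SMILES2,PROPERTY,VALUE,UNIT,SOURCE",
               "A,0.30,B,p,1.2,K,src",
               "C,0.40,,p,0.9,K,src",
               "D,1.80,E,p,2.0,K,src"), rows)
  err <- tryCatch(read_mixture_dataset(rows),
                  mixqspr_structure_error = function(e) conditionMessage(e))
  expect_match(err, "row 2")
  expect_match(err, "row 3")
})

test_that("SMILES canonicalization backend unifies equivalent notations", {
  canon <- canonicalizer_openbabel()
  out <- canon(c("OCC", "CCO", "C(C)O"))
  expect_length(unique(out), 1)
  expect_identical(canon(out), out)  # idempotent

  rec <- canonicalize_record(list(SMILES1 = "OCC", MOLAR_FRACTION = 0.4,
                                  SMILES2 = "c1ccccc1", VALUE = 1),
                             canonicalizer = canon)
  expect_equal(rec$comp2, canon("CCO"))
  expect_error(canon("not_a_smiles("), class = "mixqspr_structure_error")
})
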