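min_csv <- function(path) {
  writeLines(c(
    "study_id,year,design_class,disease_class,disease,treatment_class,contains_chemotherapy,dose_label,dose_components,n_evaluable_dlt,n_dlt,n_evaluable_or,n_or",
    "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d1,A=10,3,0,,",
    "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d2,A=20,3,1,,",
    "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d3,A=30,6,2,,"
  ), path)
  path
}

test_that("a minimal well-formed CSV reads into a validated database", {
  f <- min_csv(tempfile(fileext = ".csv"))
  db <- read_database(f)
  expect_s3_class(db, "dose_db")
  expect_equal(nrow(db$studies), 1)
  expect_equal(nrow(db$records), 3)
  expect_equal(db$records$n_dlt, c(0, 1, 2))
  # missing OR cells stay missing, never zero
  expect_true(all(is.na(db$records$n_or)))
})

test_that("invariant violations are reported naming the offending rows", {
  f <- min_csv(tempfile(fileext = ".csv"))
  lines <- readLines(f)
  lines[3] <- "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d2,A=20,3,4,,"
  writeLines(lines, f)
  expect_error(read_database(f), "record row 2.*n_dlt exceeds")
  # a record with neither outcome pair is rejected
  lines[3] <- "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d2,A=20,,,,"
  writeLines(lines, f)
  expect_error(read_database(f), "neither DLT nor OR")
})

test_that("schema mismatches list the missing columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("study_id,year", "s1,2012"), f)
  expect_error(read_database(f), "missing columns.*dose_label")
  expect_error(read_database(tempfile()), "not found")
})

test_that("write then read round-trips synthetic databases exactly", {
  for (sd in c(11, 12)) {
    sim <- sample_database(scenario_spec(n_studies = 10, seed = sd))
    f <- tempfile(fileext = ".csv")
    write_database(sim$db, f)
    db2 <- read_database(f)
    expect_equal(
      as.data.frame(dplyr::arrange(sim$db$studies, study_id)),
      as.data.frame(dplyr::arrange(db2$studies, study_id))
    )
    r1 <- as.data.frame(sim$db$records)
    r2 <- as.data.frame(db2$records)
    r2$n_evaluable_dlt <- as.integer(r2$n_evaluable_dlt)
    r2$n_dlt <- as.integer(r2$n_dlt)
    expect_equal(r1[c("study_id", "dose_label", "dose_components")],
                 r2[c("study_id", "dose_label", "dose_components")])
    expect_equal(r1$n_dlt, r2$n_dlt)
    expect_equal(r1$n_or, as.integer(r2$n_or))
  }
})

test_that("combination doses serialise losslessly", {
  comps <- c(A = 12.5, B = 30)
  s <- dosemono:::format_dose_components(comps)
  expect_equal(dosemono:::parse_dose_components(s), comps)
  expect_error(dosemono:::parse_dose_components("A=x"), "non-numeric")
  expect_error(dosemono:::parse_dose_components(""), "empty")
})

test_that("an empty database writes a header-only file", {
  studies <- tibble::tibble(
    study_id = character(), year = numeric(), design_class = character(),
    disease_class = character(), disease = character(),
    treatment_class = character(), contains_chemotherapy = logical()
  )
  records <- tibble::tibble(
    study_id = character(), dose_label = character(),
    dose_components = character(), n_evaluable_dlt = numeric(),
    n_dlt = numeric(), n_evaluable_or = numeric(), n_or = numeric()
  )
  db <- dose_db(studies, records)
  f <- tempfile(fileext = ".csv")
  write_database(db, f)
  expect_length(readLines(f), 1)
})

test_that("a pre-formed series_id column is honoured when present", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,year,design_class,disease_class,disease,treatment_class,contains_chemotherapy,dose_label,dose_components,n_evaluable_dlt,n_dlt,n_evaluable_or,n_or,series_id",
    "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d1,A=10,3,0,,,g1",
    "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d2,A=20,3,1,,,g1",
    "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d3,A=15,6,2,,,g2"
  ), f)
  db <- read_database(f)
  out <- build_all_series(db, "DLT")
  expect_length(out, 2)
  ids <- vapply(out, function(s) s$series_id, character(1))
  expect_setequal(ids, c("s1/DLT/g1", "s1/DLT/g2"))
  k <- vapply(out, function(s) nrow(s$points), integer(1))
  expect_setequal(k, c(2L, 1L))
  # a non-ascending pre-formed series is an error
  lines <- readLines(f)
  lines[3] <- "s1,2012,rule_based,non_haematological,Solid tumours,Inhibitor,FALSE,d2,A=5,3,1,,,g1"
  writeLines(lines, f)
  expect_error(build_all_series(read_database(f), "DLT"), "ascending")
})

test_that("characteristics table counts, percentages, and dose-level IQR", {
  studies <- tibble::tibble(
    study_id = c("s1", "s2"), year = c(2010, 2012),
    design_class = c("rule_based", "model_based"),
    disease_class = c("haematological", "non_haematological"),
    disease = c("AML", "Solid tumours"),
    treatment_class = c("Inhibitor", "Chemotherapy"),
    contains_chemotherapy = c(FALSE, TRUE)
  )
  records <- tibble::tibble(
    study_id = c("s1", "s2"), dose_label = c("d1", "d1"),
    dose_components = c("A=10", "A=10"),
    n_evaluable_dlt = c(3, 3), n_dlt = c(0, 1),
    n_evaluable_or = c(NA, NA), n_or = c(NA, NA)
  )
  db <- dose_db(studies, records)
  sd <- list(
    analysis_series("s1", "DLT", n = c(3, 3), events = c(0, 1)),
    analysis_series("s2", "DLT", n = rep(3, 4), events = rep(0, 4)),
    analysis_series("s2", "DLT", n = rep(3, 5), events = rep(1, 5))
  )
  ct <- characteristics_table(db, sd, list())
  design <- ct[ct$block == "Experimental design", ]
  expect_equal(design$n_manuscripts[design$category == "rule_based"], 1)
  expect_equal(design$pct_manuscripts[design$category == "rule_based"], 50)
  # counts within each block conserve the totals
  for (b in setdiff(unique(ct$block), "Number of dose-levels")) {
    rows <- ct[ct$block == b, ]
    expect_equal(sum(rows$n_manuscripts), 2)
    expect_equal(sum(rows$n_dlt_series), 3)
  }
  # series of 2, 4, 5 levels: type-7 quantiles give median 4, IQR (3, 4.5)
  lvl <- ct[ct$block == "Number of dose-levels", ]
  expect_equal(lvl$category, sprintf("%g (%g, %g)", 4, 3, 4.5))
  expect_equal(lvl$n_dlt_series, 3)
  expect_match(format(ct), "rule_based: 1 \\(50%\\)")
})

test_that("empty inputs give a table of zeros, not an error", {
  sim <- sample_database(scenario_spec(n_studies = 2, seed = 5))
  ct <- characteristics_table(sim$db, list(), list())
  expect_true(all(ct$n_dlt_series == 0, na.rm = TRUE))
  lvl <- ct[ct$block == "Number of dose-levels", ]
  expect_equal(lvl$category, "0 (0, 0)")
})
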