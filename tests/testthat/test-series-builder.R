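test_that("dose comparison implements the component-wise product order", {
  d1 <- dose_combination(c(A = 10, B = 20))
  d2 <- dose_combination(c(A = 20, B = 10))
  d3 <- dose_combination(c(A = 20, B = 20))
  expect_identical(compare_doses(d1, d2), "incomparable")
  expect_identical(compare_doses(d1, d3), "less")
  expect_identical(compare_doses(d3, d2), "greater")
  expect_identical(compare_doses(d1, d1), "equal")
  # an agent absent from one dose counts as amount zero
  a <- dose_combination(c(A = 10))
  ab <- dose_combination(c(A = 10, B = 5))
  expect_identical(compare_doses(a, ab), "less")
  expect_identical(compare_doses(ab, a), "greater")
  b <- dose_combination(c(B = 10))
  expect_identical(compare_doses(a, b), "incomparable")
})

test_that("the crossed-pair combination splits into two series sharing the top dose", {
  ch <- build_series(worked_example_doses())
  expect_length(ch, 2)
  expect_equal(sort(vapply(ch, paste, character(1), collapse = ",")),
               c("1,3", "2,3"))
})

test_that("ordered inputs return one chain; diamonds split around the middle", {
  ordered <- lapply(c(10, 20, 30), function(a) dose_combination(c(A = a)))
  expect_equal(build_series(ordered), list(1:3))
  ch <- build_series(diamond_doses())
  expect_length(ch, 2)
  expect_equal(sort(vapply(ch, paste, character(1), collapse = ",")),
               c("1,2,4", "1,3,4"))
  expect_equal(build_series(list()), list())
  dup <- list(dose_combination(c(A = 10)), dose_combination(c(A = 10), "other"))
  expect_error(build_series(dup), "distinct")
})

test_that("chain covers satisfy the series-formation rules on random posets", {
  set.seed(101)
  for (case in 1:30) {
    n <- sample(3:7, 1)
    doses <- random_dose_poset(n, two_agent = runif(1) < 0.8)
    ch <- build_series(doses)
    # coverage: every dose in at least one chain
    expect_setequal(unique(unlist(ch)), seq_len(n))
    # chains strictly ascending under the partial order
    for (c1 in ch) {
      if (length(c1) > 1) {
        for (i in seq_len(length(c1) - 1)) {
          expect_identical(compare_doses(doses[[c1[i]]], doses[[c1[i + 1]]]),
                           "less")
        }
      }
      # maximality: no dose extends the chain
      for (d in setdiff(seq_len(n), c1)) {
        cmps <- vapply(c1, function(i) compare_doses(doses[[d]], doses[[i]]),
                       character(1))
        expect_false(all(cmps %in% c("less", "greater")))
      }
    }
    # the longest emitted chain is a maximum chain of the poset
    expect_equal(max(lengths(ch)), bf_longest_chain(doses))
    # repetition count and selection agree with the brute-force optimum
    oracle <- bf_chain_cover(doses)
    if (!is.null(oracle)) {
      expect_equal(sum(lengths(ch)), sum(lengths(oracle)))
      key <- function(cc) sort(vapply(cc, paste, character(1), collapse = ","))
      expect_equal(key(ch), key(oracle))
    }
  }
})

records_for <- function(doses, n_dlt, e_dlt, n_or = NA, e_or = NA) {
  tibble::tibble(
    study_id = "s1",
    dose_label = vapply(doses, function(d) d$label, character(1)),
    dose_components = vapply(doses, function(d) {
      paste(names(d$components), d$components, sep = "=", collapse = "; ")
    }, character(1)),
    n_evaluable_dlt = n_dlt, n_dlt = e_dlt,
    n_evaluable_or = n_or, n_or = e_or
  )
}

test_that("analysis series attach counts and ordinal levels along each chain", {
  ordered <- lapply(c(10, 20, 30), function(a) {
    dose_combination(c(A = a), sprintf("d%d", a / 10))
  })
  recs <- records_for(ordered, n_dlt = c(3, 3, 6), e_dlt = c(0, 1, 2))
  out <- make_analysis_series(recs, "DLT")
  expect_length(out, 1)
  expect_equal(out[[1]]$points$level, 1:3)
  expect_equal(out[[1]]$points$events, c(0L, 1L, 2L))
  expect_true(out[[1]]$fittable)
})

test_that("the worked combination example yields two series sharing the top counts", {
  recs <- records_for(worked_example_doses(),
                      n_dlt = c(3, 3, 6), e_dlt = c(0, 1, 2))
  out <- make_analysis_series(recs, "DLT")
  expect_length(out, 2)
  for (sr in out) {
    expect_equal(nrow(sr$points), 2)
    expect_equal(sr$points$level, 1:2)
    # dose 3's counts feature in both series
    expect_equal(sr$points$n[2], 6L)
    expect_equal(sr$points$events[2], 2L)
  }
  expect_setequal(vapply(out, function(s) s$points$dose_label[1], character(1)),
                  c("d1", "d2"))
})

test_that("series are built only over doses reporting the requested outcome", {
  ordered <- lapply(c(10, 20, 30, 40), function(a) {
    dose_combination(c(A = a), sprintf("d%d", a / 10))
  })
  recs <- records_for(ordered, n_dlt = rep(3, 4), e_dlt = c(0, 0, 1, 2),
                      n_or = c(3, NA, 3, NA), e_or = c(1, NA, 2, NA))
  out_or <- make_analysis_series(recs, "OR")
  expect_length(out_or, 1)
  expect_equal(nrow(out_or[[1]]$points), 2)
  expect_equal(out_or[[1]]$points$dose_label, c("d1", "d3"))
  # a study with no OR counts at all yields an empty list, not an error
  recs2 <- records_for(ordered, n_dlt = rep(3, 4), e_dlt = rep(0, 4))
  expect_length(make_analysis_series(recs2, "OR"), 0)
})

test_that("orphan doses become flagged non-fittable singleton series", {
  doses <- list(dose_combination(c(A = 10), "a"),
                dose_combination(c(B = 10), "b"))
  recs <- records_for(doses, n_dlt = c(3, 3), e_dlt = c(0, 1))
  out <- make_analysis_series(recs, "DLT")
  expect_length(out, 2)
  expect_false(any(vapply(out, function(s) s$fittable, logical(1))))
})
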