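test_that("transition tallies match an independent per-record counting loop", {
  set.seed(42)
  for (rep in 1:50) {
    id <- sample(side_effect_ids(), 1)
    cohort <- random_cell_cohort(sample(10:120, 1), "SBRT", id)
    tl <- tally_transitions(cohort, "SBRT", id)
    expect_identical(tl$counts, naive_tally(cohort, id))
    expect_identical(sum(tl$counts), nrow(cohort))
    expect_identical(tl$row_totals, rowSums(naive_tally(cohort, id)))
  }
})

test_that("tallying validates its inputs", {
  expect_identical(
    sum(tally_transitions(
      fixture_fig1_cohort()[0, ], "SBRT", "erectile_function")$counts),
    0L
  )
  mixed <- fixture_fig1_cohort()
  mixed$treatment_id[1] <- "EBRT_standard"
  expect_error(tally_transitions(mixed, "SBRT", "erectile_function"),
    class = "prostaid_validation_error")
  offscale <- fixture_fig1_cohort()
  offscale$post_level[1] <- "110%"
  expect_error(tally_transitions(offscale, "SBRT", "erectile_function"),
    class = "prostaid_validation_error")
})

test_that("row normalization reproduces hand-computed probabilities", {
  counts <- matrix(0L, 5, 5)
  counts[1, ] <- c(2L, 1L, 1L, 0L, 0L)
  m <- estimate_matrix(counts, "SBRT", "erectile_function")
  expect_equal(unname(m$probabilities[1, ]), c(0.5, 0.25, 0.25, 0, 0))
  expect_identical(unname(m$row_totals[1]), 4)

  # one record per diagonal cell -> identity matrix
  m2 <- estimate_matrix(diag(1L, 5), "SBRT", "erectile_function")
  expect_equal(unname(m2$probabilities), diag(1, 5))

  expect_error(estimate_matrix(matrix(-1L, 5, 5), "SBRT",
    "erectile_function"), class = "prostaid_validation_error")
  expect_error(estimate_matrix(matrix(0L, 4, 4), "SBRT",
    "erectile_function"), class = "prostaid_validation_error")
})

test_that("occupied rows are row-stochastic and empty rows follow the identity policy", {
  set.seed(7)
  for (rep in 1:20) {
    id <- sample(side_effect_ids(), 1)
    cohort <- random_cell_cohort(sample(c(3, 15, 80), 1), "EBRT_HDR", id)
    tl <- tally_transitions(cohort, "EBRT_HDR", id)
    m <- estimate_matrix(tl$counts, "EBRT_HDR", id)
    expect_true(all(m$probabilities >= 0))
    expect_true(all(abs(rowSums(m$probabilities) - 1) < 1e-9))
    empty <- m$row_totals == 0
    expect_identical(m$empty_rows, unname(empty))
    for (i in which(empty)) {
      expect_equal(unname(m$probabilities[i, ]),
        as.numeric(seq_along(m$levels) == i))
    }
  }
})

test_that("add-alpha smoothing shifts mass without breaking stochasticity", {
  counts <- matrix(0L, 5, 5)
  counts[1, 1] <- 10L
  m <- estimate_matrix(counts, "SBRT", "erectile_function", alpha = 1)
  expect_equal(unname(m$probabilities[1, ]), c(11, 1, 1, 1, 1) / 15)
  # with smoothing, unobserved rows become uniform rather than identity
  expect_equal(unname(m$probabilities[2, ]), rep(0.2, 5))
  expect_true(all(abs(rowSums(m$probabilities) - 1) < 1e-9))
  expect_false(any(m$empty_rows))
})

test_that("the active-surveillance convention is the identity matrix", {
  m <- identity_toxicity_matrix("erectile_function")
  expect_equal(unname(m$probabilities), diag(1, 5))
  m6 <- identity_toxicity_matrix("nocturia")
  expect_equal(unname(m6$probabilities), diag(1, 6))
  # identity row + exceedance = indicator(pre worse than threshold)
  lv <- m$levels
  for (pre in lv) {
    for (thr in lv) {
      expect_equal(
        exceedance_probability(m, pre, thr),
        as.numeric(is_worse("erectile_function", pre, thr))
      )
    }
  }
})

test_that("pre-treatment state predicts post-treatment state when the truth is diagonal", {
  set.seed(11)
  lv <- scale_levels("erectile_function")
  n <- 1000
  pre <- sample(lv, n, replace = TRUE)
  truth <- generate_truth_matrices("SBRT", diagonal = 0.85, decay = 0.5,
    jitter = 0, seed = 1)
  mat <- truth$matrix[[which(truth$side_effect_id == "erectile_function")]]
  post <- vapply(pre, function(p) {
    sample(lv, 1, prob = mat$probabilities[match(p, lv), ])
  }, character(1))
  cohort <- tibble::tibble(patient_id = as.character(seq_len(n)),
    treatment_id = "SBRT", side_effect_id = "erectile_function",
    pre_level = pre, post_level = post)
  res <- assess_pretreatment_predictiveness(cohort)
  expect_gt(res$statistic, 0.7)
  expect_lt(res$p_value, 1e-6)

  # shuffled post levels: no association
  cohort$post_level <- sample(cohort$post_level)
  res0 <- assess_pretreatment_predictiveness(cohort)
  expect_lt(abs(res0$statistic), 0.1)

  # perfectly monotone mapping: rho exactly 1
  cohort$post_level <- cohort$pre_level
  res1 <- assess_pretreatment_predictiveness(cohort)
  expect_equal(res1$statistic, 1)
})

test_that("degenerate predictiveness inputs are undefined, not zero", {
  cohort <- fixture_fig1_cohort()  # constant pre level
  res <- assess_pretreatment_predictiveness(cohort)
  expect_true(is.na(res$statistic))
  expect_true(is.na(res$p_value))
})

test_that("matrices round-trip through JSON and CSV", {
  tl <- tally_transitions(fixture_fig1_cohort(), "SBRT", "erectile_function")
  m <- estimate_matrix(tl$counts, "SBRT", "erectile_function")

  jpath <- withr::local_tempfile(fileext = ".json")
  write_toxicity_matrix(m, jpath)
  back <- read_toxicity_matrix(jpath)
  expect_identical(back$counts, m$counts)
  expect_identical(back$probabilities, m$probabilities)
  expect_identical(back$treatment_id, "SBRT")

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_toxicity_matrix(m, cpath)
  back2 <- read_toxicity_matrix(cpath, "SBRT", "erectile_function")
  expect_identical(back2$counts, m$counts)
  expect_error(read_toxicity_matrix(cpath),
    class = "prostaid_validation_error")  # CSV needs ids
})

test_that("malformed matrix files are rejected", {
  jpath <- withr::local_tempfile(fileext = ".json")
  # probabilities inconsistent with counts / rows summing to 1.5
  jsonlite::write_json(list(
    treatment_id = "SBRT", side_effect_id = "erectile_function",
    levels = scale_levels("erectile_function"),
    counts = lapply(1:5, function(i) as.list(as.integer(diag(5)[i, ]))),
    probabilities = lapply(1:5, function(i) as.list(1.5 * diag(5)[i, ]))
  ), jpath, auto_unbox = TRUE)
  expect_error(read_toxicity_matrix(jpath),
    class = "prostaid_validation_error")

  # unknown level label
  jsonlite::write_json(list(
    treatment_id = "SBRT", side_effect_id = "erectile_function",
    levels = c("110%", "75%", "50%", "25%", "0%"),
    counts = lapply(1:5, function(i) as.list(as.integer(diag(5)[i, ])))
  ), jpath, auto_unbox = TRUE)
  expect_error(read_toxicity_matrix(jpath),
    class = "prostaid_validation_error")
})

test_that("cohort-wide estimation yields one matrix per treatment by side effect", {
  truth <- generate_truth_matrices(seed = 5)
  cohort <- sample_cohort(cohort_spec(truth, n_per_treatment = 40, seed = 5))
  mats <- estimate_toxicity_matrices(cohort)
  expect_identical(nrow(mats), nrow(truth))
  expect_true(all(vapply(mats$matrix, inherits, logical(1),
    "toxicity_matrix")))
  expect_true(all(vapply(mats$matrix, function(m)
    all(abs(rowSums(m$probabilities) - 1) < 1e-9), logical(1))))
  d <- tidy(mats$matrix[[1]])
  expect_identical(nrow(d), length(mats$matrix[[1]]$levels)^2L |> as.integer())
  expect_equal(sum(d$n), mats$n[1])
})
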