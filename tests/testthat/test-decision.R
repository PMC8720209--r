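# A two-treatment catalog where every number is fixed by hand.
toy_catalog <- function(p_a = 0.9, p_b = 0.8) {
  prostaid:::new_treatment_catalog(
    treatments = c("SBRT", "EBRT_standard"),
    eligibility = list(INTERMEDIATE = c("SBRT", "EBRT_standard")),
    success = tibble::tibble(
      treatment_id = c("SBRT", "EBRT_standard"),
      risk_broad = "INTERMEDIATE",
      p_ffbf = c(p_a, p_b)
    )
  )
}

# Identity matrices for every side effect of one treatment.
identity_set <- function(treatment_id) {
  tibble::tibble(
    treatment_id = treatment_id,
    side_effect_id = side_effect_ids(),
    matrix = lapply(side_effect_ids(), identity_toxicity_matrix,
      treatment_id = treatment_id)
  )
}

# Matrices that send every pre level to the worst level with certainty.
worst_set <- function(treatment_id) {
  tibble::tibble(
    treatment_id = treatment_id,
    side_effect_id = side_effect_ids(),
    matrix = lapply(side_effect_ids(), function(id) {
      k <- length(scale_levels(id))
      p <- matrix(0, k, k)
      p[, k] <- 1
      as_toxicity_matrix(p, treatment_id, id)
    })
  )
}

test_that("the hand-computable additive example returns $800 exactly", {
  catalog <- toy_catalog(p_a = 0.9)
  # ED row: half the mass stays at 100%, half falls to 25% -> exceedance 0.5
  # above a 50% threshold; other side effects identity.
  ed <- matrix(0, 5, 5); ed[, 1] <- 0.5; ed[, 4] <- 0.5
  mats <- identity_set("SBRT")
  mats$matrix[[which(mats$side_effect_id == "erectile_function")]] <-
    as_toxicity_matrix(ed, "SBRT", "erectile_function")

  ids <- side_effect_ids()
  worst <- vapply(ids, function(id) utils::tail(scale_levels(id), 1),
    character(1))
  thr <- as.list(worst)
  thr$erectile_function <- "50%"
  profile <- validate_profile(preference_profile(
    thresholds = thr,
    wta_side_effect = stats::setNames(c(1000, 0, 0, 0), ids),
    wta_alternative_burden = c(SBRT = 100),
    wta_failure = 2000
  ), catalog)

  cc <- component_costs(best_health_state(), profile, "SBRT", mats,
    catalog, "INTERMEDIATE")
  expect_equal(cc$exceedance_erectile_function, 0.5)
  expect_equal(cc$se_cost, 500)
  expect_equal(cc$burden_cost, 100)
  expect_equal(cc$failure_cost, 200)
  expect_equal(cc$total, 800)
})

test_that("all-zero dollars yield zero components; tolerated surveillance costs nothing", {
  catalog <- default_catalog()
  profile <- tolerant_profile(catalog)
  mats <- generate_truth_matrices(
    setdiff(treatment_ids(), "active_surveillance"), seed = 2)
  cc <- component_costs(best_health_state(), profile, "SBRT", mats, catalog,
    "LOW")
  expect_identical(cc$se_cost, 0)
  expect_identical(unname(cc$burden_cost), 0)
  expect_identical(cc$failure_cost, 0)
  expect_identical(cc$total, 0)

  # active surveillance with pre-state within all thresholds: exactly zero
  # side-effect cost, whatever the dollar values
  ids <- side_effect_ids()
  rich <- validate_profile(preference_profile(
    thresholds = stats::setNames(as.list(
      vapply(ids, function(id) scale_levels(id)[2], character(1))), ids),
    wta_side_effect = stats::setNames(rep(50000, 4), ids),
    wta_failure = 100000
  ), catalog)
  cc_as <- component_costs(best_health_state(), rich, "active_surveillance",
    NULL, catalog, "LOW")
  expect_identical(cc_as$se_cost, 0)
})

test_that("total always equals the sum of its three components", {
  set.seed(99)
  catalog <- toy_catalog()
  ids <- side_effect_ids()
  for (rep in 1:200) {
    mats <- dplyr::bind_rows(lapply(c("SBRT", "EBRT_standard"), function(tr) {
      tibble::tibble(treatment_id = tr, side_effect_id = ids,
        matrix = lapply(ids, function(id)
          as_toxicity_matrix(random_prob_matrix(id), tr, id)))
    }))
    profile <- validate_profile(preference_profile(
      thresholds = stats::setNames(as.list(vapply(ids, function(id)
        sample(scale_levels(id), 1), character(1))), ids),
      wta_side_effect = stats::setNames(round(stats::runif(4, 0, 5e4)), ids),
      wta_alternative_burden = stats::setNames(
        round(stats::runif(2, 0, 5e4)), c("SBRT", "EBRT_standard")),
      wta_failure = round(stats::runif(1, 0, 5e4))
    ), catalog)
    state <- parse_health_state(stats::setNames(as.list(
      vapply(ids, function(id) sample(scale_levels(id), 1), character(1))),
      ids))
    ev <- rank_alternatives(state, profile, mats, catalog, "INTERMEDIATE")
    expect_equal(ev$total,
      ev$se_cost + ev$burden_cost + ev$failure_cost, tolerance = 1e-12)
    expect_identical(sum(ev$is_best), 1L)
    expect_setequal(ev$rank[ev$eligible], seq_len(sum(ev$eligible)))
  }
})

test_that("ranking orders by ascending burden and breaks ties deterministically", {
  catalog <- toy_catalog(p_a = 0.9, p_b = 0.9)
  mats <- dplyr::bind_rows(identity_set("SBRT"), identity_set("EBRT_standard"))
  profile <- tolerant_profile(catalog)
  profile$wta_alternative_burden[] <- c(SBRT = 800, EBRT_standard = 300)
  ev <- rank_alternatives(best_health_state(), profile, mats, catalog,
    "INTERMEDIATE")
  expect_identical(ev$rank[ev$alternative == "SBRT"], 2L)
  expect_identical(ev$rank[ev$alternative == "EBRT_standard"], 1L)
  expect_true(ev$is_best[ev$alternative == "EBRT_standard"])

  # exact tie: the catalog order (least-intensive first) wins
  profile$wta_alternative_burden[] <- c(SBRT = 500, EBRT_standard = 500)
  tie <- rank_alternatives(best_health_state(), profile, mats, catalog,
    "INTERMEDIATE")
  expect_true(tie$is_best[tie$alternative == "SBRT"])

  # loading burden onto SBRT weakly lowers its rank
  profile$wta_alternative_burden[] <- c(SBRT = 10000, EBRT_standard = 500)
  worse <- rank_alternatives(best_health_state(), profile, mats, catalog,
    "INTERMEDIATE")
  expect_gte(worse$rank[worse$alternative == "SBRT"],
    tie$rank[tie$alternative == "SBRT"])
})

test_that("ranking is invariant to input row order", {
  catalog <- default_catalog()
  mats <- generate_truth_matrices(
    setdiff(treatment_ids(), "active_surveillance"), seed = 4)
  profile <- validate_profile(read_preference_profile(
    demo_bundle("demo_preferences.json")), catalog)
  state <- best_health_state()
  ev <- rank_alternatives(state, profile, mats, catalog, "LOW")
  set.seed(1)
  shuffled <- mats[sample(nrow(mats)), ]
  ev2 <- rank_alternatives(state, profile, shuffled, catalog, "LOW")
  expect_identical(tibble::as_tibble(ev), tibble::as_tibble(ev2))
})

test_that("a component-wise dominated alternative never outranks its dominator", {
  catalog <- toy_catalog(p_a = 0.95, p_b = 0.6)
  mats <- dplyr::bind_rows(identity_set("SBRT"), worst_set("EBRT_standard"))
  ids <- side_effect_ids()
  set.seed(17)
  for (rep in 1:100) {
    profile <- validate_profile(preference_profile(
      thresholds = stats::setNames(as.list(vapply(ids, function(id)
        sample(scale_levels(id), 1), character(1))), ids),
      wta_side_effect = stats::setNames(round(stats::runif(4, 0, 1e4)), ids),
      wta_alternative_burden = c(SBRT = 0,
        EBRT_standard = round(stats::runif(1, 0, 1e4))),
      wta_failure = round(stats::runif(1, 0, 1e4))
    ), catalog)
    ev <- rank_alternatives(best_health_state(), profile, mats, catalog,
      "INTERMEDIATE")
    expect_lt(ev$rank[ev$alternative == "SBRT"],
      ev$rank[ev$alternative == "EBRT_standard"])
  }
})

test_that("eligibility follows the catalog map", {
  catalog <- default_catalog()
  expect_true(all(c("active_surveillance", "SBRT") %in%
    eligible_alternatives("LOW", catalog)))
  expect_false("active_surveillance" %in%
    eligible_alternatives("HIGH", catalog))
  expect_error(eligible_alternatives("MODERATE", catalog),
    class = "prostaid_validation_error")
  expect_error(prostaid:::new_treatment_catalog(
    treatments = "SBRT", eligibility = list(LOW = character()),
    success = tibble::tibble(treatment_id = "SBRT", risk_broad = "LOW",
      p_ffbf = 0.9)), class = "prostaid_validation_error")
})

test_that("every alternative has a supporting preference profile (no deterministic dominance)", {
  catalog <- default_catalog()
  mats <- generate_truth_matrices(
    setdiff(treatment_ids(), "active_surveillance"), seed = 1)
  state <- best_health_state()
  risk_for <- c(
    active_surveillance = "LOW", SBRT = "LOW", EBRT_standard = "LOW",
    EBRT_hypofractionated = "LOW", EBRT_HDR = "INTERMEDIATE",
    EBRT_ADT = "INTERMEDIATE", EBRT_HDR_ADT = "HIGH"
  )
  for (alt in names(risk_for)) {
    res <- find_supporting_preferences(alt, state, mats, catalog,
      risk_for[[alt]], search = search_config(seed = 1))
    expect_true(res$found, label = paste("supporting profile for", alt))
    ev <- rank_alternatives(state, res$profile, mats, catalog,
      risk_for[[alt]])
    expect_true(ev$is_best[ev$alternative == alt])
  }
})

test_that("with the burden lever off a strictly dominated alternative is honestly not-found", {
  catalog <- toy_catalog(p_a = 0.95, p_b = 0.6)
  mats <- dplyr::bind_rows(identity_set("SBRT"), worst_set("EBRT_standard"))
  res <- find_supporting_preferences("EBRT_standard", best_health_state(),
    mats, catalog, "INTERMEDIATE",
    search = search_config(burden_lever = FALSE, seed = 2))
  expect_false(res$found)
  expect_null(res$profile)
  expect_gt(res$n_tried, 0)

  winner <- find_supporting_preferences("SBRT", best_health_state(), mats,
    catalog, "INTERMEDIATE",
    search = search_config(burden_lever = FALSE, seed = 2))
  expect_true(winner$found)

  expect_error(find_supporting_preferences("EBRT_HDR", best_health_state(),
    mats, catalog, "INTERMEDIATE"), class = "prostaid_validation_error")
})

test_that("tidy, glance and autoplot summarize an evaluation", {
  catalog <- default_catalog()
  mats <- generate_truth_matrices(
    setdiff(treatment_ids(), "active_surveillance"), seed = 3)
  profile <- validate_profile(read_preference_profile(
    demo_bundle("demo_preferences.json")), catalog)
  ev <- rank_alternatives(best_health_state(), profile, mats, catalog, "LOW")
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), length(catalog$treatments))
  g <- glance(ev)
  expect_identical(g$n_eligible, sum(td$eligible))
  expect_identical(g$best_alternative, td$alternative[which(td$is_best)])
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
  pm <- autoplot(mats$matrix[[1]])
  expect_s3_class(pm, "ggplot")
})
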