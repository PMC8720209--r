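# Shared fixtures and independent oracles for the suite.

# Naive per-record counting loop: the independent oracle for
# tally_transitions.
naive_tally <- function(records, side_effect_id) {
  lv <- scale_levels(side_effect_id)
  counts <- matrix(0L, length(lv), length(lv),
    dimnames = list(pre = lv, post = lv))
  for (r in seq_len(nrow(records))) {
    i <- match(records$pre_level[r], lv)
    j <- match(records$post_level[r], lv)
    counts[i, j] <- counts[i, j] + 1L
  }
  counts
}

# Brute-force exceedance: enumerate every post outcome and add up the mass
# on outcomes strictly worse than the threshold.
brute_exceedance <- function(probabilities, levels, pre_level, threshold) {
  total <- 0
  for (j in seq_along(levels)) {
    if (match(levels[j], levels) > match(threshold, levels)) {
      total <- total + probabilities[match(pre_level, levels), j]
    }
  }
  total
}

# One random paired-record cohort for a single (treatment, side effect) cell.
random_cell_cohort <- function(n, treatment_id = "SBRT",
                               side_effect_id = "erectile_function") {
  lv <- scale_levels(side_effect_id)
  tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    treatment_id = treatment_id,
    side_effect_id = side_effect_id,
    pre_level = sample(lv, n, replace = TRUE),
    post_level = sample(lv, n, replace = TRUE)
  )
}

# A random row-stochastic matrix over the levels of one side effect.
random_prob_matrix <- function(side_effect_id) {
  k <- length(scale_levels(side_effect_id))
  m <- matrix(stats::rexp(k * k), k, k)
  m / rowSums(m)
}

# A best-possible pre-treatment health state.
best_health_state <- function() {
  parse_health_state(list(
    erectile_function = "100%", urinary_incontinence = "rarely or never",
    nocturia = "0", bowel_incontinence = "rarely or never"
  ))
}

# A fully tolerant preference profile (worst-level thresholds, zero dollars).
tolerant_profile <- function(catalog = default_catalog()) {
  ids <- side_effect_ids()
  worst <- vapply(ids, function(id) utils::tail(scale_levels(id), 1),
    character(1))
  validate_profile(preference_profile(
    thresholds = as.list(worst),
    wta_side_effect = stats::setNames(rep(0, length(ids)), ids),
    wta_failure = 0
  ), catalog)
}

demo_bundle <- function(file) {
  system.file("extdata", file, package = "prostaid")
}
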