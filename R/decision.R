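#' Wrap a probability matrix as a toxicity matrix
#'
#' Useful for ground-truth matrices from the synthetic-cohort generator,
#' which carry probabilities but no observed counts.
#'
#' @param probabilities Square row-stochastic matrix over the levels of
#'   `side_effect_id`, best level first.
#' @param treatment_id,side_effect_id Identity of the matrix.
#' @param scales A scale registry tibble.
#' @return A `toxicity_matrix` with `counts = NULL`.
#' @export
as_toxicity_matrix <- function(probabilities, treatment_id, side_effect_id,
                               scales = side_effect_scales()) {
  lv <- scale_levels(side_effect_id, scales)
  k <- length(lv)
  if (!is.matrix(probabilities) || nrow(probabilities) != k ||
    ncol(probabilities) != k) {
    rlang::abort(paste0("probabilities must be ", k, "x", k, " for ",
      side_effect_id), class = "prostaid_validation_error")
  }
  if (any(probabilities < 0) || any(abs(rowSums(probabilities) - 1) > 1e-9)) {
    rlang::abort("probabilities must be nonnegative with rows summing to 1",
      class = "prostaid_validation_error")
  }
  dimnames(probabilities) <- list(pre = lv, post = lv)
  structure(
    list(treatment_id = treatment_id, side_effect_id = side_effect_id,
      levels = lv, counts = NULL, row_totals = NULL,
      probabilities = probabilities, empty_rows = rep(FALSE, k), alpha = 0),
    class = "toxicity_matrix"
  )
}

# Look up the matrix for (treatment, side effect) in a matrix-set tibble
# (columns treatment_id, side_effect_id, matrix). Active surveillance falls
# back to the identity convention when no matrix is supplied.
lookup_matrix <- function(matrices, treatment_id, side_effect_id,
                          scales = side_effect_scales()) {
  if (!is.null(matrices)) {
    hit <- which(matrices$treatment_id == treatment_id &
      matrices$side_effect_id == side_effect_id)
    if (length(hit) == 1) return(matrices$matrix[[hit]])
  }
  if (treatment_id == "active_surveillance") {
    return(identity_toxicity_matrix(side_effect_id, scales = scales))
  }
  rlang::abort(paste0("No toxicity matrix for (", treatment_id, ", ",
    side_effect_id, ")"), class = "prostaid_validation_error")
}

#' Component costs of one treatment alternative
#'
#' The linear additive value function prices an alternative as the sum of
#' three expected burdens, all in dollars (lower is better):
#' side-effect cost = sum over the four side effects of
#' P(post level worse than threshold | pre level) x WTA(side effect);
#' burden cost = the stated payment to endure the alternative's non-medical
#' attributes; failure cost = (1 - P(5-year FFBF)) x WTA(failure).
#'
#' @param pre_state A health state tibble from [parse_health_state()].
#' @param profile A validated [preference_profile()].
#' @param alternative A treatment id.
#' @param matrices A matrix-set tibble (`treatment_id`, `side_effect_id`,
#'   `matrix` list column), e.g. from [estimate_toxicity_matrices()].
#'   Active surveillance defaults to the identity convention.
#' @param catalog A treatment catalog.
#' @param risk_broad Broad risk category of the patient.
#' @param scales A scale registry tibble.
#' @return A one-row tibble: `alternative`, one `exceedance_*` column per
#'   side effect, `se_cost`, `burden_cost`, `failure_cost`, `total`.
#' @export
component_costs <- function(pre_state, profile, alternative, matrices,
                            catalog = default_catalog(), risk_broad,
                            scales = side_effect_scales()) {
  exc <- vapply(scales$side_effect_id, function(id) {
    m <- lookup_matrix(matrices, alternative, id, scales)
    exceedance_probability(m, health_state_level(pre_state, id),
      profile$thresholds[[id]], scales)
  }, numeric(1))
  se_cost <- sum(exc * profile$wta_side_effect[scales$side_effect_id])
  burden_cost <- unname(profile$wta_alternative_burden[alternative])
  if (is.na(burden_cost)) burden_cost <- 0
  failure_cost <- (1 - success_probability(catalog, alternative, risk_broad)) *
    profile$wta_failure
  out <- tibble::tibble(alternative = alternative)
  for (id in scales$side_effect_id) out[[paste0("exceedance_", id)]] <- exc[[id]]
  out$se_cost <- se_cost
  out$burden_cost <- burden_cost
  out$failure_cost <- failure_cost
  out$total <- se_cost + burden_cost + failure_cost
  out
}

#' Rank eligible treatment alternatives by expected dollar burden
#'
#' Evaluates every catalog alternative for the patient's risk category,
#' ranks the eligible ones by ascending total expected cost (lower burden =
#' better) and flags the unique best. Ties are broken by the fixed catalog
#' order, least-intensive treatment first, so ranking is deterministic and
#' independent of input order. The result is a pure function of its inputs:
#' re-running after any single preference change reproduces the real-time
#' toggle semantics of an interactive aid.
#'
#' @inheritParams component_costs
#' @return A `da_evaluation` tibble: one row per catalog alternative with
#'   `eligible`, the component-cost columns (NA when ineligible), `rank`
#'   (1..n over eligible alternatives) and `is_best`.
#' @export
rank_alternatives <- function(pre_state, profile, matrices,
                              catalog = default_catalog(), risk_broad,
                              scales = side_effect_scales()) {
  elig <- eligible_alternatives(risk_broad, catalog)
  rows <- lapply(catalog$treatments, function(alt) {
    if (alt %in% elig) {
      dplyr::mutate(
        component_costs(pre_state, profile, alt, matrices, catalog,
          risk_broad, scales),
        eligible = TRUE, .after = 1
      )
    } else {
      tibble::tibble(alternative = alt, eligible = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  # stable order = catalog order, so ties resolve least-intensive first
  ord <- order(out$total[out$eligible])
  out$rank <- NA_integer_
  out$rank[out$eligible][ord] <- seq_along(ord)
  out$is_best <- !is.na(out$rank) & out$rank == 1L
  structure(out,
    class = c("da_evaluation", class(out)),
    risk_broad = risk_broad,
    pre_state = pre_state,
    profile = profile
  )
}

#' @export
tidy.da_evaluation <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.da_evaluation <- function(x, ...) {
  best <- x$alternative[x$is_best]
  tibble::tibble(
    risk_broad = attr(x, "risk_broad"),
    n_alternatives = nrow(x),
    n_eligible = sum(x$eligible),
    best_alternative = best,
    best_total = x$total[x$is_best]
  )
}

#' Bar chart of the evaluation result
#'
#' Renders the expected dollar burden of each eligible alternative, best
#' alternative in teal and the others in red.
#'
#' @param object A `da_evaluation` from [rank_alternatives()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.da_evaluation <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$eligible)
  d$alternative <- factor(d$alternative, levels = rev(d$alternative[order(d$rank)]))
  ggplot2::ggplot(d, ggplot2::aes(.data$total, .data$alternative,
    fill = .data$is_best)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#008080", `FALSE` = "#C0392B"),
      labels = c(`TRUE` = "best", `FALSE` = "other"), name = NULL) +
    ggplot2::labs(
      x = "expected burden (dollars; lower is better)", y = NULL,
      title = paste0("Treatment ranking (", attr(object, "risk_broad"),
        " risk)")
    ) +
    ggplot2::theme_minimal()
}

#' Text rendering of an evaluation
#'
#' @param x A `da_evaluation`.
#' @param ... Passed on.
#' @export
print.da_evaluation <- function(x, ...) {
  cat("Decision-aid evaluation —", attr(x, "risk_broad"), "risk\n")
  d <- dplyr::arrange(
    dplyr::select(
      dplyr::filter(tibble::as_tibble(x), .data$eligible),
      "alternative", "se_cost", "burden_cost", "failure_cost", "total",
      "rank", "is_best"
    ),
    .data$rank
  )
  print(as.data.frame(d), row.names = FALSE)
  inelig <- x$alternative[!x$eligible]
  if (length(inelig) > 0) {
    cat("Ineligible for this risk group:", paste(inelig, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Search configuration for the preference-space search
#'
#' @param dollar_grid Candidate dollar values for side-effect,
#'   failure and burden weights.
#' @param burden_lever If `TRUE`, the per-alternative burden dollars are a
#'   free lever: the search may load arbitrary burden onto competitors.
#' @param n_random Number of seeded random dollar assignments tried per
#'   threshold combination, in addition to the structured single-attribute
#'   assignments.
#' @param seed Seed for the random draws.
#' @return A list of class `search_config`.
#' @export
search_config <- function(dollar_grid = c(0, 100, 1000, 10000),
                          burden_lever = TRUE, n_random = 25, seed = 1L) {
  structure(list(dollar_grid = dollar_grid, burden_lever = burden_lever,
    n_random = n_random, seed = as.integer(seed)), class = "search_config")
}

# Is `alternative` the unique minimizer of total cost under `profile`?
is_unique_best <- function(alternative, pre_state, profile, matrices, catalog,
                           risk_broad, scales) {
  ev <- rank_alternatives(pre_state, profile, matrices, catalog, risk_broad,
    scales)
  totals <- ev$total[ev$eligible]
  names(totals) <- ev$alternative[ev$eligible]
  tgt <- totals[[alternative]]
  all(totals[names(totals) != alternative] > tgt + 1e-9)
}

#' Find a preference profile under which an alternative wins
#'
#' Searches preference space for a profile making the given alternative the
#' unique minimizer of expected burden. With the burden lever enabled the
#' answer is immediate: load the maximum grid burden onto every competitor.
#' With the lever disabled the search walks a documented grid — every
#' combination of per-side-effect thresholds, crossed with structured
#' single-attribute dollar assignments from `dollar_grid` plus seeded random
#' assignments — and reports honest failure if nothing on the grid works
#' (e.g. for a strictly dominated alternative).
#'
#' @param alternative Target treatment id; must be eligible for `risk_broad`.
#' @inheritParams component_costs
#' @param search A [search_config()].
#' @return A list: `found` (logical), `profile` (the supporting
#'   `preference_profile`, or `NULL`), `n_tried` (profiles evaluated).
#' @export
find_supporting_preferences <- function(alternative, pre_state, matrices,
                                        catalog = default_catalog(),
                                        risk_broad,
                                        search = search_config(),
                                        scales = side_effect_scales()) {
  elig <- eligible_alternatives(risk_broad, catalog)
  if (!alternative %in% elig) {
    rlang::abort(paste0("'", alternative, "' is not eligible for ",
      risk_broad, " risk"), class = "prostaid_validation_error")
  }
  ids <- scales$side_effect_id
  worst <- stats::setNames(
    vapply(ids, function(id) utils::tail(scale_levels(id, scales), 1),
      character(1)), ids)
  base_burden <- stats::setNames(rep(0, length(catalog$treatments)),
    catalog$treatments)
  n_tried <- 0L

  try_profile <- function(profile) {
    profile <- validate_profile(profile, catalog, scales)
    n_tried <<- n_tried + 1L
    if (is_unique_best(alternative, pre_state, profile, matrices, catalog,
      risk_broad, scales)) profile else NULL
  }

  if (search$burden_lever) {
    burden <- base_burden
    burden[setdiff(elig, alternative)] <- max(search$dollar_grid)
    hit <- try_profile(preference_profile(
      thresholds = as.list(worst),
      wta_side_effect = stats::setNames(rep(0, length(ids)), ids),
      wta_alternative_burden = burden, wta_failure = 0
    ))
    if (!is.null(hit)) return(list(found = TRUE, profile = hit,
      n_tried = n_tried))
  }

  # Grid over threshold combinations x structured dollar assignments:
  # one attribute (a single side effect, or failure) carries each nonzero
  # grid value at a time, plus seeded random grid assignments. Exceedance
  # probabilities are precomputed per (alternative, side effect, threshold
  # level) so each candidate reduces to a dot product; a hit is re-verified
  # through the full ranking path before being returned.
  level_sets <- lapply(ids, function(id) scale_levels(id, scales))
  names(level_sets) <- ids
  exc <- lapply(ids, function(id) {
    pre <- health_state_level(pre_state, id)
    do.call(rbind, lapply(elig, function(alt) {
      m <- lookup_matrix(matrices, alt, id, scales)
      vapply(level_sets[[id]], function(thr)
        exceedance_probability(m, pre, thr, scales), numeric(1))
    }))
  })
  names(exc) <- ids
  fail_p <- vapply(elig, function(alt)
    1 - success_probability(catalog, alt, risk_broad), numeric(1))
  tgt_i <- match(alternative, elig)

  thr_grid <- expand.grid(lapply(level_sets, seq_along))
  nonzero <- setdiff(search$dollar_grid, 0)
  candidates <- list()
  for (v in nonzero) {
    for (id in ids) {
      wse <- stats::setNames(rep(0, length(ids)), ids)
      wse[id] <- v
      candidates[[length(candidates) + 1]] <- list(wse = wse, wf = 0)
    }
    candidates[[length(candidates) + 1]] <- list(
      wse = stats::setNames(rep(0, length(ids)), ids), wf = v)
  }
  set.seed(search$seed)
  random_dollars <- replicate(search$n_random, list(
    wse = stats::setNames(sample(search$dollar_grid, length(ids),
      replace = TRUE), ids),
    wf = sample(search$dollar_grid, 1)
  ), simplify = FALSE)
  candidates <- c(candidates, random_dollars)

  for (r in seq_len(nrow(thr_grid))) {
    E <- matrix(0, length(elig), length(ids), dimnames = list(elig, ids))
    for (id in ids) E[, id] <- exc[[id]][, thr_grid[[id]][r]]
    for (cand in candidates) {
      totals <- drop(E %*% cand$wse[ids]) + cand$wf * fail_p
      n_tried <- n_tried + 1L
      if (all(totals[-tgt_i] > totals[tgt_i] + 1e-9)) {
        thr <- purrr::imap(level_sets, function(lv, id) lv[thr_grid[[id]][r]])
        hit <- try_profile(preference_profile(
          thresholds = thr, wta_side_effect = cand$wse,
          wta_alternative_burden = base_burden, wta_failure = cand$wf
        ))
        if (!is.null(hit)) return(list(found = TRUE, profile = hit,
          n_tried = n_tried))
      }
    }
  }
  list(found = FALSE, profile = NULL, n_tried = n_tried)
}
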