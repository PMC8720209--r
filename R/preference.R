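#' Build a preference profile
#'
#' A preference profile records, per side effect, the patient's maximum
#' tolerated level ("once all side effects have stabilized 1+ year after
#' treatment") and the dollar amount we would have to pay the patient to
#' accept living strictly worse than that level for the rest of their life;
#' per treatment alternative, the payment required to endure its non-medical
#' attributes (visits, time at the hospital, ...); and the payment required
#' to accept biochemical failure. Amounts are willingness to GET PAID, so the
#' patient's account balance never limits the answer; the engine treats them
#' as burden magnitudes with no upper cap.
#'
#' @param thresholds Named character vector/list: side effect id -> a level
#'   of its scale (the maximum tolerance; the threshold level itself is
#'   tolerated).
#' @param wta_side_effect Named numeric: side effect id -> dollars >= 0.
#' @param wta_alternative_burden Named numeric: treatment id -> dollars >= 0
#'   (0 allowed and default for omitted treatments when validated against a
#'   catalog with `fill_missing_burden = TRUE`).
#' @param wta_failure Dollars >= 0 to accept biochemical failure.
#' @return A `preference_profile` object (a list with the four components).
#' @export
preference_profile <- function(thresholds, wta_side_effect,
                               wta_alternative_burden = numeric(),
                               wta_failure = 0) {
  structure(
    list(
      thresholds = as.list(thresholds),
      wta_side_effect = unlist(wta_side_effect),
      wta_alternative_burden = unlist(wta_alternative_burden),
      wta_failure = as.numeric(wta_failure)
    ),
    class = "preference_profile"
  )
}

#' Validate a preference profile against scales and catalog
#'
#' Checks the profile invariants — one threshold and one nonnegative dollar
#' value per side effect, a nonnegative burden per catalog alternative, a
#' nonnegative failure value — and normalizes all currency to whole dollars.
#'
#' @param profile A [preference_profile()].
#' @param catalog A treatment catalog, default [default_catalog()].
#' @param scales A scale registry tibble.
#' @param fill_missing_burden If `TRUE` (default), alternatives without a
#'   stated burden get $0 rather than an error.
#' @return The validated, normalized profile.
#' @export
validate_profile <- function(profile, catalog = default_catalog(),
                             scales = side_effect_scales(),
                             fill_missing_burden = TRUE) {
  stopifnot(inherits(profile, "preference_profile"))
  ids <- scales$side_effect_id
  abort_v <- function(msg) rlang::abort(msg, class = "prostaid_validation_error")

  miss <- setdiff(ids, names(profile$thresholds))
  if (length(miss) > 0) abort_v(paste0("Missing threshold for: ",
    paste(miss, collapse = ", ")))
  extra <- setdiff(names(profile$thresholds), ids)
  if (length(extra) > 0) abort_v(paste0("Threshold for unknown side effect: ",
    paste(extra, collapse = ", ")))
  for (id in ids) level_index(id, profile$thresholds[[id]], scales)

  miss <- setdiff(ids, names(profile$wta_side_effect))
  if (length(miss) > 0) abort_v(paste0("Missing willingness-to-accept value for: ",
    paste(miss, collapse = ", ")))
  money <- c(profile$wta_side_effect, profile$wta_alternative_burden,
    failure = profile$wta_failure)
  if (anyNA(money) || any(!is.finite(money)) || any(money < 0)) {
    abort_v("All dollar values must be finite and nonnegative")
  }

  unknown <- setdiff(names(profile$wta_alternative_burden), catalog$treatments)
  if (length(unknown) > 0) abort_v(paste0("Burden value for unknown treatment: ",
    paste(unknown, collapse = ", ")))
  burden <- stats::setNames(rep(0, length(catalog$treatments)),
    catalog$treatments)
  burden[names(profile$wta_alternative_burden)] <- profile$wta_alternative_burden
  if (!fill_missing_burden) {
    miss <- setdiff(catalog$treatments, names(profile$wta_alternative_burden))
    if (length(miss) > 0) abort_v(paste0("Missing burden value for: ",
      paste(miss, collapse = ", ")))
  }

  profile$wta_side_effect <- round(profile$wta_side_effect[ids])
  profile$wta_alternative_burden <- round(burden)
  profile$wta_failure <- round(profile$wta_failure)
  profile$thresholds <- profile$thresholds[ids]
  profile
}

#' Probability that a side effect ends up worse than the threshold
#'
#' Given a transition-matrix row for the patient's pre-treatment level, sums
#' the probability mass on post-treatment levels strictly worse than the
#' stated maximum tolerance. The threshold level itself is tolerated:
#' tolerating waking 2 times a night means the payment applies to waking
#' MORE than 2 times.
#'
#' @param matrix A `toxicity_matrix` (or anything with `$probabilities` and
#'   `$levels`, e.g. a synthetic truth matrix wrapped by
#'   [as_toxicity_matrix()]).
#' @param pre_level The patient's pre-treatment level (vectorized).
#' @param threshold The maximum tolerated level.
#' @param scales A scale registry tibble.
#' @return Exceedance probability in [0, 1], one per `pre_level`.
#' @examples
#' m <- identity_toxicity_matrix("erectile_function")
#' exceedance_probability(m, "100%", "50%")  # 0: potency persists at 100%
#' @export
exceedance_probability <- function(matrix, pre_level, threshold,
                                   scales = side_effect_scales()) {
  id <- matrix$side_effect_id
  i <- level_index(id, pre_level, scales)
  t <- level_index(id, threshold, scales)
  worse <- seq_along(matrix$levels) > t  # later in the scale = worse
  unname(vapply(i, function(row) sum(matrix$probabilities[row, worse]),
    numeric(1)))
}

#' Elicitation prompt for the value page
#'
#' Generates the willingness-to-accept question for one side effect,
#' mirroring exactly the level chosen on the threshold page.
#'
#' @param side_effect_id One of [side_effect_ids()].
#' @param threshold The level chosen as maximum tolerance.
#' @param scales A scale registry tibble.
#' @return A single prompt string restating the threshold level verbatim.
#' @export
threshold_value_prompt <- function(side_effect_id, threshold,
                                   scales = side_effect_scales()) {
  level_index(side_effect_id, threshold, scales)
  label <- gsub("_", " ", side_effect_id)
  paste0(
    "You indicated your maximum tolerance for ", label, " is '", threshold,
    "'. How much would we have to pay you to accept a ", label,
    " level worse than '", threshold, "' for the rest of your life?"
  )
}

# JSON-safe representation (named vectors become objects, not bare arrays).
profile_to_list <- function(profile) {
  list(
    thresholds = profile$thresholds,
    wta_side_effect = as.list(profile$wta_side_effect),
    wta_alternative_burden = as.list(profile$wta_alternative_burden),
    wta_failure = profile$wta_failure
  )
}

#' Read / write a preference profile as JSON
#'
#' @param path File path.
#' @param profile A [preference_profile()].
#' @return `read_preference_profile()` returns a `preference_profile`;
#'   `write_preference_profile()` returns `path` invisibly.
#' @export
read_preference_profile <- function(path) {
  raw <- jsonlite::fromJSON(path)
  for (f in c("thresholds", "wta_side_effect", "wta_failure")) {
    if (is.null(raw[[f]])) {
      rlang::abort(paste0("Preference file ", path, " lacks field '", f, "'"),
        class = "prostaid_validation_error")
    }
  }
  preference_profile(
    thresholds = raw$thresholds,
    wta_side_effect = unlist(raw$wta_side_effect),
    wta_alternative_burden = unlist(raw$wta_alternative_burden) %||% numeric(),
    wta_failure = raw$wta_failure
  )
}

#' @rdname read_preference_profile
#' @export
write_preference_profile <- function(profile, path) {
  stopifnot(inherits(profile, "preference_profile"))
  jsonlite::write_json(profile_to_list(profile), path, auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(path)
}
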