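#' Ordinal side-effect scales
#'
#' The decision aid models four radiation-related side effects as ordered
#' ordinal scales, best level first. The erectile-function, urinary- and
#' bowel-incontinence items follow EPIC response sets; nocturia follows the
#' IPSS item (times woken per night, 0 through 5 or more).
#'
#' @return A tibble with one row per side effect: `side_effect_id`,
#'   `question` (the elicitation wording), and `levels` (a list column of
#'   ordered level labels, best first; later means worse).
#' @examples
#' side_effect_scales()
#' @export
side_effect_scales <- function() {
  tibble::tibble(
    side_effect_id = c(
      "erectile_function", "urinary_incontinence",
      "nocturia", "bowel_incontinence"
    ),
    question = c(
      "Over the past 4 weeks, what percentage of the time that you wanted to have an erection were you able to achieve one?",
      "Over the past 4 weeks, how often have you had uncontrolled leakage of urine?",
      "Over the past 4 weeks, how many times have you woken up to go to the bathroom after you went to bed?",
      "Over the past 4 weeks, how often have you had uncontrolled leakage of stool or feces?"
    ),
    levels = list(
      c("100%", "75%", "50%", "25%", "0%"),
      c("rarely or never", "about once a week", "more than once a week",
        "about once a day", "more than once a day"),
      c("0", "1", "2", "3", "4", "5+"),
      c("rarely or never", "about once a week", "more than once a week",
        "about once a day", "more than once a day")
    )
  )
}

#' Side-effect identifiers
#'
#' @return Character vector of the four modeled side effects.
#' @export
side_effect_ids <- function() side_effect_scales()$side_effect_id

#' Levels of one side-effect scale
#'
#' @param side_effect_id One of [side_effect_ids()].
#' @param scales A scale registry tibble, by default [side_effect_scales()].
#' @return Character vector of ordinal labels, best first.
#' @export
scale_levels <- function(side_effect_id, scales = side_effect_scales()) {
  i <- match(side_effect_id, scales$side_effect_id)
  if (is.na(i)) {
    rlang::abort(
      paste0("Unknown side effect: '", side_effect_id, "'"),
      class = "prostaid_validation_error"
    )
  }
  scales$levels[[i]]
}

level_index <- function(side_effect_id, level, scales = side_effect_scales()) {
  lv <- scale_levels(side_effect_id, scales)
  idx <- match(level, lv)
  if (anyNA(idx)) {
    bad <- unique(level[is.na(idx)])
    rlang::abort(
      paste0(
        "Response '", bad[1], "' is not a level of the ", side_effect_id,
        " scale (levels: ", paste(lv, collapse = ", "), ")"
      ),
      class = "prostaid_validation_error"
    )
  }
  idx
}

#' Strict ordinal "worse than" comparison
#'
#' Levels later in a scale are worse (lower potency, more frequent leakage,
#' more awakenings). The comparison is strict: a level is never worse than
#' itself.
#'
#' @param side_effect_id One of [side_effect_ids()].
#' @param a,b Level labels on that scale (vectorized, recycled).
#' @param scales A scale registry tibble.
#' @return Logical: is `a` strictly worse than `b`?
#' @examples
#' is_worse("erectile_function", "25%", "50%")  # TRUE
#' is_worse("nocturia", "2", "2")               # FALSE
#' @export
is_worse <- function(side_effect_id, a, b, scales = side_effect_scales()) {
  level_index(side_effect_id, a, scales) > level_index(side_effect_id, b, scales)
}

#' Parse raw questionnaire answers into a health state
#'
#' A health state holds one level per side effect. Input is a named list or
#' character vector keyed by side-effect id; every side effect must be
#' answered and every answer must be a level of its scale.
#'
#' @param answers Named list or character vector, names in
#'   [side_effect_ids()], values raw responses.
#' @param scales A scale registry tibble.
#' @return A tibble with columns `side_effect_id` and `level`, one row per
#'   side effect, in registry order.
#' @examples
#' parse_health_state(list(
#'   erectile_function = "75%", urinary_incontinence = "rarely or never",
#'   nocturia = "2", bowel_incontinence = "rarely or never"
#' ))
#' @export
parse_health_state <- function(answers, scales = side_effect_scales()) {
  answers <- as.list(answers)
  ids <- scales$side_effect_id
  missing <- setdiff(ids, names(answers))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Missing answer for side effect(s): ", paste(missing, collapse = ", ")),
      class = "prostaid_validation_error"
    )
  }
  unknown <- setdiff(names(answers), ids)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("Unknown side effect(s): ", paste(unknown, collapse = ", ")),
      class = "prostaid_validation_error"
    )
  }
  state <- tibble::tibble(
    side_effect_id = ids,
    level = unname(vapply(ids, function(id) as.character(answers[[id]]),
      character(1)))
  )
  # validates each level against its scale (plain loop so the validation
  # condition class survives to callers)
  for (i in seq_len(nrow(state))) {
    level_index(state$side_effect_id[i], state$level[i], scales)
  }
  state
}

health_state_level <- function(state, side_effect_id) {
  state$level[match(side_effect_id, state$side_effect_id)]
}

#' Read / write a scale registry as JSON
#'
#' The registry is configurable: deployments can swap question wording or
#' response sets so long as each scale stays a totally ordered list of
#' distinct labels, best first.
#'
#' @param path File path.
#' @param scales Registry tibble to write.
#' @return `read_scale_registry()` returns the registry tibble;
#'   `write_scale_registry()` returns `path` invisibly.
#' @export
read_scale_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  scales <- tibble::tibble(
    side_effect_id = vapply(raw, `[[`, character(1), "side_effect_id"),
    question = vapply(raw, `[[`, character(1), "question"),
    levels = lapply(raw, function(x) as.character(unlist(x$levels)))
  )
  validate_scale_registry(scales)
}

#' @rdname read_scale_registry
#' @export
write_scale_registry <- function(scales, path) {
  validate_scale_registry(scales)
  entries <- purrr::pmap(scales, function(side_effect_id, question, levels) {
    list(side_effect_id = side_effect_id, question = question, levels = levels)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

validate_scale_registry <- function(scales) {
  stopifnot(all(c("side_effect_id", "question", "levels") %in% names(scales)))
  if (anyDuplicated(scales$side_effect_id)) {
    rlang::abort("Duplicate side_effect_id in scale registry",
      class = "prostaid_validation_error")
  }
  for (lv in scales$levels) {
    if (length(lv) < 2 || anyDuplicated(lv)) {
      rlang::abort("Each scale needs at least two distinct ordered levels",
        class = "prostaid_validation_error")
    }
  }
  scales
}
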