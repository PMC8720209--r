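T_STAGES <- c("cT1c", "cT2a", "cT2b", "cT2c", "cT3a", "cT3b", "cT4")

NCCN_GROUPS <- c(
  "very_low", "low", "favorable_intermediate",
  "unfavorable_intermediate", "high", "very_high"
)

BROAD_RISK <- c("LOW", "INTERMEDIATE", "HIGH")

#' Build a clinical profile
#'
#' Collects the NCCN staging inputs — clinical T stage, Grade Group, PSA and
#' biopsy-core features — as a validated one-row tibble. Several profiles can
#' be combined with `dplyr::bind_rows()` and classified together.
#'
#' @param t_stage Clinical stage, one of cT1c, cT2a, cT2b, cT2c, cT3a, cT3b, cT4.
#' @param grade_group Histologic Grade Group, integer 1-5.
#' @param psa Prostate-specific antigen in ng/mL, > 0.
#' @param cores_positive,cores_total Positive and total biopsy core counts.
#' @param max_single_core_involvement Largest percent involvement of any
#'   single positive core (0-100). May be `NA` when unreported; classification
#'   fails with a gap error only if the value is decisive.
#' @param cores_with_grade_group_4_or_5 Number of cores showing Grade Group 4
#'   or 5 disease.
#' @param primary_gleason_pattern Primary Gleason pattern 3-5.
#' @return A one-row tibble with the validated fields.
#' @examples
#' clinical_profile("cT1c", grade_group = 1, psa = 6,
#'                  cores_positive = 2, cores_total = 12,
#'                  max_single_core_involvement = 40)
#' @export
clinical_profile <- function(t_stage, grade_group, psa,
                             cores_positive, cores_total,
                             max_single_core_involvement = NA_real_,
                             cores_with_grade_group_4_or_5 = 0L,
                             primary_gleason_pattern = NA_integer_) {
  p <- tibble::tibble(
    t_stage = as.character(t_stage),
    grade_group = as.integer(grade_group),
    primary_gleason_pattern = as.integer(primary_gleason_pattern),
    psa = as.numeric(psa),
    cores_positive = as.integer(cores_positive),
    cores_total = as.integer(cores_total),
    max_single_core_involvement = as.numeric(max_single_core_involvement),
    cores_with_grade_group_4_or_5 = as.integer(cores_with_grade_group_4_or_5)
  )
  validate_clinical_profile(p)
}

validate_clinical_profile <- function(p) {
  check <- function(ok, msg) {
    if (!all(ok, na.rm = FALSE) || anyNA(ok)) {
      rlang::abort(msg, class = "prostaid_validation_error")
    }
  }
  check(p$t_stage %in% T_STAGES,
    paste0("t_stage must be one of: ", paste(T_STAGES, collapse = ", ")))
  check(p$grade_group %in% 1:5, "grade_group must be an integer 1-5")
  check(is.na(p$primary_gleason_pattern) | p$primary_gleason_pattern %in% 3:5,
    "primary_gleason_pattern must be 3-5 when given")
  check(p$psa > 0, "psa must be a positive ng/mL value")
  check(p$cores_total >= 1, "cores_total must be at least 1")
  check(p$cores_positive >= 0 & p$cores_positive <= p$cores_total,
    "cores_positive must lie in [0, cores_total]")
  check(p$cores_with_grade_group_4_or_5 >= 0 &
    p$cores_with_grade_group_4_or_5 <= p$cores_positive,
    "cores_with_grade_group_4_or_5 must lie in [0, cores_positive]")
  if (!all(is.na(p$max_single_core_involvement) |
    (p$max_single_core_involvement >= 0 & p$max_single_core_involvement <= 100))) {
    rlang::abort("max_single_core_involvement must be a percent in [0, 100]",
      class = "prostaid_validation_error")
  }
  p
}

#' Map a fine NCCN group onto the three broad categories
#'
#' Very-low and low map to LOW, the two intermediate groups to INTERMEDIATE,
#' and high and very-high to HIGH — the three-way simplification under which
#' most outcome data are reported.
#'
#' @param nccn_group Character vector of NCCN group labels.
#' @return Character vector over `LOW`, `INTERMEDIATE`, `HIGH`.
#' @export
to_broad_category <- function(nccn_group) {
  bad <- setdiff(unique(nccn_group), NCCN_GROUPS)
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown NCCN group: ", bad[1]),
      class = "prostaid_validation_error")
  }
  unname(c(
    very_low = "LOW", low = "LOW",
    favorable_intermediate = "INTERMEDIATE",
    unfavorable_intermediate = "INTERMEDIATE",
    high = "HIGH", very_high = "HIGH"
  )[nccn_group])
}

# One profile -> one fine NCCN group. Rules are evaluated most to least
# severe so that "no very high risk features and exactly one high risk
# feature" reads as printed. Intermediate risk factors (IRFs): cT2b-cT2c,
# Grade Group 2 or 3, PSA 10-20 ng/mL. High-risk features: cT3a, Grade Group
# 4 or 5, PSA > 20 ng/mL.
classify_one <- function(t_stage, grade_group, primary_gleason_pattern, psa,
                         cores_positive, cores_total,
                         max_single_core_involvement,
                         cores_with_grade_group_4_or_5) {
  high_features <- (t_stage == "cT3a") + (grade_group >= 4) + (psa > 20)

  very_high <- t_stage %in% c("cT3b", "cT4") ||
    isTRUE(primary_gleason_pattern == 5) ||
    high_features >= 2 ||
    cores_with_grade_group_4_or_5 > 4
  if (very_high) return("very_high")

  if (high_features == 1) return("high")

  irf <- (t_stage %in% c("cT2b", "cT2c")) + (grade_group %in% 2:3) +
    (psa >= 10 & psa <= 20)
  if (irf >= 1) {
    unfavorable <- irf >= 2 || grade_group == 3 ||
      cores_positive / cores_total >= 0.5
    return(if (unfavorable) "unfavorable_intermediate" else "favorable_intermediate")
  }

  # Remaining profiles: cT1c-cT2a, Grade Group 1, PSA < 10.
  maybe_very_low <- t_stage == "cT1c" && cores_positive < 3
  if (maybe_very_low) {
    if (is.na(max_single_core_involvement)) {
      rlang::abort(
        paste0(
          "Classification gap: profile meets every very-low criterion except ",
          "that max_single_core_involvement is unreported, which decides ",
          "very_low ('< 50% in each core') versus low"
        ),
        class = "prostaid_classification_gap"
      )
    }
    if (max_single_core_involvement < 50) return("very_low")
  }
  "low"
}

#' Classify NCCN risk group
#'
#' Applies the NCCN risk-stratification rules to each clinical profile and
#' appends the fine six-level group and its broad three-level category.
#' Rules are evaluated in precedence order from very-high down, so the
#' "exactly one high-risk feature" rule for the high group is applied only
#' after very-high features are excluded.
#'
#' @param profiles A data frame of clinical profiles, as built by
#'   [clinical_profile()] (one row per patient).
#' @return The input as a tibble with `nccn_group` and `risk_broad` columns
#'   appended.
#' @examples
#' clinical_profile("cT3a", grade_group = 4, psa = 15,
#'                  cores_positive = 6, cores_total = 12,
#'                  cores_with_grade_group_4_or_5 = 3) |>
#'   classify_nccn()
#' @export
classify_nccn <- function(profiles) {
  profiles <- validate_clinical_profile(tibble::as_tibble(profiles))
  fields <- c(
    "t_stage", "grade_group", "primary_gleason_pattern", "psa",
    "cores_positive", "cores_total", "max_single_core_involvement",
    "cores_with_grade_group_4_or_5"
  )
  groups <- vapply(seq_len(nrow(profiles)), function(i) {
    do.call(classify_one, as.list(profiles[i, fields]))
  }, character(1))
  dplyr::mutate(profiles,
    nccn_group = groups,
    risk_broad = to_broad_category(groups)
  )
}
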