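#' Treatment identifiers, least-intensive first
#'
#' The fixed order (active surveillance, then single-modality radiation, then
#' combined-modality courses) is also the deterministic tie-break order used
#' by [rank_alternatives()].
#'
#' @return Character vector of the seven treatment alternatives.
#' @export
treatment_ids <- function() {
  c(
    "active_surveillance", "SBRT", "EBRT_standard", "EBRT_hypofractionated",
    "EBRT_HDR", "EBRT_ADT", "EBRT_HDR_ADT"
  )
}

#' Default treatment catalog
#'
#' The catalog holds the seven alternatives, an eligibility map per broad
#' risk category, and a 5-year freedom-from-biochemical-failure (FFBF)
#' success probability per eligible (treatment, risk) pair. Eligibility
#' follows standard NCCN-style convention: active surveillance only for
#' low-risk disease; ADT-containing courses for intermediate and high risk.
#'
#' The FFBF values shipped here are ILLUSTRATIVE PLACEHOLDERS in a plausible
#' range, not trial estimates; deployments should supply institution-specific
#' values via [read_catalog()]. Analyses that depend on success either fix
#' these numbers explicitly or are invariant to them.
#'
#' @return A `treatment_catalog`: list with `treatments`, `eligibility`
#'   (named list, broad risk -> treatment ids), `success` (tibble with
#'   `treatment_id`, `risk_broad`, `p_ffbf`) and `note`.
#' @export
default_catalog <- function() {
  success <- tibble::tribble(
    ~treatment_id,           ~risk_broad,    ~p_ffbf,
    "active_surveillance",   "LOW",          0.92,
    "SBRT",                  "LOW",          0.95,
    "EBRT_standard",         "LOW",          0.93,
    "EBRT_hypofractionated", "LOW",          0.93,
    "SBRT",                  "INTERMEDIATE", 0.90,
    "EBRT_standard",         "INTERMEDIATE", 0.88,
    "EBRT_hypofractionated", "INTERMEDIATE", 0.88,
    "EBRT_HDR",              "INTERMEDIATE", 0.92,
    "EBRT_ADT",              "INTERMEDIATE", 0.90,
    "EBRT_ADT",              "HIGH",         0.80,
    "EBRT_HDR_ADT",          "HIGH",         0.85
  )
  new_treatment_catalog(
    treatments = treatment_ids(),
    eligibility = list(
      LOW = c("active_surveillance", "SBRT", "EBRT_standard",
        "EBRT_hypofractionated"),
      INTERMEDIATE = c("SBRT", "EBRT_standard", "EBRT_hypofractionated",
        "EBRT_HDR", "EBRT_ADT"),
      HIGH = c("EBRT_ADT", "EBRT_HDR_ADT")
    ),
    success = success,
    note = paste(
      "Success probabilities (5-year FFBF) are illustrative placeholders,",
      "not trial estimates; supply institution-specific values in production."
    )
  )
}

new_treatment_catalog <- function(treatments, eligibility, success,
                                  note = NULL) {
  cat <- structure(
    list(treatments = treatments, eligibility = eligibility,
      success = tibble::as_tibble(success), note = note),
    class = "treatment_catalog"
  )
  validate_catalog(cat)
}

validate_catalog <- function(catalog) {
  abort_v <- function(msg) rlang::abort(msg, class = "prostaid_validation_error")
  if (length(catalog$treatments) == 0) abort_v("Catalog has no treatments")
  for (risk in names(catalog$eligibility)) {
    elig <- catalog$eligibility[[risk]]
    if (length(elig) == 0) abort_v(paste0("Empty eligibility entry for ", risk))
    bad <- setdiff(elig, catalog$treatments)
    if (length(bad) > 0) abort_v(paste0("Eligibility for ", risk,
      " names unknown treatment: ", bad[1]))
    for (t in elig) {
      p <- catalog$success$p_ffbf[catalog$success$treatment_id == t &
        catalog$success$risk_broad == risk]
      if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
        abort_v(paste0("Missing or invalid success probability for (", t,
          ", ", risk, ")"))
      }
    }
  }
  catalog
}

#' @export
print.treatment_catalog <- function(x, ...) {
  cat("Treatment catalog:", length(x$treatments), "alternatives\n")
  for (risk in names(x$eligibility)) {
    cat(" ", risk, "->", paste(x$eligibility[[risk]], collapse = ", "), "\n")
  }
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}

#' Eligible alternatives for a broad risk category
#'
#' @param risk_broad One of `LOW`, `INTERMEDIATE`, `HIGH`.
#' @param catalog A treatment catalog.
#' @return Character vector of eligible treatment ids, in catalog order.
#' @export
eligible_alternatives <- function(risk_broad, catalog = default_catalog()) {
  elig <- catalog$eligibility[[risk_broad]]
  if (is.null(elig) || length(elig) == 0) {
    rlang::abort(paste0("No eligibility entry for risk category '",
      risk_broad, "'"), class = "prostaid_validation_error")
  }
  intersect(catalog$treatments, elig)
}

success_probability <- function(catalog, treatment_id, risk_broad) {
  p <- catalog$success$p_ffbf[catalog$success$treatment_id == treatment_id &
    catalog$success$risk_broad == risk_broad]
  if (length(p) != 1) {
    rlang::abort(paste0("No success probability for (", treatment_id, ", ",
      risk_broad, ")"), class = "prostaid_validation_error")
  }
  p
}

#' Read / write a treatment catalog (JSON or YAML)
#'
#' @param path File path; `.yaml`/`.yml` uses YAML, anything else JSON.
#' @param catalog A treatment catalog to write (JSON only).
#' @return `read_catalog()` returns a validated `treatment_catalog`;
#'   `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      rlang::abort("The 'yaml' package is required for YAML catalogs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  success <- tibble::as_tibble(as.data.frame(
    do.call(rbind, lapply(
      if (is.data.frame(raw$success)) split(raw$success, seq_len(nrow(raw$success))) else raw$success,
      function(r) data.frame(
        treatment_id = as.character(r$treatment_id),
        risk_broad = as.character(r$risk_broad),
        p_ffbf = as.numeric(r$p_ffbf)
      )
    ))
  ))
  new_treatment_catalog(
    treatments = as.character(unlist(raw$treatments)),
    eligibility = lapply(raw$eligibility, function(x) as.character(unlist(x))),
    success = success,
    note = raw$note
  )
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  jsonlite::write_json(list(
    treatments = catalog$treatments,
    eligibility = catalog$eligibility,
    success = catalog$success,
    note = catalog$note
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
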