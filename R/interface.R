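SCHEMA_VERSION <- "1.0"

#' Read a clinical profile or health state from JSON
#'
#' @param path File path.
#' @return [read_clinical_profile()] returns a validated one-row profile
#'   tibble; [read_health_state()] a health-state tibble.
#' @export
read_clinical_profile <- function(path) {
  raw <- jsonlite::fromJSON(path)
  needed <- c("t_stage", "grade_group", "psa", "cores_positive", "cores_total")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0) {
    rlang::abort(paste0("Profile file ", path, " lacks field(s): ",
      paste(miss, collapse = ", ")), class = "prostaid_validation_error")
  }
  clinical_profile(
    t_stage = raw$t_stage, grade_group = raw$grade_group, psa = raw$psa,
    cores_positive = raw$cores_positive, cores_total = raw$cores_total,
    max_single_core_involvement = raw$max_single_core_involvement %||% NA_real_,
    cores_with_grade_group_4_or_5 = raw$cores_with_grade_group_4_or_5 %||% 0L,
    primary_gleason_pattern = raw$primary_gleason_pattern %||% NA_integer_
  )
}

#' @rdname read_clinical_profile
#' @export
read_health_state <- function(path) {
  parse_health_state(jsonlite::fromJSON(path))
}

load_matrix_dir <- function(dir, scales = side_effect_scales()) {
  paths <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(paths) == 0) {
    rlang::abort(paste0("No matrix JSON files found in ", dir),
      class = "prostaid_validation_error")
  }
  mats <- lapply(paths, read_toxicity_matrix, scales = scales)
  tibble::tibble(
    treatment_id = vapply(mats, `[[`, character(1), "treatment_id"),
    side_effect_id = vapply(mats, `[[`, character(1), "side_effect_id"),
    matrix = mats
  )
}

# The standard and hypofractionated EBRT arms derive from the same trial,
# so by default the hypofractionated arm reuses the standard-arm matrices
# unless per-arm matrices were supplied.
share_ebrt_matrices <- function(matrices) {
  has_hypo <- any(matrices$treatment_id == "EBRT_hypofractionated")
  std <- matrices[matrices$treatment_id == "EBRT_standard", ]
  if (has_hypo || nrow(std) == 0) return(matrices)
  hypo <- dplyr::mutate(std, treatment_id = "EBRT_hypofractionated")
  dplyr::bind_rows(matrices, hypo)
}

#' Run the full evaluation pipeline on input files
#'
#' Classification, eligibility, toxicity lookup and ranking executed as one
#' pure pipeline: clinical profile -> NCCN risk group -> eligible
#' alternatives -> exceedance and cost components -> ranking. The written
#' artifact echoes all inputs (audit trail) and serializes currency as
#' integer dollars, so re-running identical inputs yields byte-identical
#' output.
#'
#' @param profile_path,health_state_path,preference_path JSON input files.
#' @param out_path Output path for the evaluation artifact.
#' @param catalog_path Optional catalog JSON/YAML; default catalog otherwise.
#' @param matrix_dir Optional directory of toxicity-matrix JSON files. When
#'   absent, deterministic synthetic demonstration matrices are generated
#'   under `seed` (labelled as such in the output).
#' @param format `"json"` (full breakdown) or `"csv"` (one row per
#'   alternative).
#' @param seed Seed for the synthetic demonstration matrices.
#' @return The `da_evaluation`, invisibly; the artifact is written to
#'   `out_path`.
#' @export
run_evaluate <- function(profile_path, health_state_path, preference_path,
                         out_path, catalog_path = NULL, matrix_dir = NULL,
                         format = c("json", "csv"), seed = 1L) {
  format <- match.arg(format)
  profile <- read_clinical_profile(profile_path)
  state <- read_health_state(health_state_path)
  catalog <- if (is.null(catalog_path)) default_catalog() else
    read_catalog(catalog_path)
  prefs <- validate_profile(read_preference_profile(preference_path), catalog)
  matrix_source <- if (is.null(matrix_dir)) "synthetic_demo" else matrix_dir
  matrices <- if (is.null(matrix_dir)) {
    generate_truth_matrices(seed = seed)
  } else {
    load_matrix_dir(matrix_dir)
  }
  matrices <- share_ebrt_matrices(matrices)

  classified <- classify_nccn(profile)
  ev <- rank_alternatives(state, prefs, matrices, catalog,
    classified$risk_broad[1])

  if (format == "csv") {
    utils::write.csv(evaluation_rows(ev), out_path, row.names = FALSE)
  } else {
    artifact <- list(
      schema_version = SCHEMA_VERSION,
      inputs = list(
        clinical_profile = as.list(profile[1, ]),
        health_state = stats::setNames(as.list(state$level),
          state$side_effect_id),
        preferences = profile_to_list(prefs),
        matrix_source = matrix_source
      ),
      risk = list(nccn_group = classified$nccn_group[1],
        broad = classified$risk_broad[1]),
      results = purrr::transpose(evaluation_rows(ev))
    )
    jsonlite::write_json(artifact, out_path, auto_unbox = TRUE, digits = NA,
      pretty = TRUE, na = "null")
  }
  invisible(ev)
}

# One row per alternative with currency as integer dollars.
evaluation_rows <- function(ev) {
  d <- tibble::as_tibble(ev)
  for (col in c("se_cost", "burden_cost", "failure_cost", "total")) {
    d[[col]] <- as.integer(round(d[[col]]))
  }
  d
}

cli_usage <- function() {
  paste(
    "prostaid — personalized prostate-cancer decision-aid engine",
    "",
    "Usage: prostaid <command> [options]",
    "",
    "Commands:",
    "  classify          --profile <json> [--out <json>]",
    "  build-matrices    --cohort <csv> --out-dir <dir> [--alpha <num>]",
    "  evaluate          --profile <json> --health-state <json>",
    "                    --preferences <json> --out <path>",
    "                    [--catalog <json|yaml>] [--matrix-dir <dir>]",
    "                    [--format json|csv] [--seed <int>]",
    "  search-dominance  --health-state <json> --risk <LOW|INTERMEDIATE|HIGH>",
    "                    --out <json> [--matrix-dir <dir>] [--seed <int>]",
    "                    [--no-burden-lever]",
    "  simulate          --out <csv> [--n <int>] [--seed <int>]",
    "                    [--matrix-out-dir <dir>]",
    "  demo              --out <json>",
    sep = "\n"
  )
}

parse_cli_args <- function(args) {
  opts <- list(flags = character())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      rlang::abort(paste0("Unexpected argument: ", a),
        class = "prostaid_validation_error")
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts$flags <- c(opts$flags, key)
      i <- i + 1
    } else {
      opts[[gsub("-", "_", key)]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}

require_opt <- function(opts, name) {
  v <- opts[[gsub("-", "_", name)]]
  if (is.null(v)) {
    rlang::abort(paste0("Missing required option --", name),
      class = "prostaid_validation_error")
  }
  v
}

#' Command-line entry point
#'
#' Dispatches the decision-aid subcommands (`classify`, `build-matrices`,
#' `evaluate`, `search-dominance`, `simulate`, `demo`). A thin Rscript
#' wrapper around this function ships in `inst/cli/prostaid.R`.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Exit code, invisibly: 0 success, 1 usage error, 2 validation
#'   error, 3 classification gap.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0 || args[1] %in% c("-h", "--help", "help")) {
      cat(cli_usage(), "\n")
      return(invisible(if (length(args) == 0) 1L else 0L))
    }
    cmd <- args[1]
    opts <- parse_cli_args(args[-1])
    switch(cmd,
      classify = cli_classify(opts),
      `build-matrices` = cli_build_matrices(opts),
      evaluate = cli_evaluate(opts),
      `search-dominance` = cli_search_dominance(opts),
      simulate = cli_simulate(opts),
      demo = cli_demo(opts),
      {
        cat(cli_usage(), "\n")
        rlang::abort(paste0("Unknown command: ", cmd),
          class = "prostaid_validation_error")
      }
    )
    0L
  },
  prostaid_classification_gap = function(e) {
    message("classification gap: ", conditionMessage(e))
    3L
  },
  prostaid_validation_error = function(e) {
    message("validation error: ", conditionMessage(e))
    2L
  })
  invisible(code)
}

cli_classify <- function(opts) {
  classified <- classify_nccn(read_clinical_profile(require_opt(opts, "profile")))
  out <- list(nccn_group = classified$nccn_group[1],
    broad = classified$risk_broad[1])
  if (!is.null(opts$out)) {
    jsonlite::write_json(out, opts$out, auto_unbox = TRUE, pretty = TRUE)
  }
  cat("NCCN group:", out$nccn_group, "| broad:", out$broad, "\n")
}

cli_build_matrices <- function(opts) {
  cohort <- utils::read.csv(require_opt(opts, "cohort"),
    stringsAsFactors = FALSE)
  out_dir <- require_opt(opts, "out-dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mats <- estimate_toxicity_matrices(cohort,
    alpha = as.numeric(opts$alpha %||% 0))
  purrr::walk(mats$matrix, function(m) {
    write_toxicity_matrix(m, file.path(out_dir,
      paste0(m$treatment_id, "__", m$side_effect_id, ".json")))
  })
  cat("Wrote", nrow(mats), "matrices to", out_dir, "\n")
}

cli_evaluate <- function(opts) {
  ev <- run_evaluate(
    profile_path = require_opt(opts, "profile"),
    health_state_path = require_opt(opts, "health-state"),
    preference_path = require_opt(opts, "preferences"),
    out_path = require_opt(opts, "out"),
    catalog_path = opts$catalog,
    matrix_dir = opts$matrix_dir,
    format = opts$format %||% "json",
    seed = as.integer(opts$seed %||% 1)
  )
  best <- ev$alternative[ev$is_best]
  cat("Best alternative:", best, "($",
    as.integer(round(ev$total[ev$is_best])), "expected burden )\n")
}

cli_search_dominance <- function(opts) {
  state <- read_health_state(require_opt(opts, "health-state"))
  risk <- require_opt(opts, "risk")
  catalog <- if (is.null(opts$catalog)) default_catalog() else
    read_catalog(opts$catalog)
  seed <- as.integer(opts$seed %||% 1)
  matrices <- share_ebrt_matrices(
    if (is.null(opts$matrix_dir)) generate_truth_matrices(seed = seed)
    else load_matrix_dir(opts$matrix_dir))
  lever <- !("no-burden-lever" %in% opts$flags)
  res <- purrr::map(eligible_alternatives(risk, catalog), function(alt) {
    hit <- find_supporting_preferences(alt, state, matrices, catalog, risk,
      search = search_config(burden_lever = lever, seed = seed))
    list(alternative = alt, found = hit$found, n_tried = hit$n_tried,
      profile = if (hit$found) profile_to_list(hit$profile) else NULL)
  })
  jsonlite::write_json(res, require_opt(opts, "out"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE, na = "null")
  cat("Supporting preferences found for",
    sum(vapply(res, `[[`, logical(1), "found")), "of", length(res),
    "eligible alternatives\n")
}

cli_simulate <- function(opts) {
  seed <- as.integer(opts$seed %||% 1)
  truth <- generate_truth_matrices(seed = seed)
  spec <- cohort_spec(truth, n_per_treatment = as.integer(opts$n %||% 150),
    seed = seed)
  cohort <- sample_cohort(spec)
  utils::write.csv(cohort, require_opt(opts, "out"), row.names = FALSE)
  if (!is.null(opts$matrix_out_dir)) {
    dir.create(opts$matrix_out_dir, showWarnings = FALSE, recursive = TRUE)
    purrr::walk(truth$matrix, function(m) {
      jsonlite::write_json(list(
        treatment_id = m$treatment_id, side_effect_id = m$side_effect_id,
        levels = m$levels,
        probabilities = unname(apply(m$probabilities, 1, as.list,
          simplify = FALSE))
      ), file.path(opts$matrix_out_dir,
        paste0("truth__", m$treatment_id, "__", m$side_effect_id, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  cat("Simulated", nrow(cohort), "paired records\n")
}

cli_demo <- function(opts) {
  bundle <- system.file("extdata", package = "prostaid")
  run_evaluate(
    profile_path = file.path(bundle, "demo_profile.json"),
    health_state_path = file.path(bundle, "demo_health_state.json"),
    preference_path = file.path(bundle, "demo_preferences.json"),
    out_path = require_opt(opts, "out"),
    catalog_path = file.path(bundle, "catalog.json")
  )
  cat("Demo evaluation written to", opts$out, "\n")
}
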