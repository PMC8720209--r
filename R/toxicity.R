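#' Tally pre/post transitions by frequentist count
#'
#' Counts paired PRO records into a square pre-level by post-level matrix for
#' one treatment and side effect. Each conditional row of the later
#' probability table is the frequentist count for that starting state.
#'
#' @param records A data frame of paired records with columns `patient_id`,
#'   `treatment_id`, `side_effect_id`, `pre_level`, `post_level`.
#' @param treatment_id,side_effect_id The cell to tally; records for other
#'   cells are an error (filter first, e.g. with [estimate_toxicity_matrices()]).
#' @param scales A scale registry tibble.
#' @return A list with integer matrix `counts` (dimnames = scale levels) and
#'   integer vector `row_totals`.
#' @export
tally_transitions <- function(records, treatment_id, side_effect_id,
                              scales = side_effect_scales()) {
  records <- tibble::as_tibble(records)
  needed <- c("treatment_id", "side_effect_id", "pre_level", "post_level")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("records lack column(s): ", paste(missing, collapse = ", ")),
      class = "prostaid_validation_error")
  }
  if (nrow(records) > 0 &&
    (!all(records$treatment_id == treatment_id) ||
      !all(records$side_effect_id == side_effect_id))) {
    rlang::abort("records contain rows for a different treatment or side effect",
      class = "prostaid_validation_error")
  }
  lv <- scale_levels(side_effect_id, scales)
  k <- length(lv)
  counts <- matrix(0L, k, k, dimnames = list(pre = lv, post = lv))
  if (nrow(records) > 0) {
    i <- level_index(side_effect_id, records$pre_level, scales)
    j <- level_index(side_effect_id, records$post_level, scales)
    tab <- table(factor(i, levels = seq_len(k)), factor(j, levels = seq_len(k)))
    counts[] <- as.integer(tab)
  }
  list(counts = counts, row_totals = rowSums(counts))
}

#' Estimate a toxicity transition matrix from counts
#'
#' Normalizes each occupied row of the count matrix to conditional
#' probabilities P(post level | pre level). Rows with no observations get the
#' identity row (the state persists) and are flagged in `empty_rows`; this
#' conservative policy keeps every matrix usable and mirrors the
#' active-surveillance convention. Optional add-alpha (Laplace) smoothing is
#' available; the default is none.
#'
#' @param counts Square nonnegative integer matrix with level dimnames, as
#'   produced by [tally_transitions()].
#' @param treatment_id,side_effect_id Identity of the matrix.
#' @param alpha Add-alpha smoothing pseudo-count per cell (default 0).
#' @param scales A scale registry tibble.
#' @return A `toxicity_matrix` object: list with `treatment_id`,
#'   `side_effect_id`, `levels`, `counts`, `row_totals`, `probabilities`,
#'   `empty_rows`, `alpha`.
#' @export
estimate_matrix <- function(counts, treatment_id, side_effect_id,
                            alpha = 0, scales = side_effect_scales()) {
  lv <- scale_levels(side_effect_id, scales)
  k <- length(lv)
  if (!is.matrix(counts) || nrow(counts) != k || ncol(counts) != k) {
    rlang::abort(paste0("counts must be a ", k, "x", k, " matrix for ", side_effect_id),
      class = "prostaid_validation_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("counts must be nonnegative integers",
      class = "prostaid_validation_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(pre = lv, post = lv)
  row_totals <- rowSums(counts)
  probs <- matrix(0, k, k, dimnames = dimnames(counts))
  empty <- row_totals == 0 & alpha == 0
  for (i in seq_len(k)) {
    if (empty[i]) {
      probs[i, i] <- 1
    } else {
      probs[i, ] <- (counts[i, ] + alpha) / (row_totals[i] + alpha * k)
    }
  }
  structure(
    list(
      treatment_id = treatment_id, side_effect_id = side_effect_id,
      levels = lv, counts = counts, row_totals = row_totals,
      probabilities = probs, empty_rows = unname(empty), alpha = alpha
    ),
    class = "toxicity_matrix"
  )
}

#' Identity toxicity matrix (active-surveillance convention)
#'
#' Active surveillance involves no active treatment, so no side effects are
#' attributed to it: every pre-treatment level persists with probability 1.
#'
#' @param side_effect_id One of [side_effect_ids()].
#' @param treatment_id Label for the matrix, default `"active_surveillance"`.
#' @param scales A scale registry tibble.
#' @return A `toxicity_matrix` with identity probabilities and zero counts.
#' @export
identity_toxicity_matrix <- function(side_effect_id,
                                     treatment_id = "active_surveillance",
                                     scales = side_effect_scales()) {
  lv <- scale_levels(side_effect_id, scales)
  k <- length(lv)
  m <- estimate_matrix(matrix(0L, k, k), treatment_id, side_effect_id,
    scales = scales)
  m$empty_rows <- rep(FALSE, k)  # identity rows are the convention, not a gap
  m
}

#' Estimate all toxicity matrices in a cohort
#'
#' Splits a paired-record cohort by treatment and side effect and estimates
#' one transition matrix per cell.
#'
#' @inheritParams tally_transitions
#' @param alpha Add-alpha smoothing per cell (default 0).
#' @return A tibble with columns `treatment_id`, `side_effect_id`, `n`
#'   (records) and `matrix` (list column of `toxicity_matrix`).
#' @export
estimate_toxicity_matrices <- function(records, alpha = 0,
                                       scales = side_effect_scales()) {
  records <- tibble::as_tibble(records)
  records |>
    dplyr::group_by(.data$treatment_id, .data$side_effect_id) |>
    dplyr::group_modify(function(d, key) {
      tl <- tally_transitions(
        dplyr::mutate(d,
          treatment_id = key$treatment_id,
          side_effect_id = key$side_effect_id
        ),
        key$treatment_id, key$side_effect_id, scales
      )
      tibble::tibble(
        n = nrow(d),
        matrix = list(estimate_matrix(tl$counts, key$treatment_id,
          key$side_effect_id, alpha, scales))
      )
    }) |>
    dplyr::ungroup()
}

#' @export
print.toxicity_matrix <- function(x, digits = 2, ...) {
  cat("Toxicity transition matrix —", x$treatment_id, "/", x$side_effect_id, "\n")
  cat("Row totals:", paste(x$row_totals, collapse = ", "), "\n")
  print(round(100 * x$probabilities, digits))
  if (any(x$empty_rows)) {
    cat("Unobserved pre-level rows (identity-filled):",
      paste(x$levels[x$empty_rows], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a toxicity matrix into long form
#'
#' @param x A `toxicity_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (pre, post) cell: `treatment_id`,
#'   `side_effect_id`, `pre_level`, `post_level`, `n`, `probability`.
#' @export
tidy.toxicity_matrix <- function(x, ...) {
  k <- length(x$levels)
  idx <- cbind(rep(seq_len(k), times = k), rep(seq_len(k), each = k))
  tibble::tibble(
    treatment_id = x$treatment_id,
    side_effect_id = x$side_effect_id,
    pre_level = rep(x$levels, times = k),
    post_level = rep(x$levels, each = k),
    n = if (is.null(x$counts)) NA_integer_ else as.integer(x$counts[idx]),
    probability = x$probabilities[idx]
  )
}

#' Heatmap of a toxicity transition matrix
#'
#' @param object A `toxicity_matrix`.
#' @param ... Unused.
#' @return A ggplot: pre level on the y axis (best on top), post level on the
#'   x axis, tile fill = transition probability.
#' @export
autoplot.toxicity_matrix <- function(object, ...) {
  d <- tidy.toxicity_matrix(object)
  d$pre_level <- factor(d$pre_level, levels = rev(object$levels))
  d$post_level <- factor(d$post_level, levels = object$levels)
  ggplot2::ggplot(d, ggplot2::aes(.data$post_level, .data$pre_level,
    fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%%", 100 * .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#008080",
      limits = c(0, 1)) +
    ggplot2::labs(
      title = paste(object$treatment_id, "/", object$side_effect_id),
      x = "post-treatment level", y = "pre-treatment level",
      fill = "P(post | pre)"
    ) +
    ggplot2::theme_minimal()
}

#' How well does the pre-treatment state predict the post-treatment state?
#'
#' Computes a Spearman rank correlation between the ordinal pre- and
#' post-treatment levels (encoded as scale ranks) for every treatment by
#' side-effect cell of a cohort. Degenerate cells — fewer than two records,
#' or constant pre or post levels — are reported as `NA` (undefined), never
#' as zero.
#'
#' @inheritParams tally_transitions
#' @return A tibble with `treatment_id`, `side_effect_id`, `n`, `statistic`
#'   (Spearman's rho) and `p_value`.
#' @export
assess_pretreatment_predictiveness <- function(records,
                                               scales = side_effect_scales()) {
  tibble::as_tibble(records) |>
    dplyr::group_by(.data$treatment_id, .data$side_effect_id) |>
    dplyr::group_modify(function(d, key) {
      pre <- level_index(key$side_effect_id, d$pre_level, scales)
      post <- level_index(key$side_effect_id, d$post_level, scales)
      if (nrow(d) < 2 || stats::sd(pre) == 0 || stats::sd(post) == 0) {
        return(tibble::tibble(n = nrow(d), statistic = NA_real_,
          p_value = NA_real_))
      }
      ct <- suppressWarnings(
        stats::cor.test(pre, post, method = "spearman", exact = FALSE))
      tibble::tibble(n = nrow(d),
        statistic = unname(ct$estimate), p_value = ct$p.value)
    }) |>
    dplyr::ungroup()
}

#' Write / read a toxicity matrix
#'
#' JSON files carry the full object (ids, levels, counts, probabilities);
#' CSV carries one count matrix per file with post levels as header and pre
#' levels as the first column, so the treatment and side effect must be
#' supplied when reading CSV. Reading validates shape against the scale and
#' row-stochasticity of any stored probabilities.
#'
#' @param x A `toxicity_matrix`.
#' @param path File path; format inferred from the `.json` / `.csv` extension.
#' @param treatment_id,side_effect_id Required when reading CSV.
#' @param scales A scale registry tibble.
#' @return `read_toxicity_matrix()` returns a `toxicity_matrix`;
#'   `write_toxicity_matrix()` returns `path` invisibly.
#' @export
write_toxicity_matrix <- function(x, path) {
  stopifnot(inherits(x, "toxicity_matrix"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      treatment_id = x$treatment_id,
      side_effect_id = x$side_effect_id,
      levels = x$levels,
      counts = unname(x$counts),       # serialized as nested row arrays
      probabilities = unname(x$probabilities),
      alpha = x$alpha
    ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    d <- as.data.frame(x$counts)
    utils::write.csv(cbind(pre_level = rownames(x$counts), d), path,
      row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_toxicity_matrix
#' @export
read_toxicity_matrix <- function(path, treatment_id = NULL,
                                 side_effect_id = NULL,
                                 scales = side_effect_scales()) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    side_effect_id <- side_effect_id %||% raw$side_effect_id
    treatment_id <- treatment_id %||% raw$treatment_id
    lv <- scale_levels(side_effect_id, scales)
    if (!identical(as.character(raw$levels), lv)) {
      rlang::abort(paste0("Level labels in ", path,
        " do not match the ", side_effect_id, " scale"),
        class = "prostaid_validation_error")
    }
    cm <- raw$counts
    if (!is.matrix(cm)) cm <- do.call(rbind, cm)
    counts <- matrix(as.integer(cm), nrow(cm), ncol(cm))
    m <- estimate_matrix(counts, treatment_id, side_effect_id,
      alpha = raw$alpha %||% 0, scales = scales)
    if (!is.null(raw$probabilities)) {
      pm <- raw$probabilities
      if (!is.matrix(pm)) pm <- do.call(rbind, pm)
      stored <- matrix(as.numeric(pm), nrow(pm), ncol(pm))
      sums <- rowSums(stored)
      if (any(abs(sums - 1) > 1e-9)) {
        rlang::abort(paste0("Stored probability row sums deviate from 1 in ",
          path), class = "prostaid_validation_error")
      }
      if (max(abs(stored - m$probabilities)) > 1e-9) {
        rlang::abort(paste0("Stored probabilities in ", path,
          " are inconsistent with the stored counts"),
          class = "prostaid_validation_error")
      }
    }
    m
  } else {
    if (is.null(treatment_id) || is.null(side_effect_id)) {
      rlang::abort("treatment_id and side_effect_id are required for CSV input",
        class = "prostaid_validation_error")
    }
    d <- utils::read.csv(path, check.names = FALSE)
    lv <- scale_levels(side_effect_id, scales)
    if (!identical(as.character(d$pre_level), lv) ||
      !identical(names(d)[-1], lv)) {
      rlang::abort(paste0("CSV levels in ", path, " do not match the ",
        side_effect_id, " scale"), class = "prostaid_validation_error")
    }
    counts <- as.matrix(d[, -1])
    estimate_matrix(counts, treatment_id, side_effect_id, scales = scales)
  }
}
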