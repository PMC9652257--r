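# Full comparison of the four difficulty scores over one cohort.

#' Run the full difficulty-score comparison
#'
#' One call reproduces the whole analysis over a cohort: per-patient score
#' panels, dichotomised and composite outcomes (textbook-outcome threshold
#' from the cohort's 75th percentile of stay unless overridden), separate
#' per-class logistic models for each of the nine outcomes and each score,
#' the Spearman concordance matrix, and a random-forest permutation
#' importance ranking per outcome. All randomness derives from one root
#' seed, recorded in the result.
#'
#' @param cohort A cohort tibble.
#' @param seed Root seed for the forests.
#' @param trees Trees per forest (default 500).
#' @param los_threshold Textbook-outcome stay threshold; `NULL` computes the
#'   75th percentile.
#' @param config A [segment_config()].
#' @return An object of class `dss_analysis`: a list with `panel`, `flags`,
#'   `composites`, `or_table`, `concordance`, `importance` (a named list of
#'   [rf_importance()] tibbles, `NULL` with an explanatory note for a
#'   degenerate outcome) and `settings`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 120, seed = 3))
#' fit <- run_full_analysis(cohort, seed = 3, trees = 50)
#' generics::tidy(fit)
run_full_analysis <- function(cohort, seed = 1L, trees = 500,
                              los_threshold = NULL,
                              config = segment_config()) {
  panel <- score_cohort(cohort, config)
  flags <- outcome_flags(cohort)
  if (is.null(los_threshold)) {
    los_threshold <- los_percentile_threshold(cohort)
  }
  comps <- composite_outcomes(cohort, los_threshold)
  ors <- or_table(cohort, config, los_threshold)
  conc <- spearman_concordance(panel)
  outc <- dplyr::arrange(analysis_outcomes(flags, comps), .data$patient_id)
  feats <- analysis_features(cohort, panel)
  outcome_names <- setdiff(names(outc), "patient_id")
  importance <- lapply(outcome_names, function(oc) {
    tryCatch(
      rf_importance(feats, outc[[oc]], trees = trees,
                    seed = substream_seed(seed, paste0("rf_", oc))),
      error = function(e) structure(list(note = conditionMessage(e)),
                                    class = "dss_importance_skipped")
    )
  })
  names(importance) <- outcome_names
  structure(
    list(panel = panel, flags = flags, composites = comps, or_table = ors,
         concordance = conc, importance = importance,
         settings = list(seed = as.integer(seed), trees = trees,
                         los_threshold_days = comps$to_los_threshold_days[1],
                         importance_metric = "OOB permutation importance",
                         class_coding = paste(
                           "collapsed 3-level ordinals; reference = lowest;",
                           "histology indicator-expanded in forests"),
                         multiple_testing = "none")),
    class = "dss_analysis"
  )
}

#' @export
print.dss_analysis <- function(x, ...) {
  n <- nrow(x$panel)
  cat(sprintf("Difficulty-score comparison over %d patients\n", n))
  cat(sprintf("  textbook-outcome stay threshold: %d days\n",
              x$settings$los_threshold_days))
  cat(sprintf("  composite rates: OO %.1f%%, PO %.1f%%, TO %.1f%%\n",
              100 * mean(x$composites$oo), 100 * mean(x$composites$po),
              100 * mean(x$composites$to)))
  conv <- sum(!x$or_table$reference & x$or_table$converged, na.rm = TRUE)
  tot <- sum(!x$or_table$reference)
  cat(sprintf("  odds-ratio rows: %d (%d converged)\n", tot, conv))
  cat("  concordance (Spearman, collapsed classes):\n")
  print(round(unclass(x$concordance), 3))
  invisible(x)
}

#' Tidy a difficulty-score analysis
#'
#' Returns the per-class odds-ratio table (one row per outcome, score and
#' class) in broom convention.
#'
#' @param x A `dss_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dss_analysis <- function(x, ...) {
  x$or_table
}

#' One-row summary of a difficulty-score analysis
#'
#' @param x A `dss_analysis`.
#' @param ... Unused.
#' @return A tibble with one row: cohort size, composite-outcome rates, the
#'   textbook-outcome stay threshold and model convergence counts.
#' @export
glance.dss_analysis <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$panel),
    oo_rate = mean(x$composites$oo),
    po_rate = mean(x$composites$po),
    to_rate = mean(x$composites$to),
    to_los_threshold_days = x$settings$los_threshold_days,
    n_or_rows = sum(!x$or_table$reference),
    n_converged = sum(!x$or_table$reference & x$or_table$converged,
                      na.rm = TRUE),
    seed = x$settings$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
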