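# ggplot2 displays for the result types.

#' Plot a concordance matrix
#'
#' Heat-map of the pairwise Spearman correlations between the four
#' difficulty scores.
#'
#' @param object A `dss_concordance` matrix from [spearman_concordance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dss_concordance <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("score_a", "score_b", "rho")
  ggplot2::ggplot(df, ggplot2::aes(.data$score_a, .data$score_b,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       na.rm = TRUE) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b",
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  title = "Concordance of difficulty scores") +
    ggplot2::theme_minimal()
}

#' Plot a variable-importance ranking
#'
#' @param object A `dss_importance` tibble from [rf_importance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dss_importance <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      variable = stats::reorder(.data$variable,
                                                .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$variable)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = "Permutation importance (OOB accuracy decrease)",
                  y = NULL, title = "Random-forest variable importance") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-class odds ratios
#'
#' Odds ratios with 95% Wald intervals for every difficulty score and
#' outcome in an analysis; non-converged (separated) rows are drawn without
#' interval whiskers.
#'
#' @param x A `dss_analysis` or an [or_table()] tibble.
#' @param outcomes Optional character vector restricting the outcomes shown.
#' @return A ggplot object.
#' @export
plot_or_forest <- function(x, outcomes = NULL) {
  tab <- if (inherits(x, "dss_analysis")) x$or_table else x
  tab <- dplyr::filter(tab, !.data$reference, !is.na(.data$odds_ratio))
  if (!is.null(outcomes)) {
    tab <- dplyr::filter(tab, .data$outcome %in% outcomes)
  }
  tab <- dplyr::mutate(tab, label = paste(.data$dss, .data$class_label))
  ggplot2::ggplot(tab, ggplot2::aes(.data$odds_ratio, .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL,
                  title = "Per-class odds ratios by difficulty score") +
    ggplot2::theme_minimal()
}

#' Plot a difficulty-score analysis
#'
#' @param object A `dss_analysis`.
#' @param type `"concordance"`, `"importance"` or `"odds_ratios"`.
#' @param outcome Outcome name for `type = "importance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dss_analysis <- function(object,
                                  type = c("concordance", "importance",
                                           "odds_ratios"),
                                  outcome = "to_failure", ...) {
  type <- match.arg(type)
  switch(type,
    concordance = autoplot(object$concordance),
    importance = {
      imp <- object$importance[[outcome]]
      if (is.null(imp) || inherits(imp, "dss_importance_skipped")) {
        stop(sprintf("no importance ranking available for '%s'", outcome),
             call. = FALSE)
      }
      autoplot(imp) + ggplot2::labs(subtitle = outcome)
    },
    odds_ratios = plot_or_forest(object)
  )
}
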