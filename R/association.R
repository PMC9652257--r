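# Score concordance, per-class logistic odds ratios, and forest importance.

dss_systems <- function() c("halls", "hasegawa", "kawaguchi", "iwate")

#' Spearman concordance matrix of the four difficulty scores
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between the
#' four difficulty systems over a scored cohort, computed on the collapsed
#' 3-level ordinals by default or on the native classes.
#'
#' @param panel A score panel from [score_cohort()] (>= 3 patients).
#' @param collapsed Use collapsed 3-level ordinals (default) or native
#'   classes.
#' @return A symmetric 4x4 matrix of class `dss_concordance`; entries for a
#'   score that is constant across the cohort are `NA` and the affected
#'   systems are recorded in attribute `zero_variance`.
#' @export
#' @examples
#' panel <- score_cohort(simulate_cohort(sim_config(n = 100, seed = 1)))
#' spearman_concordance(panel)
spearman_concordance <- function(panel, collapsed = TRUE) {
  if (nrow(panel) < 3) {
    stop("concordance needs at least 3 patients", call. = FALSE)
  }
  cols <- if (collapsed) {
    paste0(dss_systems(), "_collapsed")
  } else {
    c("halls_class", "hasegawa_class", "kawaguchi_group", "iwate_class")
  }
  x <- vapply(cols, function(cl) as.numeric(as.integer(panel[[cl]])),
              numeric(nrow(panel)))
  colnames(x) <- dss_systems()
  constant <- apply(x, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  structure(rho, class = c("dss_concordance", class(rho)),
            zero_variance = dss_systems()[constant],
            collapsed = collapsed)
}

#' Per-class logistic odds ratios for one outcome
#'
#' Maximum-likelihood logistic regression of a binary outcome on difficulty
#' class indicators, the lowest observed class as reference. Reports the
#' odds ratio, 95% Wald interval and two-sided Wald p value per
#' non-reference class. Complete or quasi-separation (non-convergence, or a
#' coefficient standard error above 50 on the log-odds scale) is flagged by
#' `converged = FALSE` with undefined CI bounds while the point estimate and
#' p value are retained.
#'
#' @param outcome Logical (or 0/1) outcome vector.
#' @param classes Factor or ordinal vector of difficulty classes.
#' @param dss_name Label stored in the `dss` column.
#' @param se_cap Standard-error threshold above which the fit is declared
#'   diverged (default 50).
#' @return A tibble with one row per class: `dss`, `class_label`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `reference`, `converged`,
#'   `n`, `events`.
#' @export
#' @examples
#' y <- rep(c(TRUE, FALSE), c(30, 170))
#' cls <- rep(c(1, 2), each = 100)
#' fit_class_logistic(y, cls)
fit_class_logistic <- function(outcome, classes, dss_name = "dss",
                               se_cap = 50) {
  outcome <- as.logical(outcome)
  if (length(outcome) != length(classes)) {
    stop("outcome and classes must have the same length", call. = FALSE)
  }
  cls <- droplevels(factor(classes))
  if (nlevels(cls) < 2) {
    stop("degenerate design: a single observed class level", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(
    outcome ~ cls, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-14, maxit = 200)
  ))
  sm <- suppressWarnings(summary(fit))$coefficients
  lv <- levels(cls)
  counts <- tapply(outcome, cls, length)
  events <- tapply(outcome, cls, sum)
  rows <- lapply(seq_along(lv), function(i) {
    if (i == 1) {
      return(tibble::tibble(
        dss = dss_name, class_label = lv[1], odds_ratio = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
        reference = TRUE, converged = TRUE,
        n = as.integer(counts[[1]]), events = as.integer(events[[1]])
      ))
    }
    term <- paste0("cls", lv[i])
    est <- sm[term, "Estimate"]
    se <- sm[term, "Std. Error"]
    ok <- fit$converged && se <= se_cap
    tibble::tibble(
      dss = dss_name, class_label = lv[i], odds_ratio = exp(est),
      ci_low = if (ok) exp(est - 1.96 * se) else NA_real_,
      ci_high = if (ok) exp(est + 1.96 * se) else NA_real_,
      p_value = sm[term, "Pr(>|z|)"],
      reference = FALSE, converged = ok,
      n = as.integer(counts[[i]]), events = as.integer(events[[i]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-level (trend) logistic odds ratio
#'
#' Logistic regression of a binary outcome on the collapsed difficulty
#' level coded numerically (1, 2, 3), estimating a single odds ratio per
#' one-level increase in difficulty — the quantity the synthetic generator
#' injects through `effect_log_or`.
#'
#' @inheritParams fit_class_logistic
#' @return A one-row tibble: `dss`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `converged`.
#' @export
fit_trend_logistic <- function(outcome, classes, dss_name = "dss",
                               se_cap = 50) {
  outcome <- as.logical(outcome)
  lev <- as.numeric(as.integer(classes))
  if (length(unique(lev)) < 2) {
    stop("degenerate design: a single observed class level", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(
    outcome ~ lev, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-14, maxit = 200)
  ))
  sm <- suppressWarnings(summary(fit))$coefficients
  est <- sm["lev", "Estimate"]
  se <- sm["lev", "Std. Error"]
  ok <- fit$converged && se <= se_cap
  tibble::tibble(
    dss = dss_name, odds_ratio = exp(est),
    ci_low = if (ok) exp(est - 1.96 * se) else NA_real_,
    ci_high = if (ok) exp(est + 1.96 * se) else NA_real_,
    p_value = sm["lev", "Pr(>|z|)"], converged = ok
  )
}

collapsed_class_factor <- function(level) {
  factor(c("low", "intermediate", "high")[level],
         levels = c("low", "intermediate", "high"))
}

# The nine outcome columns modelled against each score.
analysis_outcomes <- function(flags, composites) {
  tibble::tibble(
    patient_id = flags$patient_id,
    long_operative_time = flags$long_operative_time,
    high_blood_loss = flags$high_blood_loss,
    conversion = flags$conversion,
    prolonged_los = flags$prolonged_los,
    any_complication = flags$any_complication,
    severe_complication = flags$severe_complication,
    oo_failure = !composites$oo[match(flags$patient_id,
                                      composites$patient_id)],
    po_failure = !composites$po[match(flags$patient_id,
                                      composites$patient_id)],
    to_failure = !composites$to[match(flags$patient_id,
                                      composites$patient_id)]
  )
}

#' Odds-ratio table across outcomes and difficulty scores
#'
#' Fits, for each of the nine analysed outcomes (the six dichotomised single
#' outcomes plus failure of the operative, postoperative and textbook
#' composites), a separate logistic model per difficulty score on its
#' collapsed 3-level classes. A model whose design degenerates (e.g. a
#' single observed class in a tiny cohort) contributes flag rows instead of
#' aborting the table.
#'
#' @param cohort A cohort tibble.
#' @param config A [segment_config()].
#' @param los_threshold Textbook-outcome stay threshold; `NULL` (default)
#'   computes the cohort's 75th percentile.
#' @return A tibble of per-class rows with an `outcome` column prepended to
#'   the [fit_class_logistic()] columns.
#' @export
or_table <- function(cohort, config = segment_config(),
                     los_threshold = NULL) {
  panel <- score_cohort(cohort, config)
  flags <- outcome_flags(cohort)
  comps <- composite_outcomes(cohort, los_threshold)
  outc <- dplyr::arrange(analysis_outcomes(flags, comps), .data$patient_id)
  stopifnot(identical(panel$patient_id, outc$patient_id))
  outcome_names <- setdiff(names(outc), "patient_id")
  purrr::map_dfr(outcome_names, function(oc) {
    purrr::map_dfr(dss_systems(), function(ds) {
      cls <- collapsed_class_factor(panel[[paste0(ds, "_collapsed")]])
      res <- tryCatch(
        fit_class_logistic(outc[[oc]], cls, dss_name = ds),
        error = function(e) tibble::tibble(
          dss = ds, class_label = NA_character_, odds_ratio = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
          reference = FALSE, converged = FALSE,
          n = length(cls), events = sum(outc[[oc]], na.rm = TRUE)
        )
      )
      dplyr::mutate(res, outcome = oc, .before = 1)
    })
  })
}

#' Random-forest permutation importance of the difficulty scores
#'
#' Ranks candidate predictors of a binary outcome by out-of-bag permutation
#' importance (mean decrease in out-of-bag accuracy when the predictor's
#' values are permuted) from a seeded classification forest. The default
#' candidate set is the four collapsed difficulty scores plus BMI, ASA, sex,
#' liver histology (indicator-expanded), cardiologic and vascular
#' comorbidity, chronic kidney disease, diabetes and portal hypertension.
#'
#' @param data A data frame of predictors (numeric, logical or factor
#'   columns), one row per patient.
#' @param outcome Logical outcome vector aligned with `data`.
#' @param trees Number of trees (default 500).
#' @param mtry Predictors tried per split; default `floor(sqrt(p))`.
#' @param seed Integer seed making the forest deterministic.
#' @return A tibble of class `dss_importance` with columns `variable`,
#'   `importance`, `rank`, sorted by decreasing importance (ties broken by
#'   variable name); forest settings are stored in attribute `settings`.
#' @export
rf_importance <- function(data, outcome, trees = 500, mtry = NULL,
                          seed = 1L) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2) {
    stop("degenerate outcome: constant across the cohort", call. = FALSE)
  }
  df <- as.data.frame(lapply(data, function(col) {
    if (is.logical(col)) as.integer(col)
    else if (is.factor(col)) as.integer(col)
    else as.numeric(col)
  }))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(df))))
  df$.outcome <- factor(outcome, levels = c(FALSE, TRUE))
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = df,
    num.trees = trees, mtry = mtry, importance = "permutation",
    seed = seed, num.threads = 1, respect.unordered.factors = FALSE
  )
  imp <- fit$variable.importance
  out <- tibble::tibble(variable = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$variable) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(out, class = c("dss_importance", class(out)),
            settings = list(trees = trees, mtry = mtry, seed = seed,
                            metric = "OOB permutation importance",
                            n = nrow(df)))
}

# Candidate predictor frame: collapsed scores as integer ordinals, liver
# histology indicator-expanded, comorbidity flags as 0/1.
analysis_features <- function(cohort, panel) {
  pat <- cohort |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$patient_id)
  stopifnot(identical(pat$patient_id, panel$patient_id))
  tibble::tibble(
    halls = panel$halls_collapsed,
    hasegawa = panel$hasegawa_collapsed,
    kawaguchi = panel$kawaguchi_collapsed,
    iwate = panel$iwate_collapsed,
    bmi = pat$bmi,
    asa = pat$asa,
    sex_male = pat$sex == "M",
    histology_steatosis = pat$liver_histology == "steatosis",
    histology_cirrhosis = pat$liver_histology == "cirrhosis",
    cardiologic = pat$comorb_cardiologic,
    vascular = pat$comorb_vascular,
    ckd = pat$comorb_ckd,
    diabetes = pat$comorb_diabetes,
    portal_hypertension = pat$portal_hypertension
  )
}
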