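# Binarised single outcomes and the three composite measures.
#
# Boundary semantics follow the clinical dichotomies: the favorable side is
# inclusive (<= 240 min, <= 500 ml, <= 5 days), so a value exactly at the
# threshold is favorable.

#' Dichotomised single-outcome flags
#'
#' One row per patient with the standard unfavorable-outcome indicators:
#' operative time over 240 min, blood loss over 500 ml, conversion to open
#' surgery, length of stay over 5 days, any complication (Clavien--Dindo
#' >= 1) and severe complication (Clavien--Dindo >= 3).
#'
#' @param cohort A cohort tibble.
#' @return A tibble: `patient_id`, `long_operative_time`, `high_blood_loss`,
#'   `conversion`, `prolonged_los`, `any_complication`,
#'   `severe_complication`.
#' @export
outcome_flags <- function(cohort) {
  cohort |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      long_operative_time = .data$operative_time_min > 240,
      high_blood_loss = .data$blood_loss_ml > 500,
      conversion = .data$conversion,
      prolonged_los = .data$los_days > 5,
      any_complication = .data$clavien_dindo >= 1,
      severe_complication = .data$clavien_dindo >= 3
    )
}

#' Nearest-rank percentile of length of stay
#'
#' The q-th percentile of per-patient length of stay under the nearest-rank
#' (type 1) definition: the smallest observed value whose cumulative
#' proportion reaches q. Stated explicitly because stay is integer-valued
#' and interpolating definitions disagree.
#'
#' @param cohort A cohort tibble.
#' @param q Percentile as a fraction; default 0.75.
#' @return Integer number of days.
#' @export
#' @examples
#' \dontrun{los_percentile_threshold(cohort)}
los_percentile_threshold <- function(cohort, q = 0.75) {
  los <- dplyr::distinct(cohort, .data$patient_id, .keep_all = TRUE)$los_days
  if (length(los) == 0) stop("empty cohort", call. = FALSE)
  as.integer(sort(los)[ceiling(q * length(los))])
}

#' Operative outcome
#'
#' Achieved when all three intra-operative criteria are met: no conversion
#' to open surgery, operative time at most 240 min, and blood loss at most
#' 500 ml.
#'
#' @param conversion Logical.
#' @param operative_time_min,blood_loss_ml Numeric.
#' @return Logical vector.
#' @export
operative_outcome <- function(conversion, operative_time_min, blood_loss_ml) {
  !conversion & operative_time_min <= 240 & blood_loss_ml <= 500
}

#' Postoperative outcome
#'
#' Achieved when the patient had no complication (Clavien--Dindo 0) and a
#' length of stay of at most 5 days.
#'
#' @param clavien_dindo Integer grade 0--5.
#' @param los_days Integer days.
#' @return Logical vector.
#' @export
postoperative_outcome <- function(clavien_dindo, los_days) {
  clavien_dindo == 0 & los_days <= 5
}

#' Textbook outcome
#'
#' All-or-none composite: no moderate or severe intra-operative event
#' (Satava grade at most I), no severe complication (Clavien--Dindo at most
#' II), no prolonged stay (over the supplied threshold, canonically the
#' cohort's 75th percentile), a radical R0 resection, and neither
#' readmission nor death within 90 days.
#'
#' @param satava_grade Character/factor in none/I/II/III.
#' @param clavien_dindo Integer grade 0--5.
#' @param los_days Integer days.
#' @param margin `"R0"` or `"R1"`.
#' @param readmission_90d,mortality_90d Logical.
#' @param los_threshold_days Stay threshold in days (>= 1).
#' @return Logical vector.
#' @export
textbook_outcome <- function(satava_grade, clavien_dindo, los_days, margin,
                             readmission_90d, mortality_90d,
                             los_threshold_days) {
  if (any(los_threshold_days < 1)) {
    stop("los_threshold_days must be at least 1", call. = FALSE)
  }
  as.character(satava_grade) %in% c("none", "I") &
    clavien_dindo <= 2 &
    los_days <= los_threshold_days &
    margin == "R0" &
    !readmission_90d &
    !mortality_90d
}

#' Composite outcomes per patient
#'
#' Evaluates the operative (OO), postoperative (PO) and textbook (TO)
#' composites for every patient. The textbook-outcome stay threshold
#' defaults to the cohort's 75th percentile of stay
#' ([los_percentile_threshold()]); pass `los_threshold` to override it. The
#' threshold used is recorded in column `to_los_threshold_days`.
#'
#' @param cohort A cohort tibble.
#' @param los_threshold Integer days, or `NULL` (default) to compute the
#'   75th percentile from the cohort.
#' @return A tibble: `patient_id`, `oo`, `po`, `to`,
#'   `to_los_threshold_days`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 50, seed = 1))
#' composite_outcomes(cohort)
composite_outcomes <- function(cohort, los_threshold = NULL) {
  if (is.null(los_threshold)) {
    los_threshold <- los_percentile_threshold(cohort)
  }
  cohort |>
    dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      oo = operative_outcome(.data$conversion, .data$operative_time_min,
                             .data$blood_loss_ml),
      po = postoperative_outcome(.data$clavien_dindo, .data$los_days),
      to = textbook_outcome(.data$satava_grade, .data$clavien_dindo,
                            .data$los_days, .data$margin,
                            .data$readmission_90d, .data$mortality_90d,
                            los_threshold),
      to_los_threshold_days = as.integer(los_threshold)
    )
}
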