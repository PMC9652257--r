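# Cohort table: typed per-patient records with CSV I/O and validation.
#
# A cohort is a tibble with one row per resection target; patient-level
# fields (demographics, liver status, history, peri-operative outcomes) are
# repeated across the rows of a multi-resection patient and must be
# consistent.  `segments` is a list-column of Couinaud label vectors in
# memory and a semicolon-separated cell on disk.

cohort_columns <- function() {
  c("patient_id", "resection_index", "age_years", "sex", "bmi", "asa",
    "child_pugh", "platelets_1e9_per_L", "portal_hypertension",
    "liver_histology", "previous_open_liver_resection",
    "neoadjuvant_chemotherapy", "comorb_cardiologic", "comorb_vascular",
    "comorb_diabetes", "comorb_respiratory", "comorb_neurologic",
    "comorb_ckd", "approach", "resection_type", "segments", "tumor_size_cm",
    "malignant", "proximity_major_vessels", "operative_time_min",
    "blood_loss_ml", "conversion", "transfusion", "satava_grade",
    "clavien_dindo", "los_days", "margin", "readmission_90d", "mortality_90d")
}

cohort_logical_columns <- function() {
  c("portal_hypertension", "previous_open_liver_resection",
    "neoadjuvant_chemotherapy", "comorb_cardiologic", "comorb_vascular",
    "comorb_diabetes", "comorb_respiratory", "comorb_neurologic",
    "comorb_ckd", "malignant", "proximity_major_vessels", "conversion",
    "transfusion", "readmission_90d", "mortality_90d")
}

# Patient-level columns that must be constant across a patient's rows.
cohort_patient_columns <- function() {
  setdiff(cohort_columns(),
          c("resection_index", "resection_type", "segments", "tumor_size_cm",
            "malignant", "proximity_major_vessels"))
}

resection_types <- function() {
  c("wedge", "anatomical_segmentectomy", "left_lateral_sectionectomy",
    "sectionectomy_other", "left_hepatectomy", "right_hepatectomy",
    "central_hepatectomy", "extended_hepatectomy")
}

satava_levels <- function() c("none", "I", "II", "III")

#' Read a cohort CSV
#'
#' Reads a per-resection cohort table (one row per resection target; patients
#' with multiple targets occupy several rows sharing `patient_id`), parses
#' the `segments` cell into a list-column, and validates every record.
#'
#' @param path Path to a cohort CSV with the columns listed in
#'   [cohort_columns()]. Booleans are encoded 0/1 on disk.
#' @param strict If `TRUE` (default) any invalid row aborts with an error
#'   naming the field and row; if `FALSE`, offending patients are dropped
#'   with a message giving the count.
#' @param config A [segment_config()], used to expand bare `"4"` labels.
#' @return A cohort tibble; attribute `provenance` is set to `"observed"`.
#' @export
read_cohort <- function(path, strict = TRUE, config = segment_config()) {
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(
    .default = readr::col_character()), show_col_types = FALSE))
  missing <- setdiff(cohort_columns(), hdr)
  if (length(missing) > 0) {
    stop("cohort CSV is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    child_pugh = readr::col_character(),
    liver_histology = readr::col_character(),
    approach = readr::col_character(),
    resection_type = readr::col_character(),
    segments = readr::col_character(),
    satava_grade = readr::col_character(),
    margin = readr::col_character(),
    bmi = readr::col_double(),
    platelets_1e9_per_L = readr::col_double(),
    tumor_size_cm = readr::col_double(),
    .default = readr::col_integer()
  ), progress = FALSE, show_col_types = FALSE)
  x <- raw[, cohort_columns()]
  for (col in cohort_logical_columns()) {
    x[[col]] <- as.logical(x[[col]])
  }
  x$segments <- lapply(strsplit(ifelse(is.na(x$segments), "", x$segments),
                                ";", fixed = TRUE), trimws)
  x <- tibble::as_tibble(x)
  x <- validate_cohort(x, strict = strict, config = config)
  attr(x, "provenance") <- "observed"
  x
}

#' Write a cohort CSV
#'
#' Serialises a cohort tibble back to the flat CSV schema: booleans as 0/1,
#' segment sets as semicolon-separated cells. `read_cohort()` of the written
#' file reproduces the cohort field-for-field.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, cohort_columns()]
  for (col in cohort_logical_columns()) {
    out[[col]] <- as.integer(out[[col]])
  }
  out$segments <- vapply(out$segments, paste, character(1), collapse = ";")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Collect row-level validation problems as a tibble(row, field, message).
cohort_problems <- function(x, config = segment_config()) {
  n <- nrow(x)
  probs <- list()
  note <- function(rows, field, msg) {
    if (length(rows) > 0) {
      probs[[length(probs) + 1]] <<-
        tibble::tibble(row = rows, field = field, message = msg)
    }
  }
  bad_enum <- function(col, levels) {
    which(is.na(x[[col]]) | !x[[col]] %in% levels)
  }
  note(bad_enum("sex", c("M", "F")), "sex", "must be M or F")
  note(bad_enum("child_pugh", c("A", "B")), "child_pugh", "must be A or B")
  note(bad_enum("liver_histology", c("healthy", "steatosis", "cirrhosis")),
       "liver_histology", "must be healthy/steatosis/cirrhosis")
  note(bad_enum("approach", c("pure_laparoscopic", "hybrid_or_hand_assisted")),
       "approach", "unknown approach")
  note(bad_enum("resection_type", resection_types()),
       "resection_type", "unknown resection type")
  note(bad_enum("satava_grade", satava_levels()),
       "satava_grade", "must be none/I/II/III")
  note(bad_enum("margin", c("R0", "R1")), "margin", "must be R0 or R1")
  note(which(is.na(x$asa) | !x$asa %in% 1:4), "asa", "must be in 1-4")
  note(which(is.na(x$clavien_dindo) | x$clavien_dindo < 0 |
               x$clavien_dindo > 5),
       "clavien_dindo", "must be in 0-5")
  note(which(is.na(x$bmi) | x$bmi <= 0), "bmi", "must be positive")
  note(which(is.na(x$platelets_1e9_per_L) | x$platelets_1e9_per_L <= 0),
       "platelets_1e9_per_L", "must be positive")
  note(which(is.na(x$tumor_size_cm) | x$tumor_size_cm < 0),
       "tumor_size_cm", "must be non-negative")
  note(which(is.na(x$los_days) | x$los_days < 1), "los_days",
       "must be at least 1")
  note(which(is.na(x$operative_time_min) | x$operative_time_min < 1),
       "operative_time_min", "must be positive")
  note(which(is.na(x$blood_loss_ml) | x$blood_loss_ml < 0),
       "blood_loss_ml", "must be non-negative")
  note(which(is.na(x$age_years) | x$age_years < 0), "age_years",
       "must be non-negative")
  for (col in cohort_logical_columns()) {
    note(which(is.na(x[[col]])), col, "must be 0/1")
  }
  vocab_ok <- vapply(x$segments, function(s) {
    s <- unlist(lapply(s, function(l) if (l == "4") "4b" else l))
    length(s) > 0 && all(s %in% segment_vocabulary())
  }, logical(1))
  note(which(!vocab_ok), "segments",
       "segment labels must be non-empty and drawn from the vocabulary")
  note(which(x$mortality_90d & x$clavien_dindo != 5), "mortality_90d",
       "90-day mortality requires clavien_dindo = 5")
  dup <- duplicated(paste(x$patient_id, x$resection_index))
  note(which(dup), "resection_index", "duplicated within patient")
  # patient-level consistency across a patient's rows
  for (col in cohort_patient_columns()) {
    if (col == "patient_id") next
    tab <- tapply(x[[col]], x$patient_id,
                  function(v) length(unique(v)) > 1)
    bad_ids <- names(tab)[tab]
    note(which(x$patient_id %in% bad_ids & !duplicated(x$patient_id)),
         col, "inconsistent across a patient's resection rows")
  }
  if (length(probs) == 0) {
    tibble::tibble(row = integer(), field = character(), message = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(probs), .data$row)
  }
}

#' Validate a cohort tibble
#'
#' Checks enumerations, numeric ranges, segment vocabulary, uniqueness of
#' `(patient_id, resection_index)`, consistency of patient-level fields
#' across a patient's resection rows, and the rule that 90-day mortality can
#' only accompany Clavien--Dindo grade 5.
#'
#' @inheritParams read_cohort
#' @param cohort A cohort tibble.
#' @return The validated cohort (strict mode) or the cohort with offending
#'   patients removed (non-strict mode).
#' @export
validate_cohort <- function(cohort, strict = TRUE, config = segment_config()) {
  cohort$segments <- parse_segments_lenient(cohort$segments, config)
  probs <- cohort_problems(cohort, config)
  if (nrow(probs) == 0) return(cohort)
  if (strict) {
    p <- probs[1, ]
    stop(sprintf(
      "cohort validation failed: %d problem(s); first: row %d, field '%s' %s",
      nrow(probs), p$row, p$field, p$message), call. = FALSE)
  }
  bad_patients <- unique(cohort$patient_id[probs$row])
  message(sprintf("dropping %d patient(s) (%d row-level problem(s))",
                  length(bad_patients), nrow(probs)))
  dplyr::filter(cohort, !.data$patient_id %in% bad_patients)
}

# Expand plain "4" labels without erroring on out-of-vocabulary labels
# (those are reported by cohort_problems instead).
parse_segments_lenient <- function(segments, config = segment_config()) {
  expand4 <- switch(config$plain4, "4b" = "4b", "4a" = "4a",
                    both = c("4a", "4b"))
  lapply(segments, function(s) {
    unique(unlist(lapply(s, function(l) if (identical(l, "4")) expand4 else l),
                  use.names = FALSE))
  })
}

# Round half away from zero to `digits`, as clinical tables are formatted.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Summarise a cohort in baseline-table style
#'
#' Produces the count and percentage of each level of the standard baseline
#' and outcome variables (one row per level), with percentages rendered to
#' one decimal, half-up — the `"28 (8.1)"` style of clinical baseline tables.
#' Tumor malignancy is summarised per patient (malignant if any target is).
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `variable`, `level`, `n`, `pct`, `label`.
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) {
    stop("cannot summarise an empty cohort", call. = FALSE)
  }
  pat <- cohort |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(malignant_any = any(.data$malignant)) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  n_total <- nrow(pat)
  lvl <- function(x, levels) factor(x, levels = levels)
  yn <- function(x) lvl(ifelse(x, "yes", "no"), c("no", "yes"))
  vars <- list(
    age = lvl(ifelse(pat$age_years >= 65, ">=65 years", "<65 years"),
              c("<65 years", ">=65 years")),
    sex = lvl(ifelse(pat$sex == "M", "male", "female"), c("male", "female")),
    bmi = lvl(ifelse(pat$bmi >= 25, ">=25", "<25"), c("<25", ">=25")),
    asa = lvl(ifelse(pat$asa >= 3, "3-4", "1-2"), c("1-2", "3-4")),
    cardiologic_comorbidity = yn(pat$comorb_cardiologic),
    vascular_comorbidity = yn(pat$comorb_vascular),
    diabetes = yn(pat$comorb_diabetes),
    respiratory_comorbidity = yn(pat$comorb_respiratory),
    neurologic_comorbidity = yn(pat$comorb_neurologic),
    chronic_kidney_disease = yn(pat$comorb_ckd),
    liver_histology = lvl(pat$liver_histology,
                          c("healthy", "steatosis", "cirrhosis")),
    portal_hypertension = yn(pat$portal_hypertension),
    child_pugh = lvl(pat$child_pugh, c("A", "B")),
    platelets = lvl(ifelse(pat$platelets_1e9_per_L <= 100, "<=100", ">100"),
                    c("<=100", ">100")),
    neoadjuvant_chemotherapy = yn(pat$neoadjuvant_chemotherapy),
    previous_open_liver_resection = yn(pat$previous_open_liver_resection),
    malignant_disease = yn(pat$malignant_any),
    operative_time = lvl(ifelse(pat$operative_time_min > 240,
                                ">240 min", "<=240 min"),
                         c("<=240 min", ">240 min")),
    blood_loss = lvl(ifelse(pat$blood_loss_ml > 500, ">500 ml", "<=500 ml"),
                     c("<=500 ml", ">500 ml")),
    conversion = yn(pat$conversion),
    transfusion = yn(pat$transfusion),
    intraoperative_events = lvl(pat$satava_grade, satava_levels()),
    complications = lvl(ifelse(pat$clavien_dindo == 0, "none",
                               ifelse(pat$clavien_dindo <= 2,
                                      "Clavien-Dindo 1-2",
                                      "Clavien-Dindo >=3")),
                        c("none", "Clavien-Dindo 1-2", "Clavien-Dindo >=3")),
    length_of_stay = lvl(ifelse(pat$los_days > 5, ">5 days", "<=5 days"),
                         c("<=5 days", ">5 days")),
    margin = lvl(pat$margin, c("R0", "R1")),
    readmission_90d = yn(pat$readmission_90d),
    mortality_90d = yn(pat$mortality_90d)
  )
  purrr::imap_dfr(vars, function(v, nm) {
    tab <- table(v)
    tibble::tibble(
      variable = nm,
      level = names(tab),
      n = as.integer(tab),
      pct = round_half_up(100 * as.integer(tab) / n_total, 1)
    )
  }) |>
    dplyr::mutate(label = sprintf("%d (%.1f)", .data$n, .data$pct))
}
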