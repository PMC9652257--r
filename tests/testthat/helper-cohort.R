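# Builders for hand-made cohort rows and small fixtures.

# One fully valid cohort row (per-resection) with overridable fields.
cohort_row <- function(patient_id = "P1", resection_index = 1L,
                       age_years = 60L, sex = "M", bmi = 24, asa = 2L,
                       child_pugh = "A", platelets_1e9_per_L = 200,
                       portal_hypertension = FALSE,
                       liver_histology = "healthy",
                       previous_open_liver_resection = FALSE,
                       neoadjuvant_chemotherapy = FALSE,
                       comorb_cardiologic = FALSE, comorb_vascular = FALSE,
                       comorb_diabetes = FALSE, comorb_respiratory = FALSE,
                       comorb_neurologic = FALSE, comorb_ckd = FALSE,
                       approach = "pure_laparoscopic",
                       resection_type = "wedge", segments = "3",
                       tumor_size_cm = 2, malignant = FALSE,
                       proximity_major_vessels = FALSE,
                       operative_time_min = 120L, blood_loss_ml = 100L,
                       conversion = FALSE, transfusion = FALSE,
                       satava_grade = "none", clavien_dindo = 0L,
                       los_days = 4L, margin = "R0",
                       readmission_90d = FALSE, mortality_90d = FALSE) {
  tibble::tibble(
    patient_id = patient_id, resection_index = resection_index,
    age_years = age_years, sex = sex, bmi = bmi, asa = asa,
    child_pugh = child_pugh, platelets_1e9_per_L = platelets_1e9_per_L,
    portal_hypertension = portal_hypertension,
    liver_histology = liver_histology,
    previous_open_liver_resection = previous_open_liver_resection,
    neoadjuvant_chemotherapy = neoadjuvant_chemotherapy,
    comorb_cardiologic = comorb_cardiologic,
    comorb_vascular = comorb_vascular, comorb_diabetes = comorb_diabetes,
    comorb_respiratory = comorb_respiratory,
    comorb_neurologic = comorb_neurologic, comorb_ckd = comorb_ckd,
    approach = approach, resection_type = resection_type,
    segments = list(strsplit(segments, ";", fixed = TRUE)[[1]]),
    tumor_size_cm = tumor_size_cm, malignant = malignant,
    proximity_major_vessels = proximity_major_vessels,
    operative_time_min = operative_time_min, blood_loss_ml = blood_loss_ml,
    conversion = conversion, transfusion = transfusion,
    satava_grade = satava_grade, clavien_dindo = clavien_dindo,
    los_days = los_days, margin = margin, readmission_90d = readmission_90d,
    mortality_90d = mortality_90d
  )
}

make_cohort <- function(...) dplyr::bind_rows(...)

# Compare cohort contents ignoring attributes such as provenance.
expect_same_cohort <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b),
               ignore_attr = TRUE)
}
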