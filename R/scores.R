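# The four difficulty scoring systems for laparoscopic liver resection.
#
# All per-target calculators are vectorised: scalar arguments recycle, and
# `segments` accepts either semicolon-separated strings or a list of label
# vectors.  `score_cohort()` is the data-frame-first entry point.

normalize_segments <- function(segments, config) {
  parse_segments(segments, config)
}

# Brisbane major: an enumerated major hepatectomy type, or >=3 contiguous
# segments.
is_major_resection <- function(resection_type, segments,
                               config = segment_config()) {
  segments <- normalize_segments(segments, config)
  enumerated <- resection_type %in% c("left_hepatectomy", "right_hepatectomy",
                                      "central_hepatectomy",
                                      "extended_hepatectomy")
  by_extent <- vapply(segments, function(s) {
    length(s) >= 3 && segments_contiguous(s)
  }, logical(1))
  enumerated | by_extent
}

#' Halls (Southampton) difficulty score
#'
#' Points: 4 for a major resection; 2 for an anatomical resection of one or
#' two segments including a posterosuperior segment (parse configurable via
#' [segment_config()]); 0 for every other resection; tumor size 3--5 cm 2
#' points, over 5 cm 3 points; malignant tumor 2 points; previous open liver
#' resection 5 points; neoadjuvant chemotherapy 1 point. Range 0--15.
#'
#' @param resection_type One of [resection_types()][cohort_columns].
#' @param segments Semicolon-separated Couinaud labels or list of label
#'   vectors.
#' @param tumor_size_cm Tumor size in centimetres.
#' @param malignant,previous_open_liver_resection,neoadjuvant_chemotherapy
#'   Logical flags.
#' @param config A [segment_config()].
#' @return Integer vector of scores.
#' @export
#' @examples
#' halls_score("anatomical_segmentectomy", "7", 4, malignant = TRUE)
halls_score <- function(resection_type, segments, tumor_size_cm, malignant,
                        previous_open_liver_resection = FALSE,
                        neoadjuvant_chemotherapy = FALSE,
                        config = segment_config()) {
  segments <- normalize_segments(segments, config)
  major <- is_major_resection(resection_type, segments, config)
  n_seg <- lengths(segments)
  ps <- any_posterosuperior(segments, config)
  two_pt <- !major & resection_type != "wedge" & n_seg <= 2
  if (config$halls_two_point_requires_ps) two_pt <- two_pt & ps
  res_pts <- ifelse(major, 4L, ifelse(two_pt, 2L, 0L))
  size_pts <- ifelse(tumor_size_cm > 5, 3L,
                     ifelse(tumor_size_cm >= 3, 2L, 0L))
  as.integer(res_pts + size_pts + 2L * as.logical(malignant) +
               5L * as.logical(previous_open_liver_resection) +
               1L * as.logical(neoadjuvant_chemotherapy))
}

#' Halls difficulty class
#'
#' Published bins: low (less than 2), moderate (3 to 5), high (6 to 9),
#' extremely high (10 to 15). The published bins omit a score of exactly 2;
#' by default it is classed low (configurable through
#' `segment_config(halls_low_max=)`).
#'
#' @param score Integer Halls scores in 0--15.
#' @param config A [segment_config()].
#' @return Factor with levels low, moderate, high, extremely_high.
#' @export
halls_class <- function(score, config = segment_config()) {
  if (any(is.na(score) | score < 0 | score > 15)) {
    stop("Halls score must lie in 0-15", call. = FALSE)
  }
  low_max <- config$halls_low_max
  cls <- ifelse(score <= low_max, "low",
                ifelse(score <= 5, "moderate",
                       ifelse(score <= 9, "high", "extremely_high")))
  factor(cls, levels = c("low", "moderate", "high", "extremely_high"))
}

#' Hasegawa difficulty score
#'
#' Points: resection type (wedge and left lateral sectionectomy 0,
#' segmentectomy 2, major resections 3); tumor location (segments 7--8: 2,
#' 5--6: 1, 2--3--4: 0; segment 1 per configuration, default 2), taken as
#' the maximum over the involved segments; BMI >= 30 kg/m2 1 point;
#' platelets <= 100 x 10^9/L 1 point. Range 0--7.
#'
#' @inheritParams halls_score
#' @param bmi Body-mass index (kg/m2).
#' @param platelets_1e9_per_L Platelet count (10^9/L).
#' @return Integer vector of scores.
#' @export
#' @examples
#' hasegawa_score("right_hepatectomy", "5;6;7;8", bmi = 31,
#'                platelets_1e9_per_L = 90)
hasegawa_score <- function(resection_type, segments, bmi,
                           platelets_1e9_per_L,
                           config = segment_config()) {
  segments <- normalize_segments(segments, config)
  major <- is_major_resection(resection_type, segments, config)
  type_pts <- ifelse(
    major, 3L,
    ifelse(resection_type %in% c("wedge", "left_lateral_sectionectomy"),
           0L, 2L))
  loc_pts <- vapply(segments, function(s) {
    as.integer(max(config$hasegawa_points[s]))
  }, integer(1))
  as.integer(type_pts + loc_pts + (bmi >= 30) + (platelets_1e9_per_L <= 100))
}

#' Hasegawa difficulty class
#'
#' Published bins: low (score <= 1), medium (2--3), high (>= 4).
#'
#' @param score Integer Hasegawa scores in 0--7.
#' @return Factor with levels low, medium, high.
#' @export
hasegawa_class <- function(score) {
  if (any(is.na(score) | score < 0 | score > 7)) {
    stop("Hasegawa score must lie in 0-7", call. = FALSE)
  }
  cls <- ifelse(score <= 1, "low", ifelse(score <= 3, "medium", "high"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Kawaguchi (IMM) difficulty group
#'
#' Group I: wedge resections and left lateral sectionectomy. Group II: left
#' hepatectomy and anterolateral anatomical segmentectomy. Group III:
#' posterosuperior segmentectomy, right hepatectomy, central hepatectomy and
#' extended hepatectomy. Non-left-lateral sectionectomies interpolate the
#' segmentectomy split: III if any involved segment is posterosuperior,
#' else II.
#'
#' @inheritParams halls_score
#' @return Factor with levels I, II, III.
#' @export
#' @examples
#' kawaguchi_group("anatomical_segmentectomy", "2")
kawaguchi_group <- function(resection_type, segments,
                            config = segment_config()) {
  segments <- normalize_segments(segments, config)
  ps <- any_posterosuperior(segments, config)
  grp <- character(length(ps))
  grp[resection_type %in% c("wedge", "left_lateral_sectionectomy")] <- "I"
  grp[resection_type == "left_hepatectomy"] <- "II"
  grp[resection_type %in% c("right_hepatectomy", "central_hepatectomy",
                            "extended_hepatectomy")] <- "III"
  split_types <- resection_type %in% c("anatomical_segmentectomy",
                                       "sectionectomy_other")
  grp[split_types] <- ifelse(ps[split_types], "III", "II")
  factor(grp, levels = c("I", "II", "III"))
}

#' Iwate difficulty score
#'
#' Points: tumor size >= 3 cm 1 point; tumor location (per-segment weights,
#' 1--3 for anterolateral and 4--5 for posterosuperior segments, maximum
#' over the involved segments); extent of resection (wedge 0, left lateral
#' sectionectomy 2, segmentectomy 3, sectionectomy and more 4); proximity to
#' major vessels 1 point; Child--Pugh B 1 point; hybrid or hand-assisted
#' technique -1 point. The total is clamped at 0 from below. Range 0--12.
#'
#' @inheritParams halls_score
#' @param proximity_major_vessels Logical flag.
#' @param child_pugh `"A"` or `"B"`.
#' @param approach `"pure_laparoscopic"` or `"hybrid_or_hand_assisted"`.
#' @return Integer vector of scores.
#' @export
#' @examples
#' iwate_score("right_hepatectomy", "5;6;7;8", 4,
#'             proximity_major_vessels = TRUE, child_pugh = "B")
iwate_score <- function(resection_type, segments, tumor_size_cm,
                        proximity_major_vessels = FALSE, child_pugh = "A",
                        approach = "pure_laparoscopic",
                        config = segment_config()) {
  segments <- normalize_segments(segments, config)
  loc_pts <- vapply(segments, function(s) {
    as.integer(max(config$iwate_weights[s]))
  }, integer(1))
  extent_pts <- dplyr::case_match(
    resection_type,
    "wedge" ~ 0L,
    "left_lateral_sectionectomy" ~ 2L,
    "anatomical_segmentectomy" ~ 3L,
    c("sectionectomy_other", "left_hepatectomy", "right_hepatectomy",
      "central_hepatectomy", "extended_hepatectomy") ~ 4L
  )
  raw <- (tumor_size_cm >= 3) + loc_pts + extent_pts +
    as.logical(proximity_major_vessels) + (child_pugh == "B") -
    (approach == "hybrid_or_hand_assisted")
  as.integer(pmax(0L, raw))
}

#' Iwate difficulty class
#'
#' Published bins: low (1--3), intermediate (4--6), advanced (7--9), expert
#' (10--12). A score of 0 (attainable through the hybrid -1 adjustment) is
#' classed low.
#'
#' @param score Integer Iwate scores in 0--12.
#' @return Factor with levels low, intermediate, advanced, expert.
#' @export
iwate_class <- function(score) {
  if (any(is.na(score) | score < 0 | score > 12)) {
    stop("Iwate score must lie in 0-12", call. = FALSE)
  }
  cls <- ifelse(score <= 3, "low",
                ifelse(score <= 6, "intermediate",
                       ifelse(score <= 9, "advanced", "expert")))
  factor(cls, levels = c("low", "intermediate", "advanced", "expert"))
}

#' Collapse a native difficulty class to the common 3-level ordinal
#'
#' To compare three-class systems (Hasegawa, Kawaguchi) with four-class
#' systems (Halls, Iwate), the two highest classes of the four-class systems
#' are merged, giving every score a 1/2/3 ordinal.
#'
#' @param class Factor or character of native class labels.
#' @param system One of `"halls"`, `"hasegawa"`, `"kawaguchi"`, `"iwate"`.
#' @return Integer vector with values in 1--3.
#' @export
#' @examples
#' collapse_class(c("low", "extremely_high"), "halls")
collapse_class <- function(class,
                           system = c("halls", "hasegawa", "kawaguchi",
                                      "iwate")) {
  system <- match.arg(system)
  map <- switch(system,
    halls = c(low = 1L, moderate = 2L, high = 3L, extremely_high = 3L),
    hasegawa = c(low = 1L, medium = 2L, high = 3L),
    kawaguchi = c(I = 1L, II = 2L, III = 3L),
    iwate = c(low = 1L, intermediate = 2L, advanced = 3L, expert = 3L)
  )
  out <- unname(map[as.character(class)])
  if (any(is.na(out))) {
    stop(sprintf("unknown %s class label", system), call. = FALSE)
  }
  out
}

#' Score every resection target
#'
#' Adds the per-target Halls, Hasegawa and Iwate scores and the Kawaguchi
#' group to a cohort table (one row per resection).
#'
#' @param cohort A cohort tibble.
#' @param config A [segment_config()].
#' @return The cohort with columns `halls`, `hasegawa`, `kawaguchi_grp`,
#'   `iwate` appended.
#' @export
score_targets <- function(cohort, config = segment_config()) {
  dplyr::mutate(
    cohort,
    halls = halls_score(.data$resection_type, .data$segments,
                        .data$tumor_size_cm, .data$malignant,
                        .data$previous_open_liver_resection,
                        .data$neoadjuvant_chemotherapy, config = config),
    hasegawa = hasegawa_score(.data$resection_type, .data$segments,
                              .data$bmi, .data$platelets_1e9_per_L,
                              config = config),
    kawaguchi_grp = kawaguchi_group(.data$resection_type, .data$segments,
                                    config = config),
    iwate = iwate_score(.data$resection_type, .data$segments,
                        .data$tumor_size_cm, .data$proximity_major_vessels,
                        .data$child_pugh, .data$approach, config = config)
  )
}

#' Per-patient difficulty score panel
#'
#' Computes all four difficulty scores for every patient. When a patient has
#' multiple resection targets each score is taken on the most challenging
#' one, i.e. the per-system maximum over the patient's targets (for
#' Kawaguchi, the highest group). Native classes and the collapsed 3-level
#' ordinals are derived from those maxima.
#'
#' @param cohort A cohort tibble (one row per resection target).
#' @param config A [segment_config()].
#' @return A tibble with one row per patient: `patient_id`, the four scores
#'   (`halls_score`, `hasegawa_score`, `iwate_score`), `kawaguchi_group`,
#'   the native classes and the four `*_collapsed` ordinals.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 20, seed = 1))
#' score_cohort(cohort)
score_cohort <- function(cohort, config = segment_config()) {
  scored <- score_targets(cohort, config)
  panel <- scored |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      halls_score = max(.data$halls),
      hasegawa_score = max(.data$hasegawa),
      kawaguchi_group = levels(.data$kawaguchi_grp)[
        max(as.integer(.data$kawaguchi_grp))],
      iwate_score = max(.data$iwate),
      .groups = "drop"
    )
  panel |>
    dplyr::mutate(
      kawaguchi_group = factor(.data$kawaguchi_group,
                               levels = c("I", "II", "III")),
      halls_class = halls_class(.data$halls_score, config),
      hasegawa_class = hasegawa_class(.data$hasegawa_score),
      iwate_class = iwate_class(.data$iwate_score),
      halls_collapsed = collapse_class(.data$halls_class, "halls"),
      hasegawa_collapsed = collapse_class(.data$hasegawa_class, "hasegawa"),
      kawaguchi_collapsed = collapse_class(.data$kawaguchi_group, "kawaguchi"),
      iwate_collapsed = collapse_class(.data$iwate_class, "iwate")
    ) |>
    dplyr::select("patient_id", "halls_score", "halls_class",
                  "hasegawa_score", "hasegawa_class", "kawaguchi_group",
                  "iwate_score", "iwate_class", "halls_collapsed",
                  "hasegawa_collapsed", "kawaguchi_collapsed",
                  "iwate_collapsed")
}
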