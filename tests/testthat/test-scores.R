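# The four difficulty scoring rules.

test_that("Halls points follow the published component scheme", {
  # major + malignant >5cm + previous open + chemo reaches the ceiling
  expect_identical(
    halls_score("right_hepatectomy", "5;6;7;8", 6, TRUE, TRUE, TRUE), 15L)
  # nothing scores
  expect_identical(halls_score("wedge", "3", 2, FALSE), 0L)
  # posterosuperior segmentectomy, 4 cm malignant: 2 + 2 + 2
  expect_identical(
    halls_score("anatomical_segmentectomy", "7", 4, TRUE), 6L)
  # previous open liver resection contributes exactly 5 points
  expect_identical(
    halls_score("wedge", "5", 2, FALSE, TRUE) -
      halls_score("wedge", "5", 2, FALSE, FALSE), 5L)
  # size thresholds: 3-5 cm is 2 points, > 5 cm is 3
  expect_identical(halls_score("wedge", "5", 3, FALSE), 2L)
  expect_identical(halls_score("wedge", "5", 5, FALSE), 2L)
  expect_identical(halls_score("wedge", "5", 5.1, FALSE), 3L)
  # the 2-point tier needs a posterosuperior segment under the default parse
  expect_identical(halls_score("anatomical_segmentectomy", "5", 2, FALSE), 0L)
  cfg <- segment_config(halls_two_point_requires_ps = FALSE)
  expect_identical(
    halls_score("anatomical_segmentectomy", "5", 2, FALSE, config = cfg), 2L)
})

test_that("three contiguous segments count as a major resection", {
  # 5;6;7 is contiguous -> major tier (4 points)
  expect_identical(halls_score("sectionectomy_other", "5;6;7", 2, FALSE), 4L)
  # 2;6;8 is not contiguous -> not major, not the 2-point tier (3 segments)
  expect_identical(halls_score("sectionectomy_other", "2;6;8", 2, FALSE), 0L)
  # major tier (3) plus the segment-7 location points (2)
  expect_identical(hasegawa_score("sectionectomy_other", "5;6;7", 24, 200),
                   3L + 2L)
})

test_that("Halls classes bin the score with the gap at 2 resolved to low", {
  expect_identical(as.character(halls_class(c(1, 2, 3, 5, 6, 9, 10, 15))),
                   c("low", "low", "moderate", "moderate", "high", "high",
                     "extremely_high", "extremely_high"))
  expect_error(halls_class(16), "0-15")
  expect_error(halls_class(-1), "0-15")
})

test_that("Hasegawa points and classes follow the published scheme", {
  expect_identical(hasegawa_score("right_hepatectomy", "5;6;7;8", 31, 90), 7L)
  expect_identical(hasegawa_score("wedge", "3", 24, 200), 0L)
  expect_identical(hasegawa_score("left_lateral_sectionectomy", "2;3",
                                  24, 200), 0L)
  expect_identical(hasegawa_score("anatomical_segmentectomy", "6", 24, 200),
                   3L)
  # boundary semantics: BMI >= 30 and platelets <= 100 score
  expect_identical(hasegawa_score("wedge", "3", 30, 100), 2L)
  expect_identical(as.character(hasegawa_class(c(0, 1, 2, 3, 4, 7))),
                   c("low", "low", "medium", "medium", "high", "high"))
  expect_error(hasegawa_class(8), "0-7")
})

test_that("Kawaguchi groups follow the published lists", {
  expect_identical(as.character(kawaguchi_group("left_lateral_sectionectomy",
                                                "2;3")), "I")
  expect_identical(as.character(kawaguchi_group("wedge", "8")), "I")
  expect_identical(as.character(kawaguchi_group("right_hepatectomy",
                                                "5;6;7;8")), "III")
  expect_identical(as.character(kawaguchi_group("left_hepatectomy",
                                                "2;3;4a;4b")), "II")
  expect_identical(as.character(kawaguchi_group("anatomical_segmentectomy",
                                                "2")), "II")
  expect_identical(as.character(kawaguchi_group("anatomical_segmentectomy",
                                                "8")), "III")
  # non-left-lateral sectionectomy interpolates the segmentectomy split
  expect_identical(as.character(kawaguchi_group("sectionectomy_other",
                                                "6;7")), "III")
  expect_identical(as.character(kawaguchi_group("sectionectomy_other",
                                                "4b;5")), "II")
})

test_that("Iwate points and classes follow the published scheme", {
  expect_identical(
    iwate_score("right_hepatectomy", "5;6;7;8", 4, TRUE, "B"), 12L)
  expect_identical(
    iwate_score("wedge", "3", 2, approach = "hybrid_or_hand_assisted"), 0L)
  # left lateral sectionectomy adds 2 extent points over a wedge
  expect_identical(
    iwate_score("left_lateral_sectionectomy", "3", 2) -
      iwate_score("wedge", "3", 2), 2L)
  # location weight enters through the configured table
  cfg <- segment_config(iwate_weights = c("1" = 4, "2" = 2, "3" = 2,
                                          "4a" = 4, "4b" = 3, "5" = 3,
                                          "6" = 2, "7" = 5, "8" = 5))
  expect_identical(
    iwate_score("left_lateral_sectionectomy", "3", 2, config = cfg),
    2L + 2L)
  expect_identical(as.character(iwate_class(c(0, 3, 4, 6, 7, 9, 10, 12))),
                   c("low", "low", "intermediate", "intermediate",
                     "advanced", "advanced", "expert", "expert"))
  expect_error(iwate_class(13), "0-12")
})

test_that("score maxima and minima match brute-force enumeration", {
  grid <- target_grid()
  halls_max <- max(mapply(function(tp, sg) {
    max(halls_score(tp, list(sg), c(2, 4, 6), TRUE, TRUE, TRUE))
  }, grid$type, grid$segments))
  iwate_max <- max(mapply(function(tp, sg) {
    max(iwate_score(tp, list(sg), c(2, 4), TRUE, "B"))
  }, grid$type, grid$segments))
  hasegawa_max <- max(mapply(function(tp, sg) {
    hasegawa_score(tp, list(sg), 31, 90)
  }, grid$type, grid$segments))
  expect_identical(halls_max, 15L)
  expect_identical(iwate_max, 12L)
  expect_identical(hasegawa_max, 7L)
  mins <- mapply(function(tp, sg) {
    min(halls_score(tp, list(sg), 2, FALSE),
        hasegawa_score(tp, list(sg), 24, 200),
        iwate_score(tp, list(sg), 2,
                    approach = "hybrid_or_hand_assisted"))
  }, grid$type, grid$segments)
  expect_identical(min(mins), 0L)
})

test_that("raising any point-scoring feature never lowers a score", {
  set.seed(42)
  grid <- target_grid()
  idx <- sample(nrow(grid), 60)
  for (i in idx) {
    tp <- grid$type[i]
    sg <- list(grid$segments[[i]])
    base_halls <- halls_score(tp, sg, 2, FALSE, FALSE, FALSE)
    expect_gte(halls_score(tp, sg, 4, FALSE, FALSE, FALSE), base_halls)
    expect_gte(halls_score(tp, sg, 2, TRUE, FALSE, FALSE), base_halls)
    expect_gte(halls_score(tp, sg, 2, FALSE, TRUE, FALSE), base_halls)
    expect_gte(halls_score(tp, sg, 2, FALSE, FALSE, TRUE), base_halls)
    base_hase <- hasegawa_score(tp, sg, 24, 200)
    expect_gte(hasegawa_score(tp, sg, 31, 200), base_hase)
    expect_gte(hasegawa_score(tp, sg, 24, 90), base_hase)
    base_iwate <- iwate_score(tp, sg, 2)
    expect_gte(iwate_score(tp, sg, 4), base_iwate)
    expect_gte(iwate_score(tp, sg, 2, proximity_major_vessels = TRUE),
               base_iwate)
    expect_gte(iwate_score(tp, sg, 2, child_pugh = "B"), base_iwate)
    # hybrid is the one subtraction: exactly one point, clamped at zero
    hybrid <- iwate_score(tp, sg, 2, approach = "hybrid_or_hand_assisted")
    expect_identical(hybrid, max(0L, base_iwate - 1L))
  }
})

test_that("class bins are exhaustive and weakly increasing in the score", {
  h <- halls_class(0:15)
  expect_false(anyNA(h))
  expect_true(all(diff(as.integer(h)) >= 0))
  hs <- hasegawa_class(0:7)
  expect_false(anyNA(hs))
  expect_true(all(diff(as.integer(hs)) >= 0))
  iw <- iwate_class(0:12)
  expect_false(anyNA(iw))
  expect_true(all(diff(as.integer(iw)) >= 0))
})

test_that("collapsing merges only the two highest classes", {
  expect_identical(collapse_class(c("low", "moderate", "high",
                                    "extremely_high"), "halls"),
                   c(1L, 2L, 3L, 3L))
  expect_identical(collapse_class(c("low", "intermediate", "advanced",
                                    "expert"), "iwate"),
                   c(1L, 2L, 3L, 3L))
  expect_identical(collapse_class(c("low", "medium", "high"), "hasegawa"),
                   1:3)
  expect_identical(collapse_class(c("I", "II", "III"), "kawaguchi"), 1:3)
  expect_error(collapse_class("bogus", "halls"), "unknown")
  # monotone surjection onto 1..3 for every system
  for (sys in c("halls", "iwate")) {
    lv <- if (sys == "halls") c("low", "moderate", "high", "extremely_high")
          else c("low", "intermediate", "advanced", "expert")
    out <- collapse_class(lv, sys)
    expect_identical(sort(unique(out)), 1:3)
    expect_true(all(diff(out) >= 0))
  }
})

test_that("multi-resection panels take the per-system maximum", {
  co <- make_cohort(
    cohort_row("P1", resection_index = 1L, resection_type = "wedge",
               segments = "3", tumor_size_cm = 1, malignant = FALSE),
    cohort_row("P1", resection_index = 2L,
               resection_type = "right_hepatectomy", segments = "5;6;7;8",
               tumor_size_cm = 6, malignant = TRUE)
  )
  panel <- score_cohort(co)
  expect_identical(panel$halls_score, 9L)  # 4 + 3 + 2 from the major target
  # element-wise max oracle: score each row alone and combine
  single_panels <- lapply(1:2, function(i) {
    x <- co[i, ]
    x$patient_id <- "P1"
    score_cohort(x)
  })
  expect_identical(panel$halls_score,
                   max(vapply(single_panels, function(p) p$halls_score,
                              integer(1))))
  expect_identical(panel$iwate_score,
                   max(vapply(single_panels, function(p) p$iwate_score,
                              integer(1))))
  expect_identical(panel$hasegawa_score,
                   max(vapply(single_panels, function(p) p$hasegawa_score,
                              integer(1))))
  expect_identical(
    as.integer(panel$kawaguchi_group),
    max(vapply(single_panels,
               function(p) as.integer(p$kawaguchi_group), integer(1))))
  # duplicating a target changes nothing
  dup <- dplyr::bind_rows(co[2, ], dplyr::mutate(co[2, ],
                                                 resection_index = 3L))
  expect_identical(score_cohort(dup)$halls_score,
                   score_cohort(co[2, ])$halls_score)
})

test_that("a randomly scored panel equals the per-target loop oracle", {
  co <- simulate_cohort(sim_config(n = 80, seed = 9))
  panel <- score_cohort(co)
  oracle <- vapply(split(co, co$patient_id), function(rows) {
    max(vapply(seq_len(nrow(rows)), function(i) {
      halls_score(rows$resection_type[i], rows$segments[i],
                  rows$tumor_size_cm[i], rows$malignant[i],
                  rows$previous_open_liver_resection[i],
                  rows$neoadjuvant_chemotherapy[i])
    }, integer(1)))
  }, integer(1))
  expect_identical(panel$halls_score,
                   unname(oracle[panel$patient_id]))
})

test_that("plain segment 4 expands per configuration", {
  expect_identical(parse_segments("4")[[1]], "4b")
  expect_identical(parse_segments("4", segment_config(plain4 = "4a"))[[1]],
                   "4a")
  expect_identical(parse_segments("4", segment_config(plain4 = "both"))[[1]],
                   c("4a", "4b"))
  expect_error(parse_segments("9"), "vocabulary")
  # 4a is posterosuperior, 4b is not: the expansion decides Kawaguchi III/II
  expect_identical(
    as.character(kawaguchi_group("anatomical_segmentectomy", "4",
                                 segment_config(plain4 = "4a"))), "III")
  expect_identical(
    as.character(kawaguchi_group("anatomical_segmentectomy", "4")), "II")
})

test_that("segment-weight configuration is validated against the ranges", {
  expect_error(segment_config(iwate_weights = c("1" = 4, "2" = 5, "3" = 1,
                                                "4a" = 4, "4b" = 3, "5" = 3,
                                                "6" = 2, "7" = 5, "8" = 5)),
               "anterolateral")
  expect_error(segment_config(iwate_weights = c("1" = 4, "2" = 2, "3" = 1,
                                                "4a" = 4, "4b" = 3, "5" = 3,
                                                "6" = 2, "7" = 3, "8" = 5)),
               "posterosuperior")
})
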