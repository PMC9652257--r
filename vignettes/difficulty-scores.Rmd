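---
title: "Comparing difficulty scores for laparoscopic liver resection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing difficulty scores for laparoscopic liver resection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverdss)
```

## Scope and model

Four rule-based difficulty scoring systems (DSS) for laparoscopic liver
resection — Halls, Hasegawa, Kawaguchi and Iwate — map pre- and
intra-operative features (resection type and Couinaud segments, tumor size
and malignancy, BMI, platelets, Child–Pugh class, surgical history,
approach) to a points total and a difficulty class. The package implements
the calculators, the composite peri-operative outcomes used to evaluate
them (operative, postoperative and textbook outcome), a synthetic cohort
generator, and the comparison machinery: Spearman concordance, per-class
logistic odds ratios, and random-forest permutation importance.

To put three-class systems (Hasegawa, Kawaguchi) and four-class systems
(Halls, Iwate) on a common ordinal scale, the two highest classes of the
four-class systems are merged, so every patient gets a 1/2/3 level per
system (`collapse_class()`). Concordance and all association models run on
those collapsed levels by default; `spearman_concordance(collapsed =
FALSE)` switches to native classes, since either convention is defensible.

When one procedure removes several targets, each score is evaluated on the
patient's most challenging target, implemented as the per-system maximum
over targets (for Kawaguchi, the highest group). Taking the maximum per
system — rather than electing a single globally "worst" target — is
deterministic and needs no tie-breaking; the two readings differ only for
patients whose targets are incomparable across systems.

## Interpreting the published point schemes

Several aspects of the original score descriptions are underdetermined.
Each is resolved by an explicit, configurable default in
`segment_config()`:

* **Halls 2-point tier.** "Anatomical resections of one or two segments
  including posterosuperior segments" is parsed literally: 2 points only
  when the resection involves a posterosuperior segment
  (`halls_two_point_requires_ps = TRUE`); with `FALSE`, every non-major
  anatomical resection of one or two segments earns the 2 points.
* **Halls class gap.** The published bins "less than 2" and "3 to 5" omit a
  score of exactly 2; it is classed low (`halls_low_max = 2`), keeping the
  bins exhaustive without inventing a fifth class.
* **Iwate class gap.** A score of 0 is attainable via the −1
  hybrid-technique adjustment but the lowest published bin starts at 1;
  0 maps to low, the lowest difficulty by construction. The raw sum is also
  clamped at 0 from below.
* **Iwate location weights.** Only the ranges are published (anterolateral
  1–3, posterosuperior 4–5 points). The defaults follow the commonly cited
  per-segment chart — 2→2, 3→1, 4b→3, 5→3, 6→2 anterolateral; 1→4, 4a→4,
  7→5, 8→5 posterosuperior — and `segment_config()` rejects any replacement
  violating the ranges. Weight-dependent tests are parametric in this
  table.
* **Posterosuperior set.** Defaults to the conventional {1, 4a, 7, 8}.
  Because sub-segments 4a and 4b differ in posterosuperior membership, the
  vocabulary splits segment 4; a bare `"4"` in input expands to 4b by
  default (`plain4`), the conservative choice for every rule keyed on
  posterosuperior involvement.
* **Hasegawa segment 1** is not covered by the published 7–8/5–6/2–3–4
  location tiers; it defaults to 2 points, treated like the other
  difficult-access segments.
* **Brisbane major rule.** A major hepatectomy is an enumerated major type
  or any resection of ≥3 contiguous segments. Contiguity uses a standard
  anatomical adjacency graph over the nine labels (e.g. 5–6, 6–7, 7–8,
  4a–8, 1 adjacent to 2/4a/7/8); the graph is an approximation of liver
  anatomy, adequate because only connectivity of ≥3-segment sets matters.
* **Off-list resection types.** Non-left-lateral sectionectomies take the
  Hasegawa segmentectomy tier (2 points) unless the Brisbane rule makes
  them major (3), and the Kawaguchi II/III split for them follows the
  anterolateral/posterosuperior segmentectomy rule.
* **Benign disease** simply contributes 0 malignancy points; nothing else
  in the schemes distinguishes it.

## Outcome definitions

The dichotomised single outcomes use inclusive favorable boundaries:
operative time ≤ 240 min, blood loss ≤ 500 ml and stay ≤ 5 days pass; 241,
501 and 6 fail. The composites are conjunctions:

* operative outcome — no conversion, time ≤ 240 min, loss ≤ 500 ml;
* postoperative outcome — Clavien–Dindo 0 and stay ≤ 5 days;
* textbook outcome — Satava ≤ I (an uneventful procedure and a grade-I
  event both pass), Clavien–Dindo ≤ II, stay ≤ the cohort's 75th
  percentile, R0 margin, no 90-day readmission or death.

The textbook-outcome stay threshold is the nearest-rank (type 1)
percentile: the smallest observed value whose cumulative proportion reaches
q. Stay is integer-valued, so interpolating percentile definitions disagree
with one another; the nearest-rank value is always an observed stay. The
fixed 5-day dichotomy and the percentile threshold are deliberately
separate parameters — they need not coincide, and `composite_outcomes()`
records the threshold it used with every evaluation.

## The synthetic generator

`sim_config()`/`simulate_cohort()` stand in for an observed series. The
defaults encode a 346-patient single-centre case mix: feature marginals
(male 58.1%, age ≥ 65 53.7%, BMI ≥ 25 56.4%, ASA 3–4 32.9%, cirrhosis
34.4%, portal hypertension 18.2%, platelets ≤ 100×10⁹/L 12.7%, Child–Pugh B
3.3%, malignant disease 82.6%, …) and a resection-type mix chosen so the
implied Kawaguchi I/II/III distribution is ≈ 62/21/17%. Pre-operative
chemotherapy defaults to 13% of patients receiving it. Where a marginal has
no published anchor (previous open resection, hybrid approach, vessel
proximity), a small clinically plausible default is fixed once and
documented in `sim_config()`.

Difficulty is not injected as a hidden label: it emerges from the generated
resection and tumor features, so all four scores are computable and
mutually correlated much as in real series. Each binary outcome then
follows a logistic model `logit(p) = b + β·(level − 1)` in the collapsed
Kawaguchi level, with per-level log odds ratios `effect_log_or` (defaults
between log 1.2 and log 3, directionally matching reported associations)
and the intercept `b` solved by `uniroot` over the realized levels so the
configured marginal prevalence is hit exactly in expectation for any
effect size. Continuous outcomes (operative time, blood loss, stay) are
difficulty-shifted discretised log-normals drawn truncated to the side of
their threshold that the binary flag dictates, so flags and values can
never contradict; severe complications imply a complication, and 90-day
mortality (default prevalence 0) forces Clavien–Dindo 5. One root seed
feeds named sub-streams per variable, so regeneration is byte-identical
and adding a variable does not perturb earlier draws.

What the generator does **not** emulate: joint feature dependence beyond
the difficulty link (e.g. cirrhosis is independent of platelets), any
covariate effect on outcomes other than difficulty, transfer of caseload
over time, and multi-resection procedures (one target per simulated
patient; multi-target scoring is exercised with hand-built fixtures).
Passing tests on synthetic cohorts therefore demonstrate that the
machinery recovers what was injected — not that any particular clinical
association holds in real data.

## Statistical choices

* **Odds ratios.** Each DSS is fitted in its own logistic model on class
  indicators with the lowest collapsed class as reference — matching how
  such comparisons are tabulated — rather than jointly adjusted. Intervals
  are Wald (symmetric on the log scale), and p values are two-sided Wald
  tests. Complete or quasi-separation (a class with zero events) yields a
  finite-iteration estimate with a huge standard error: any coefficient SE
  above 50 on the log-odds scale, or IRLS non-convergence, flags the row
  `converged = FALSE` and suppresses the interval while retaining the
  point estimate and p value. No multiple-testing correction is applied;
  the report metadata says so.
* **IRLS tolerance.** `glm` is run with relative-deviance tolerance 1e-14
  (maxit 200). At looser tolerances the reported standard errors can
  differ from the closed-form 2×2 Wald SE by ~1e-6 relative, which the
  test suite's six-significant-figure agreement with the cross-product
  odds ratio would reject.
* **Trend fits.** `fit_trend_logistic()` codes the collapsed level
  numerically and estimates one odds ratio per level increase — the
  quantity the generator injects, used by the parameter-recovery tests.
* **Concordance.** Spearman's rank correlation with average ranks for
  ties, via `stats::cor`; a score constant across the cohort has no rank
  variance, so its entries are undefined and flagged rather than forced.
* **Forests.** All analysed outcomes are binary, so classification forests
  are used with out-of-bag permutation importance (mean decrease in OOB
  accuracy under per-variable permutation), 500 trees and
  `mtry = floor(sqrt(p))` by default, seeded and single-threaded for
  determinism. Collapsed scores enter as integer ordinals; liver histology
  is indicator-expanded; rankings are sorted by decreasing importance with
  ties broken alphabetically. The settings travel with every result.

## Validation scale

The suite validates marginal calibration on one cohort of 50,000 patients
(3 standard errors), parameter recovery on 20 replicates of 20,000
patients (per-level odds ratio within ±15%), forest rankings on 20
replicates of 5,000 patients, and everything else on cohorts of a few
hundred; these sizes make the Monte-Carlo bands tight enough to be
meaningful while the whole suite completes in a few minutes.

## Limitations

The scoring rules reproduce the published point schemes as written;
ambiguities are resolved by the configurable defaults above, and a
different reading of, say, the Halls 2-point tier changes individual
scores. The synthetic cohorts are scaffolding for verification, not a
claim about any real population, and analyses of them cannot validate the
clinical performance of any DSS. Complication grades arrive pre-graded
(Clavien–Dindo, Satava) — the package does not derive them from clinical
source data.
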