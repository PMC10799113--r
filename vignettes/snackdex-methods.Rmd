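---
title: "Methods: from timed food diaries to snacking phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from timed food diaries to snacking phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snackdex)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data generator does and does not emulate.

## Eating occasions

An *eating occasion* is a maximal chain of logged entries on one
participant-day in which every consecutive pair is separated by at most 30
minutes (`gap_min`, single-linkage chaining). Two readings of a
"30-minute window" rule are possible — anchoring a window at the first
entry, or chaining — and they differ for sequences like 09:00 / 09:25 /
09:50. We chain, because separation "from the preceding and succeeding
occasion" is a symmetric, pairwise notion; the package's oracle tests
verify the partition against an exhaustive transitive-closure clustering.
Two further boundary decisions: a gap of *exactly* 30 minutes merges
(≤ merges, > splits), and occasions never cross midnight, because the diary
is day-indexed; a 23:50/00:10 pair remains two occasions. Both choices are
deterministic and tested, and both are configurable only by changing the
day indexing upstream.

Within an occasion, meal type is resolved by absorption: if any member
carries a main-meal label (breakfast/lunch/dinner), the whole occasion is a
main meal of the label of the highest-energy main-labelled member, ties
going to the earliest member. Mixed-label occasions are common in real
diaries (a dessert logged as "snack" minutes after dinner), and no
published rule exists for multi-main-label occasions, so the energy
tie-break is our choice; it is invariant to entry order.

A snack is an occasion whose resolved type is snack or drink, except a
single drink item at or below 50 kcal (`drink_kcal_max`): low-calorie
coffees and teas would otherwise dominate frequency counts. Alcoholic
beverages are removed *before* occasion construction on free-living days,
so their energy contributes to neither day totals nor snack metrics.

Cleaning thresholds (all strict where stated): quantities > 2000 g
removed; free-living days kept only with totals in 500–5000 kcal (women) /
500–8000 kcal (men); participants kept only with ≥ 2 surviving free-living
days; test-meal days never enter snacking analyses.

## The Snack Diet Index

The SDI is a cohort-relative, food-group-direction score. For each scored
level-3 food group, a participant's share of snack energy from that group
is ranked into `bins` cohort quantile bins (default 5); groups marked
healthful (+1) contribute the bin number, unhealthful (−1) groups the
reversed bin, neutral (0) groups nothing; the component sum is affinely
rescaled to `range` (default 1–11, so the printed scale of a familiar
snack-quality index is reproduced). The aggregation formula itself is our
construction: published snack-quality indices state the direction
assignments but not the binning arithmetic, so we use the standard
plant-based-diet-index pattern (cohort quantiles per component, reverse
scoring, summation) and keep the direction table, bin count, scoring level
and range as configuration. Consequences worth knowing:

* the SDI is **shares-based**: scaling all snack quantities by a constant
  leaves it unchanged;
* it is **cohort-relative**: a participant's score depends on the cohort
  used for binning (pass `participant_ids` to fix the reference cohort);
* ties get average ranks before binning, so the score is deterministic
  under permutation;
* participants with zero snack energy have no defined SDI and are flagged,
  not scored.

A `include_drinks = FALSE` variant scores food-only snacks; both variants
are supported because drink inclusion materially changes NOVA shares
(sugar-sweetened beverages are class 4).

## Timing patterns

Windows are half-open: morning [00:00, 12:00), afternoon [12:00, 18:00),
evening [18:00, 24:00); an occasion belongs to the window of its *start*
time (the end or an energy-weighted midpoint would differ only for
occasions spanning a boundary, which are rare and start-anchored in the
data we emulate). A snacker's pattern is the earliest window holding at
least 50% of snack energy (`threshold`); at-or-above is deliberate, so a
participant at exactly 50% is a window snacker, and ties across windows go
to the earliest window. Grazers are defined purely negatively (no window
reaches the threshold). Late-evening snacking is any snack occasion
starting at or after 21:00 (`cutoff`), strict at the minute.

First-occasion-time matching bins each snacker's mean first-eating-occasion
time at `bin_width` = 30 min and keeps `min(n_late, n_day)` participants
per group per bin by seeded sampling without replacement. The matched
groups have identical bin histograms by construction; the original
analysis states only that matching was done, not how, so the histogram
method was chosen for transparency and testability (a rank test on the
matched groups is non-significant in ≥ 95% of seeded runs, which the test
suite checks).

## Biomarker derivations

iAUC integrates concentration minus the fasting (t = 0) value by exact
trapezoids over [0, horizon] minutes and multiplies by 60 to report
mmol/L·s (mIU/L·s for insulin). The default `clip` policy integrates only
the positive part — the conventional incremental AUC — splitting any
baseline-crossing segment at its root, so the result is exact for
piecewise-linear curves rather than grid-approximate; `net` keeps negative
area. Tests verify both policies against an independent fine-grid numeric
oracle at 10^-6 relative tolerance. Horizons are 120 min
(glucose/insulin) and 360 min (TG, assayed hourly). HOMA-IR uses the
Matthews constant 22.5 with glucose in mmol/L and insulin in mIU/L.
Harris–Benedict uses the classic 1919 coefficients. The FFQ plausibility
filter excludes questionnaires with > 10 unanswered items or energy/BMR
outside 0.52–2.58 (a cohort mean ± 2 SD convention; `ffq_ratio_bounds()`
recomputes the bounds on any cohort). The 10-year ASCVD risk score is an
externally computed input carried through the panel, not re-implemented.

## Association models

All models adjust for age, sex, BMI, physical activity, education and
main-meal quality. Sex and education enter as indicator contrasts and
activity as ordered indicators; the encodings are unstated in the source
analyses, and indicator coding is the least-assumption default. Missing
data are handled complete-case per model with `n` reported per fit, and
rank-deficient designs raise an error naming the collinear columns rather
than silently dropping them. FDR control is Benjamini–Hochberg with one
family per exposure (the outcome panel tested against that exposure).
Plain (non-robust) standard errors are reported, matching the style of the
estimates being emulated.

## Twin-aware microbiome framework

Classification targets come from quartile tails of a continuous trait
(rank-based quartiles; middle half unassigned). Class thresholds are
computed on the full cohort before splitting — a documented leakage trade-off:
computing them per training fold would change the class definition across
iterations, and the threshold uses only the trait, not the features.
Each of `n_iter` = 100 iterations draws an 80/20 split and removes from
*training* any sample whose twin is in *test*; an exhaustive audit across
100 seeds confirms no pair ever straddles. Forests use 200 trees with
ranger defaults otherwise (the emulated analysis states no
hyperparameters). Regression predictions are calibrated by an OLS of
training truth on training predictions, applied to test predictions and
clipped to the training target range. Features are species-level relative
abundances used as-is (no CLR or other transform), matching the stated
input. The aggregate across iterations is the **median** (the mean is a
fraction of a point away in practice; the median is robust to the skewed
per-iteration AUC distribution on 20-sample test folds).

The permutation null for the classifier re-permutes the labels at the
start of *every* iteration (`null_permute = TRUE`). A single fixed
permutation is not a usable null here: when the features carry a strong
low-dimensional signal axis, its chance correlation with one fixed random
labelling (standard error ≈ n^-1/2) shifts every iteration the same way,
and the median AUC can sit far from 0.5 without any true association.

Matched-subset resampling draws equal-sized high/low snack-quality groups,
accepting a subset only if the groups' main-meal-quality scores are not
significantly different (Mann–Whitney p above `p_floor` = 0.05) and the
subset overlaps every previously accepted subset below Jaccard 0.5
(strict). Rejection sampling is budgeted by `max_tries` and returns a
partial collection with a warning when the constraints are infeasible
(for instance when the nuisance score separates the classes completely).

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture. It draws a
cohort whose headline behaviour matches the free-living study conditions
being emulated: 73% female, age 46 ± 12, BMI log-normal around 25.5, 2–4
diary days, breakfast/lunch/dinner at typical clock times, ~2.3 snacks/day
contributing ~24 ± 16% of daily energy (the generator's self-check targets),
a 13/39/31/17% morning/afternoon/evening/grazer mixture, roughly a third
late-evening snackers, about three-quarters of snack energy from
unhealthful (ultra-processed) groups, and a negative frequency–quality
correlation. Grazers are generated as genuinely peakless: their snack
counts are multiples of three cycled evenly across the windows with
low-variance energies, because a "grazer" whose few snacks cluster by
chance is indistinguishable from a window snacker at classification time.

Two design choices matter for interpreting the tests:

* **Planted effects are conditional on realised exposures.** Markers are
  generated *after* the diary pipeline has run, as linear functions of the
  pipeline-derived SDI and late-evening flag (plus age, sex, BMI) with
  Gaussian noise. The planted coefficients (fasting TG −0.02 mmol/L per
  SDI unit, insulin −0.15 mIU/L, hunger −0.52 points, TG 6 h iAUC
  −400 mmol/L·s, late-evening HbA1c +0.08%) are therefore the *true*
  regression coefficients of the fitted models — no errors-in-variables
  attenuation — so confidence-interval coverage is a meaningful check of
  the estimator, and replicate experiments can redraw markers on a fixed
  diary design (`generate_markers()`), which is exactly the
  repeated-sampling experiment for those models.
* **Postprandial curves are piecewise linear** with knots on the sampling
  grid (peak at 60 min returning to baseline by 120 min for glucose and
  insulin; peak at 240 min with partial return for TG), not physiological
  ODEs, so every curve's iAUC has a closed form that is stored in the
  truth record and compared against the trapezoid implementation at 10^-6
  relative tolerance.

The microbiome table is log-normal per species with a twin-shared latent
(mixing weight 0.5 on both the diet latent and the microbiome), a planted
shift of 20 of 300 species proportional to standardised snack quality, and
optionally a shift proportional to main-meal quality — the planted
confound. The confound scenario used by the acceptance checks
(`meal_sdi_cor = 0.6`, `mb_conf_lfc = 1.5`, `mb_lfc = 0.2`) makes the
diet–microbiome signal mostly attributable to overall diet, so
meal-quality matching visibly lowers the classification AUC; with the
weaker default coupling the matched-vs-unmatched difference drowns in
resampling noise, which is itself informative about how strong a confound
must be before matching changes conclusions.

What the generator does **not** emulate: real food vocabularies and
nutrient databases, energy under-reporting, seasonality, work/free-day
structure, midnight-crossing eating, dependence between diary days, and
non-linear marker–exposure relationships. Passing tests therefore
demonstrate that the estimators and pipeline are correct and calibrated
under the stated generative assumptions — not that the emulated cohort's
substantive findings replicate.

## Problem sizes and numerical conventions

The test suite and acceptance checks run at: 800 participants for cohort
descriptives, coverage (200 marker redraws) and FDR calibration (500
null redraws of a 12-outcome panel); 1000 random participant-days against
the occasion oracle; 100 random curves against the fine-grid iAUC oracle;
200 samples × 300 species × 100 iterations for the microbiome classifier;
20 matched and 20 unmatched subsets of 60 + 60 participants for the
confounding comparison. Tolerances: 10^-6 relative for iAUC against its
oracle, 10^-8 for OLS against the normal equations, exact equality for BH
against brute force. Degenerate inputs error early and descriptively:
all-equal traits for class definition, constant vectors for rank
correlation (flagged `NA`, not an error), singleton ANCOVA groups,
missing fasting points, horizons beyond the sampled range.
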