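# snackdex

Snacking behaviour analysis from timed food diaries: eating-occasion
construction, snack quality and timing metrics, postprandial biomarker
derivations, covariate-adjusted association models, and a twin-aware
microbiome classification framework — with a seeded synthetic-cohort
generator so the entire pipeline is testable end to end without access to
managed-access cohort data.

## Who this is for

Nutritional epidemiologists and biostatisticians working with
high-resolution weighed diet logs (app- or diary-based), who need a tested,
reproducible path from raw timed food entries to per-participant snacking
phenotypes and their associations with cardiometabolic markers and gut
microbiome composition.

## What it computes

**Eating occasions.** Logged foods and drinks on a participant-day are
chained into one eating occasion while consecutive entries are ≤ 30 min
apart; a gap > 30 min starts a new occasion. Occasions containing any
main-meal-labelled item take that meal's type (snacks logged with a meal
are absorbed into it); the rest are snacks or drinks. A single drink of
≤ 50 kcal never counts as a snack. Cleaning removes unidentifiable foods,
quantities > 2000 g and alcoholic beverages; days outside sex-specific
energy bounds (500–5000 kcal women, 500–8000 kcal men) and participants
with < 2 surviving free-living days are excluded.

**Snack quality.** Per participant: snack frequency (occasions/day,
grouped 0/1/2/>2), snack share of daily energy (mean of daily
proportions), NOVA class 1–4 energy shares, and a Snack Diet Index (SDI) —
a plant-based-diet-index-style score in which each scored food group's
share of snack energy is ranked into cohort quantile bins (default
quintiles), healthful groups score their bin, unhealthful groups the
reversed bin, and the component sum is rescaled to 1–11 (higher =
healthier). Meal-vs-snack quality discordance is cross-tabulated from the
score halves.

**Timing.** Morning `[00:00–12:00)` / afternoon `[12:00–18:00)` / evening
`[18:00–24:00)` snack-energy shares; a participant is a morning, afternoon
or evening snacker when ≥ 50% of snack energy falls in that window, and a
grazer otherwise; anyone with a snack at or after 21:00 is a late-evening
snacker. Late vs day-time snackers can be matched on first-eating-occasion
time by 30-min-bin subsampling.

**Biomarkers.** Incremental area under the curve (iAUC) above fasting by
exact trapezoids (2 h for glucose/insulin, 6 h for triglycerides;
below-baseline area clipped by default), reported in mmol/L·s; HOMA-IR =
glucose × insulin / 22.5; Harris–Benedict basal metabolic rate; the
FFQ energy/BMR plausibility filter (0.52–2.58, > 10 missing items); hunger
summaries requiring ≥ 7 rated days.

**Associations.** OLS and ANCOVA adjusted for age, sex, BMI, physical
activity, education and main-meal quality; Benjamini–Hochberg FDR per
outcome family; Spearman correlations; top/bottom SDI quintile contrasts
within frequent snackers (≥ 2 snacks/day).

**Microbiome.** Random-forest classification/regression of snacking traits
from species-level relative abundances: 100 bootstrap iterations of an
80/20 split with twin-aware training-set pruning (no twin pair ever
straddles train/test), quartile-tail class definitions, calibrated
regression, and meal-quality-matched subset resampling (Mann–Whitney
balance, pairwise Jaccard < 0.5).

## Worked example

```r
library(snackdex)

cohort <- generate_cohort(cohort_config(n_participants = 800), seed = 1)
prof   <- snack_profiles(occasion_pipeline(cohort$entries, cohort$participants,
                                           cohort$catalog),
                         cohort$catalog, cohort$scoring)

mean(prof$snacks_per_day[prof$is_snacker])   # 2.34 snacks/day in snackers
mean(prof$snack_energy_share)                # 0.234 of daily energy
table(prof$pattern)
#>  morning afternoon   evening    grazer
#>      123       296       208       140
spearman(prof$sdi, prof$nova4_share)$rho     # -0.848: lower SDI, more
                                             # ultra-processed snack energy

panel <- build_marker_panel(cohort$series, cohort$fasting, cohort$hunger)
d <- merge(merge(panel, prof[c("participant_id", "sdi")]), cohort$participants)
fit_linear(d, "fasting_tg", "sdi")
#>      outcome exposure    beta    se p_value  ci_lo  ci_hi   n
#> 1 fasting_tg      sdi -0.0116 0.015   0.442 -0.041 0.0179 695
```

The fitted slope estimates the generator's planted per-SDI-unit fasting-TG
effect (−0.02 mmol/L here); its confidence interval covers the truth at
the nominal rate across replicate marker draws (see the acceptance tests).

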