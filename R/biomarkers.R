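#' Incremental area under a postprandial curve
#'
#' Trapezoidal integral of concentration minus the fasting (t = 0) value
#' over `[0, horizon]` minutes, converted to unit-seconds (x60). The curve
#' is treated as piecewise linear between sampled time points; if the
#' horizon falls between points the curve is interpolated at the horizon.
#' Under the default `clip` policy, segments below baseline contribute
#' nothing (the positive part is integrated exactly, splitting segments at
#' baseline crossings); the `net` policy keeps negative areas.
#'
#' @param time_min Strictly increasing sampling times in minutes, starting
#'   at 0 (the fasting sample).
#' @param conc Concentrations at `time_min` (mmol/L or mIU/L), all
#'   non-negative.
#' @param horizon Integration horizon in minutes (120 for glucose/insulin,
#'   360 for triglycerides); must not exceed the last time point.
#' @param policy `"clip"` (positive incremental area, the conventional
#'   iAUC) or `"net"`.
#' @return iAUC in unit-seconds.
#' @export
iauc <- function(time_min, conc, horizon, policy = c("clip", "net")) {
  policy <- match.arg(policy)
  stopifnot(length(time_min) == length(conc), length(time_min) >= 2)
  if (time_min[1] != 0) stop("series must start at t = 0 (fasting point)")
  if (any(diff(time_min) <= 0)) stop("time points must be strictly increasing")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  if (horizon > time_min[length(time_min)]) {
    stop("horizon beyond the last sampled time point")
  }
  keep <- time_min <= horizon
  t <- time_min[keep]
  y <- conc[keep] - conc[1]
  if (t[length(t)] < horizon) {
    y <- c(y, stats::approx(time_min, conc - conc[1], xout = horizon)$y)
    t <- c(t, horizon)
  }
  area <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    y0 <- y[i]; y1 <- y[i + 1]
    if (policy == "net") {
      area <- area + dt * (y0 + y1) / 2
    } else if (y0 >= 0 && y1 >= 0) {
      area <- area + dt * (y0 + y1) / 2
    } else if (y0 <= 0 && y1 <= 0) {
      # fully below baseline: contributes nothing
    } else {
      # one baseline crossing inside the segment: keep the positive triangle
      tc <- dt * y0 / (y0 - y1)
      area <- area + if (y0 > 0) tc * y0 / 2 else (dt - tc) * y1 / 2
    }
  }
  area * 60
}

#' Homeostatic model assessment of insulin resistance
#'
#' Matthews formula: fasting glucose (mmol/L) times fasting insulin (mIU/L)
#' divided by 22.5.
#'
#' @param fasting_glucose mmol/L, non-negative.
#' @param fasting_insulin mIU/L, non-negative.
#' @return HOMA-IR index (vectorised).
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose < 0, na.rm = TRUE) || any(fasting_insulin < 0, na.rm = TRUE)) {
    stop("fasting values must be non-negative")
  }
  fasting_glucose * fasting_insulin / 22.5
}

#' Basal metabolic rate by the classic Harris-Benedict equations
#'
#' @param sex `"M"` or `"F"` (vectorised).
#' @param weight_kg,height_cm,age_years Positive anthropometrics.
#' @return kcal/day.
#' @export
harris_benedict_bmr <- function(sex, weight_kg, height_cm, age_years) {
  stopifnot(all(sex %in% c("M", "F")))
  if (any(weight_kg <= 0) || any(height_cm <= 0) || any(age_years <= 0)) {
    stop("anthropometrics must be positive")
  }
  ifelse(sex == "M",
         66.473 + 13.7516 * weight_kg + 5.0033 * height_cm - 6.755 * age_years,
         655.0955 + 9.5634 * weight_kg + 1.8496 * height_cm - 4.6756 * age_years)
}

#' Mean hunger rating with a minimum-days rule
#'
#' Mean of all visual-analogue-scale ratings (0--100) for participants with
#' ratings on at least `min_days` distinct days; `NA` otherwise.
#'
#' @param ratings Data.frame `participant_id`, `day_index`, `rating`.
#' @param min_days Minimum distinct rating days (default 7).
#' @return Data.frame `participant_id`, `hunger_mean`, `n_days`.
#' @export
hunger_summary <- function(ratings, min_days = 7) {
  if (any(ratings$rating < 0 | ratings$rating > 100, na.rm = TRUE)) {
    stop("hunger ratings must be on the 0-100 scale")
  }
  n_days <- tapply(ratings$day_index, ratings$participant_id,
                   function(d) length(unique(d)))
  mu <- tapply(ratings$rating, ratings$participant_id, mean)
  ids <- names(mu)
  data.frame(participant_id = ids,
             hunger_mean = ifelse(n_days[ids] >= min_days, as.numeric(mu), NA_real_),
             n_days = as.integer(n_days[ids]),
             stringsAsFactors = FALSE)
}

#' Food-frequency-questionnaire plausibility filter
#'
#' Excludes a questionnaire when more than `max_missing` items are
#' unanswered, or when reported energy over basal metabolic rate falls
#' outside plausibility bounds (default 0.52--2.58, the cohort mean +/- 2 SD
#' convention).
#'
#' @param energy_kcal FFQ-derived energy intake, kcal/day.
#' @param bmr Basal metabolic rate, kcal/day (see
#'   [harris_benedict_bmr()]).
#' @param missing_items Count of unanswered items.
#' @param bounds Lower/upper bounds on energy/BMR.
#' @param max_missing Missing-item cut-off (strictly more excludes).
#' @return Logical: `TRUE` when the questionnaire is plausible (vectorised).
#' @export
ffq_plausibility <- function(energy_kcal, bmr, missing_items = 0,
                             bounds = c(0.52, 2.58), max_missing = 10) {
  stopifnot(all(bmr > 0))
  ratio <- energy_kcal / bmr
  missing_items <= max_missing & ratio >= bounds[1] & ratio <= bounds[2]
}

#' Plausibility bounds from a cohort of energy/BMR ratios
#'
#' Mean +/- 2 SD of the ratio, the convention behind the default bounds of
#' [ffq_plausibility()].
#'
#' @param energy_kcal,bmr Cohort vectors.
#' @return Numeric length-2 bounds.
#' @export
ffq_ratio_bounds <- function(energy_kcal, bmr) {
  r <- energy_kcal / bmr
  mean(r) + c(-2, 2) * stats::sd(r)
}

#' Assemble the cardiometabolic marker panel
#'
#' Computes 2 h iAUCs for glucose and insulin and the 6 h iAUC for
#' triglycerides from a long-format postprandial series, HOMA-IR from the
#' fasting points, and the hunger summary, then joins them onto the fasting
#' panel (which carries the remaining assayed and anthropometric values,
#' including any externally computed risk score, as passthrough inputs).
#'
#' @param series Long data.frame `participant_id`, `analyte`
#'   (`glucose`/`insulin`/`tg`/...), `time_min`, `value`.
#' @param fasting Wide data.frame of fasting/anthropometric markers, one row
#'   per participant.
#' @param hunger Optional hunger ratings (see [hunger_summary()]).
#' @param policy iAUC policy, `"clip"` by default.
#' @return `fasting` augmented with `glucose_2h_iauc`, `insulin_2h_iauc`,
#'   `tg_6h_iauc`, `homa_ir`, and `hunger_mean` when ratings are given.
#' @export
build_marker_panel <- function(series, fasting, hunger = NULL, policy = "clip") {
  one <- function(analyte, horizon) {
    s <- series[series$analyte == analyte, ]
    if (nrow(s) == 0) return(NULL)
    res <- vapply(split(s, s$participant_id), function(d) {
      d <- d[order(d$time_min), ]
      iauc(d$time_min, d$value, horizon, policy)
    }, 0)
    data.frame(participant_id = names(res), value = as.numeric(res),
               stringsAsFactors = FALSE)
  }
  panel <- fasting
  for (spec in list(c("glucose", 120, "glucose_2h_iauc"),
                    c("insulin", 120, "insulin_2h_iauc"),
                    c("tg", 360, "tg_6h_iauc"))) {
    v <- one(spec[1], as.numeric(spec[2]))
    if (!is.null(v)) {
      names(v)[2] <- spec[3]
      panel <- merge(panel, v, by = "participant_id", all.x = TRUE)
    }
  }
  if (all(c("fasting_glucose", "fasting_insulin") %in% names(panel))) {
    panel$homa_ir <- homa_ir(panel$fasting_glucose, panel$fasting_insulin)
  }
  if (!is.null(hunger)) {
    hs <- hunger_summary(hunger)
    panel <- merge(panel, hs[c("participant_id", "hunger_mean")],
                   by = "participant_id", all.x = TRUE)
  }
  panel
}
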