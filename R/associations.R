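.default_covariates <- c("age", "sex", "bmi", "activity_level", "education",
                         "main_meal_quality")

.model_frame <- function(data, outcome, exposure, covariates) {
  cols <- c(outcome, exposure, covariates)
  missing <- setdiff(cols, names(data))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  d <- data[cols]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  # categorical encodings: sex/education as indicator contrasts, activity as
  # ordered indicators; characters become factors
  for (col in covariates) {
    if (is.character(d[[col]]) || is.logical(d[[col]])) d[[col]] <- factor(d[[col]])
  }
  d
}

.check_full_rank <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(co)[is.na(co)], collapse = ", "))
  }
}

#' Covariate-adjusted linear association
#'
#' Ordinary least squares of a continuous outcome on a continuous exposure
#' plus the adjustment set (by default age, sex, BMI, physical activity,
#' education and main-meal quality). Complete cases only; the reported
#' effect is the exposure coefficient with its two-sided p-value.
#'
#' @param data Data.frame holding all variables.
#' @param outcome,exposure Column names.
#' @param covariates Character vector of adjustment columns.
#' @return One-row data.frame: `outcome`, `exposure`, `beta`, `se`,
#'   `p_value`, `ci_lo`, `ci_hi`, `n`.
#' @export
fit_linear <- function(data, outcome, exposure, covariates = .default_covariates) {
  d <- .model_frame(data, outcome, exposure, covariates)
  f <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- stats::lm(f, data = d)
  .check_full_rank(fit)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)[exposure, ]
  data.frame(outcome = outcome, exposure = exposure,
             beta = sm[exposure, 1], se = sm[exposure, 2],
             p_value = sm[exposure, 4],
             ci_lo = ci[1], ci_hi = ci[2], n = nrow(d),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Linear model of the outcome on a categorical exposure plus the adjustment
#' set. The omnibus p comes from the nested-model F test for the group
#' factor; adjusted group means and pairwise contrasts come from estimated
#' marginal means.
#'
#' @param data Data.frame.
#' @param outcome Outcome column.
#' @param group Categorical exposure column (at least 2 groups of at least
#'   2 members each).
#' @param covariates Adjustment columns.
#' @return `list(omnibus_p, f_statistic, means, contrasts, n)`; `means` and
#'   `contrasts` are data.frames from [emmeans::emmeans()].
#' @export
fit_ancova <- function(data, outcome, group, covariates = .default_covariates) {
  d <- .model_frame(data, outcome, group, covariates)
  d[[group]] <- factor(d[[group]])
  sizes <- table(d[[group]])
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  f_full <- stats::reformulate(c(group, covariates), response = outcome)
  fit <- stats::lm(f_full, data = d)
  .check_full_rank(fit)
  fit0 <- stats::lm(stats::reformulate(covariates, response = outcome), data = d)
  an <- stats::anova(fit0, fit)
  em <- emmeans::emmeans(fit, specs = group)
  data.frame_means <- as.data.frame(em)
  contrasts <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  list(omnibus_p = an[2, "Pr(>F)"], f_statistic = an[2, "F"],
       means = data.frame_means, contrasts = contrasts, n = nrow(d))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1, for one family of
#' tests (conventionally, the outcome panel tested against one exposure).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with average-rank ties and an asymptotic two-sided
#' p-value. A constant input yields `NA` with a flag rather than an error.
#'
#' @param x,y Paired numeric vectors, `n >= 3` complete pairs.
#' @return `list(rho, p_value, n, defined)`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x), defined = TRUE)
}

#' Top and bottom score quintiles within frequent snackers
#'
#' Restricts to frequent snackers (at least `min_freq` snacks/day), ranks
#' the score with stable (first-occurrence) tie-breaking, cuts ranks into
#' five equal groups, and returns extreme-quintile membership. These
#' extremes, together with non-snackers, feed [fit_ancova()].
#'
#' @param profiles Snack profile data.frame (needs `participant_id`,
#'   `snacks_per_day`, and the score column).
#' @param score Score column name (e.g. `"sdi"`).
#' @param min_freq Frequent-snacker threshold, snacks/day.
#' @return Data.frame `participant_id`, `quintile` (1..5), `extreme`
#'   (`"Q1"`, `"Q5"` or `NA`), restricted to frequent snackers with a
#'   non-missing score.
#' @export
quintile_extremes <- function(profiles, score = "sdi", min_freq = 2) {
  d <- profiles[!is.na(profiles[[score]]) & profiles$snacks_per_day >= min_freq, ]
  n <- nrow(d)
  if (n < 5) stop("need at least 5 frequent snackers for quintiles")
  r <- rank(d[[score]], ties.method = "first")
  q <- ceiling(5 * r / n)
  data.frame(participant_id = d$participant_id, quintile = q,
             extreme = ifelse(q == 1, "Q1", ifelse(q == 5, "Q5", NA_character_)),
             stringsAsFactors = FALSE)
}

#' Fit one exposure against an outcome panel with FDR control
#'
#' Runs [fit_linear()] for each outcome and adjusts the p-values as one
#' Benjamini-Hochberg family.
#'
#' @param data Data.frame.
#' @param outcomes Character vector of outcome columns.
#' @param exposure Exposure column.
#' @param covariates Adjustment columns.
#' @return Data.frame of per-outcome results with `fdr_adjusted_p`.
#' @export
association_panel <- function(data, outcomes, exposure,
                              covariates = .default_covariates) {
  res <- do.call(rbind, lapply(outcomes, function(o) {
    fit_linear(data, o, exposure, covariates)
  }))
  res$fdr_adjusted_p <- bh_fdr(res$p_value)
  res
}
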