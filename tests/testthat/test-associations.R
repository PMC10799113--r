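sim_frame <- function(n, beta = 0, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    exposure = rnorm(n), age = rnorm(n, 45, 10),
    sex = sample(c("F", "M"), n, replace = TRUE), bmi = rnorm(n, 25, 4),
    activity_level = sample(c("<1/week", "1-4/week", ">=5/week"), n, TRUE),
    education = sample(1:5, n, TRUE), main_meal_quality = rnorm(n, 55, 8)
  )
  d$outcome <- 1 + beta * d$exposure + 0.02 * d$age + 0.1 * (d$sex == "M") + rnorm(n)
  d
}

test_that("fit_linear equals the closed-form OLS oracle on small instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:20, 1)
    d <- data.frame(outcome = rnorm(n), exposure = rnorm(n), age = rnorm(n),
                    bmi = rnorm(n))
    res <- fit_linear(d, "outcome", "exposure", c("age", "bmi"))
    X <- cbind(1, d$exposure, d$age, d$bmi)
    expect_equal(res$beta, oracle_ols(X, d$outcome)[2, 1], tolerance = 1e-8)
    expect_equal(res$n, n)
  }
})

test_that("fit_linear is calibrated under the null and recovers a planted slope", {
  hits <- 0
  for (s in 1:200) {
    d <- sim_frame(500, beta = 0, seed = s)
    r <- fit_linear(d, "outcome", "exposure",
                    c("age", "sex", "bmi", "activity_level", "education",
                      "main_meal_quality"))
    if (abs(r$beta) < 2 * r$se) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.93)
  d <- sim_frame(5000, beta = -0.02, seed = 77)
  r <- fit_linear(d, "outcome", "exposure", c("age", "sex", "bmi"))
  expect_lt(r$ci_lo, -0.02 + 1e-12)
  expect_gt(r$ci_hi, -0.02 - 1e-12)
})

test_that("a duplicated exposure raises a rank-deficiency error naming the term", {
  d <- sim_frame(100)
  d$copy <- d$exposure
  expect_error(fit_linear(d, "outcome", "exposure", c("age", "copy")),
               "rank-deficient.*copy")
})

test_that("two-group ANCOVA reduces to the covariate-adjusted t-test (F = t^2)", {
  d <- sim_frame(80, seed = 5)
  d$grp <- rep(c("a", "b"), 40)
  res <- fit_ancova(d, "outcome", "grp", c("age", "bmi"))
  fit <- stats::lm(outcome ~ grp + age + bmi, data = d)
  tval <- summary(fit)$coefficients["grpb", 3]
  expect_equal(res$f_statistic, tval^2, tolerance = 1e-8)
  expect_equal(nrow(res$means), 2)
  expect_equal(nrow(res$contrasts), 1)
  d$solo <- c("x", rep("y", 79))
  expect_error(fit_ancova(d, "outcome", "solo", c("age")), "singleton")
})

test_that("ANCOVA omnibus p is uniform under identical group distributions", {
  set.seed(12)
  ps <- replicate(400, {
    d <- data.frame(outcome = rnorm(60), grp = sample(rep(c("a", "b", "c"), 20)),
                    age = rnorm(60))
    fit_ancova(d, "outcome", "grp", "age")$omnibus_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:10, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    # order preservation on the sorted input
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("spearman handles perfect association, ties and constants", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  xt <- c(1, 2, 2, 3); yt <- c(1, 3, 2, 4)
  got <- spearman(xt, yt)
  # exhaustive average-rank computation
  expect_equal(got$rho, stats::cor(rank(xt), rank(yt)))
  cst <- spearman(rep(1, 10), rnorm(10))
  expect_false(cst$defined)
  expect_true(is.na(cst$rho))
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("quintile extremes are formed within frequent snackers only", {
  prof <- data.frame(participant_id = sprintf("P%02d", 1:14),
                     snacks_per_day = c(rep(2.5, 10), rep(0.5, 4)),
                     sdi = c(1:10, 11, 12, 13, 14))
  q <- quintile_extremes(prof, "sdi", min_freq = 2)
  expect_equal(nrow(q), 10)
  expect_equal(sum(q$extreme == "Q1", na.rm = TRUE), 2)
  expect_equal(sum(q$extreme == "Q5", na.rm = TRUE), 2)
  expect_false(any(prof$participant_id[prof$snacks_per_day < 2] %in% q$participant_id))
  # all-tied scores still give equal-sized groups via stable ranks
  prof$sdi <- 5
  q2 <- quintile_extremes(prof, "sdi", min_freq = 2)
  expect_equal(as.vector(table(q2$quintile)), rep(2, 5))
  expect_error(quintile_extremes(prof[1:4, ], "sdi"), "at least 5")
})

test_that("association_panel adjusts p-values as one BH family", {
  d <- sim_frame(300, beta = 0.5, seed = 3)
  d$out2 <- rnorm(300)
  res <- association_panel(d, c("outcome", "out2"), "exposure", c("age", "bmi"))
  expect_equal(res$fdr_adjusted_p, bh_fdr(res$p_value))
  expect_true(all(res$fdr_adjusted_p >= res$p_value))
})
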