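test_that("snack frequency averages over included days and bins by rounded mean", {
  co <- tiny_catalog()
  # P1: 3 snacks day 1, 1 snack day 2 -> 2.0/day, group "2"
  e <- rbind(
    mk_entries("P1", 1, c(480, 600, 840, 1020), c("N1", "H1", "U1", "H1"),
               c(800, 100, 150, 100), c("breakfast", "snack", "snack", "snack")),
    mk_entries("P1", 2, c(480, 840), c("N1", "U1"), c(800, 150),
               c("breakfast", "snack")),
    # P2: no snacks at all
    mk_entries("P2", 1, 480, "N1", 800, "breakfast"),
    mk_entries("P2", 2, 480, "N1", 800, "breakfast"),
    # P3: 3 and 3 snacks -> ">2"
    mk_entries("P3", 1, c(480, 600, 840, 1020), c("N1", "H1", "U1", "H1"),
               c(800, 100, 150, 100), c("breakfast", "snack", "snack", "snack")),
    mk_entries("P3", 2, c(480, 600, 840, 1020), c("N1", "H1", "U1", "H1"),
               c(800, 100, 150, 100), c("breakfast", "snack", "snack", "snack"))
  )
  pl <- occasion_pipeline(e, mk_participants(c("P1", "P2", "P3")), co)
  fr <- snack_frequency(pl$occasions, pl$days)
  expect_equal(fr$snacks_per_day[fr$participant_id == "P1"], 2.0)
  expect_equal(as.character(fr$frequency_group[fr$participant_id == "P1"]), "2")
  expect_equal(fr$snacks_per_day[fr$participant_id == "P2"], 0)
  expect_false(fr$is_snacker[fr$participant_id == "P2"])
  expect_equal(fr$snacks_per_day[fr$participant_id == "P3"], 3.0)
  expect_equal(as.character(fr$frequency_group[fr$participant_id == "P3"]), ">2")
})

test_that("snack energy share is the mean of daily proportions", {
  co <- tiny_catalog()
  # day 1: 2000 kcal total, 500 from snacks (0.25); day 2: 0.20 vs 0.30 design
  e <- rbind(
    mk_entries("P1", 1, c(480, 840), c("N1", "U1"), c(1500, 500),
               c("breakfast", "snack")),
    mk_entries("P1", 2, c(480, 840), c("N1", "U1"), c(1600, 400),
               c("breakfast", "snack")),
    mk_entries("P2", 2, c(480, 840), c("N1", "U1"), c(1400, 600),
               c("breakfast", "snack")),
    mk_entries("P2", 3, c(480, 840), c("N1", "U1"), c(1600, 400),
               c("breakfast", "snack"))
  )
  pl <- occasion_pipeline(e, mk_participants(c("P1", "P2")), co)
  sh <- snack_energy_share(pl$occasions, pl$days)
  expect_equal(sh$snack_energy_share[sh$participant_id == "P1"], mean(c(0.25, 0.20)))
  # day proportions 0.30 and 0.20 average to 0.25 (not pooled kcal)
  expect_equal(sh$snack_energy_share[sh$participant_id == "P2"], 0.25)
})

test_that("SDI matches a hand-ranked two-bin oracle and preserves order", {
  # snack-energy shares: H / U / neutral
  # A (80,10,10), B (50,20,30), C (30,30,40), D (10,60,30)
  pl <- toy_quality_cohort(h = c(80, 50, 30, 10), u = c(10, 20, 30, 60),
                           n = c(10, 30, 40, 30))
  tab <- scoring_table(c(fruit = 1, chocolate = -1, cheese = 0, coffee = 0,
                         smoothie = 0, beer = 0), bins = 2, range = c(1, 11))
  sdi <- compute_sdi(pl$occasions, pl$entries, tiny_catalog(), tab)
  # hand oracle over the two scored groups:
  # H shares .8,.5,.3,.1 -> ranks D1 C2 B3 A4 -> bins 1,1,2,2
  # U shares .1,.2,.3,.6 -> ranks A1 B2 C3 D4 -> bins 1,1,2,2 -> reversed 2,2,1,1
  # sums A4 B4 C2 D2; rescale [2,4] -> [1,11]: A 11, B 11, C 1, D 1
  got <- sdi$sdi[match(c("Q1", "Q2", "Q3", "Q4"), sdi$participant_id)]
  expect_equal(got, c(11, 11, 1, 1))
  # with quartile bins the four sums separate completely and preserve order
  tab4 <- scoring_table(c(fruit = 1, chocolate = -1, cheese = 0, coffee = 0,
                          smoothie = 0, beer = 0), bins = 4, range = c(1, 11))
  sdi4 <- compute_sdi(pl$occasions, pl$entries, tiny_catalog(), tab4)
  expect_equal(order(-sdi4$sdi[match(sprintf("Q%d", 1:4), sdi4$participant_id)]),
               1:4)
})

test_that("SDI is invariant to scaling snack energy and monotone in unhealthful share", {
  base <- toy_quality_cohort(h = c(80, 50, 30, 10), u = c(10, 20, 30, 60),
                             n = c(10, 30, 40, 30))
  scaled <- toy_quality_cohort(h = c(80, 50, 30, 10), u = c(10, 20, 30, 60),
                               n = c(10, 30, 40, 30), scale = 3)
  tab <- catalog_scoring_table(tiny_catalog(), bins = 2, range = c(1, 11))
  s1 <- compute_sdi(base$occasions, base$entries, tiny_catalog(), tab)
  s2 <- compute_sdi(scaled$occasions, scaled$entries, tiny_catalog(), tab)
  expect_equal(s1$sdi, s2$sdi)
  # raising B's unhealthful share (others rescaled) never raises B's SDI
  tab4 <- catalog_scoring_table(tiny_catalog(), bins = 4, range = c(1, 11))
  for (extra in c(10, 25, 45)) {
    worse <- toy_quality_cohort(h = c(80, 50 - extra * 5 / 8, 30, 10),
                                u = c(10, 20 + extra, 30, 60),
                                n = c(10, 30 - extra * 3 / 8, 40, 30))
    sw <- compute_sdi(worse$occasions, worse$entries, tiny_catalog(), tab4)
    s0 <- compute_sdi(base$occasions, base$entries, tiny_catalog(), tab4)
    expect_lte(sw$sdi[sw$participant_id == "Q2"], s0$sdi[s0$participant_id == "Q2"])
  }
})

test_that("mirrored participants get mirrored SDI under a symmetric two-group table", {
  pl <- toy_quality_cohort(h = c(70, 30, 55, 45), u = c(30, 70, 45, 55),
                           n = c(0, 0, 0, 0))
  tab <- scoring_table(c(fruit = 1, chocolate = -1, cheese = 0, coffee = 0,
                         smoothie = 0, beer = 0), bins = 2, range = c(1, 11))
  sdi <- compute_sdi(pl$occasions, pl$entries, tiny_catalog(), tab)
  s <- sdi$sdi[match(sprintf("Q%d", 1:4), sdi$participant_id)]
  expect_equal(s[1] + s[2], 12)  # lo + hi of the 1-11 range
  expect_equal(s[3] + s[4], 12)
})

test_that("NOVA shares are energy-weighted and sum to one across classes", {
  pl <- toy_quality_cohort(h = c(300, 50), u = c(300, 500), n = c(0, 0))
  nv <- nova_shares(pl$occasions, pl$entries, tiny_catalog())
  # Q1: 300 kcal NOVA-1 (apple) + 300 kcal NOVA-4 (chocolate) -> 0.5 each
  q1 <- nv[nv$participant_id == "Q1", ]
  expect_equal(q1$nova1_share, 0.5)
  expect_equal(q1$nova4_share, 0.5)
  sums <- rowSums(nv[paste0("nova", 1:4, "_share")])
  expect_equal(sums, rep(1, nrow(nv)), ignore_attr = TRUE)
  # all-ultra-processed snacker
  pl2 <- toy_quality_cohort(h = c(0.0001, 50), u = c(200, 100), n = c(0, 0))
  nv2 <- nova_shares(pl2$occasions, pl2$entries, tiny_catalog())
  expect_gt(nv2$nova4_share[nv2$participant_id == "Q1"], 0.999)
})

test_that("SDI anticorrelates with ultra-processed snack share on the synthetic cohort", {
  prof <- shared_cohort()$derived$profiles
  ok <- !is.na(prof$sdi)
  r4 <- spearman(prof$sdi[ok], prof$nova4_share[ok])
  r1 <- spearman(prof$sdi[ok], prof$nova1_share[ok])
  expect_lt(r4$rho, 0)
  expect_gt(r1$rho, 0)
  expect_lt(r4$p_value, 0.001)
})

test_that("popular snack groups respect the event threshold and hand-summed energy", {
  co <- tiny_catalog()
  # fruit: 3 snack events; chocolate: 2 events -> threshold 3 keeps fruit only
  e <- rbind(
    mk_entries("P1", 1, c(480, 600, 840), c("N1", "H1", "U1"), c(1000, 100, 100),
               c("breakfast", "snack", "snack")),
    mk_entries("P1", 2, c(480, 600), c("N1", "H1"), c(1000, 100),
               c("breakfast", "snack")),
    mk_entries("P2", 1, c(480, 600, 840), c("N1", "H1", "U1"), c(1000, 200, 100),
               c("breakfast", "snack", "snack"))
  )
  pl <- occasion_pipeline(e, mk_participants(c("P1", "P2")), co)
  top <- popular_snacks(pl$occasions, pl$entries, co, pl$days, min_events = 3)
  expect_equal(top$group, "fruit")
  expect_equal(top$n_events, 3L)
  # P1: fruit 100/day over 2 days, daily mean (1200 + 1100)/2; P2: 200/1300
  p1 <- (100 + 100) / 2 / mean(c(1200, 1100))
  p2 <- 200 / 1300
  expect_equal(top$pct_daily_energy, 100 * mean(c(p1, p2)))
  expect_equal(nrow(popular_snacks(pl$occasions, pl$entries, co, pl$days,
                                   min_events = 4)), 0)
})

test_that("discordance is 0 for identical, 1 for anti-ranked, ~0.5 for independent scores", {
  x <- c(5, 3, 8, 1, 9, 2)
  expect_equal(discordance(x, x)$discordant_fraction, 0)
  expect_equal(discordance(x, -x)$discordant_fraction, 1)
  set.seed(99)
  d <- discordance(runif(10000), runif(10000))
  expect_lt(abs(d$discordant_fraction - 0.5), 0.02)
  expect_equal(sum(d$quadrants), 10000)
})
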