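build1 <- function(times, labels = "snack", kcal = 100, food = "H1") {
  e <- mk_entries("P1", 1, times, food, kcal, labels)
  build_occasions(e, tiny_catalog())
}

test_that("the 30-min chaining rule splits and merges as specified", {
  # 09:00, 09:10, 09:50 -> {09:00, 09:10} and {09:50} (40-min gap splits)
  b <- build1(c(540, 550, 590))
  expect_equal(nrow(b$occasions), 2)
  expect_equal(b$occasions$start_time, c(540, 590))
  expect_equal(b$occasions$n_entries, c(2L, 1L))
  # chained 29-min gaps stay one occasion
  b2 <- build1(c(540, 569, 598))
  expect_equal(nrow(b2$occasions), 1)
  # a gap of exactly 30 minutes merges; 31 splits
  expect_equal(nrow(build1(c(540, 570))$occasions), 1)
  expect_equal(nrow(build1(c(540, 571))$occasions), 2)
  # single entry is its own occasion
  b3 <- build1(600)
  expect_equal(b3$occasions$start_time, 600)
  expect_equal(b3$occasions$energy_kcal, 100)
  # empty input -> empty output
  expect_equal(nrow(build_occasions(mk_entries("P1", 1, numeric(0), "H1", 100, "snack")[0, ],
                                    tiny_catalog())$occasions), 0)
})

test_that("meal-type resolution absorbs snacks and breaks ties by energy then time", {
  m <- mk_entries("P1", 1, c(540, 550), "H1", c(300, 80), c("breakfast", "snack"))
  expect_equal(resolve_meal_type(m), "breakfast")
  m2 <- mk_entries("P1", 1, c(540, 550), "H1", c(80, 80), c("snack", "snack"))
  expect_equal(resolve_meal_type(m2), "snack")
  m3 <- mk_entries("P1", 1, c(720, 730), "H1", c(300, 500), c("lunch", "dinner"))
  expect_equal(resolve_meal_type(m3), "dinner")
  # energy tie between main labels -> earliest member
  m4 <- mk_entries("P1", 1, c(720, 730), "H1", c(400, 400), c("dinner", "lunch"))
  expect_equal(resolve_meal_type(m4), "dinner")
  m5 <- mk_entries("P1", 1, c(600, 610), "D1", c(5, 5), c("drink", "drink"))
  expect_equal(resolve_meal_type(m5), "drink")
})

test_that("snack identification applies the 50 kcal single-drink rule", {
  co <- tiny_catalog()
  # single coffee at 40 kcal is not a snack; at exactly 50 kcal still not
  for (k in c(40, 50)) {
    b <- build_occasions(mk_entries("P1", 1, 960, "D1", k, "drink"), co)
    expect_false(b$occasions$is_snack)
  }
  # 120 kcal smoothie labelled snack is a snack (passes the rule)
  b <- build_occasions(mk_entries("P1", 1, 960, "D2", 120, "snack"), co)
  expect_true(b$occasions$is_snack)
  # 80 kcal apple snack is a snack; a meal never is
  b2 <- build_occasions(mk_entries("P1", 1, c(600, 960), "H1", 80,
                                   c("breakfast", "snack")), co)
  expect_equal(b2$occasions$is_snack, c(FALSE, TRUE))
  # a multi-item occasion containing a low-calorie drink is still a snack
  e <- mk_entries("P1", 1, c(960, 970), c("H1", "D1"), c(80, 4), "snack")
  b3 <- build_occasions(e, co)
  expect_true(b3$occasions$is_snack)
})

test_that("entry filters remove implausible quantities, alcohol and unidentifiable foods", {
  co <- tiny_catalog()
  e <- mk_entries("P1", 1, c(540, 600, 660, 720), c("H1", "H1", "A1", "H1"),
                  100, "snack")
  e$quantity_g <- c(2500, 2000, 300, 100)
  e$unidentifiable <- c(FALSE, FALSE, FALSE, TRUE)
  out <- apply_entry_filters(e, co)
  expect_equal(out$entries$clock_time, 600)   # exactly 2000 g kept
  expect_setequal(out$log$reason, c("implausible quantity", "alcohol", "unidentifiable food"))
  # alcohol is kept on test-meal days (exclusion list applies to free-living)
  e2 <- mk_entries("P1", 1, 660, "A1", 100, "drink", day_type = "test")
  expect_equal(nrow(apply_entry_filters(e2, co)$entries), 1)
})

test_that("day and participant inclusion use sex-specific energy bounds", {
  parts <- mk_participants(c("PF", "PM"), sex = c("F", "M"))
  days <- data.frame(
    participant_id = c("PF", "PF", "PM", "PM", "PM"),
    day_index = c(1, 2, 1, 2, 3),
    day_type = c("free_living", "free_living", "free_living", "free_living", "test"),
    total_kcal = c(450, 2000, 7000, 2500, 3000),
    stringsAsFactors = FALSE
  )
  out <- apply_day_and_participant_filters(days, parts)
  expect_false(out$days$included[1])                    # female 450 kcal
  expect_match(out$days$exclusion_reason[1], "cut-offs")
  expect_true(out$days$included[3])                     # male 7000 kcal
  expect_false(out$days$included[5])                    # test day
  # PF has 1 surviving day -> excluded; PM has 2 -> included
  expect_equal(out$participants$included[match(c("PF", "PM"), out$participants$participant_id)],
               c(FALSE, TRUE))
})

test_that("occasion partition matches the exhaustive oracle and is order-invariant", {
  set.seed(31)
  co <- tiny_catalog()
  for (rep in 1:40) {
    n <- sample(1:12, 1)
    times <- sort(sample(300:1380, n))
    e <- mk_entries("P1", 1, times, "H1", 100, "snack")
    b <- build_occasions(e, co)
    impl <- b$entries$occasion_id[order(b$entries$clock_time)]
    impl <- match(impl, unique(impl))
    expect_equal(impl, oracle_gap_clusters(times))
    # permutation invariance
    sh <- e[sample(n), , drop = FALSE]
    b2 <- build_occasions(sh, co)
    impl2 <- b2$entries$occasion_id[order(b2$entries$clock_time)]
    expect_equal(match(impl2, unique(impl2)), impl)
  }
})

test_that("occasion totals conserve entry energy and rebuilding is idempotent", {
  cohort <- shared_cohort()
  pl <- cohort$derived$pipeline
  expect_equal(sum(pl$occasions$energy_kcal), sum(pl$entries$energy_kcal))
  # per-day conservation
  occ_day <- rowsum(pl$occasions$energy_kcal,
                    paste(pl$occasions$participant_id, pl$occasions$day_index))
  ent_day <- rowsum(pl$entries$energy_kcal,
                    paste(pl$entries$participant_id, pl$entries$day_index))
  expect_equal(occ_day[order(rownames(occ_day)), 1], ent_day[order(rownames(ent_day)), 1])
  # idempotence: occasions rebuilt from one occasion's members stay whole
  some <- sample(unique(pl$entries$occasion_id), 50)
  for (oid in some) {
    sub <- pl$entries[pl$entries$occasion_id == oid, ]
    expect_equal(nrow(build_occasions(sub, cohort$catalog)$occasions), 1)
  }
})
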