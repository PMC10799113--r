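# Shared synthetic cohorts, generated once per test run.
.cohort_cache <- new.env()

shared_cohort <- function() {
  if (is.null(.cohort_cache$main)) {
    .cohort_cache$main <- generate_cohort(cohort_config(n_participants = 800), seed = 1042)
  }
  .cohort_cache$main
}

# A minimal hand catalog: one healthful, one unhealthful, one neutral food,
# a low-calorie drink, a caloric drink and a beer.
tiny_catalog <- function() {
  data.frame(
    food_id = c("H1", "U1", "N1", "D1", "D2", "A1"),
    name = c("apple", "choc bar", "cheese", "coffee", "smoothie", "beer"),
    group_l1 = c("Fruit", "Conf", "Dairy", "Bev", "Bev", "Alc"),
    group_l2 = c("Fruit", "Conf", "Cheese", "Hot", "Smoothie", "Beer"),
    group_l3 = c("fruit", "chocolate", "cheese", "coffee", "smoothie", "beer"),
    nova_class = c(1, 4, 3, 1, 1, 3),
    healthful_direction = c(1, -1, 0, 0, 1, 0),
    is_drink = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    is_alcohol = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    energy_per_100g = c(52, 535, 403, 2, 60, 43),
    carb_g = c(12, 59, 1.3, 0.2, 14, 3.6),
    fat_g = c(0.2, 30, 33, 0, 0.2, 0),
    protein_g = c(0.3, 7.7, 25, 0.1, 0.6, 0.5),
    sugar_g = c(10, 52, 0.5, 0, 12, 0),
    stringsAsFactors = FALSE
  )
}

# Build a diary-entry data.frame from (participant, day, time, food, kcal,
# label) vectors with sensible defaults for the remaining fields.
mk_entries <- function(pid, day, time, food, kcal, label,
                       day_type = "free_living", qty = 100) {
  n <- length(time)
  data.frame(
    participant_id = rep_len(pid, n), day_index = rep_len(day, n),
    clock_time = time, food_id = rep_len(food, n),
    quantity_g = rep_len(qty, n), energy_kcal = rep_len(kcal, n),
    carb_g = rep_len(0, n), fat_g = rep_len(0, n),
    protein_g = rep_len(0, n), sugar_g = rep_len(0, n),
    reported_meal_label = rep_len(label, n),
    day_type = rep_len(day_type, n), stringsAsFactors = FALSE
  )
}

mk_participants <- function(ids, sex = "F") {
  n <- length(ids)
  data.frame(
    participant_id = ids, age = 40, sex = rep_len(sex, n), bmi = 24,
    education = 3, activity_level = "1-4/week", twin_pair_id = NA_character_,
    main_meal_quality = 55, stringsAsFactors = FALSE
  )
}

# A small cohort over the tiny catalog with controlled per-participant
# snack-energy splits across the healthful (H1) / unhealthful (U1) /
# neutral (N1) groups; used by the hand-computed SDI oracles.
toy_quality_cohort <- function(h, u, n, scale = 1) {
  ids <- sprintf("Q%d", seq_along(h))
  e <- do.call(rbind, lapply(seq_along(h), function(i) {
    mk_entries(ids[i], 1,
               c(480, 600, 840, 1020, 1140),
               c("N1", "H1", "U1", "N1", "N1"),
               c(600, h[i] * scale, u[i] * scale, n[i] * scale, 700),
               c("breakfast", "snack", "snack", "snack", "dinner"))
  }))
  occasion_pipeline(e, mk_participants(ids), tiny_catalog())
}
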