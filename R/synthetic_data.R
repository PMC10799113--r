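#' Synthetic food catalog
#'
#' A compact catalog emulating the structure real diet databases provide: a
#' three-level food-group tree, NOVA classes, healthfulness directions for
#' the snack index (healthful groups are minimally processed, unhealthful
#' groups ultra-processed, mirroring how the two taxonomies align in
#' practice), drink/alcohol flags and energy densities per 100 g.
#'
#' @return A validated catalog data.frame.
#' @export
synthetic_catalog <- function() {
  row <- function(id, name, l1, l2, l3, nova, dir, drink, alc, kcal,
                  carb, fat, prot, sugar) {
    data.frame(food_id = id, name = name, group_l1 = l1, group_l2 = l2,
               group_l3 = l3, nova_class = nova, healthful_direction = dir,
               is_drink = drink, is_alcohol = alc, energy_per_100g = kcal,
               carb_g = carb, fat_g = fat, protein_g = prot, sugar_g = sugar,
               stringsAsFactors = FALSE)
  }
  cat_df <- rbind(
    # healthful snack groups (+1)
    row("FR01", "apple", "Fruit & vegetables", "Fruit", "fresh_fruit", 1, 1, FALSE, FALSE, 52, 12, 0.2, 0.3, 10),
    row("FR02", "banana", "Fruit & vegetables", "Fruit", "fresh_fruit", 1, 1, FALSE, FALSE, 89, 23, 0.3, 1.1, 12),
    row("VG01", "carrot sticks", "Fruit & vegetables", "Vegetables", "raw_vegetables", 1, 1, FALSE, FALSE, 41, 10, 0.2, 0.9, 4.7),
    row("NT01", "almonds", "Protein foods", "Nuts & seeds", "nuts_seeds", 1, 1, FALSE, FALSE, 579, 22, 50, 21, 4.4),
    row("NT02", "mixed nuts", "Protein foods", "Nuts & seeds", "nuts_seeds", 1, 1, FALSE, FALSE, 607, 21, 54, 20, 4.3),
    row("DY01", "plain yogurt", "Dairy", "Yogurt", "plain_yogurt", 1, 1, FALSE, FALSE, 61, 4.7, 3.3, 3.5, 4.7),
    row("BV04", "fruit smoothie", "Beverages", "Juices & smoothies", "smoothies", 1, 1, TRUE, FALSE, 60, 14, 0.2, 0.6, 12),
    # unhealthful snack groups (-1), ultra-processed
    row("CF01", "milk chocolate bar", "Snacks & confectionery", "Confectionery", "chocolate", 4, -1, FALSE, FALSE, 535, 59, 30, 7.7, 52),
    row("CF02", "gummy sweets", "Snacks & confectionery", "Confectionery", "sweets_candy", 4, -1, FALSE, FALSE, 340, 77, 0.2, 6.9, 46),
    row("BK01", "chocolate biscuit", "Snacks & confectionery", "Biscuits & cakes", "biscuits_cakes", 4, -1, FALSE, FALSE, 480, 64, 24, 5.6, 35),
    row("BK02", "blueberry muffin", "Snacks & confectionery", "Biscuits & cakes", "biscuits_cakes", 4, -1, FALSE, FALSE, 380, 50, 17, 5.2, 28),
    row("CR01", "salted crisps", "Snacks & confectionery", "Savoury snacks", "crisps_savoury", 4, -1, FALSE, FALSE, 536, 50, 34, 6.6, 0.6),
    row("BV01", "cola", "Beverages", "Soft drinks", "sugar_sweetened_beverages", 4, -1, TRUE, FALSE, 42, 10.6, 0, 0, 10.6),
    # neutral (0)
    row("DY02", "cheddar cheese", "Dairy", "Cheese", "cheese", 3, 0, FALSE, FALSE, 403, 1.3, 33, 25, 0.5),
    row("BV02", "black coffee", "Beverages", "Hot drinks", "coffee_tea", 1, 0, TRUE, FALSE, 2, 0.2, 0, 0.1, 0),
    row("BV03", "tea with milk", "Beverages", "Hot drinks", "coffee_tea", 1, 0, TRUE, FALSE, 8, 0.8, 0.4, 0.4, 0.8),
    # main-meal foods (neutral for the snack index)
    row("GR01", "porridge oats", "Grains & starches", "Breakfast cereals", "porridge_oats", 1, 0, FALSE, FALSE, 379, 60, 8, 11, 1.1),
    row("GR02", "cornflakes", "Grains & starches", "Breakfast cereals", "breakfast_cereal", 4, 0, FALSE, FALSE, 370, 84, 0.9, 7.5, 8),
    row("GR03", "wholemeal bread", "Grains & starches", "Bread", "bread_rolls", 3, 0, FALSE, FALSE, 265, 42, 3.5, 12, 3.8),
    row("GR04", "white rice", "Grains & starches", "Rice & pasta", "rice_pasta", 1, 0, FALSE, FALSE, 130, 28, 0.3, 2.7, 0.1),
    row("GR05", "pasta bake", "Grains & starches", "Rice & pasta", "rice_pasta", 3, 0, FALSE, FALSE, 160, 22, 5, 6.5, 3),
    row("PR01", "boiled eggs", "Protein foods", "Eggs", "egg_dishes", 1, 0, FALSE, FALSE, 155, 1.1, 11, 13, 1.1),
    row("PR02", "roast chicken", "Protein foods", "Poultry", "chicken_dishes", 1, 0, FALSE, FALSE, 190, 0, 7.4, 29, 0),
    row("PR03", "baked salmon", "Protein foods", "Fish", "fish_dishes", 1, 0, FALSE, FALSE, 206, 0, 12, 22, 0),
    row("VG02", "steamed vegetables", "Fruit & vegetables", "Vegetables", "cooked_vegetables", 1, 0, FALSE, FALSE, 80, 13, 1.5, 3.5, 5),
    row("VG03", "jacket potato", "Fruit & vegetables", "Potatoes", "potato_dishes", 1, 0, FALSE, FALSE, 93, 21, 0.1, 2.5, 1.2),
    row("RM01", "lasagne ready meal", "Grains & starches", "Ready meals", "ready_meals", 4, 0, FALSE, FALSE, 150, 15, 6, 8, 4),
    row("DY03", "semi-skimmed milk", "Dairy", "Milk", "milk", 1, 0, TRUE, FALSE, 50, 4.8, 1.8, 3.6, 4.8),
    row("DY04", "butter", "Dairy", "Fats & spreads", "butter_spreads", 2, 0, FALSE, FALSE, 717, 0.6, 81, 0.9, 0.6),
    row("BV05", "orange juice", "Beverages", "Juices & smoothies", "fruit_juice", 3, 0, TRUE, FALSE, 45, 10.4, 0.1, 0.7, 8.4),
    # alcohol (excluded upstream of snack analysis)
    row("AL01", "lager", "Alcohol", "Beer", "beer", 3, 0, TRUE, TRUE, 43, 3.6, 0, 0.5, 0),
    row("AL02", "red wine", "Alcohol", "Wine", "wine", 3, 0, TRUE, TRUE, 83, 2.6, 0, 0.1, 0.6)
  )
  validate_catalog(cat_df)
  cat_df
}

#' Scoring table derived from a catalog
#'
#' Uses the catalog's per-group healthfulness direction at the chosen group
#' level (directions must be consistent within a group).
#'
#' @param catalog Food catalog.
#' @param bins,range,level See [scoring_table()].
#' @return A `scoring_table`.
#' @export
catalog_scoring_table <- function(catalog, bins = 5, range = c(1, 11),
                                  level = "group_l3") {
  dirs <- tapply(catalog$healthful_direction, catalog[[level]], function(d) {
    u <- unique(d)
    if (length(u) > 1) stop("inconsistent directions within a group")
    u
  })
  scoring_table(stats::setNames(as.numeric(dirs), names(dirs)),
                bins = bins, range = range, level = level)
}

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the study conditions of a free-living UK adult cohort
#' with 2--4 weighed-diary days: 73% female, age 46 +/- 12, BMI around
#' 25.6, about 2.3 snacks/day contributing roughly a quarter of daily
#' energy, a 13/39/31/17% morning/afternoon/evening/grazer timing mixture,
#' about a third late-evening snackers, and planted effect sizes echoing
#' reported associations (per-SDI-unit fasting-TG slope -0.02, insulin
#' -0.15, hunger -0.52, TG 6 h iAUC -400 mmol/L.s; late-evening HbA1c
#' shift +0.08%).
#'
#' @param n_participants Cohort size.
#' @param ... Overrides for any default listed below.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 800, ...) {
  cfg <- list(
    n_participants = n_participants,
    prop_female = 0.73,
    age_mean = 46, age_sd = 12, age_range = c(18, 65),
    bmi_meanlog = log(25.2), bmi_sdlog = 0.17,
    twin_fraction = 0.30,
    days_probs = c(`2` = 0.35, `3` = 0.40, `4` = 0.25),
    # meal timing (minutes since midnight) and energy (kcal)
    meal_time_mean = c(breakfast = 485, lunch = 775, dinner = 1100),
    meal_time_sd = c(breakfast = 35, lunch = 35, dinner = 35),
    meal_skip_prob = c(breakfast = 0.12, lunch = 0.06, dinner = 0.03),
    meal_kcal_mean = c(breakfast = 420, lunch = 620, dinner = 700),
    meal_kcal_sd = c(breakfast = 110, lunch = 150, dinner = 160),
    dessert_prob = 0.15,
    # snacking behaviour
    snack_rate_shape = 4, snack_rate_mean = 2.7,
    snack_kcal_meanlog = log(220), snack_kcal_sdlog = 0.55,
    snack_kcal_part_sdlog = 0.80,   # participant-level appetite multiplier
    pattern_mix = c(morning = 0.13, afternoon = 0.39, evening = 0.31, grazer = 0.17),
    pattern_fidelity = 0.85,
    late_prone_prob = 0.55,
    healthful_logit_mean = -0.95, healthful_logit_sd = 1.0,
    neutral_snack_prob = 0.10,
    freq_quality_cor = -0.35,
    drink_rate = 0.9, alcohol_day_prob = 0.18,
    twin_diet_mix = 0.5,
    # emulation targets used by generator self-checks
    target_snack_share_mean = 0.24, target_snack_share_sd = 0.16,
    # main-meal quality (plant-based-index-style score) and its coupling
    meal_quality_mean = 55, meal_quality_sd = 8, meal_sdi_cor = 0.25,
    # planted marker effects (0 = null)
    beta_sdi_tg = -0.02, beta_sdi_insulin = -0.15, beta_sdi_hunger = -0.52,
    beta_sdi_tg6_iauc = -400,
    delta_late_hba1c = 0.08, delta_late_g2_iauc = 900,
    sdi_reference = 5.7,
    tg_sd = 0.45, insulin_sd = 5.5, hba1c_sd = 0.33, hunger_sd = 16,
    hunger_short_prob = 0.10,
    # microbiome
    mb_species = 300, mb_signal_species = 20, mb_lfc = 0.8, mb_conf_lfc = 0,
    mb_sigma = 2.0, mb_twin_mix = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_participants > 0,
            abs(sum(cfg$pattern_mix) - 1) < 1e-8,
            all(cfg$pattern_mix >= 0),
            cfg$tg_sd >= 0, cfg$insulin_sd >= 0, cfg$hba1c_sd >= 0)
  structure(cfg, class = "cohort_config")
}

#' A null configuration (no planted effects)
#'
#' @param n_participants Cohort size.
#' @param ... Further overrides.
#' @return A `cohort_config` with every planted effect set to zero.
#' @export
null_config <- function(n_participants = 800, ...) {
  cohort_config(n_participants = n_participants,
                beta_sdi_tg = 0, beta_sdi_insulin = 0, beta_sdi_hunger = 0,
                beta_sdi_tg6_iauc = 0, delta_late_hba1c = 0,
                delta_late_g2_iauc = 0, mb_lfc = 0, mb_conf_lfc = 0, ...)
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate synthetic participants
#'
#' Draws demographics, twin pairs (with a shared diet latent), the latent
#' snack-quality propensity and snack rate (negatively correlated), the
#' assigned timing pattern, late-evening proneness, and the main-meal
#' quality score (correlated with the quality latent by `meal_sdi_cor`).
#' Uses the current RNG state.
#'
#' @param cfg A [cohort_config()].
#' @return Data.frame of participants; latent fields carry a `.` prefix and
#'   are echoed into the truth record by [generate_cohort()].
#' @export
generate_participants <- function(cfg) {
  n <- cfg$n_participants
  id <- sprintf("P%04d", seq_len(n))
  sex <- ifelse(stats::runif(n) < cfg$prop_female, "F", "M")
  age <- .rtruncnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
  bmi <- stats::rlnorm(n, cfg$bmi_meanlog, cfg$bmi_sdlog)
  height <- ifelse(sex == "M", stats::rnorm(n, 176, 7), stats::rnorm(n, 163, 6.5))
  weight <- bmi * (height / 100)^2
  education <- sample(1:5, n, replace = TRUE, prob = c(0.05, 0.15, 0.30, 0.30, 0.20))
  activity <- sample(c("<1/week", "1-4/week", ">=5/week"), n, replace = TRUE,
                     prob = c(0.2, 0.5, 0.3))
  n_pairs <- floor(n * cfg$twin_fraction / 2)
  twin <- rep(NA_character_, n)
  if (n_pairs > 0) twin[seq_len(2 * n_pairs)] <- rep(sprintf("T%03d", seq_len(n_pairs)), each = 2)
  # diet latent with a twin-shared component
  z_pair <- stats::rnorm(n)
  if (n_pairs > 0) {
    shared <- stats::rnorm(n_pairs)
    z_pair[seq_len(2 * n_pairs)] <- rep(shared, each = 2)
  }
  w <- cfg$twin_diet_mix
  z_q <- w * z_pair + sqrt(1 - w^2) * stats::rnorm(n)
  rho <- cfg$freq_quality_cor
  z_r <- rho * z_q + sqrt(1 - rho^2) * stats::rnorm(n)
  q <- stats::plogis(cfg$healthful_logit_mean + cfg$healthful_logit_sd * z_q)
  rate <- stats::qgamma(stats::pnorm(z_r), shape = cfg$snack_rate_shape,
                        rate = cfg$snack_rate_shape / cfg$snack_rate_mean)
  cmq <- cfg$meal_sdi_cor
  meal_quality <- cfg$meal_quality_mean + cfg$meal_quality_sd *
    (cmq * z_q + sqrt(1 - cmq^2) * stats::rnorm(n))
  pattern <- sample(names(cfg$pattern_mix), n, replace = TRUE, prob = cfg$pattern_mix)
  late_prone <- stats::runif(n) < cfg$late_prone_prob
  days_n <- sample(as.integer(names(cfg$days_probs)), n, replace = TRUE,
                   prob = cfg$days_probs)
  data.frame(
    participant_id = id, age = age, sex = sex, bmi = bmi,
    height_cm = height, weight_kg = weight, education = education,
    activity_level = activity, twin_pair_id = twin,
    main_meal_quality = meal_quality, days_n = days_n,
    .quality_propensity = q, .snack_rate = rate, .pattern = pattern,
    .late_prone = late_prone,
    stringsAsFactors = FALSE
  )
}

# window placement grids: base start, per-day jitter, inter-snack step,
# in-slot spread, per-day cap. Chosen so within-window snacks are > 30 min
# apart (distinct occasions) and clear of typical meal times.
.win_grid <- list(
  morning   = list(base = 585, jitter = 0,  step = 60, spread = 22, cap = 2L),
  afternoon = list(base = 880, jitter = 0,  step = 64, spread = 26, cap = 3L),
  evening   = list(base = 1185, jitter = 0, step = 36, spread = 5,  cap = 2L)
)
# late-evening-prone participants draw evening snacks on a later grid
.win_grid_late <- list(base = 1245, jitter = 0, step = 75, spread = 30, cap = 2L)

#' Generate diary entries for a cohort
#'
#' Builds 2--4 free-living days per participant with breakfast/lunch/dinner
#' around typical clock times, occasional within-meal desserts (absorbed
#' into the meal by the 30-min rule), snacks placed in the participant's
#' preferred time window at the configured fidelity (grazers spread snacks
#' evenly across windows), low-calorie drink events, and occasional
#' alcoholic drinks (removed by the cleaning filters). Uses the current RNG
#' state.
#'
#' @param participants Output of [generate_participants()].
#' @param catalog Food catalog.
#' @param cfg A [cohort_config()].
#' @return Diary entry data.frame in the internal schema.
#' @export
generate_entries <- function(participants, catalog, cfg) {
  pools <- list(
    healthful = catalog$food_id[catalog$healthful_direction == 1],
    unhealthful = catalog$food_id[catalog$healthful_direction == -1 & !catalog$is_drink],
    unhealthful_drink = catalog$food_id[catalog$healthful_direction == -1 & catalog$is_drink],
    neutral = c("DY02"),
    coffee = c("BV02", "BV03"),
    alcohol = catalog$food_id[catalog$is_alcohol],
    breakfast = c("GR01", "GR02", "GR03", "PR01", "DY04", "DY03", "BV05", "FR01"),
    lunch = c("GR03", "PR02", "PR03", "GR05", "DY02", "VG02"),
    dinner = c("PR02", "PR03", "GR04", "GR05", "VG02", "VG03", "RM01")
  )
  dens <- stats::setNames(catalog$energy_per_100g, catalog$food_id)

  pd <- data.frame(
    participant_id = rep(participants$participant_id, participants$days_n),
    day_index = unlist(lapply(participants$days_n, seq_len)),
    stringsAsFactors = FALSE
  )
  pidx <- match(pd$participant_id, participants$participant_id)
  npd <- nrow(pd)
  out <- list()
  emit <- function(pidv, dayv, timev, foodv, kcalv, labelv) {
    qty <- pmax(1, round(100 * kcalv / dens[foodv], 1))
    out[[length(out) + 1L]] <<- data.frame(
      participant_id = pidv, day_index = dayv,
      clock_time = pmin(pmax(round(timev), 0), 1439),
      food_id = foodv, quantity_g = qty, energy_kcal = kcalv,
      reported_meal_label = labelv, stringsAsFactors = FALSE
    )
  }

  # --- main meals ---
  for (meal in .main_meals) {
    have <- stats::runif(npd) >= cfg$meal_skip_prob[[meal]]
    rows <- which(have)
    m_time <- round(stats::rnorm(length(rows), cfg$meal_time_mean[[meal]],
                                 cfg$meal_time_sd[[meal]]))
    m_time <- pmin(pmax(m_time, 300), 1380)
    m_kcal <- pmax(120, stats::rnorm(length(rows), cfg$meal_kcal_mean[[meal]],
                                     cfg$meal_kcal_sd[[meal]]))
    n_items <- sample(1:3, length(rows), replace = TRUE, prob = c(0.45, 0.35, 0.20))
    ridx <- rep(seq_along(rows), n_items)
    item_seq <- sequence(n_items)
    wts <- stats::runif(length(ridx), 0.5, 1.5)
    tot_w <- rowsum(wts, ridx)[, 1]
    kcal_i <- m_kcal[ridx] * wts / tot_w[ridx]
    foods <- sample(pools[[meal]], length(ridx), replace = TRUE)
    emit(pd$participant_id[rows][ridx], pd$day_index[rows][ridx],
         m_time[ridx] + (item_seq - 1) * 4 + floor(stats::runif(length(ridx), 0, 4)),
         foods, kcal_i, meal)
    if (meal != "breakfast") {
      des <- stats::runif(length(rows)) < cfg$dessert_prob
      if (any(des)) {
        dn <- sum(des)
        emit(pd$participant_id[rows][des], pd$day_index[rows][des],
             m_time[des] + 12 + floor(stats::runif(dn, 0, 6)),
             sample(pools$unhealthful, dn, replace = TRUE),
             stats::rlnorm(dn, log(140), 0.4), "snack")
      }
    }
  }

  # --- snacks ---
  pat <- participants$.pattern[pidx]
  rate <- participants$.snack_rate[pidx]
  is_grazer <- pat == "grazer"
  k_day <- stats::rpois(npd, rate)
  # grazers: fixed multiple-of-three totals spread evenly over days and
  # cycled across windows, so no window ever holds a clear energy peak
  gz_ids <- participants$participant_id[participants$.pattern == "grazer"]
  gz_total <- stats::setNames(3L * sample(2:4, length(gz_ids), replace = TRUE,
                                          prob = c(0.4, 0.4, 0.2)), gz_ids)
  if (any(is_grazer)) {
    dn <- participants$days_n[pidx]
    tot <- gz_total[pd$participant_id]
    base <- floor(tot / dn)
    extra <- tot - base * dn
    k_day[is_grazer] <- (base + (pd$day_index <= extra))[is_grazer]
  }
  k_day <- pmin(k_day, 7L)
  srow <- rep(seq_len(npd), k_day)
  ns <- length(srow)
  s_pat <- pat[srow]
  windows <- c("morning", "afternoon", "evening")
  s_win <- character(ns)
  non_gz <- s_pat != "grazer"
  keep_pref <- stats::runif(ns) < cfg$pattern_fidelity
  s_win[non_gz & keep_pref] <- s_pat[non_gz & keep_pref]
  off <- non_gz & !keep_pref
  if (any(off)) {
    s_win[off] <- vapply(s_pat[off], function(p) sample(setdiff(windows, p), 1), "")
  }
  if (any(!non_gz)) {
    # cycle windows over each grazer's full snack sequence
    gidx <- which(!non_gz)
    seq_in_part <- stats::ave(gidx, pd$participant_id[srow[gidx]], FUN = seq_along)
    s_win[gidx] <- windows[((seq_in_part - 1) %% 3) + 1]
  }
  # within participant-day-window index, capped
  key <- paste(srow, s_win, sep = "\r")
  widx <- stats::ave(seq_len(ns), key, FUN = seq_along)
  lp <- participants$.late_prone[pidx][srow]
  cap <- ifelse(s_win == "morning", .win_grid$morning$cap,
                ifelse(s_win == "afternoon", .win_grid$afternoon$cap, 2L))
  keep <- widx <= cap
  srow <- srow[keep]; s_win <- s_win[keep]; widx <- widx[keep]; lp <- lp[keep]
  ns <- length(srow)
  base <- numeric(ns); step <- numeric(ns); spread <- numeric(ns)
  for (w in windows) {
    g <- .win_grid[[w]]
    sel <- s_win == w & !(w == "evening" & lp)
    base[sel] <- g$base; step[sel] <- g$step; spread[sel] <- g$spread
  }
  sel <- s_win == "evening" & lp
  base[sel] <- .win_grid_late$base; step[sel] <- .win_grid_late$step
  spread[sel] <- .win_grid_late$spread
  s_time <- base + (widx - 1) * step + floor(stats::runif(ns, 0, spread + 1))

  q <- participants$.quality_propensity[pidx][srow]
  u <- stats::runif(ns)
  cat_pick <- ifelse(u < q * (1 - cfg$neutral_snack_prob), "healthful",
                     ifelse(u < q * (1 - cfg$neutral_snack_prob) + cfg$neutral_snack_prob,
                            "neutral", "unhealthful"))
  s_food <- character(ns)
  for (cp in c("healthful", "neutral")) {
    n_cp <- sum(cat_pick == cp)
    if (n_cp) s_food[cat_pick == cp] <- sample(pools[[cp]], n_cp, replace = TRUE)
  }
  n_uh <- sum(cat_pick == "unhealthful")
  if (n_uh) {
    uh_pool <- c(rep(pools$unhealthful, 3), pools$unhealthful_drink)
    s_food[cat_pick == "unhealthful"] <- sample(uh_pool, n_uh, replace = TRUE)
  }
  appetite <- stats::rlnorm(nrow(participants), 0, cfg$snack_kcal_part_sdlog)
  gz_sd <- 0.30  # grazers draw near-equal snack energies (no energy peak)
  s_kcal <- stats::rlnorm(ns, cfg$snack_kcal_meanlog,
                          ifelse(s_pat[keep] == "grazer", gz_sd, cfg$snack_kcal_sdlog)) *
    appetite[pidx[srow]]
  emit(pd$participant_id[srow], pd$day_index[srow], s_time, s_food, s_kcal, "snack")

  # --- low-calorie drinks and alcohol ---
  k_drink <- stats::rpois(npd, cfg$drink_rate)
  drow <- rep(seq_len(npd), k_drink)
  if (length(drow)) {
    emit(pd$participant_id[drow], pd$day_index[drow],
         stats::runif(length(drow), 600, 1020),
         sample(pools$coffee, length(drow), replace = TRUE),
         stats::runif(length(drow), 1, 12), "drink")
  }
  alc <- which(stats::runif(npd) < cfg$alcohol_day_prob)
  if (length(alc)) {
    emit(pd$participant_id[alc], pd$day_index[alc],
         stats::runif(length(alc), 1230, 1350),
         sample(pools$alcohol, length(alc), replace = TRUE),
         stats::rlnorm(length(alc), log(180), 0.3), "drink")
  }

  e <- do.call(rbind, out)
  idx <- match(e$food_id, catalog$food_id)
  frac <- e$quantity_g / 100
  e$carb_g <- frac * catalog$carb_g[idx]
  e$fat_g <- frac * catalog$fat_g[idx]
  e$protein_g <- frac * catalog$protein_g[idx]
  e$sugar_g <- frac * catalog$sugar_g[idx]
  e$day_type <- "free_living"
  e$energy_kcal <- round(e$energy_kcal, 1)
  e <- e[order(e$participant_id, e$day_index, e$clock_time), .entry_cols]
  rownames(e) <- NULL
  e
}

#' Generate the marker panel conditional on diet-derived exposures
#'
#' Fasting markers, anthropometrics, postprandial curves and hunger ratings
#' are drawn conditionally on the pipeline-derived Snack Diet Index and
#' late-evening flag (plus age, sex and BMI), so every planted coefficient
#' in the configuration is the true regression coefficient of the
#' corresponding marker model. Postprandial curves are piecewise linear with
#' knots on the sampling grid (peak-and-return shapes), so their incremental
#' areas have closed forms, which are returned as truth. Uses the current
#' RNG state.
#'
#' @param participants Participant table.
#' @param profiles Snack profiles (needs `sdi`, `late_evening`).
#' @param cfg A [cohort_config()].
#' @param include_series Generate postprandial curves and hunger ratings
#'   (skippable for marker-only replicates).
#' @return `list(fasting, series, hunger, truth)`; `fasting` carries the
#'   non-computed panel fields, `truth` the per-participant analytic iAUCs.
#' @export
generate_markers <- function(participants, profiles, cfg, include_series = TRUE) {
  p <- participants
  n <- nrow(p)
  m <- match(p$participant_id, profiles$participant_id)
  sdi <- profiles$sdi[m]
  late <- profiles$late_evening[m]
  sdi_c <- ifelse(is.na(sdi), 0, sdi - cfg$sdi_reference)
  late01 <- ifelse(is.na(late), 0, as.numeric(late))
  age_c <- p$age - 46
  bmi_c <- p$bmi - 25.5
  male <- as.numeric(p$sex == "M")

  fasting <- data.frame(
    participant_id = p$participant_id,
    weight = p$weight_kg,
    waist_hip_ratio = pmax(0.6, 0.85 + 0.004 * bmi_c + 0.06 * male + stats::rnorm(n, 0, 0.05)),
    visceral_fat_g = pmax(50, 420 + 42 * bmi_c + 6 * age_c + 180 * male + stats::rnorm(n, 0, 150)),
    sbp = pmax(80, 118 + 0.35 * age_c + 0.6 * bmi_c + 4 * male + stats::rnorm(n, 0, 11)),
    ldl = pmax(0.5, 3.3 + 0.015 * age_c + 0.02 * bmi_c + stats::rnorm(n, 0, 0.8)),
    total_cholesterol = pmax(1, 5.2 + 0.018 * age_c + 0.02 * bmi_c + stats::rnorm(n, 0, 0.9)),
    glyca = pmax(0.5, 1.25 + 0.004 * age_c + 0.012 * bmi_c + stats::rnorm(n, 0, 0.15)),
    hba1c = pmax(3.5, 5.46 + cfg$delta_late_hba1c * late01 + 0.006 * age_c +
                   stats::rnorm(n, 0, cfg$hba1c_sd)),
    fasting_glucose = pmax(2.5, 5.1 + 0.012 * age_c + 0.02 * bmi_c +
                             stats::rnorm(n, 0, 0.35)),
    fasting_insulin = pmax(0.5, 9 + cfg$beta_sdi_insulin * sdi_c + 0.3 * bmi_c +
                             stats::rnorm(n, 0, cfg$insulin_sd)),
    fasting_tg = pmax(0.05, 1.25 + cfg$beta_sdi_tg * sdi_c + 0.02 * bmi_c +
                        0.15 * male + stats::rnorm(n, 0, cfg$tg_sd)),
    ascvd_risk = stats::rlnorm(n, log(4), 0.8),  # passthrough external score
    stringsAsFactors = FALSE
  )

  series <- NULL
  hunger <- NULL
  truth <- list()
  if (include_series) {
    # peak heights (above fasting) of piecewise-linear peak-and-return curves
    h_g <- pmax(0.3, stats::rnorm(n, 2.1 + (cfg$delta_late_g2_iauc / 3600) * late01, 1.2))
    h_i <- pmax(2, stats::rnorm(n, 32 + 2 * bmi_c, 12))
    h_t <- pmax(0.05, stats::rnorm(n, 0.85 + (cfg$beta_sdi_tg6_iauc / 12600) * sdi_c +
                                     0.015 * bmi_c, 0.5))
    t_gi <- c(0, 15, 30, 60, 120, 180, 240, 270, 300, 360)
    shape_gi <- c(0, 0.25, 0.5, 1, 0, 0, 0, 0, 0, 0)   # peak at 60, back at 120
    t_tg <- seq(0, 360, by = 60)
    shape_tg <- c(0, 0.25, 0.5, 0.75, 1, 0.75, 0.5)    # peak at 240, partial return
    mk <- function(analyte, tpts, shape, base, h) {
      data.frame(
        participant_id = rep(p$participant_id, each = length(tpts)),
        analyte = analyte, time_min = rep(tpts, n),
        value = rep(base, each = length(tpts)) + as.vector(t(outer(h, shape))),
        stringsAsFactors = FALSE
      )
    }
    series <- rbind(
      mk("glucose", t_gi, shape_gi, fasting$fasting_glucose, h_g),
      mk("insulin", t_gi, shape_gi, fasting$fasting_insulin, h_i),
      mk("tg", t_tg, shape_tg, fasting$fasting_tg, h_t)
    )
    # closed forms: triangle 0-60-120 for glucose/insulin, rise 0-240 plus
    # trapezoid 240-360 (to half peak) for TG; minutes -> seconds
    truth$iauc_glucose_2h <- stats::setNames(3600 * h_g, p$participant_id)
    truth$iauc_insulin_2h <- stats::setNames(3600 * h_i, p$participant_id)
    truth$iauc_tg_6h <- stats::setNames(12600 * h_t, p$participant_id)

    n_days_r <- ifelse(stats::runif(n) < cfg$hunger_short_prob, 5L, 9L)
    hrow <- rep(seq_len(n), n_days_r)
    mu_h <- pmin(95, pmax(5, 55 + cfg$beta_sdi_hunger * sdi_c + stats::rnorm(n, 0, cfg$hunger_sd)))
    hunger <- data.frame(
      participant_id = p$participant_id[hrow],
      day_index = sequence(n_days_r),
      rating = pmin(100, pmax(0, stats::rnorm(length(hrow), mu_h[hrow], 8))),
      stringsAsFactors = FALSE
    )
  }
  list(fasting = fasting, series = series, hunger = hunger, truth = truth)
}

#' Generate a compositional microbiome table
#'
#' Species abundances are log-normal: per-species base levels plus
#' independent noise, a twin-shared latent mixed in at `mb_twin_mix`, a
#' planted shift of `mb_signal_species` species proportional to the
#' standardised signal score (`mb_lfc` per SD), and optionally a shift
#' proportional to a nuisance score (`mb_conf_lfc`, the planted confound).
#' Rows are renormalised to sum to one. Uses the current RNG state.
#'
#' @param ids Sample/participant identifiers.
#' @param signal_score Numeric signal (e.g. SDI), NA allowed (treated as
#'   cohort mean).
#' @param twin_pair Twin-pair ids aligned with `ids` (NA = singleton).
#' @param cfg A [cohort_config()].
#' @param nuisance_score Optional confounder (e.g. main-meal quality).
#' @return `list(abundance, signal_species)`.
#' @export
generate_microbiome <- function(ids, signal_score, twin_pair = NULL, cfg = cohort_config(),
                                nuisance_score = NULL) {
  n <- length(ids)
  S <- cfg$mb_species
  z <- as.numeric(scale(ifelse(is.na(signal_score), mean(signal_score, na.rm = TRUE),
                               signal_score)))
  mu <- stats::rnorm(S, 0, 1.5)
  E <- matrix(stats::rnorm(n * S, 0, cfg$mb_sigma), n, S)
  if (!is.null(twin_pair)) {
    w <- cfg$mb_twin_mix
    pair_ids <- unique(twin_pair[!is.na(twin_pair)])
    if (length(pair_ids)) {
      Z_pair <- matrix(stats::rnorm(length(pair_ids) * S, 0, cfg$mb_sigma),
                       length(pair_ids), S)
      paired <- !is.na(twin_pair)
      E[paired, ] <- w * Z_pair[match(twin_pair[paired], pair_ids), , drop = FALSE] +
        sqrt(1 - w^2) * E[paired, , drop = FALSE]
    }
  }
  logA <- matrix(mu, n, S, byrow = TRUE) + E
  sig <- sample.int(S, cfg$mb_signal_species)
  logA[, sig] <- logA[, sig] + cfg$mb_lfc * z
  if (!is.null(nuisance_score) && cfg$mb_conf_lfc != 0) {
    zn <- as.numeric(scale(nuisance_score))
    logA[, sig] <- logA[, sig] + cfg$mb_conf_lfc * zn
  }
  A <- exp(logA)
  A <- A / rowSums(A)
  dimnames(A) <- list(ids, sprintf("s__species_%03d", seq_len(S)))
  list(abundance = A, signal_species = colnames(A)[sig])
}

#' Generate a full synthetic cohort
#'
#' Draws participants and a diary, runs the occasion/profile pipeline to
#' realise each participant's Snack Diet Index, timing pattern and
#' late-evening flag, then generates markers, postprandial curves, hunger
#' ratings and a microbiome table conditional on those realised exposures.
#' Fully reproducible from `seed`; every planted parameter is echoed in the
#' `truth` record.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @return A list: `participants`, `catalog`, `scoring`, `entries`,
#'   `fasting`, `series`, `hunger`, `microbiome`, `truth`, and `derived`
#'   (the internal `pipeline` and `profiles`, provided for convenience).
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = 1) {
  set.seed(seed)
  catalog <- synthetic_catalog()
  scoring <- catalog_scoring_table(catalog)
  participants <- generate_participants(cfg)
  entries <- generate_entries(participants, catalog, cfg)
  pub_part <- participants[setdiff(names(participants),
                                   c(".quality_propensity", ".snack_rate",
                                     ".pattern", ".late_prone", "days_n"))]
  pipeline <- occasion_pipeline(entries, pub_part, catalog)
  profiles <- snack_profiles(pipeline, catalog, scoring)
  if (all(!profiles$is_snacker)) warning("config produced no snackers")
  markers <- generate_markers(participants, profiles, cfg, include_series = TRUE)
  snackers <- profiles[!is.na(profiles$sdi), ]
  mb <- generate_microbiome(
    snackers$participant_id, snackers$sdi,
    twin_pair = pub_part$twin_pair_id[match(snackers$participant_id,
                                            pub_part$participant_id)],
    cfg = cfg,
    nuisance_score = pub_part$main_meal_quality[match(snackers$participant_id,
                                                      pub_part$participant_id)]
  )
  truth <- c(list(
    config = cfg, seed = seed,
    beta_sdi_tg = cfg$beta_sdi_tg, beta_sdi_insulin = cfg$beta_sdi_insulin,
    beta_sdi_hunger = cfg$beta_sdi_hunger, beta_sdi_tg6_iauc = cfg$beta_sdi_tg6_iauc,
    delta_late_hba1c = cfg$delta_late_hba1c, delta_late_g2_iauc = cfg$delta_late_g2_iauc,
    pattern_mix = cfg$pattern_mix,
    pattern_assigned = stats::setNames(participants$.pattern, participants$participant_id),
    late_prone = stats::setNames(participants$.late_prone, participants$participant_id),
    quality_propensity = stats::setNames(participants$.quality_propensity,
                                         participants$participant_id),
    snack_rate = stats::setNames(participants$.snack_rate, participants$participant_id),
    microbiome_signal_species = mb$signal_species
  ), markers$truth)
  list(participants = pub_part, catalog = catalog, scoring = scoring,
       entries = entries, fasting = markers$fasting, series = markers$series,
       hunger = markers$hunger, microbiome = mb$abundance, truth = truth,
       derived = list(pipeline = pipeline, profiles = profiles))
}

#' Write a generated cohort to disk in the formats the readers accept
#'
#' Diary, participants, fasting panel, postprandial series and hunger
#' ratings as CSV, the abundance matrix as TSV, the catalog as CSV and the
#' truth record as JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(cohort$entries, file.path(dir, "diary.csv"))
  write_table(cohort$participants, file.path(dir, "participants.csv"))
  write_table(cohort$catalog, file.path(dir, "catalog.csv"))
  write_table(cohort$fasting, file.path(dir, "fasting.csv"))
  write_table(cohort$series, file.path(dir, "series.csv"))
  write_table(cohort$hunger, file.path(dir, "hunger.csv"))
  write_abundance(cohort$microbiome, file.path(dir, "abundance.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}
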