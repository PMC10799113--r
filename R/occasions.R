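#' Entry-level cleaning filters
#'
#' Removes, with a reasoned exclusion log: foods not resolvable in the
#' catalog (`unidentifiable`), entries with implausible quantities
#' (strictly greater than `max_quantity_g`), and alcoholic beverages on
#' free-living days. Alcohol is dropped before occasions are built, so its
#' energy never counts toward day totals or snack metrics.
#'
#' @param entries Diary entries (from [read_diary()] or the generator).
#' @param catalog Food catalog.
#' @param max_quantity_g Implausible-quantity cut-off in grams; the rule is
#'   strict (`> 2000` g removed, exactly 2000 g kept).
#' @return `list(entries, log)`: the kept entries and a data.frame of
#'   removals with participant, day, food and reason.
#' @export
apply_entry_filters <- function(entries, catalog, max_quantity_g = 2000) {
  if (!"unidentifiable" %in% names(entries)) {
    entries$unidentifiable <- !(entries$food_id %in% catalog$food_id)
  }
  is_alc <- catalog$is_alcohol[match(entries$food_id, catalog$food_id)]
  is_alc[is.na(is_alc)] <- FALSE
  free <- entries$day_type == "free_living"

  reason <- rep(NA_character_, nrow(entries))
  reason[entries$unidentifiable] <- "unidentifiable food"
  reason[is.na(reason) & entries$quantity_g > max_quantity_g] <- "implausible quantity"
  reason[is.na(reason) & is_alc & free] <- "alcohol"

  drop <- !is.na(reason)
  log <- data.frame(
    participant_id = entries$participant_id[drop],
    day_index = entries$day_index[drop],
    food_id = entries$food_id[drop],
    reason = reason[drop],
    stringsAsFactors = FALSE
  )
  list(entries = entries[!drop, , drop = FALSE], log = log)
}

#' Aggregate timed entries into eating occasions
#'
#' Entries on the same participant-day are chained into one occasion while
#' each consecutive gap is at most `gap_min` minutes (single linkage); a gap
#' strictly greater than `gap_min` starts a new occasion. Occasions never
#' cross calendar days. Nutrients are summed within each occasion, the meal
#' type is resolved (main-meal labels absorb co-occurring snacks/drinks) and
#' snack occasions are flagged.
#'
#' @param entries Cleaned diary entries; any number of participant-days.
#' @param catalog Food catalog (for drink flags in the snack rule).
#' @param gap_min Chaining gap in minutes; a gap of exactly `gap_min`
#'   merges.
#' @param drink_kcal_max Single low-calorie-drink exclusion threshold
#'   (occasions that are one drink item at or below this energy are not
#'   snacks).
#' @return `list(occasions, entries)`: an occasion table (start/end time,
#'   totals, `resolved_meal_type`, `is_snack`, `single_food`) and the input
#'   entries with an `occasion_id` column.
#' @export
build_occasions <- function(entries, catalog, gap_min = 30, drink_kcal_max = 50) {
  if (nrow(entries) == 0) {
    occ <- data.frame(
      occasion_id = integer(), participant_id = character(), day_index = integer(),
      start_time = numeric(), end_time = numeric(), n_entries = integer(),
      energy_kcal = numeric(), carb_g = numeric(), fat_g = numeric(),
      protein_g = numeric(), sugar_g = numeric(),
      resolved_meal_type = character(), is_snack = logical(), single_food = logical()
    )
    return(list(occasions = occ, entries = cbind(entries, occasion_id = integer(0))))
  }
  ord <- order(entries$participant_id, entries$day_index, entries$clock_time)
  e <- entries[ord, , drop = FALSE]
  n <- nrow(e)
  same_day <- c(FALSE, e$participant_id[-1] == e$participant_id[-n] &
                  e$day_index[-1] == e$day_index[-n])
  gap <- c(Inf, diff(e$clock_time))
  new_occ <- !(same_day & gap <= gap_min)
  e$occasion_id <- cumsum(new_occ)

  agg <- rowsum(e[.nutrient_cols], e$occasion_id)
  first <- which(new_occ)
  last <- c(first[-1] - 1L, n)
  occ <- data.frame(
    occasion_id = e$occasion_id[first],
    participant_id = e$participant_id[first],
    day_index = e$day_index[first],
    day_type = e$day_type[first],
    start_time = e$clock_time[first],
    end_time = e$clock_time[last],
    n_entries = as.integer(last - first + 1L),
    stringsAsFactors = FALSE
  )
  occ <- cbind(occ, agg[match(occ$occasion_id, as.integer(rownames(agg))), , drop = FALSE])
  rownames(occ) <- NULL

  occ$resolved_meal_type <- .resolve_meal_types(e)
  occ$single_food <- occ$n_entries == 1L

  # single low-calorie drink rule + snack identification
  is_drink <- catalog$is_drink[match(e$food_id, catalog$food_id)]
  is_drink[is.na(is_drink)] <- FALSE
  single_drink <- occ$single_food & is_drink[first]
  occ$is_snack <- occ$resolved_meal_type %in% c("snack", "drink") &
    !(single_drink & occ$energy_kcal <= drink_kcal_max)
  list(occasions = occ, entries = e)
}

# Vectorised meal-type resolution over all occasions of a sorted,
# occasion_id-labelled entry table. If any member carries a main-meal label
# the occasion takes the label of the highest-energy main-labelled member
# (ties -> earliest member); otherwise "snack" if any member is a snack,
# else "drink".
.resolve_meal_types <- function(e) {
  is_main <- e$reported_meal_label %in% .main_meals
  o <- order(e$occasion_id, -is_main, -ifelse(is_main, e$energy_kcal, 0), e$clock_time)
  top <- e[o, ][!duplicated(e$occasion_id[o]), ]
  any_snack <- tapply(e$reported_meal_label == "snack", e$occasion_id, any)
  label <- ifelse(top$reported_meal_label %in% .main_meals,
                  top$reported_meal_label,
                  ifelse(as.logical(any_snack[as.character(top$occasion_id)]),
                         "snack", "drink"))
  unname(label)
}

#' Resolve the meal type of a single occasion
#'
#' Main-meal labels absorb co-occurring snacks and drinks; among several
#' main-meal labels the highest-energy member wins, ties going to the
#' earliest member. Occasions with only snack/drink labels resolve to
#' `"snack"` when any member is snack-labelled, otherwise `"drink"`.
#'
#' @param members Entries of one occasion (`reported_meal_label`,
#'   `energy_kcal`, `clock_time`).
#' @return A single meal-type label.
#' @export
resolve_meal_type <- function(members) {
  stopifnot(nrow(members) >= 1)
  members$occasion_id <- 1L
  members <- members[order(members$clock_time), , drop = FALSE]
  .resolve_meal_types(members)
}

#' Is an occasion a snack?
#'
#' True when the resolved type is snack or drink, unless the occasion is a
#' single drink item at or below the low-calorie threshold. Alcohol never
#' reaches this test (removed upstream by [apply_entry_filters()]).
#'
#' @param occasion One row of the occasion table from [build_occasions()].
#' @param members Its member entries.
#' @param catalog Food catalog.
#' @param drink_kcal_max Low-calorie drink threshold (kcal).
#' @return Logical flag.
#' @export
is_snack_occasion <- function(occasion, members, catalog, drink_kcal_max = 50) {
  if (!occasion$resolved_meal_type %in% c("snack", "drink")) return(FALSE)
  if (nrow(members) == 1L) {
    drink <- isTRUE(catalog$is_drink[match(members$food_id, catalog$food_id)])
    if (drink && occasion$energy_kcal <= drink_kcal_max) return(FALSE)
  }
  TRUE
}

#' Day-level energy totals
#'
#' One row per participant-day present in the (cleaned) entries, with the
#' summed energy and the day type.
#'
#' @param entries Cleaned diary entries.
#' @return Data.frame `participant_id`, `day_index`, `day_type`,
#'   `total_kcal`.
#' @export
day_totals <- function(entries) {
  key <- paste(entries$participant_id, entries$day_index, sep = "\r")
  agg <- rowsum(entries$energy_kcal, key)
  first <- entries[!duplicated(key), c("participant_id", "day_index", "day_type")]
  out <- cbind(first, total_kcal = agg[match(paste(first$participant_id, first$day_index, sep = "\r"),
                                             rownames(agg)), 1])
  rownames(out) <- NULL
  out[order(out$participant_id, out$day_index), ]
}

#' Day- and participant-level inclusion filters
#'
#' A free-living day is excluded when its total energy falls outside
#' sex-specific bounds (500--5000 kcal for females, 500--8000 kcal for
#' males); test-meal days are excluded from the snacking analysis outright;
#' a participant is excluded when fewer than `min_days` free-living days
#' survive.
#'
#' @param days Day totals from [day_totals()].
#' @param participants Participant table (for `sex`).
#' @param kcal_bounds_f,kcal_bounds_m Inclusive energy bounds by sex.
#' @param min_days Minimum surviving free-living days per participant.
#' @return `list(days, participants)`: the day table with `included` and
#'   `exclusion_reason`, and the participant table with an `included` flag
#'   and the count of included days.
#' @export
apply_day_and_participant_filters <- function(days, participants,
                                              kcal_bounds_f = c(500, 5000),
                                              kcal_bounds_m = c(500, 8000),
                                              min_days = 2) {
  sex <- participants$sex[match(days$participant_id, participants$participant_id)]
  lo <- ifelse(sex == "M", kcal_bounds_m[1], kcal_bounds_f[1])
  hi <- ifelse(sex == "M", kcal_bounds_m[2], kcal_bounds_f[2])
  reason <- rep(NA_character_, nrow(days))
  reason[days$day_type != "free_living"] <- "test-meal day"
  out_of_bounds <- is.na(reason) & (days$total_kcal < lo | days$total_kcal > hi)
  reason[out_of_bounds] <- "caloric intake outside sex-specific cut-offs"
  days$included <- is.na(reason)
  days$exclusion_reason <- reason

  inc <- days[days$included, ]
  n_inc <- table(inc$participant_id)
  participants$included_days <- as.integer(n_inc[participants$participant_id])
  participants$included_days[is.na(participants$included_days)] <- 0L
  participants$included <- participants$included_days >= min_days
  list(days = days, participants = participants)
}

#' Run the full diary-to-occasions pipeline
#'
#' Convenience wrapper: entry filters, occasion construction, day totals and
#' day/participant inclusion, returning everything downstream modules need.
#'
#' @inheritParams apply_entry_filters
#' @inheritParams build_occasions
#' @param participants Participant table.
#' @return A list with `occasions`, `entries` (occasion-labelled), `days`,
#'   `participants` (with inclusion flags) and the entry `exclusion_log`.
#' @export
occasion_pipeline <- function(entries, participants, catalog,
                              gap_min = 30, drink_kcal_max = 50) {
  filt <- apply_entry_filters(entries, catalog)
  built <- build_occasions(filt$entries, catalog, gap_min = gap_min,
                           drink_kcal_max = drink_kcal_max)
  days <- day_totals(built$entries)
  inc <- apply_day_and_participant_filters(days, participants)
  list(occasions = built$occasions, entries = built$entries,
       days = inc$days, participants = inc$participants,
       exclusion_log = filt$log)
}
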