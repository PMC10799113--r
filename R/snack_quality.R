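#' Per-participant snack frequency
#'
#' Snack occasions on included free-living days, averaged over the included
#' days. Frequency groups `0 / 1 / 2 / >2` use the rounded mean (round half
#' to even, as in base R); a participant is a snacker at one or more snacks
#' per day on average.
#'
#' @param occasions Occasion table from [build_occasions()].
#' @param days Day table with inclusion flags.
#' @return Data.frame `participant_id`, `snacks_per_day`, `frequency_group`
#'   (factor `0,1,2,>2`), `is_snacker`; one row per participant with at
#'   least one included day.
#' @export
snack_frequency <- function(occasions, days) {
  inc <- days[days$included, c("participant_id", "day_index")]
  if (nrow(inc) == 0) {
    return(data.frame(participant_id = character(), snacks_per_day = numeric(),
                      frequency_group = factor(character(), levels = c("0", "1", "2", ">2")),
                      is_snacker = logical()))
  }
  key_occ <- paste(occasions$participant_id, occasions$day_index, sep = "\r")
  key_inc <- paste(inc$participant_id, inc$day_index, sep = "\r")
  occ <- occasions[occasions$is_snack & key_occ %in% key_inc, ]
  n_days <- table(inc$participant_id)
  n_snacks <- table(occ$participant_id)
  ids <- names(n_days)
  spd <- as.numeric(n_snacks[ids])
  spd[is.na(spd)] <- 0
  spd <- spd / as.numeric(n_days)
  r <- round(spd)
  grp <- ifelse(r <= 0, "0", ifelse(r == 1, "1", ifelse(r == 2, "2", ">2")))
  data.frame(
    participant_id = ids,
    snacks_per_day = spd,
    frequency_group = factor(grp, levels = c("0", "1", "2", ">2")),
    is_snacker = spd >= 1,
    stringsAsFactors = FALSE
  )
}

#' Snack share of daily energy
#'
#' For each participant, the mean over included days of the daily proportion
#' of energy from snack occasions (mean of daily proportions, not pooled
#' energy).
#'
#' @inheritParams snack_frequency
#' @return Data.frame `participant_id`, `snack_energy_share` in `[0, 1]`.
#' @export
snack_energy_share <- function(occasions, days) {
  inc <- days[days$included, ]
  key_occ <- paste(occasions$participant_id, occasions$day_index, sep = "\r")
  key_inc <- paste(inc$participant_id, inc$day_index, sep = "\r")
  occ <- occasions[key_occ %in% key_inc, ]
  key <- paste(occ$participant_id, occ$day_index, sep = "\r")
  snack_kcal <- rowsum(ifelse(occ$is_snack, occ$energy_kcal, 0), key)
  day_prop <- snack_kcal[match(key_inc, rownames(snack_kcal)), 1] / inc$total_kcal
  day_prop[is.na(day_prop)] <- 0
  share <- tapply(day_prop, inc$participant_id, mean)
  data.frame(participant_id = names(share), snack_energy_share = as.numeric(share),
             stringsAsFactors = FALSE)
}

#' Build a scoring table
#'
#' Maps food groups (by default level-3 groups) to a healthfulness
#' direction: +1 healthful (scored ascending across cohort quantile bins),
#' -1 unhealthful (reverse-scored), 0 neutral (unscored). Drives both the
#' snack diet index and, with a full-diet table, plant-based-diet-style
#' main-meal scores.
#'
#' @param directions Named numeric vector, group -> direction in
#'   \{-1, 0, 1\}.
#' @param bins Number of cohort quantile bins (default 5, quintiles).
#' @param range Target score range after affine rescaling of the component
#'   sum; `c(1, 11)` by default.
#' @param level Catalog group column used for scoring.
#' @return A `scoring_table` list.
#' @export
scoring_table <- function(directions, bins = 5, range = c(1, 11), level = "group_l3") {
  stopifnot(all(directions %in% c(-1, 0, 1)), bins >= 2, length(range) == 2,
            range[2] > range[1])
  structure(list(directions = directions, bins = bins, range = range, level = level),
            class = "scoring_table")
}

#' Read a scoring table from YAML
#'
#' Expects keys `directions` (group -> -1/0/1 mapping), and optional `bins`,
#' `range`, `level`.
#'
#' @param path YAML file.
#' @return A `scoring_table`.
#' @export
read_scoring_table <- function(path) {
  raw <- yaml::read_yaml(path)
  scoring_table(unlist(raw$directions),
                bins = if (is.null(raw$bins)) 5 else raw$bins,
                range = if (is.null(raw$range)) c(1, 11) else unlist(raw$range),
                level = if (is.null(raw$level)) "group_l3" else raw$level)
}

# Quantile bin of each value among a cohort: average ranks cut into `bins`
# equal rank intervals. Deterministic under permutation.
.quantile_bin <- function(x, bins) {
  r <- rank(x, ties.method = "average")
  pmin(pmax(ceiling(bins * r / length(x)), 1L), bins)
}

# Per-participant energy by scored food group over snack occasions.
.snack_group_energy <- function(occasions, entries, catalog, level,
                                include_drinks = TRUE) {
  snack_ids <- occasions$occasion_id[occasions$is_snack &
                                       (include_drinks | occasions$resolved_meal_type != "drink")]
  e <- entries[entries$occasion_id %in% snack_ids, , drop = FALSE]
  grp <- catalog[[level]][match(e$food_id, catalog$food_id)]
  if (nrow(e) == 0) return(NULL)
  tab <- rowsum(e$energy_kcal, paste(e$participant_id, grp, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  data.frame(participant_id = parts[, 1], group = parts[, 2],
             energy_kcal = tab[, 1], stringsAsFactors = FALSE, row.names = NULL)
}

#' Snack Diet Index
#'
#' A cohort-relative, food-group-direction score of snack healthfulness,
#' built like a plant-based diet index: each scored group's share of a
#' participant's snack energy is ranked into cohort quantile bins (default
#' quintiles); healthful groups contribute their bin number, unhealthful
#' groups the reversed bin; the component sum is affinely rescaled to the
#' configured range (default 1--11). Higher is healthier. Defined for
#' snackers; participants with zero snack energy get `NA` and are flagged.
#'
#' @param occasions,entries Occasion-labelled pipeline output.
#' @param catalog Food catalog.
#' @param table A [scoring_table()] covering every observed group.
#' @param participant_ids Cohort over which quantile bins are formed
#'   (default: every participant with snack energy).
#' @param include_drinks Score drink snacks too (`FALSE` gives the
#'   food-only variant).
#' @return Data.frame `participant_id`, `sdi`.
#' @export
compute_sdi <- function(occasions, entries, catalog, table,
                        participant_ids = NULL, include_drinks = TRUE) {
  stopifnot(inherits(table, "scoring_table"))
  ge <- .snack_group_energy(occasions, entries, catalog, table$level, include_drinks)
  if (is.null(ge)) stop("no snack energy in cohort: SDI undefined")
  obs_groups <- unique(ge$group)
  unknown <- setdiff(obs_groups, names(table$directions))
  if (length(unknown)) {
    stop("scoring table lacks directions for groups: ", paste(unknown, collapse = ", "))
  }
  if (is.null(participant_ids)) participant_ids <- sort(unique(ge$participant_id))
  ge <- ge[ge$participant_id %in% participant_ids, , drop = FALSE]

  scored <- names(table$directions)[table$directions != 0]
  total <- rowsum(ge$energy_kcal, ge$participant_id)
  ids <- rownames(total)
  shares <- matrix(0, nrow = length(ids), ncol = length(scored),
                   dimnames = list(ids, scored))
  keep <- ge$group %in% scored
  shares[cbind(match(ge$participant_id[keep], ids), match(ge$group[keep], scored))] <-
    ge$energy_kcal[keep] / total[match(ge$participant_id[keep], ids), 1]

  B <- table$bins
  comp <- matrix(0, nrow = length(ids), ncol = length(scored))
  for (j in seq_along(scored)) {
    bin <- .quantile_bin(shares[, j], B)
    comp[, j] <- if (table$directions[[scored[j]]] > 0) bin else (B + 1 - bin)
  }
  s <- rowSums(comp)
  G <- length(scored)
  lo <- table$range[1]; hi <- table$range[2]
  sdi <- lo + (s - G) / (G * B - G) * (hi - lo)

  out <- data.frame(participant_id = participant_ids, stringsAsFactors = FALSE)
  out$sdi <- sdi[match(out$participant_id, ids)]
  attr(out, "zero_snack_energy") <- setdiff(participant_ids, ids)
  out
}

#' NOVA processing-level energy shares of snacks
#'
#' Fraction of each participant's snack energy from each NOVA class; the
#' four class shares sum to 1 for every snacker.
#'
#' @inheritParams compute_sdi
#' @return Data.frame `participant_id`, `nova1_share` .. `nova4_share`.
#' @export
nova_shares <- function(occasions, entries, catalog, include_drinks = TRUE) {
  snack_ids <- occasions$occasion_id[occasions$is_snack &
                                       (include_drinks | occasions$resolved_meal_type != "drink")]
  e <- entries[entries$occasion_id %in% snack_ids, , drop = FALSE]
  nova <- catalog$nova_class[match(e$food_id, catalog$food_id)]
  ids <- sort(unique(e$participant_id))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  total <- rowsum(e$energy_kcal, e$participant_id)[ids, 1]
  for (k in 1:4) {
    kk <- rowsum(ifelse(nova == k, e$energy_kcal, 0), e$participant_id)[ids, 1]
    out[[paste0("nova", k, "_share")]] <- kk / total
  }
  out
}

#' Most frequently consumed snack food groups
#'
#' Food groups with at least `min_events` logged snack entries, ranked by
#' event count, with each group's mean contribution to its consumers' total
#' daily energy intake (percent).
#'
#' @inheritParams compute_sdi
#' @param days Day table with inclusion flags (for daily energy).
#' @param min_events Popularity threshold on logged snack events (strictly
#'   `>= min_events` kept).
#' @param level Catalog group column.
#' @return Data.frame `group`, `n_events`, `pct_daily_energy`, ranked by
#'   `n_events` descending.
#' @export
popular_snacks <- function(occasions, entries, catalog, days, min_events = 100,
                           level = "group_l3") {
  e <- entries[entries$occasion_id %in% occasions$occasion_id[occasions$is_snack], ]
  e$group <- catalog[[level]][match(e$food_id, catalog$food_id)]
  counts <- table(e$group)
  keep <- names(counts)[counts >= min_events]
  inc <- days[days$included, ]
  daily <- tapply(inc$total_kcal, inc$participant_id, mean)
  n_days <- table(inc$participant_id)
  rows <- lapply(keep, function(g) {
    eg <- e[e$group == g, ]
    per_part <- rowsum(eg$energy_kcal, eg$participant_id)
    ids <- rownames(per_part)
    per_day <- per_part[, 1] / as.numeric(n_days[ids])
    pct <- 100 * mean(per_day / as.numeric(daily[ids]), na.rm = TRUE)
    data.frame(group = g, n_events = as.integer(counts[[g]]),
               pct_daily_energy = pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(group = character(), n_events = integer(),
                                                pct_daily_energy = numeric()))))
  out[order(-out$n_events), , drop = FALSE]
}

#' Meal-vs-snack quality discordance
#'
#' Cross-tabulates top-half versus bottom-half membership of a snack-quality
#' score and a main-meal-quality score (average ranks; ranks above n/2 are
#' the top half). The discordant fraction is the probability of being in the
#' top half of one score and the bottom half of the other.
#'
#' @param snack_score,meal_score Paired numeric scores, one per participant.
#' @return `list(quadrants, discordant_fraction)` where `quadrants` is the
#'   2x2 counts table.
#' @export
discordance <- function(snack_score, meal_score) {
  stopifnot(length(snack_score) == length(meal_score))
  ok <- !is.na(snack_score) & !is.na(meal_score)
  s <- snack_score[ok]; m <- meal_score[ok]
  n <- length(s)
  top_s <- rank(s, ties.method = "average") > n / 2
  top_m <- rank(m, ties.method = "average") > n / 2
  quad <- table(snack = factor(ifelse(top_s, "top", "bottom"), c("bottom", "top")),
                meal = factor(ifelse(top_m, "top", "bottom"), c("bottom", "top")))
  disc <- mean((top_s & !top_m) | (!top_s & top_m))
  list(quadrants = quad, discordant_fraction = disc, n = n)
}

#' Assemble per-participant snack profiles
#'
#' Joins frequency, energy share, SDI, NOVA shares and (via
#' [timing_profiles()]) temporal fields into one table, restricted to
#' participants passing the inclusion filters.
#'
#' @param pipeline Output of [occasion_pipeline()].
#' @param catalog Food catalog.
#' @param table Scoring table for the SDI.
#' @param include_drinks Score drink snacks in the SDI/NOVA shares.
#' @return Data.frame, one row per included participant.
#' @export
snack_profiles <- function(pipeline, catalog, table, include_drinks = TRUE) {
  occ <- pipeline$occasions
  days <- pipeline$days
  inc_ids <- pipeline$participants$participant_id[pipeline$participants$included]
  freq <- snack_frequency(occ, days)
  share <- snack_energy_share(occ, days)
  prof <- merge(freq, share, by = "participant_id", all.x = TRUE)
  prof <- prof[prof$participant_id %in% inc_ids, , drop = FALSE]
  snackers <- prof$participant_id[prof$is_snacker]
  sdi <- compute_sdi(occ, pipeline$entries, catalog, table,
                     participant_ids = snackers, include_drinks = include_drinks)
  prof <- merge(prof, sdi, by = "participant_id", all.x = TRUE)
  nv <- nova_shares(occ, pipeline$entries, catalog, include_drinks = include_drinks)
  prof <- merge(prof, nv, by = "participant_id", all.x = TRUE)
  tp <- timing_profiles(occ, days)
  prof <- merge(prof, tp, by = "participant_id", all.x = TRUE)
  rownames(prof) <- NULL
  prof
}
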