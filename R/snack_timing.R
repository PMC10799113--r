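#' Temporal snacking windows
#'
#' Half-open clock windows used throughout: morning `[00:00, 12:00)`,
#' afternoon `[12:00, 18:00)`, evening `[18:00, 24:00)`. An occasion belongs
#' to the window containing its start time.
#'
#' @param start_time Minutes since midnight.
#' @return Factor with levels `morning`, `afternoon`, `evening`.
#' @export
snack_window <- function(start_time) {
  idx <- findInterval(start_time, c(720, 1080)) + 1L  # half-open at 12:00 / 18:00
  factor(c("morning", "afternoon", "evening")[idx],
         levels = c("morning", "afternoon", "evening"))
}

#' Per-participant snack energy shares by time window
#'
#' @param occasions Occasion table.
#' @param days Day table with inclusion flags.
#' @return Data.frame `participant_id`, `morning_share`, `afternoon_share`,
#'   `evening_share` (summing to 1 for snackers).
#' @export
window_shares <- function(occasions, days) {
  inc <- days[days$included, ]
  key_occ <- paste(occasions$participant_id, occasions$day_index, sep = "\r")
  key_inc <- paste(inc$participant_id, inc$day_index, sep = "\r")
  occ <- occasions[occasions$is_snack & key_occ %in% key_inc, ]
  w <- snack_window(occ$start_time)
  ids <- sort(unique(occ$participant_id))
  total <- rowsum(occ$energy_kcal, occ$participant_id)[ids, 1]
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (win in levels(w)) {
    kk <- rowsum(ifelse(w == win, occ$energy_kcal, 0), occ$participant_id)[ids, 1]
    out[[paste0(win, "_share")]] <- kk / total
  }
  out
}

#' Classify a temporal snacking pattern
#'
#' A snacker is a morning / afternoon / evening snacker when at least
#' `threshold` (default 50%) of their snack energy falls in that window;
#' ties across windows go to the earliest window; a snacker with no window
#' reaching the threshold is a grazer.
#'
#' @param shares Output of [window_shares()] (or a compatible data.frame).
#' @param threshold Window share needed for a peak; comparison is
#'   at-or-above.
#' @return `shares` with a `pattern` factor
#'   (`morning`,`afternoon`,`evening`,`grazer`).
#' @export
classify_pattern <- function(shares, threshold = 0.5) {
  m <- as.matrix(shares[c("morning_share", "afternoon_share", "evening_share")])
  hit <- m >= threshold
  first <- apply(hit, 1, function(r) if (any(r)) which(r)[1] else 4L)
  shares$pattern <- factor(c("morning", "afternoon", "evening", "grazer")[first],
                           levels = c("morning", "afternoon", "evening", "grazer"))
  shares
}

#' Late-evening snacker flag
#'
#' True when any snack occasion on any included day starts at or after the
#' cut-off (default 21:00).
#'
#' @param occasions Occasion table.
#' @param days Day table with inclusion flags.
#' @param cutoff Minutes since midnight; at-or-after flags.
#' @return Data.frame `participant_id`, `late_evening` for snackers (one
#'   row per participant with at least one snack occasion).
#' @export
late_evening_flag <- function(occasions, days, cutoff = 21 * 60) {
  inc <- days[days$included, ]
  key_occ <- paste(occasions$participant_id, occasions$day_index, sep = "\r")
  key_inc <- paste(inc$participant_id, inc$day_index, sep = "\r")
  occ <- occasions[occasions$is_snack & key_occ %in% key_inc, ]
  late <- tapply(occ$start_time >= cutoff, occ$participant_id, any)
  data.frame(participant_id = names(late), late_evening = as.logical(late),
             stringsAsFactors = FALSE)
}

#' Mean first-eating-occasion time
#'
#' Mean over included days of the start time of the day's first eating
#' occasion of any type.
#'
#' @inheritParams late_evening_flag
#' @return Data.frame `participant_id`, `first_occasion_time` (minutes).
#' @export
first_occasion_time <- function(occasions, days) {
  inc <- days[days$included, ]
  key_occ <- paste(occasions$participant_id, occasions$day_index, sep = "\r")
  key_inc <- paste(inc$participant_id, inc$day_index, sep = "\r")
  occ <- occasions[key_occ %in% key_inc, ]
  key <- paste(occ$participant_id, occ$day_index, sep = "\r")
  firsts <- tapply(occ$start_time, key, min)
  pid <- sub("\r.*$", "", names(firsts))
  fot <- tapply(as.numeric(firsts), pid, mean)
  data.frame(participant_id = names(fot), first_occasion_time = as.numeric(fot),
             stringsAsFactors = FALSE)
}

#' Assemble timing profiles
#'
#' Window shares, pattern label, late-evening flag and mean first-occasion
#' time in one table.
#'
#' @inheritParams late_evening_flag
#' @param threshold Pattern peak threshold.
#' @return Data.frame, one row per snacker.
#' @export
timing_profiles <- function(occasions, days, threshold = 0.5, cutoff = 21 * 60) {
  ws <- classify_pattern(window_shares(occasions, days), threshold)
  le <- late_evening_flag(occasions, days, cutoff)
  fot <- first_occasion_time(occasions, days)
  out <- merge(ws, le, by = "participant_id", all.x = TRUE)
  merge(out, fot, by = "participant_id", all.x = TRUE)
}

#' Match late-evening and day-time snackers on first-occasion time
#'
#' Bins first-eating-occasion times at `bin_width` minutes and, within each
#' bin, retains `min(n_late, n_day)` participants from each group by seeded
#' sampling without replacement, so the matched groups have identical bin
#' histograms.
#'
#' @param ids Participant identifiers.
#' @param late Logical group indicator (late-evening vs day-time).
#' @param first_time First-occasion time, minutes since midnight.
#' @param bin_width Bin width in minutes (default 30).
#' @param seed Integer seed for the subsampling.
#' @return Character vector of matched participant ids (empty, with a
#'   warning, when the distributions do not overlap).
#' @export
match_first_occasion <- function(ids, late, first_time, bin_width = 30, seed = 1) {
  stopifnot(length(ids) == length(late), length(late) == length(first_time))
  bin <- floor(first_time / bin_width)
  kept <- character()
  rng <- .seeded_rng(seed)
  for (b in sort(unique(bin))) {
    in_b <- bin == b
    g1 <- ids[in_b & late]
    g0 <- ids[in_b & !late]
    k <- min(length(g1), length(g0))
    if (k > 0) {
      kept <- c(kept, .sample_n(g1, k, rng), .sample_n(g0, k, rng))
    }
  }
  if (length(kept) == 0) warning("no overlapping first-occasion time bins; empty matched set")
  kept
}

# Local RNG helpers: evolve an RNG state without touching the global stream.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({ set.seed(seed); .Random.seed })
  env
}

.sample_n <- function(x, k, rng) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- x[sample.int(length(x), k)]
  rng$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  out
}
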