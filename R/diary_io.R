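#' @keywords internal
"_PACKAGE"

# Column schemas shared by readers, writers and the cohort generator.
.catalog_cols <- c(
  "food_id", "name", "group_l1", "group_l2", "group_l3", "nova_class",
  "healthful_direction", "is_drink", "is_alcohol", "energy_per_100g",
  "carb_g", "fat_g", "protein_g", "sugar_g"
)

.entry_cols <- c(
  "participant_id", "day_index", "clock_time", "food_id", "quantity_g",
  "energy_kcal", "carb_g", "fat_g", "protein_g", "sugar_g",
  "reported_meal_label", "day_type"
)

.meal_labels <- c("breakfast", "lunch", "dinner", "snack", "drink")
.main_meals <- c("breakfast", "lunch", "dinner")

.nutrient_cols <- c("energy_kcal", "carb_g", "fat_g", "protein_g", "sugar_g")

#' Read a food catalog
#'
#' The catalog carries, per food, a three-level food-group hierarchy, the
#' NOVA processing class (1--4), a healthfulness direction used by the diet
#' index (+1 healthful, -1 unhealthful, 0 neutral), drink/alcohol flags, and
#' nutrient densities per 100 g. Both a YAML file (a top-level `foods` list)
#' and a flat CSV are accepted.
#'
#' @param path Path to a `.yaml`/`.yml` or `.csv` catalog file.
#' @return A data.frame with one row per food, validated by
#'   [validate_catalog()].
#' @export
read_catalog <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    foods <- if (!is.null(raw$foods)) raw$foods else raw
    cat_df <- do.call(rbind, lapply(foods, function(f) {
      as.data.frame(f[.catalog_cols], stringsAsFactors = FALSE)
    }))
  } else {
    cat_df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  validate_catalog(cat_df)
}

#' Validate a food catalog
#'
#' Checks column completeness, NOVA classes in 1--4, non-negative nutrient
#' densities, direction labels in \{-1, 0, +1\}, and food-group tree
#' consistency (each level-3 group maps to a single level-2 group, each
#' level-2 group to a single level-1 group).
#'
#' @param catalog A catalog data.frame.
#' @return The catalog, invisibly unchanged, or an error.
#' @export
validate_catalog <- function(catalog) {
  missing <- setdiff(.catalog_cols, names(catalog))
  if (length(missing)) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(catalog$food_id)) stop("duplicate food_id in catalog")
  if (!all(catalog$nova_class %in% 1:4)) stop("nova_class must be in 1..4")
  if (!all(catalog$healthful_direction %in% c(-1, 0, 1))) {
    stop("healthful_direction must be -1, 0 or +1")
  }
  num <- c("energy_per_100g", "carb_g", "fat_g", "protein_g", "sugar_g")
  if (any(as.matrix(catalog[num]) < 0, na.rm = TRUE)) {
    stop("nutrient densities must be non-negative")
  }
  # tree consistency: child group determines its parent
  l3 <- unique(catalog[c("group_l3", "group_l2")])
  if (anyDuplicated(l3$group_l3)) {
    stop("group_l3 maps to more than one group_l2: tree inconsistency")
  }
  l2 <- unique(catalog[c("group_l2", "group_l1")])
  if (anyDuplicated(l2$group_l2)) {
    stop("group_l2 maps to more than one group_l1: tree inconsistency")
  }
  invisible(catalog)
}

.parse_hhmm <- function(x) {
  ok <- grepl("^([01]?[0-9]|2[0-3]):[0-5][0-9]$", x)
  mins <- rep(NA_real_, length(x))
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    mins[ok] <- vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
  }
  list(minutes = mins, ok = ok)
}

#' Read a timed food diary
#'
#' Accepts UTF-8 CSV (columns `participant_id`, `day_index`, `time` as
#' `HH:MM` or `clock_time` in minutes since midnight, `food_id`,
#' `quantity_g`, optional per-entry nutrients, `meal_label`, `day_type`) or
#' JSON-lines with the same fields. Entries are returned sorted by
#' participant, day and clock time. Nutrients absent from the file are
#' computed from `quantity_g` times the catalog density per 100 g. Rows whose
#' `food_id` is not in the catalog are kept but flagged `unidentifiable`
#' (they are removed by [apply_entry_filters()]); malformed times are
#' collected as parse problems.
#'
#' @param path Diary file (`.csv` or `.jsonl`).
#' @param catalog Catalog data.frame from [read_catalog()].
#' @return A data.frame of diary entries with an `unidentifiable` flag and a
#'   `problems` attribute (data.frame of line-numbered record errors).
#' @export
read_diary <- function(path, catalog) {
  stopifnot(file.exists(path))
  if (grepl("\\.jsonl$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE))
    nm <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) { r[setdiff(nm, names(r))] <- NA; r[nm] })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1 for CSV
  problems <- list()

  if (!"clock_time" %in% names(df)) {
    if (!"time" %in% names(df)) stop("diary needs a 'time' (HH:MM) or 'clock_time' column")
    parsed <- .parse_hhmm(df$time)
    bad <- !parsed$ok
    if (any(bad)) {
      problems[[length(problems) + 1L]] <- data.frame(
        line = df$.line[bad], field = "time",
        problem = paste0("malformed timestamp '", df$time[bad], "'")
      )
    }
    df$clock_time <- parsed$minutes
    df <- df[!bad, , drop = FALSE]
  }
  if (any(df$clock_time < 0 | df$clock_time > 1439, na.rm = TRUE)) {
    stop("clock_time out of [0, 1439]")
  }
  if ("meal_label" %in% names(df) && !"reported_meal_label" %in% names(df)) {
    df$reported_meal_label <- df$meal_label
  }
  if (!"day_type" %in% names(df)) df$day_type <- "free_living"
  stopifnot(all(df$reported_meal_label %in% .meal_labels))
  if (any(df$quantity_g <= 0, na.rm = TRUE)) stop("quantity_g must be positive")

  df$unidentifiable <- !(df$food_id %in% catalog$food_id)
  if (any(df$unidentifiable)) {
    problems[[length(problems) + 1L]] <- data.frame(
      line = df$.line[df$unidentifiable], field = "food_id",
      problem = paste0("unknown food_id '", df$food_id[df$unidentifiable], "'")
    )
  }

  idx <- match(df$food_id, catalog$food_id)
  dens <- catalog[idx, c("energy_per_100g", "carb_g", "fat_g", "protein_g", "sugar_g")]
  for (i in seq_along(.nutrient_cols)) {
    col <- .nutrient_cols[i]
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
    need <- is.na(df[[col]]) & !df$unidentifiable
    df[[col]][need] <- df$quantity_g[need] * dens[need, i] / 100
  }

  df <- df[order(df$participant_id, df$day_index, df$clock_time), , drop = FALSE]
  out <- df[c(.entry_cols, "unidentifiable")]
  rownames(out) <- NULL
  attr(out, "problems") <- if (length(problems)) {
    do.call(rbind, problems)
  } else {
    data.frame(line = integer(), field = character(), problem = character())
  }
  out
}

#' Write any tabular result as UTF-8 CSV
#'
#' Round-trip safe: `read.csv(write_table(x))` reproduces `x` field for
#' field, including unicode food names. An empty collection yields a
#' header-only file.
#'
#' @param records Data.frame to write (may have zero rows, never zero
#'   columns).
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records), ncol(records) > 0)
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Validate participants and entries as a cohort
#'
#' Produces a report (not an error) listing orphan entries referencing
#' unknown participants, twin-pair identifiers not shared by exactly two
#' participants, and out-of-range participant fields. Hard violations should
#' stop a pipeline before any analysis.
#'
#' @param participants Participant data.frame (`participant_id`, `age`,
#'   `sex`, `bmi`, `education`, `activity_level`, `twin_pair_id`,
#'   `main_meal_quality`).
#' @param entries Diary entry data.frame.
#' @return Data.frame with columns `type`, `id`, `message`; zero rows when
#'   the cohort is consistent.
#' @export
validate_cohort <- function(participants, entries) {
  report <- list()
  add <- function(type, id, message) {
    report[[length(report) + 1L]] <<- data.frame(
      type = type, id = as.character(id), message = message,
      stringsAsFactors = FALSE
    )
  }
  orphan <- setdiff(unique(entries$participant_id), participants$participant_id)
  for (id in orphan) add("orphan_entry", id, "diary entries for unknown participant")

  tp <- participants$twin_pair_id
  tp <- tp[!is.na(tp) & nzchar(tp)]
  sizes <- table(tp)
  for (id in names(sizes)[sizes != 2]) {
    add("twin_pair_cardinality", id,
        sprintf("twin_pair_id used by %d participants (must be 2)", sizes[[id]]))
  }
  bad_age <- participants$participant_id[!is.na(participants$age) & participants$age <= 0]
  for (id in bad_age) add("out_of_range", id, "age must be positive")
  bad_bmi <- participants$participant_id[!is.na(participants$bmi) & participants$bmi <= 0]
  for (id in bad_bmi) add("out_of_range", id, "bmi must be positive")
  bad_t <- entries$clock_time < 0 | entries$clock_time > 1439
  if (any(bad_t, na.rm = TRUE)) {
    add("out_of_range", paste(entries$participant_id[which(bad_t)], collapse = ","),
        "clock_time outside [0, 1439]")
  }
  if (length(report)) do.call(rbind, report) else {
    data.frame(type = character(), id = character(), message = character())
  }
}

#' Read a species-level relative-abundance matrix from TSV
#'
#' Samples in rows, species in columns, first column `sample_id`. Each row
#' must sum to 1 within 1e-6 and all entries must be non-negative.
#'
#' @param path TSV file.
#' @return Numeric matrix with sample ids as rownames.
#' @export
read_abundance <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  validate_abundance(m)
  m
}

#' @rdname read_abundance
#' @param m Abundance matrix to check.
#' @export
validate_abundance <- function(m) {
  if (any(m < 0)) stop("abundances must be non-negative")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-6)) stop("abundance rows must sum to 1 (tol 1e-6)")
  invisible(m)
}

#' Write an abundance matrix as TSV
#'
#' @param m Sample-by-species matrix, rows summing to 1.
#' @param path Output path.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
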