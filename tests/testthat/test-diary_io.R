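test_that("CSV diaries parse, sort, and fill nutrients from the catalog", {
  cat_df <- tiny_catalog()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,day_index,time,food_id,quantity_g,energy_kcal,meal_label,day_type",
    "P1,1,13:00,N1,30,,lunch,free_living",
    "P1,1,09:00,H1,150,78,breakfast,free_living",
    "P1,1,10:30,U1,50,,snack,free_living"
  ), f)
  d <- read_diary(f, cat_df)
  expect_equal(nrow(d), 3)
  expect_equal(d$clock_time, c(540, 630, 780))  # sorted by time
  # 50 g of a 535 kcal/100 g food with blank energy
  expect_equal(d$energy_kcal[d$food_id == "U1"], 50 * 535 / 100)
  expect_equal(nrow(attr(d, "problems")), 0)
})

test_that("unknown foods are flagged unidentifiable with line numbers; bad times are parse errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,day_index,time,food_id,quantity_g,energy_kcal,meal_label,day_type",
    "P1,1,09:00,NOPE,100,100,snack,free_living",
    "P1,1,25:99,H1,100,52,snack,free_living",
    "P1,1,11:00,H1,100,52,snack,free_living"
  ), f)
  d <- read_diary(f, tiny_catalog())
  expect_equal(nrow(d), 2)  # malformed-time row dropped
  expect_true(d$unidentifiable[d$food_id == "NOPE"])
  pr <- attr(d, "problems")
  expect_setequal(pr$field, c("food_id", "time"))
  expect_true(2 %in% pr$line[pr$field == "food_id"])
  # unidentifiable entries are excluded downstream
  kept <- apply_entry_filters(d, tiny_catalog())
  expect_false("NOPE" %in% kept$entries$food_id)
})

test_that("nutrient recomputation is linear in quantity", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,day_index,time,food_id,quantity_g,meal_label,day_type",
    "P1,1,09:00,U1,100,snack,free_living",
    "P2,1,09:00,U1,50,snack,free_living"
  ), f)
  d <- read_diary(f, tiny_catalog())
  full <- d[d$quantity_g == 100, ]
  half <- d[d$quantity_g == 50, ]
  for (col in c("energy_kcal", "carb_g", "fat_g", "protein_g", "sugar_g")) {
    expect_equal(half[[col]], full[[col]] / 2)
  }
})

test_that("JSONL diaries are equivalent to CSV", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"participant_id":"P1","day_index":1,"clock_time":540,"food_id":"H1","quantity_g":150,"meal_label":"breakfast","day_type":"free_living"}',
    '{"participant_id":"P1","day_index":1,"clock_time":630,"food_id":"U1","quantity_g":50,"meal_label":"snack","day_type":"free_living"}'
  ), f)
  d <- read_diary(f, tiny_catalog())
  expect_equal(nrow(d), 2)
  expect_equal(d$energy_kcal, c(150 * 52, 50 * 535) / 100)
})

test_that("write_table round-trips tables including unicode and empty ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  x <- data.frame(participant_id = c("P1", "P2"), name = c("crème brûlée", "müsli"),
                  value = c(1.25, -3), stringsAsFactors = FALSE)
  write_table(x, f)
  y <- utils::read.csv(f, stringsAsFactors = FALSE, encoding = "UTF-8")
  expect_equal(y, x)
  empty <- x[0, ]
  write_table(empty, f)
  y0 <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(y0), 0)
  expect_equal(names(y0), names(empty))
})

test_that("catalog YAML and CSV readers agree, and tree inconsistencies are caught", {
  cat_df <- tiny_catalog()
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(foods = lapply(seq_len(nrow(cat_df)), function(i) as.list(cat_df[i, ]))), fy)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_table(cat_df, fc)
  expect_equal(read_catalog(fy), read_catalog(fc))
  bad <- cat_df
  bad$group_l3[bad$food_id == "D2"] <- "coffee"  # "coffee" now under two l2 parents
  expect_error(validate_catalog(bad), "tree inconsistency")
  bad2 <- cat_df; bad2$nova_class[1] <- 5
  expect_error(validate_catalog(bad2), "nova")
})

test_that("validate_cohort reports orphans, twin cardinality and range violations", {
  parts <- mk_participants(c("P1", "P2", "P3"))
  parts$twin_pair_id <- c("T1", "T1", "T1")
  e <- mk_entries("P9", 1, 600, "H1", 52, "snack")
  rep <- validate_cohort(parts, e)
  expect_setequal(rep$type, c("orphan_entry", "twin_pair_cardinality"))
  parts$twin_pair_id <- c("T1", "T1", NA)
  e2 <- mk_entries("P1", 1, 600, "H1", 52, "snack")
  expect_equal(nrow(validate_cohort(parts, e2)), 0)
})

test_that("abundance matrices round-trip through TSV and are validated", {
  m <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("sp_a", "sp_b")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(m, f)
  expect_equal(read_abundance(f), m)
  expect_error(validate_abundance(m * 2), "sum to 1")
  expect_error(validate_abundance(matrix(c(-0.1, 1.1), 1, 2)), "non-negative")
})
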