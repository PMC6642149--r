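test_that("dark-lip rule removes lipless records only inside the exclusion boxes", {
  recs <- make_records(
    n = 6,
    record_id = c("limburg_nolip", "limburg_lip", "groningen_nolip",
                  "nijmegen_nolip", "boundary_nolip", "elsewhere_nolip"),
    latitude = c(51.0, 51.0, 53.2, 51.9, 51.2, 52.5),
    longitude = c(5.9, 5.9, 6.8, 5.9, 5.9, 4.8),
    dark_lip = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  out <- filter_records(recs)
  expect_setequal(out$colour$record_id,
                  c("limburg_lip", "boundary_nolip", "elsewhere_nolip"))
  rej <- out$rejections
  expect_identical(rej$rule[rej$record_id == "limburg_nolip"],
                   "no_dark_lip_limburg")
  expect_identical(rej$rule[rej$record_id == "groningen_nolip"],
                   "no_dark_lip_groningen")
  expect_identical(rej$rule[rej$record_id == "nijmegen_nolip"],
                   "no_dark_lip_nijmegen")
})

test_that("season cut-off, duplicates and apical views are handled", {
  recs <- make_records(
    n = 5,
    record_id = c("a", "a", "late", "apical", "banded"),
    day_number = c(10, 10, 199, 50, 60),
    view = c("lateral", "lateral", "lateral", "apical", "lateral"),
    colour = c("yellow", "yellow", "pink", "yellow", "pink"),
    banding_code = c("00000", "00000", "00300", NA, "00345"))
  out <- filter_records(recs, season_end_day = 198)
  expect_setequal(out$colour$record_id, c("a", "apical", "banded"))
  expect_setequal(out$banding$record_id, c("a", "banded"))
  expect_true("duplicate_id" %in% out$rejections$rule)
  expect_true("past_season_end" %in% out$rejections$rule)
  # the apical record is kept for colour but logged out of the banding set
  apical_rule <- out$rejections[out$rejections$record_id == "apical", ]
  expect_identical(apical_rule$rule, "apical_view")
  expect_identical(apical_rule$scope, "banding")
})

test_that("banding set excludes 'other' types and carries parsed pattern columns", {
  recs <- make_records(
    n = 4,
    record_id = c("five_fused", "other_type", "mid", "malformed"),
    banding_code = c("123(45)", "02300", "00300", "99999"))
  out <- filter_records(recs)
  expect_setequal(out$banding$record_id, c("five_fused", "mid"))
  b <- out$banding[out$banding$record_id == "five_fused", ]
  expect_identical(b$main_type, "five_banded")
  expect_identical(b$n_bands, 5L)
  expect_identical(b$n_fusions, 1L)
  expect_true("banding_type_other" %in% out$rejections$rule)
  expect_true("banding_code_missing_or_malformed" %in% out$rejections$rule)
})

test_that("colour set contains the banding set; filtering is idempotent", {
  set.seed(7)
  n <- 200
  recs <- make_records(
    n = n,
    latitude = runif(n, 50.8, 53.4), longitude = runif(n, 3.5, 7.0),
    day_number = sample(1:260, n, TRUE),
    colour = sample(c("yellow", "pink", "brown"), n, TRUE),
    banding_code = sample(c("00000", "00300", "00345", "12345", "123(45)",
                            "02300", NA), n, TRUE),
    view = sample(c("lateral", "apical"), n, TRUE, prob = c(0.85, 0.15)),
    dark_lip = runif(n) < 0.9,
    record_id = sample(sprintf("R%03d", 1:180), n, TRUE))
  out <- filter_records(recs)
  expect_true(all(out$banding$record_id %in% out$colour$record_id))
  expect_false(any(duplicated(out$colour$record_id)))
  expect_false(any(duplicated(out$banding$record_id)))
  # record-scope attrition reconciles exactly
  n_rec_rejected <- sum(out$rejections$scope == "record")
  expect_equal(nrow(out$colour) + n_rec_rejected, n)
  # idempotence on the surviving colour set
  again <- filter_records(out$colour[names(recs)])
  expect_identical(again$colour$record_id, out$colour$record_id)
  expect_identical(nrow(again$rejections[again$rejections$scope == "record", ]), 0L)
})

test_that("observation CSV writer and reader round-trip day numbers", {
  recs <- make_records(n = 3, day_number = c(1L, 45L, 198L),
                       banding_code = c("00000", NA, "00345"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(recs, path)
  back <- read_observations(path)
  expect_identical(back$day_number, recs$day_number)
  expect_identical(back$record_id, recs$record_id)
  expect_identical(back$banding_code, recs$banding_code)
  expect_identical(back$dark_lip, recs$dark_lip)
})

test_that("record validation rejects bad coordinates and levels", {
  expect_error(make_records(latitude = 95), "latitude")
  expect_error(make_records(colour = "green"), "colour")
  expect_error(make_records(view = "top"), "view")
  expect_error(make_records(day_number = 0), "day_number")
})
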