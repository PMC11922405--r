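test_that("a well-formed CSV round-trips into typed records", {
  path <- write_fixture_csv()
  reg <- read_registry(path)
  expect_s3_class(reg, "pain_registry")
  expect_equal(nrow(reg$patients), 3)
  expect_type(reg$patients$age, "integer")
  expect_s3_class(reg$patients$sex, "factor")
  expect_equal(reg$patients$patient_id, c("A1", "A2", "A3"))
  expect_equal(reg$parse_report$n_unparseable, 0L)
})

test_that("unparseable cells become missing with a warning, never coerced", {
  rows <- data.frame(patient_id = "B1", anesthesia_primary = "GA",
                     pnb_mode = "none", worst_pain = "6", least_pain = "2",
                     time_severe_pct = "30", age = "seventeen")
  path <- write_fixture_csv(rows = rows)
  expect_warning(reg <- read_registry(path), "unparseable")
  expect_true(is.na(reg$patients$age))
  expect_equal(reg$parse_report$n_unparseable, 1L)
})

test_that("missing mandatory columns raise a schema error; unknown columns warn", {
  rows <- data.frame(patient_id = "C1", anesthesia_primary = "GA",
                     pnb_mode = "none", least_pain = "2",
                     time_severe_pct = "30")
  expect_error(read_registry(write_fixture_csv(rows = rows)),
               "worst_pain")
  rows2 <- data.frame(patient_id = "C2", anesthesia_primary = "GA",
                      pnb_mode = "none", worst_pain = "5", least_pain = "1",
                      time_severe_pct = "20", shoe_size = "42")
  expect_warning(read_registry(write_fixture_csv(rows = rows2)),
                 "shoe_size")
})

test_that("subgroup allocation is total and deterministic on the input grid", {
  expect_equal(allocate_subgroup("SA", "continuous"), "SA&PNBc")
  expect_equal(allocate_subgroup("GA", "none"), "GA-o")
  expect_equal(allocate_subgroup("GA+SA", "single"), "excluded:failed_SA")
  expect_equal(allocate_subgroup("GA+epidural", "none"), "excluded:epidural")
  expect_equal(allocate_subgroup("SA", NA), "excluded:incomplete_anesthesia")

  grid <- expand.grid(ap = c("GA", "SA", "GA+SA", "GA+epidural"),
                      pm = c("none", "single", "continuous"),
                      stringsAsFactors = FALSE)
  out <- allocate_subgroup(grid$ap, grid$pm)
  expect_false(any(is.na(out)))
  non_excl <- out[!grepl("^excluded:", out)]
  expect_setequal(unique(non_excl), subgroup_levels())
  # deterministic
  expect_identical(out, allocate_subgroup(grid$ap, grid$pm))
})

test_that("plausibility filter enforces age/weight bounds inclusively and conserves records", {
  pts <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    age = c(17L, 18L, 45L, 60L),
    weight = c(70, 34, 30, 80),
    stringsAsFactors = FALSE)
  adm <- data.frame(patient_id = c("P4", "P4"),
                    drug = c("morphine", "morphine"),
                    route = c("oral", "oral"),
                    dose_mg = c(100000, 10), stringsAsFactors = FALSE)
  reg <- structure(list(patients = pts, administrations = adm,
                        parse_report = list()), class = "pain_registry")
  res <- plausibility_filter(reg, dose_bounds = c(morphine = 1000))
  expect_equal(res$registry$patients$patient_id, c("P2", "P4"))
  expect_equal(unname(res$exclusion_log["age<18"]), 1L)
  expect_equal(unname(res$exclusion_log["weight<34"]), 1L)
  # conservation: kept + excluded == input
  expect_equal(nrow(res$registry$patients) + sum(res$exclusion_log),
               nrow(pts))
  # implausible administration dropped, record kept
  expect_equal(nrow(res$dropped_administrations), 1)
  expect_equal(res$registry$administrations$dose_mg, 10)
  expect_true("P4" %in% res$registry$patients$patient_id)
  # idempotence
  res2 <- plausibility_filter(res$registry, dose_bounds = c(morphine = 1000))
  expect_identical(res2$registry$patients, res$registry$patients)
  expect_equal(sum(res2$exclusion_log), 0)
})

test_that("complete-case subsetting counts missingness and is idempotent", {
  d <- data.frame(worst = c(1:8, NA, 5), least = 1:10,
                  time = c(NA, 2:9, NA))
  kept <- complete_case_subset(d, c("worst", "least", "time"))
  expect_equal(nrow(kept), 7)
  expect_equal(attr(kept, "missingness"),
               c(worst = 1L, least = 0L, time = 2L))
  again <- complete_case_subset(kept, c("worst", "least", "time"))
  expect_equal(nrow(again), nrow(kept))
  expect_equal(nrow(complete_case_subset(d, character(0))), 10)
  expect_error(complete_case_subset(d, "nonexistent"), "unknown variable")
})
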