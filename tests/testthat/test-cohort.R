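test_that("fracture cohort assignment handles single, multiple and excluded sites", {
  map <- fracture_code_map()
  expect_identical(assign_fracture_cohort("S72.0", map), "hip")
  expect_identical(assign_fracture_cohort(c("S72.0", "S72.1"), map), "hip")
  expect_identical(assign_fracture_cohort("S22.0", map), "vertebrae")
  expect_identical(assign_fracture_cohort("S52.5", map), "nvnh")
  expect_identical(assign_fracture_cohort(c("S72.0", "S22.0"), map),
                   "excluded_multi_site")
  # skull fracture alone carries no eligible site
  expect_identical(assign_fracture_cohort("S02.1", map), "excluded_no_site")
  # excluded-site codes are ignored when an eligible site is present
  expect_identical(assign_fracture_cohort(c("S02.1", "S72.0"), map), "hip")
  expect_warning(out <- assign_fracture_cohort("Z99.9", map), "unmapped")
  expect_identical(out, "excluded_no_site")
  expect_error(assign_fracture_cohort(character(0), map), "non-empty")
})

test_that("eligibility enforces age and the 12-month visit rules inclusively", {
  idx <- list(admission_date = 0, discharge_date = 10)
  enc <- data.frame(date = c(-365, 375))
  el <- check_eligibility(list(birth_year = 2017 - 70), enc, idx)
  expect_true(el$eligible)  # boundaries exactly at admission-365 / discharge+365

  el <- check_eligibility(list(birth_year = 2017 - 49), enc, idx)
  expect_false(el$eligible)
  expect_true("age_under_50" %in% el$reasons)

  el <- check_eligibility(list(birth_year = 2017 - 70),
                          data.frame(date = c(-364, 375)), idx)
  expect_true("no_baseline_visit" %in% el$reasons)
  el <- check_eligibility(list(birth_year = 2017 - 70),
                          data.frame(date = c(-365, 100)), idx)
  expect_true("no_followup_visit" %in% el$reasons)
  expect_error(check_eligibility(list(birth_year = NA), enc, idx), "birth year")
})

test_that("build_cohort constructs 365-day windows clear of the index stay", {
  ds <- list(
    patients = data.frame(patient_id = "P1", sex = "female",
                          birth_year = 1940, smoking_index = 0),
    encounters = data.frame(patient_id = "P1", date = c(-400L, 400L),
                            setting = "outpatient"),
    hospitalizations = data.frame(
      patient_id = "P1", admission_date = 0L, discharge_date = 20L,
      route = "home", admission_type = "emergency",
      discharge_destination = "home_same_hospital_checkup",
      outcome = "healed", fracture_codes = "S72.0",
      n_meds_at_discharge = 1L, stringsAsFactors = FALSE),
    diagnoses = data.frame(patient_id = character(0), date = integer(0),
                           code = character(0)))
  built <- build_cohort(ds)
  expect_identical(nrow(built$cohort), 1L)
  expect_identical(nrow(built$exclusions), 0L)
  co <- built$cohort
  expect_identical(co$baseline_end - co$baseline_start + 1L, 365L)
  expect_identical(co$followup_end - co$followup_start + 1L, 365L)
  expect_lt(co$baseline_end, co$index_admission)
  expect_gt(co$followup_start, co$index_discharge)

  # empty dataset
  empty <- build_cohort(list(hospitalizations = NULL))
  expect_identical(nrow(empty$cohort), 0L)
})

test_that("cohort labels partition eligible patients; exclusions carry reasons", {
  cfg <- default_generator_config(n_patients = 3000, seed = 11)
  ds <- generate_dataset(cfg)
  built <- build_cohort(ds)
  co <- built$cohort
  expect_identical(nrow(co) + nrow(built$exclusions), 3000L)
  expect_true(all(co$fracture_cohort %in% c("hip", "vertebrae", "nvnh")))
  expect_true(all(nchar(built$exclusions$reasons) > 0))
  # cohort fractions near the configured mix (binomial 3 SE)
  for (g in names(cfg$cohort_mix)) {
    p_hat <- mean(co$fracture_cohort == g)
    expect_within_3se(p_hat, cfg$cohort_mix[[g]], nrow(co))
  }
})

test_that("an ineligible or multi-site patient lands in the exclusion log", {
  ds <- list(
    patients = data.frame(patient_id = c("P1", "P2"), sex = "female",
                          birth_year = c(1990, 1940), smoking_index = 0),
    encounters = data.frame(patient_id = c("P1", "P1", "P2", "P2"),
                            date = c(-400L, 400L, -400L, 400L),
                            setting = "outpatient"),
    hospitalizations = data.frame(
      patient_id = c("P1", "P2"), admission_date = 0L, discharge_date = 5L,
      route = "home", admission_type = "emergency",
      discharge_destination = "home_same_hospital_checkup",
      outcome = "healed", fracture_codes = c("S72.0", "S72.0;S22.0"),
      n_meds_at_discharge = 0L, stringsAsFactors = FALSE),
    diagnoses = NULL)
  built <- build_cohort(ds)
  expect_identical(nrow(built$cohort), 0L)
  expect_match(built$exclusions$reasons[built$exclusions$patient_id == "P1"],
               "age_under_50")
  expect_match(built$exclusions$reasons[built$exclusions$patient_id == "P2"],
               "multi_site_fracture")
})
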