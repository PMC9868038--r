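test_that("exposure timelines stockpile overlaps and split at 60-day gaps", {
  tl <- build_exposure_timeline(
    make_fills(c(0, 20), "bisphosphonate", 30))
  expect_equal(tl$start, 0)
  expect_equal(tl$end, 60)  # second fill shifted to start at day 30

  tl <- build_exposure_timeline(
    make_fills(c(0, 100), "bisphosphonate", 30))
  expect_equal(tl$start, c(0, 100))
  expect_equal(tl$end, c(30, 130))  # 70-day gap >= 60 is not bridged

  tl <- build_exposure_timeline(
    make_fills(c(0, 59), "bisphosphonate", 30))
  expect_equal(nrow(tl), 1)  # 29-day gap < 60 bridged into [0, 89)

  # missing supply resolved from the drug-level default (one zoledronic
  # acid infusion covers a year)
  f <- make_fills(0, "bisphosphonate", NA)
  f$drug_code <- "zoledronic_acid"
  tl <- build_exposure_timeline(f)
  expect_equal(tl$end, 365)
})

test_that("first regimen pools classes filled within 14 days of discharge", {
  r <- identify_first_regimen(make_fills(1, "active_vitamin_D3", 30), 0)
  expect_identical(r$classes, "active_vitamin_D3")
  expect_identical(r$start_date, 1)

  r <- identify_first_regimen(
    make_fills(c(1, 10), c("bisphosphonate", "active_vitamin_D3"), 30), 0)
  expect_identical(r$classes, c("active_vitamin_D3", "bisphosphonate"))

  # first fill after the window: no regimen, though follow-up treated
  expect_null(identify_first_regimen(make_fills(20, "bisphosphonate", 30), 0))
  r <- identify_first_regimen(
    make_fills(c(14, 15), c("bisphosphonate", "active_vitamin_D3"), 30), 0)
  expect_identical(r$classes, "bisphosphonate")
})

test_that("discontinuation needs a 60-day lapse before follow-up end", {
  reg <- list(classes = "bisphosphonate", start_date = 0)
  tl <- build_exposure_timeline(make_fills(0, "bisphosphonate", 30))
  d <- detect_discontinuation(tl, reg, followup_end = 366)
  expect_true(d$discontinued)
  expect_equal(d$date, 30)
  expect_equal(d$days_from_initiation, 30)

  # refill 50 days after supply end: the gap clock resets
  tl <- build_exposure_timeline(make_fills(c(0, 80), "bisphosphonate", 30))
  d <- detect_discontinuation(tl, reg, followup_end = 366)
  expect_true(d$discontinued)
  expect_equal(d$date, 110)  # exposure now ends at day 110, not 30

  # coverage through follow-up end: persistent
  tl <- build_exposure_timeline(make_fills(seq(0, 360, 30), "bisphosphonate", 30))
  expect_false(detect_discontinuation(tl, reg, followup_end = 366)$discontinued)

  # boundary: uncovered tail of exactly 59 vs 60 days
  tl <- build_exposure_timeline(make_fills(0, "bisphosphonate", 307))
  expect_false(detect_discontinuation(tl, reg, followup_end = 366)$discontinued)
  tl <- build_exposure_timeline(make_fills(0, "bisphosphonate", 306))
  expect_true(detect_discontinuation(tl, reg, followup_end = 366)$discontinued)
})

test_that("first post-discontinuation fill decides switch versus restart", {
  reg <- list(classes = "bisphosphonate", start_date = 1)
  fills <- make_fills(c(1, 120), c("bisphosphonate", "teriparatide"),
                      c(30, 28))
  disc <- list(discontinued = TRUE, date = 31, days_from_initiation = 30)
  sw <- classify_switch_restart(fills, disc, reg, followup_end = 367)
  expect_identical(sw$kind, "switch")
  expect_identical(sw$classes, "teriparatide")
  expect_equal(sw$days_from_discontinuation, 89)
  expect_equal(sw$days_from_initiation, 120 - 1)

  # same class refilled after a 70-day gap is a restart
  fills <- make_fills(c(1, 101), "active_vitamin_D3", 30)
  reg2 <- list(classes = "active_vitamin_D3", start_date = 1)
  disc2 <- list(discontinued = TRUE, date = 31, days_from_initiation = 30)
  sw <- classify_switch_restart(fills, disc2, reg2, followup_end = 367)
  expect_identical(sw$kind, "restart")

  # no fills after discontinuation
  expect_null(classify_switch_restart(make_fills(1, "bisphosphonate", 30),
                                      disc, reg, followup_end = 367))
})

test_that("augmentation requires 60 days of combined use outside the regimen window", {
  reg <- list(classes = "bisphosphonate", start_date = 0)
  tl <- rbind(
    data.frame(drug_class = "bisphosphonate", start = 0, end = 90),
    data.frame(drug_class = "active_vitamin_D3", start = 20, end = 90))
  aug <- detect_augmentation(tl, reg)
  expect_identical(aug$classes, "active_vitamin_D3")
  expect_equal(aug$date, 20)
  expect_equal(aug$days_from_initiation, 20)

  # 59-day overlap fails
  tl59 <- rbind(
    data.frame(drug_class = "bisphosphonate", start = 0, end = 90),
    data.frame(drug_class = "active_vitamin_D3", start = 31, end = 90))
  expect_null(detect_augmentation(tl59, reg))

  # a class starting inside the 14-day regimen window is not augmentation
  tl14 <- rbind(
    data.frame(drug_class = "bisphosphonate", start = 0, end = 120),
    data.frame(drug_class = "active_vitamin_D3", start = 10, end = 120))
  expect_null(detect_augmentation(tl14, reg))
})

test_that("phase classification separates baseline, inpatient and follow-up", {
  asn <- make_cohort_row(discharge = 10)
  ph <- classify_phase_treatment(make_fills(numeric(0), character(0),
                                            numeric(0)), asn)
  expect_false(ph$baseline_treated || ph$index_treated || ph$followup_treated)

  fills <- rbind(
    make_fills(-300, "bisphosphonate", 30),
    make_fills(4, "active_vitamin_D3", 10, setting = "inpatient"),
    make_fills(12, "active_vitamin_D3", 30))
  ph <- classify_phase_treatment(fills, asn)
  expect_true(ph$baseline_treated && ph$index_treated && ph$followup_treated)
  expect_equal(ph$days_from_treatment_start_to_admission, 300)
  expect_equal(ph$days_from_admission_to_initiation, 4)
  expect_equal(ph$days_from_discharge_to_initiation, 2)
  expect_equal(ph$baseline_days_with_medication, 30)
  expect_equal(ph$inpatient_days_with_medication, 7)  # days 4..10 of the stay

  fills$patient_id <- c("P1", "P2", "P1")
  expect_error(classify_phase_treatment(fills, asn), "multiple patients")
})

test_that("event dates are translation invariant", {
  set.seed(42)
  for (rep in 1:25) {
    f <- random_fill_history()
    shift <- 37
    co0 <- make_cohort_row(discharge = 0)
    co1 <- make_cohort_row(discharge = 0)
    co1[, c("index_admission", "index_discharge", "baseline_start",
            "baseline_end", "followup_start", "followup_end")] <-
      co1[, c("index_admission", "index_discharge", "baseline_start",
              "baseline_end", "followup_start", "followup_end")] + shift
    fs <- f
    fs$date <- fs$date + shift
    a0 <- analyze_treatment(f, co0)
    a1 <- analyze_treatment(fs, co1)
    expect_identical(a1$discontinued, a0$discontinued)
    expect_identical(a1$switch_restart, a0$switch_restart)
    expect_identical(a1$augmented, a0$augmented)
    expect_equal(a1$discontinuation_date,
                 a0$discontinuation_date + ifelse(is.na(a0$discontinuation_date), NA, shift))
    expect_equal(a1$mpr, a0$mpr)
  }
})

test_that("analyze_treatment agrees with the reference interval operations", {
  set.seed(11)
  for (rep in 1:60) {
    f <- random_fill_history()
    co <- make_cohort_row()
    row <- analyze_treatment(f, co)
    fu <- f[f$date >= 0 & f$date <= 365, , drop = FALSE]
    reg <- identify_first_regimen(fu, 0)
    if (is.null(reg)) {
      expect_true(is.na(row$discontinued))
      next
    }
    if (!any(f$date >= 1 & f$date <= 365)) next  # not follow-up treated
    tl <- build_exposure_timeline(fu, bridge_gap = 60)
    d <- detect_discontinuation(tl, reg, 366)
    expect_identical(row$discontinued, d$discontinued)
    if (d$discontinued) {
      expect_equal(row$discontinuation_date, d$date)
      sw <- classify_switch_restart(fu, d, reg, 366)
      expect_identical(row$switch_restart,
                       if (is.null(sw)) NA_character_ else sw$kind)
    }
    aug <- detect_augmentation(tl, reg)
    expect_identical(row$augmented, !is.null(aug))
    per <- observation_period(min(f$date[f$date >= 1 & f$date <= 365]), 366)
    expect_equal(row$mpr, compute_mpr(fu[fu$date >= 1, , drop = FALSE], per))
  }
})

test_that("event classification matches the day-grid oracle on random histories", {
  set.seed(202)
  for (rep in 1:150) {
    f <- random_fill_history()
    co <- make_cohort_row()
    row <- analyze_treatment(f, co)
    oc <- oracle_patient(f$date, f$drug_class, f$days_supply, 0, 365)
    expect_identical(row$followup_treated, oc$followup_treated)
    if (!oc$followup_treated) next
    expect_equal(row$mpr, oc$mpr, tolerance = 1e-12)
    expect_identical(row$first_regimen %in% NA, oc$first_regimen %in% NA)
    if (is.na(oc$first_regimen)) next
    expect_identical(row$first_regimen, oc$first_regimen)
    expect_identical(row$discontinued, oc$discontinued)
    if (oc$discontinued) {
      expect_equal(row$discontinuation_date, oc$disc_date)
      expect_identical(row$switch_restart, oc$sr_kind)
    }
    expect_identical(row$augmented, oc$augmented)
    if (isTRUE(oc$augmented))
      expect_equal(row$regimen_start + row$days_to_augmentation, oc$aug_date)
  }
})
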