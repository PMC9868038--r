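# shared fixtures built in code

# one-patient cohort row with admission day 0 and the given discharge day
make_cohort_row <- function(patient_id = "P1", discharge = 0) {
  data.frame(patient_id = patient_id, index_admission = 0L,
             index_discharge = as.integer(discharge),
             fracture_cohort = "hip",
             baseline_start = -365L, baseline_end = -1L,
             followup_start = as.integer(discharge + 1),
             followup_end = as.integer(discharge + 365),
             stringsAsFactors = FALSE)
}

make_fills <- function(dates, classes, supplies, setting = "outpatient",
                       patient_id = "P1") {
  m <- length(dates)
  data.frame(patient_id = rep_len(patient_id, m), date = dates,
             drug_class = rep_len(classes, m),
             days_supply = rep_len(supplies, m),
             setting = rep_len(setting, m), stringsAsFactors = FALSE)
}

# memoised large calibration run shared by the acceptance tests
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function(n = 100000, seed = 42) {
  key <- paste0("r", n, "_", seed)
  if (is.null(.acceptance_cache[[key]])) {
    cfg <- default_generator_config(n_patients = n, seed = seed)
    .acceptance_cache[[key]] <- run_pipeline(cfg)
  }
  .acceptance_cache[[key]]
}

# three-binomial-SE band check against a published percentage
expect_within_3se <- function(p_hat, p_ref, n) {
  se <- sqrt(p_hat * (1 - p_hat) / n)
  testthat::expect_lt(abs(p_hat - p_ref), 3 * se)
}
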