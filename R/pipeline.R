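#' Run the full analysis pipeline
#'
#' Generates (or accepts) a claims dataset, then runs cohort construction,
#' baseline profiling, treatment-pattern and adherence analysis, and the
#' logistic model of treatment receipt, returning every analogue of the
#' study's descriptive tables plus run metadata. Deterministic given the
#' configuration seed.
#'
#' @param config a generator configuration, or a YAML path.
#' @param dataset optional pre-built dataset (skips generation).
#' @param out_dir optional directory; when given, all result tables are
#'   written as CSV/JSON there.
#' @return list of class `osteoclaims_result`: `cohort`, `exclusions`,
#'   `profiles`, `patterns` (per-patient analysis), `baseline_summary`,
#'   `treatment_summary`, `regimen_summary`, `episode_summary`,
#'   `adl_summary`, `effects`, `auc`, `fit`, `meta`.
#' @export
run_pipeline <- function(config, dataset = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_generator_config(config)
  config <- validate_generator_config(unclass(config))
  if (is.null(dataset)) dataset <- generate_dataset(config)

  fmap <- fracture_code_map()
  cmap <- charlson_map()
  built <- build_cohort(dataset, fmap, index_year = config$index_year)
  cohort <- built$cohort
  profiles <- build_baseline_profiles(dataset, cohort, cmap, fmap,
                                      index_year = config$index_year)
  patterns <- analyze_treatment(
    dataset$dispensations, cohort,
    supply_rules = config$supply_days_by_class,
    gap_days = config$gap_days,
    regimen_window_days = config$regimen_window_days,
    min_overlap_days = config$min_overlap_days,
    mpr_threshold = config$mpr_threshold)

  fit <- NULL; effects <- NULL; auc <- NA_real_
  if (nrow(cohort) > 0) {
    enc <- encode_design(profiles)
    outcome <- as.integer(patterns$followup_treated[enc$kept])
    if (length(unique(outcome)) == 2) {
      fit <- tryCatch(fit_logistic(enc$frame, outcome), error = function(e) NULL)
      if (!is.null(fit)) {
        effects <- estimate_effects(fit)
        auc <- compute_auc(stats::fitted(fit$glm), outcome)
      }
    }
  }

  res <- structure(list(
    cohort = cohort, exclusions = built$exclusions, profiles = profiles,
    patterns = patterns,
    baseline_summary = summarize_baseline(profiles),
    treatment_summary = summarize_treatment(patterns, profiles,
                                            threshold = config$mpr_threshold),
    regimen_summary = summarize_regimens(patterns),
    episode_summary = summarize_episodes(patterns),
    adl_summary = if (nrow(dataset$adl) > 0) summarize_adl(dataset$adl) else NULL,
    effects = effects, auc = auc, fit = fit,
    meta = list(seed = config$seed, n_patients = config$n_patients,
                gap_days = config$gap_days,
                mpr_threshold = config$mpr_threshold,
                version = as.character(utils::packageVersion("osteoclaims")))),
    class = "osteoclaims_result")

  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("cohort", "exclusions", "profiles", "patterns",
               "baseline_summary", "treatment_summary", "regimen_summary",
               "episode_summary", "adl_summary", "effects"))
    if (!is.null(res[[nm]]))
      utils::write.csv(res[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  summ <- c(list(auc = res$auc), res$meta)
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# descriptive rows share one schema so numeric and categorical summaries
# stack into a single table
describe_numeric <- function(x, what) {
  x <- x[!is.na(x)]
  data.frame(measure = what, level = NA_character_, n = length(x),
             pct = NA_real_,
             mean = if (length(x)) mean(x) else NA_real_,
             sd = if (length(x) > 1) stats::sd(x) else
                  if (length(x) == 1) 0 else NA_real_,
             median = if (length(x)) stats::median(x) else NA_real_,
             min = if (length(x)) min(x) else NA_real_,
             max = if (length(x)) max(x) else NA_real_,
             stringsAsFactors = FALSE)
}

describe_categorical <- function(x, what, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(x))
  tab <- table(factor(x, levels = levels))
  data.frame(measure = what, level = levels, n = as.integer(tab),
             pct = if (length(x)) 100 * as.integer(tab) / length(x)
                   else rep(NA_real_, length(levels)),
             mean = NA_real_, sd = NA_real_, median = NA_real_,
             min = NA_real_, max = NA_real_,
             stringsAsFactors = FALSE)
}

#' Descriptive summaries (mean/SD/median + n (%) tables)
#'
#' `summarize_descriptives()` produces the continuous descriptives
#' (mean, SD, median, min, max) for a numeric vector and percentage
#' distributions for a categorical one, overall and per fracture cohort.
#'
#' @param x numeric or character vector.
#' @param by optional cohort factor of the same length.
#' @param what label for the summary rows.
#' @export
summarize_descriptives <- function(x, by = NULL, what = "value") {
  f <- if (is.numeric(x)) describe_numeric else describe_categorical
  out <- cbind(cohort = "overall", f(x, what))
  if (!is.null(by))
    for (g in sort(unique(by)))
      out <- rbind(out, cbind(cohort = g, f(x[by == g], what)))
  out
}

summarize_baseline <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0) return(NULL)
  by <- profiles$fracture_cohort
  rbind(
    summarize_descriptives(profiles$age_years, by, "age_years"),
    summarize_descriptives(profiles$age_band, by, "age_band"),
    summarize_descriptives(profiles$sex, by, "sex"),
    summarize_descriptives(profiles$los_days, by, "length_of_stay"),
    summarize_descriptives(profiles$prior_dx, by, "prior_dx"),
    summarize_descriptives(profiles$cci_score, by, "cci_score"),
    summarize_descriptives(profiles$cci_band, by, "cci_band"),
    summarize_descriptives(profiles$smoking_index, by, "smoking_index"),
    summarize_descriptives(profiles$route, by, "route"),
    summarize_descriptives(profiles$admission_type, by, "admission_type"))
}

summarize_treatment <- function(patterns, profiles, threshold = 0.8) {
  if (is.null(patterns) || nrow(patterns) == 0) return(NULL)
  by <- profiles$fracture_cohort[match(patterns$patient_id,
                                       profiles$patient_id)]
  pct_flag <- function(flag, what) {
    d <- describe_categorical(ifelse(flag, "yes", "no"), what, c("no", "yes"))
    cbind(cohort = "overall", d)
  }
  out <- rbind(
    summarize_descriptives(ifelse(patterns$baseline_treated, "yes", "no"),
                           by, "baseline_treated"),
    summarize_descriptives(ifelse(patterns$index_treated, "yes", "no"),
                           by, "index_treated"),
    summarize_descriptives(ifelse(patterns$followup_treated, "yes", "no"),
                           by, "followup_treated"))
  trt <- patterns[patterns$followup_treated, , drop = FALSE]
  byt <- by[patterns$followup_treated]
  if (nrow(trt)) {
    out <- rbind(out,
      summarize_descriptives(ifelse(trt$persistent, "yes", "no"), byt,
                             "persistent"),
      summarize_descriptives(trt$mpr, byt, "mpr"),
      cbind(cohort = "overall",
            describe_categorical(trt$mpr_bin, "mpr_bin", mpr_bin_levels())),
      summarize_descriptives(ifelse(trt$adherent, "yes", "no"), byt,
                             "adherent"))
  }
  out
}

summarize_regimens <- function(patterns) {
  if (is.null(patterns) || nrow(patterns) == 0) return(NULL)
  trt <- patterns[patterns$followup_treated & !is.na(patterns$first_regimen), ,
                  drop = FALSE]
  if (nrow(trt) == 0) return(NULL)
  describe_categorical(trt$first_regimen, "first_regimen")
}

summarize_episodes <- function(patterns) {
  if (is.null(patterns) || nrow(patterns) == 0) return(NULL)
  trt <- patterns[patterns$followup_treated, , drop = FALSE]
  if (nrow(trt) == 0) return(NULL)
  disc <- trt[!is.na(trt$discontinued) & trt$discontinued, , drop = FALSE]
  n_trt <- nrow(trt)
  n_disc <- nrow(disc)
  n_sr <- sum(!is.na(disc$switch_restart))
  n_aug <- sum(trt$augmented, na.rm = TRUE)
  rate_row <- function(what, k, denom) {
    out <- describe_numeric(numeric(0), what)
    out$n <- k
    out$pct <- if (denom) 100 * k / denom else NA_real_
    out
  }
  rbind(
    rate_row("discontinued", n_disc, n_trt),
    rate_row("switch_restart_among_discontinued", n_sr, n_disc),
    rate_row("augmented", n_aug, n_trt),
    describe_numeric(disc$days_to_discontinuation, "days_to_discontinuation"),
    describe_numeric(trt$days_to_switch_restart, "days_to_switch_restart"),
    describe_numeric(trt$days_to_augmentation, "days_to_augmentation"))
}
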