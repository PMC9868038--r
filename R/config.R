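#' Generator configuration
#'
#' The synthetic-claims generator is driven by a single configuration list
#' holding the cohort mix, covariate marginals, per-category treatment
#' log-odds, phase treatment rates, regimen mixes, the MPR decile histogram,
#' episode rates and per-class days'-supply defaults. The shipped default
#' (`inst/extdata/default_paper.yaml`) is calibrated to the published
#' hospital-database study of osteoporotic-fracture treatment patterns, so a
#' pipeline run over generated data recovers the published marginal rates
#' and odds ratios.
#'
#' Categorical mixes whose entries sum to within 0.002 of 1 (printed
#' percentages carry rounding error) are renormalized exactly; anything
#' further off is a configuration error naming the offending mix.
#'
#' @param path path to a YAML configuration file.
#' @param n_patients,seed optional overrides applied after reading.
#' @return a validated configuration list of class `"osteoclaims_config"`.
#' @export
read_generator_config <- function(path, n_patients = NULL, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(n_patients)) cfg$n_patients <- n_patients
  if (!is.null(seed)) cfg$seed <- seed
  validate_generator_config(cfg)
}

#' @rdname read_generator_config
#' @export
default_generator_config <- function(n_patients = 1000, seed = 20160201) {
  path <- system.file("extdata", "default_paper.yaml", package = "osteoclaims")
  read_generator_config(path, n_patients = n_patients, seed = seed)
}

#' Validate and normalize a generator configuration
#'
#' Checks the invariants (probabilities in \[0, 1\], mixes summing to 1,
#' `n_patients >= 0`, strictly positive days' supply) and renormalizes every
#' categorical mix exactly. Returns the normalized configuration.
#'
#' @param cfg a configuration list as read from YAML or built in code.
#' @export
validate_generator_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$n_patients) || cfg$n_patients < 0)
    stop("configuration error: n_patients must be >= 0")
  cfg$n_patients <- as.integer(cfg$n_patients)
  if (is.null(cfg$seed)) stop("configuration error: seed is required")
  cfg$seed <- as.integer(cfg$seed)

  cfg$cohort_mix <- check_mix(cfg$cohort_mix, "cohort_mix")
  for (nm in names(cfg$covariate_marginals))
    cfg$covariate_marginals[[nm]] <-
      check_mix(cfg$covariate_marginals[[nm]], paste0("covariate_marginals$", nm))
  for (ph in names(cfg$regimen_mix))
    cfg$regimen_mix[[ph]] <-
      check_mix(cfg$regimen_mix[[ph]], paste0("regimen_mix$", ph),
                renorm_any = TRUE)
  cfg$mpr_histogram <- check_mix(cfg$mpr_histogram, "mpr_histogram")
  cfg$switch_class_mix <- check_mix(cfg$switch_class_mix, "switch_class_mix",
                                    renorm_any = TRUE)
  cfg$augment_class_mix <- check_mix(cfg$augment_class_mix, "augment_class_mix",
                                     renorm_any = TRUE)
  for (nm in names(cfg$adl_marginals))
    cfg$adl_marginals[[nm]] <-
      check_mix(cfg$adl_marginals[[nm]], paste0("adl_marginals$", nm))

  for (nm in c("target_followup_rate", "baseline_treatment_rate",
               "discontinuation_rate", "switch_restart_given_disc",
               "restart_share", "augmentation_rate", "adherent_rate_treated")) {
    v <- cfg[[nm]]
    if (is.null(v) || v < 0 || v > 1)
      stop("configuration error: ", nm, " must be a probability in [0, 1]")
  }
  itr <- unlist(cfg$index_treatment_rate_by_cohort)
  if (any(itr < 0 | itr > 1))
    stop("configuration error: index_treatment_rate_by_cohort out of [0, 1]")
  if (!setequal(names(itr), names(cfg$cohort_mix)))
    stop("configuration error: index_treatment_rate_by_cohort must name every cohort")
  cfg$index_treatment_rate_by_cohort <- itr

  sup <- unlist(cfg$supply_days_by_class)
  if (any(sup <= 0))
    stop("configuration error: supply_days_by_class must be strictly positive")
  cfg$supply_days_by_class <- sup

  cfg$treatment_log_odds <- lapply(cfg$treatment_log_odds, unlist)
  if (is.null(cfg$gap_days)) cfg$gap_days <- 60
  if (is.null(cfg$regimen_window_days)) cfg$regimen_window_days <- 14
  if (is.null(cfg$min_overlap_days)) cfg$min_overlap_days <- 60
  if (is.null(cfg$mpr_threshold)) cfg$mpr_threshold <- 0.80
  if (is.null(cfg$index_year)) cfg$index_year <- 2017
  if (is.null(cfg$study_window)) cfg$study_window <- c(-730, 730)
  cfg$study_window <- as.numeric(unlist(cfg$study_window))

  class(cfg) <- "osteoclaims_config"
  cfg
}

# renormalize a categorical mix; mixes are accepted when they sum to within
# 1e-3 of 1 unless renorm_any (multi-response class frequencies can sum > 1)
check_mix <- function(mix, what, renorm_any = FALSE) {
  x <- unlist(mix)
  if (is.null(x) || length(x) == 0)
    stop("configuration error: ", what, " is missing or empty")
  if (any(!is.finite(x)) || any(x < 0))
    stop("configuration error: ", what, " has entries outside [0, 1]")
  s <- sum(x)
  if (s <= 0) stop("configuration error: ", what, " sums to 0")
  if (!renorm_any && abs(s - 1) > 2e-3)
    stop("configuration error: ", what, " does not sum to 1 (sum = ",
         format(s), ")")
  x / s
}

# deterministic per-stage seed stream derived from the single config seed
stage_seed <- function(seed, stage) {
  offs <- c(covariates = 11L, treatment = 23L, fills_followup = 37L,
            fills_index = 41L, fills_baseline = 43L, adl = 47L,
            hospital = 53L, diagnoses = 59L, encounters = 61L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 2011L + offs[[stage]]
}
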