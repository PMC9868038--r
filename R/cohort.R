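#' Fracture-site code map
#'
#' Maps ICD-10 code prefixes (dots stripped) to a skeletal fracture site:
#' `hip`, `vertebrae`, `nvnh` (non-vertebral non-hip: rib, sacrum, pubis,
#' proximal humerus, radius/ulna/forearm, proximal tibia) or
#' `excluded_site` (skull, phalanges, toes). The shipped default follows the
#' prose definition of the site groups; the map is replaceable with any CSV
#' holding columns `icd10_prefix` and `site`.
#'
#' @param path optional CSV path; default is the shipped map.
#' @return data.frame with columns `icd10_prefix`, `site`.
#' @export
fracture_code_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fracture_sites.csv", package = "osteoclaims")
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("icd10_prefix", "site") %in% names(map)))
  map$icd10_prefix <- normalize_icd10(map$icd10_prefix)
  if (anyDuplicated(map$icd10_prefix))
    stop("fracture code map: a code prefix maps to two labels")
  map
}

normalize_icd10 <- function(x) toupper(gsub("[. ]", "", x))

# longest-prefix match of each code against a prefix vector; NA when unmatched
match_icd10_prefix <- function(codes, prefixes) {
  codes <- normalize_icd10(codes)
  ord <- order(nchar(prefixes), decreasing = TRUE)
  out <- rep(NA_integer_, length(codes))
  for (i in ord) {
    hit <- is.na(out) & startsWith(codes, prefixes[i])
    out[hit] <- i
  }
  out
}

#' Assign the fracture cohort for one index hospitalization
#'
#' Patients are assigned to exactly one of three mutually exclusive cohorts
#' (`hip`, `vertebrae`, `nvnh`) from the fracture diagnosis codes of the
#' index stay. Codes mapping to two or more distinct eligible sites yield
#' `excluded_multi_site`; codes mapping to no eligible site (including
#' skull/phalanx/toe fractures) yield `excluded_no_site`. Unmapped codes
#' raise a warning and are treated as carrying no site.
#'
#' @param fracture_codes character vector of ICD-10 codes (non-empty).
#' @param map a [fracture_code_map()] data.frame.
#' @export
assign_fracture_cohort <- function(fracture_codes, map = fracture_code_map()) {
  if (length(fracture_codes) == 0 || all(is.na(fracture_codes)))
    stop("fracture codes must be non-empty")
  idx <- match_icd10_prefix(fracture_codes, map$icd10_prefix)
  if (anyNA(idx))
    warning("unmapped fracture code(s): ",
            paste(fracture_codes[is.na(idx)], collapse = ", "))
  sites <- unique(map$site[idx[!is.na(idx)]])
  eligible <- setdiff(sites, "excluded_site")
  if (length(eligible) == 0) return("excluded_no_site")
  if (length(eligible) > 1) return("excluded_multi_site")
  eligible
}

#' Eligibility of one patient for the analytic cohort
#'
#' Eligible patients are at least 50 years old at the index admission, have
#' at least one hospital encounter dated at least 12 months (365 days)
#' before the index admission, and at least one encounter at least 12
#' months after the index discharge. Both boundaries are inclusive. Each
#' failed rule contributes one reason code.
#'
#' @param patient one-row list/data.frame with `birth_year`.
#' @param encounters data.frame with `date` (integer day index).
#' @param index list/one-row data.frame with `admission_date`,
#'   `discharge_date`.
#' @param index_year calendar year containing day 0 (admission year).
#' @return list with `eligible` flag and character `reasons`.
#' @export
check_eligibility <- function(patient, encounters, index, index_year = 2017) {
  if (is.null(patient$birth_year) || is.na(patient$birth_year))
    stop("missing birth year for patient")
  reasons <- character(0)
  age <- index_year - patient$birth_year
  if (age < 50) reasons <- c(reasons, "age_under_50")
  adm <- index$admission_date
  dis <- index$discharge_date
  dates <- encounters$date
  if (!any(dates <= adm - 365)) reasons <- c(reasons, "no_baseline_visit")
  if (!any(dates >= dis + 365)) reasons <- c(reasons, "no_followup_visit")
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Build the analytic cohort from a claims dataset
#'
#' Selects each patient's index hospitalization (the earliest stay carrying
#' at least one eligible fracture code), assigns the fracture cohort,
#' enforces eligibility and constructs the 365-day baseline and follow-up
#' windows. Windows are stored as closed integer day ranges:
#' baseline `[admission - 365, admission - 1]`, follow-up
#' `[discharge + 1, discharge + 365]`, so neither overlaps the index stay.
#'
#' @param dataset a synthetic (or equivalently structured) claims dataset;
#'   see [generate_dataset()].
#' @param map a [fracture_code_map()].
#' @param index_year calendar year of day 0.
#' @return list with elements `cohort` (one row per eligible patient) and
#'   `exclusions` (patient id + semicolon-joined reasons).
#' @export
build_cohort <- function(dataset, map = fracture_code_map(), index_year = 2017) {
  hosp <- dataset$hospitalizations
  pats <- dataset$patients
  empty <- data.frame(patient_id = character(0), index_admission = integer(0),
                      index_discharge = integer(0), fracture_cohort = character(0),
                      baseline_start = integer(0), baseline_end = integer(0),
                      followup_start = integer(0), followup_end = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hosp) || nrow(hosp) == 0)
    return(list(cohort = empty,
                exclusions = data.frame(patient_id = character(0),
                                        reasons = character(0))))
  hosp <- hosp[order(hosp$patient_id, hosp$admission_date), ]
  hosp <- hosp[!duplicated(hosp$patient_id), ]  # earliest qualifying stay
  n <- nrow(hosp)

  # fracture cohort per patient, vectorized over the unpacked code lists
  codes_list <- strsplit(hosp$fracture_codes, ";", fixed = TRUE)
  all_codes <- unlist(codes_list)
  pat_i <- rep(seq_len(n), lengths(codes_list))
  midx <- match_icd10_prefix(all_codes, map$icd10_prefix)
  if (anyNA(midx))
    warning("unmapped fracture code(s): ",
            paste(unique(all_codes[is.na(midx)]), collapse = ", "))
  site <- map$site[midx]
  el_sites <- !is.na(site) & site != "excluded_site"
  u <- !duplicated(paste(pat_i, site)) & el_sites
  n_sites <- tabulate(pat_i[u], nbins = n)
  first_site <- character(n)
  first_site[pat_i[u][!duplicated(pat_i[u])]] <- site[u][!duplicated(pat_i[u])]
  cohort_lbl <- ifelse(n_sites == 0, "excluded_no_site",
                ifelse(n_sites > 1, "excluded_multi_site", first_site))

  # eligibility, vectorized over per-patient encounter date extrema
  birth <- pats$birth_year[match(hosp$patient_id, pats$patient_id)]
  if (anyNA(birth)) stop("missing birth year for patient(s)")
  enc <- dataset$encounters
  enc_min <- tapply(enc$date, enc$patient_id, min)
  enc_max <- tapply(enc$date, enc$patient_id, max)
  emin <- enc_min[hosp$patient_id]
  emax <- enc_max[hosp$patient_id]
  age_ok <- (index_year - birth) >= 50
  bl_ok <- !is.na(emin) & emin <= hosp$admission_date - 365
  fu_ok <- !is.na(emax) & emax >= hosp$discharge_date + 365

  ok <- cohort_lbl %in% c("hip", "vertebrae", "nvnh") & age_ok & bl_ok & fu_ok
  reason_str <- function(i) {
    r <- character(0)
    if (cohort_lbl[i] == "excluded_multi_site") r <- c(r, "multi_site_fracture")
    if (cohort_lbl[i] == "excluded_no_site") r <- c(r, "no_eligible_fracture_site")
    if (!age_ok[i]) r <- c(r, "age_under_50")
    if (!bl_ok[i]) r <- c(r, "no_baseline_visit")
    if (!fu_ok[i]) r <- c(r, "no_followup_visit")
    paste(r, collapse = ";")
  }
  cohort <- data.frame(
    patient_id = hosp$patient_id[ok],
    index_admission = hosp$admission_date[ok],
    index_discharge = hosp$discharge_date[ok],
    fracture_cohort = cohort_lbl[ok],
    stringsAsFactors = FALSE)
  cohort$baseline_start <- cohort$index_admission - 365L
  cohort$baseline_end <- cohort$index_admission - 1L
  cohort$followup_start <- cohort$index_discharge + 1L
  cohort$followup_end <- cohort$index_discharge + 365L
  exclusions <- data.frame(
    patient_id = hosp$patient_id[!ok],
    reasons = vapply(which(!ok), reason_str, character(1)),
    stringsAsFactors = FALSE)
  list(cohort = cohort, exclusions = exclusions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
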