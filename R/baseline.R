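#' Charlson comorbidity map
#'
#' ICD-10 prefix map for the Charlson Comorbidity Index, shipped as the
#' Quan (2005) ICD-10 coding with the original category weights. Columns:
#' `category`, `icd10_prefix`, `weight`, `hierarchy` (hierarchy pairs such
#' as complicated/uncomplicated diabetes share a label and collapse to the
#' higher weight). The map is replaceable with any CSV of the same shape;
#' the category count is taken from the loaded file.
#'
#' @param path optional CSV path; default is the shipped Quan map.
#' @export
charlson_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charlson_icd10.csv", package = "osteoclaims")
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "icd10_prefix", "weight") %in% names(map)))
  if (any(map$weight < 1)) stop("charlson map: weights must be >= 1")
  map$icd10_prefix <- normalize_icd10(map$icd10_prefix)
  if (is.null(map$hierarchy)) map$hierarchy <- ""
  map$hierarchy[is.na(map$hierarchy)] <- ""
  map
}

#' Age at the index admission
#'
#' Age is admission year minus birth year (the source records store birth
#' year only), capped at 100 years, and banded into the categories
#' 50-59, 60-69, 70-79, 80-89, >=90.
#'
#' @param birth_year integer vector of birth years.
#' @param index_year calendar year of the index admission.
#' @return data.frame with `age_years` (capped) and `age_band`.
#' @export
compute_age <- function(birth_year, index_year = 2017) {
  if (any(birth_year > index_year, na.rm = TRUE))
    stop("birth year after admission year")
  age <- as.integer(pmin(index_year - birth_year, 100L))
  data.frame(age_years = age, age_band = age_band(age),
             stringsAsFactors = FALSE)
}

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 59, 69, 79, 89, Inf),
      labels = c("50-59", "60-69", "70-79", "80-89", ">=90"),
      right = TRUE) |> as.character()
}

#' Charlson Comorbidity Index score
#'
#' Sums the weights of the distinct comorbidity categories matched by the
#' supplied (baseline-window) diagnosis codes. Each category counts once
#' regardless of how often it is coded; hierarchy pairs (diabetes with and
#' without complications, mild vs. moderate/severe liver disease,
#' malignancy vs. metastatic tumor) collapse to the higher-weight member.
#' Unmatched codes contribute 0.
#'
#' @param codes character vector of ICD-10 codes.
#' @param map a [charlson_map()].
#' @return list with `score` and character vector `categories`.
#' @export
compute_cci <- function(codes, map = charlson_map()) {
  if (length(codes) == 0)
    return(list(score = 0L, categories = character(0)))
  idx <- match_icd10_prefix(codes, map$icd10_prefix)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(list(score = 0L, categories = character(0)))
  hit <- unique(data.frame(category = map$category[idx],
                           weight = map$weight[idx],
                           hierarchy = map$hierarchy[idx],
                           stringsAsFactors = FALSE))
  # within a hierarchy group keep only the higher-weight category
  keep <- rep(TRUE, nrow(hit))
  for (h in unique(hit$hierarchy[hit$hierarchy != ""])) {
    in_h <- which(hit$hierarchy == h)
    if (length(in_h) > 1)
      keep[in_h[-which.max(hit$weight[in_h])]] <- FALSE
  }
  hit <- hit[keep, ]
  list(score = as.integer(sum(hit$weight)), categories = sort(hit$category))
}

cci_band <- function(score) {
  ifelse(score > 3, ">3", as.character(pmin(score, 3L)))
}

#' Previous osteoporosis / osteoporotic-fracture diagnoses
#'
#' Flags are true when at least one matching diagnosis code is dated
#' strictly before the index admission (any available history, not only
#' the 365-day baseline window).
#'
#' @param diagnoses data.frame with `date` and `code`.
#' @param admission index admission day.
#' @param osteo_prefixes ICD-10 prefixes identifying osteoporosis.
#' @param fracture_map a [fracture_code_map()]; any eligible fracture site
#'   counts as a prior fracture diagnosis.
#' @return list with `prior_osteoporosis`, `prior_fracture`.
#' @export
flag_prior_conditions <- function(diagnoses, admission,
                                  osteo_prefixes = c("M80", "M81"),
                                  fracture_map = fracture_code_map()) {
  if (is.null(diagnoses) || nrow(diagnoses) == 0)
    return(list(prior_osteoporosis = FALSE, prior_fracture = FALSE))
  prior <- diagnoses[diagnoses$date < admission, , drop = FALSE]
  if (nrow(prior) == 0)
    return(list(prior_osteoporosis = FALSE, prior_fracture = FALSE))
  codes <- normalize_icd10(prior$code)
  osteo <- any(vapply(normalize_icd10(osteo_prefixes),
                      function(p) any(startsWith(codes, p)), logical(1)))
  elig <- fracture_map[!fracture_map$site %in% "excluded_site", ]
  idx <- suppressWarnings(match_icd10_prefix(codes, elig$icd10_prefix))
  frac <- any(!is.na(idx))
  list(prior_osteoporosis = osteo, prior_fracture = frac)
}

# documented score range per ADL item
adl_item_ranges <- function() {
  list(eating = 0:2, transferring = 0:3, grooming = 0:1, toilet = 0:2,
       bathing = 0:1, walking = 0:3, stairs = 0:2, clothing = 0:2)
}

#' Summarize activities-of-daily-living item scores
#'
#' Counts and percentages per score level per item, with unknown/missing as
#' its own category. Out-of-range scores are an error naming the item.
#'
#' @param adl data.frame with `patient_id` and one column per ADL item
#'   (eating, transferring, grooming, toilet, bathing, walking, stairs,
#'   clothing); `NA` marks missing assessments.
#' @return data.frame with `item`, `level`, `n`, `pct`.
#' @export
summarize_adl <- function(adl) {
  ranges <- adl_item_ranges()
  out <- list()
  for (item in names(ranges)) {
    x <- adl[[item]]
    if (is.null(x)) stop("ADL item missing from table: ", item)
    bad <- !is.na(x) & !x %in% ranges[[item]]
    if (any(bad))
      stop("out-of-range ADL score for item ", item, ": ",
           paste(unique(x[bad]), collapse = ", "))
    lev <- c(as.character(rev(ranges[[item]])), "missing")
    xx <- ifelse(is.na(x), "missing", as.character(x))
    cnt <- table(factor(xx, levels = lev))
    out[[item]] <- data.frame(item = item, level = lev, n = as.integer(cnt),
                              pct = if (length(x)) 100 * as.integer(cnt) / length(x)
                                    else rep(NA_real_, length(lev)),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Baseline covariate profiles for the cohort
#'
#' Derives, per eligible patient, every model covariate from the claims
#' records alone: capped age and band, sex, length-of-stay band,
#' previous hospitalization (any inpatient encounter inside the baseline
#' window), prior osteoporosis/fracture diagnosis combination, CCI score
#' and band from baseline-window diagnoses, route/admission-type/discharge
#' destination groups, medications-at-discharge band, and smoking index.
#'
#' @param dataset claims dataset (see [generate_dataset()]).
#' @param cohort the `cohort` element of [build_cohort()].
#' @param cci a [charlson_map()].
#' @param fracture a [fracture_code_map()].
#' @param index_year calendar year of day 0.
#' @return data.frame, one row per cohort patient.
#' @export
build_baseline_profiles <- function(dataset, cohort, cci = charlson_map(),
                                    fracture = fracture_code_map(),
                                    index_year = 2017) {
  if (nrow(cohort) == 0) return(cohort)
  pats <- dataset$patients
  hosp <- dataset$hospitalizations
  hosp <- hosp[match(cohort$patient_id, hosp$patient_id), ]
  pm <- match(cohort$patient_id, pats$patient_id)

  agedf <- compute_age(pats$birth_year[pm], index_year)
  los <- hosp$discharge_date - hosp$admission_date + 1L

  n <- nrow(cohort)
  cci_score <- integer(n)
  prior_ost <- logical(n)
  prior_frac <- logical(n)
  prev_hosp <- logical(n)

  dx <- dataset$diagnoses
  if (!is.null(dx) && nrow(dx)) {
    row_i <- match(dx$patient_id, cohort$patient_id)
    keep <- !is.na(row_i)
    dxp <- row_i[keep]
    dxd <- dx$date[keep]
    codes <- normalize_icd10(dx$code[keep])

    # CCI: match baseline-window codes to categories, count each category
    # once per patient, collapse hierarchy pairs to the higher weight
    in_bl <- dxd >= cohort$baseline_start[dxp] & dxd <= cohort$baseline_end[dxp]
    midx <- match_icd10_prefix(codes[in_bl], cci$icd10_prefix)
    hitp <- dxp[in_bl][!is.na(midx)]
    midx <- midx[!is.na(midx)]
    if (length(midx)) {
      hit <- data.frame(p = hitp, category = cci$category[midx],
                        weight = cci$weight[midx],
                        hierarchy = cci$hierarchy[midx])
      hit <- hit[!duplicated(paste(hit$p, hit$category)), ]
      hit <- hit[order(-hit$weight), ]
      hh <- hit$hierarchy != ""
      drop <- rep(FALSE, nrow(hit))
      key <- paste(hit$p, hit$hierarchy)
      drop[hh] <- duplicated(key[hh])
      hit <- hit[!drop, ]
      sc <- rowsum(hit$weight, hit$p)
      cci_score[as.integer(rownames(sc))] <- sc[, 1]
    }

    # prior diagnoses: strictly before the index admission
    prior <- dxd < cohort$index_admission[dxp]
    ost <- prior & (startsWith(codes, "M80") | startsWith(codes, "M81"))
    prior_ost[unique(dxp[ost])] <- TRUE
    elig <- fracture[!fracture$site %in% "excluded_site", ]
    fidx <- match_icd10_prefix(codes, elig$icd10_prefix)
    frac <- prior & !is.na(fidx)
    prior_frac[unique(dxp[frac])] <- TRUE
  }

  enc <- dataset$encounters
  inp <- enc[enc$setting == "inpatient", , drop = FALSE]
  if (nrow(inp)) {
    row_i <- match(inp$patient_id, cohort$patient_id)
    keep <- !is.na(row_i)
    in_bl <- inp$date[keep] >= cohort$baseline_start[row_i[keep]] &
             inp$date[keep] <= cohort$baseline_end[row_i[keep]]
    prev_hosp[unique(row_i[keep][in_bl])] <- TRUE
  }

  data.frame(
    patient_id = cohort$patient_id,
    fracture_cohort = cohort$fracture_cohort,
    age_years = agedf$age_years,
    age_band = agedf$age_band,
    sex = pats$sex[pm],
    los_days = los,
    los_band = los_band(los),
    previous_hospitalization = ifelse(prev_hosp, "yes", "no"),
    prior_dx = ifelse(prior_ost & prior_frac, "osteo_and_fracture",
               ifelse(prior_ost, "osteo_only", "neither")),
    cci_score = cci_score,
    cci_band = cci_band(cci_score),
    smoking_index = pats$smoking_index[pm],
    route = hosp$route,
    route_group = route_group(hosp$route),
    admission_type = hosp$admission_type,
    admission_type_group = admission_type_group(hosp$admission_type),
    discharge_destination = hosp$discharge_destination,
    destination_group = destination_group(hosp$discharge_destination),
    meds_at_discharge = meds_band(hosp$n_meds_at_discharge),
    stringsAsFactors = FALSE)
}

# banding helpers shared by the generator and the pipeline ------------------

los_band <- function(los) {
  ifelse(los < 15, "<15", ifelse(los <= 30, "15-30", ">30"))
}

meds_band <- function(n) {
  ifelse(n >= 3, ">=3", as.character(pmin(n, 3L)))
}

route_group <- function(route) {
  ifelse(route == "home", "home", "other")
}

admission_type_group <- function(type) {
  ifelse(type %in% c("planned", "planned_rehospitalization"), "planned", type)
}

destination_group <- function(dest) {
  grp <- c(same_hospital_ward = "hospital",
           other_hospital_or_facility = "hospital",
           home_same_hospital_checkup = "home",
           home_other_hospital_checkup = "home",
           geriatric_facility = "facility", nursing_home = "facility",
           social_welfare = "facility", died = "died", other = "other_missing")
  out <- unname(grp[dest])
  out[is.na(out)] <- "other_missing"
  out
}
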