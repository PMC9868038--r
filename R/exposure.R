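#' Drug-class map
#'
#' Maps drug codes to the antiosteoporotic class taxonomy (calcium,
#' estrogen, active_vitamin_D3, bisphosphonate, SERM, calcitonin,
#' teriparatide, denosumab, ipriflavone, nandrolone, vitamin_K2) with a
#' per-drug default days' supply used when a dispensation record carries
#' none (e.g. zoledronic acid: one infusion covers a year).
#'
#' @param path optional CSV path (`drug_code`, `drug_class`,
#'   `default_days_supply`); default is the shipped map.
#' @export
drug_class_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "drug_classes.csv", package = "osteoclaims")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-class exposure timeline from dispensations
#'
#' Converts a single patient's fills into disjoint, sorted exposure
#' intervals per drug class (half-open `[start, end)` in days).
#' Overlapping same-class fills stockpile: a fill dispensed before the
#' previous supply runs out starts when that supply ends. Same-class
#' intervals separated by a gap shorter than `bridge_gap` days are bridged
#' into one continuous interval; gaps of `bridge_gap` or more split the
#' timeline.
#'
#' @param fills data.frame with `date`, `drug_class`, `days_supply`
#'   (missing supplies resolved via `drug_code` defaults, then
#'   `supply_rules`).
#' @param supply_rules named numeric of per-class default days' supply.
#' @param bridge_gap gap below which same-class intervals are bridged.
#' @return data.frame `drug_class`, `start`, `end`.
#' @export
build_exposure_timeline <- function(fills, supply_rules = NULL,
                                    bridge_gap = 60) {
  if (is.null(fills) || nrow(fills) == 0)
    return(data.frame(drug_class = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  supply <- resolve_supply(fills, supply_rules)
  out <- list()
  for (cl in unique(fills$drug_class)) {
    sel <- fills$drug_class == cl
    iv <- stockpile_intervals(fills$date[sel], supply[sel])
    iv <- bridge_intervals(iv, bridge_gap)
    out[[cl]] <- data.frame(drug_class = cl, start = iv$start, end = iv$end,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
  res[order(res$drug_class, res$start), ]
}

resolve_supply <- function(fills, supply_rules = NULL) {
  supply <- fills$days_supply
  if (is.null(supply)) supply <- rep(NA_real_, nrow(fills))
  if (anyNA(supply) && !is.null(fills$drug_code)) {
    map <- drug_class_map()
    d <- map$default_days_supply[match(fills$drug_code, map$drug_code)]
    supply[is.na(supply)] <- d[is.na(supply)]
  }
  if (anyNA(supply) && !is.null(supply_rules))
    supply[is.na(supply)] <- supply_rules[fills$drug_class[is.na(supply)]]
  if (anyNA(supply))
    stop("cannot resolve days' supply for class(es): ",
         paste(unique(fills$drug_class[is.na(supply)]), collapse = ", "))
  if (any(supply <= 0)) stop("days' supply must be positive")
  supply
}

# shift-forward stockpiling: sort by date, each fill starts at max(date,
# running end) and runs for its supply
stockpile_intervals <- function(dates, supplies) {
  ord <- order(dates)
  dates <- dates[ord]; supplies <- supplies[ord]
  start <- numeric(length(dates)); end <- numeric(length(dates))
  run_end <- -Inf
  for (i in seq_along(dates)) {
    s <- max(dates[i], run_end)
    start[i] <- s
    end[i] <- s + supplies[i]
    run_end <- end[i]
  }
  merge_touching(data.frame(start = start, end = end))
}

# merge sorted intervals: gap = 0 merges touching/overlapping intervals
# (gap_len <= 0); gap > 0 additionally bridges gaps strictly below `gap`
merge_intervals <- function(iv, gap) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv$start), ]
  out_s <- iv$start[1]; out_e <- iv$end[1]
  k <- 1
  for (i in 2:nrow(iv)) {
    gap_len <- iv$start[i] - out_e[k]
    if (gap_len <= 0 || gap_len < gap) {
      out_e[k] <- max(out_e[k], iv$end[i])
    } else {
      k <- k + 1
      out_s[k] <- iv$start[i]; out_e[k] <- iv$end[i]
    }
  }
  data.frame(start = out_s, end = out_e)
}

merge_touching <- function(iv) merge_intervals(iv, gap = 0)

bridge_intervals <- function(iv, bridge_gap) merge_intervals(iv, bridge_gap)

#' First observed treatment regimen after discharge
#'
#' The first regimen is the set of distinct drug classes with at least one
#' fill inside the regimen window `[discharge, discharge + window]`
#' (treatment must be received within 14 days after discharge to count);
#' its start date is the earliest such fill. Returns `NULL` when no fill
#' falls inside the window (the patient may still be follow-up treated).
#'
#' @param fills follow-up dispensations for one patient.
#' @param discharge index discharge day.
#' @param window regimen inclusion window in days (default 14).
#' @return list with `classes`, `start_date`, or `NULL`.
#' @export
identify_first_regimen <- function(fills, discharge, window = 14) {
  if (is.null(fills) || nrow(fills) == 0) return(NULL)
  sel <- fills$date >= discharge & fills$date <= discharge + window
  if (!any(sel)) return(NULL)
  list(classes = sort(unique(fills$drug_class[sel])),
       start_date = min(fills$date[sel]))
}

# regimen-level exposure spells: the regimen classes' (bridged) intervals
# merged whenever the gap between them is < gap days. Any regimen-class
# refill within `gap` days of running out resets the discontinuation clock,
# so a spell boundary is always a true >= gap-day lapse in regimen supply.
regimen_spells <- function(timeline, regimen_classes, gap = 60) {
  iv <- timeline[timeline$drug_class %in% regimen_classes, , drop = FALSE]
  if (nrow(iv) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  merge_intervals(iv[, c("start", "end")], gap = gap)
}

#' Detect discontinuation of the first regimen
#'
#' The regimen's exposure ends at the last covered day of its current
#' supply spell; the patient discontinues when at least `gap` days
#' (default ~60, the refill-gap rule) elapse after that point with no
#' refill of any regimen class before the end of follow-up. The
#' discontinuation date is the first uncovered day (the supply end).
#' Otherwise the patient is persistent.
#'
#' @param timeline a [build_exposure_timeline()] result.
#' @param regimen an [identify_first_regimen()] result.
#' @param followup_end exclusive end of follow-up (last follow-up day + 1).
#' @param gap minimum refill gap in days.
#' @return list `discontinued`, and when true `date`,
#'   `days_from_initiation`.
#' @export
detect_discontinuation <- function(timeline, regimen, followup_end, gap = 60) {
  stopifnot(!is.null(regimen))
  spells <- regimen_spells(timeline, regimen$classes, gap)
  if (nrow(spells) == 0)
    stop("regimen present but no exposure intervals found")
  first_end <- spells$end[1]
  tail_gap <- if (nrow(spells) > 1) spells$start[2] - first_end
              else followup_end - first_end
  if (tail_gap >= gap)
    list(discontinued = TRUE, date = first_end,
         days_from_initiation = first_end - regimen$start_date)
  else
    list(discontinued = FALSE)
}

#' Classify the first post-discontinuation event as switch or restart
#'
#' The first fill on or after the discontinuation date decides the event:
#' a class outside the first regimen is a switch (new classes recorded), a
#' regimen class is a restart. Fills at the same date are pooled; a
#' regimen-class fill among them makes the event a restart. Later fills
#' never reclassify the event.
#'
#' @param fills follow-up dispensations for the patient.
#' @param disc a [detect_discontinuation()] result with
#'   `discontinued = TRUE`.
#' @param regimen the first regimen.
#' @param followup_end exclusive end of follow-up.
#' @return `NULL` when no fill follows the discontinuation, else list with
#'   `kind` ("switch"/"restart"), `classes`, `days_from_initiation`,
#'   `days_from_discontinuation`.
#' @export
classify_switch_restart <- function(fills, disc, regimen, followup_end) {
  stopifnot(isTRUE(disc$discontinued))
  after <- fills[fills$date >= disc$date & fills$date < followup_end, ,
                 drop = FALSE]
  if (nrow(after) == 0) return(NULL)
  d0 <- min(after$date)
  classes <- sort(unique(after$drug_class[after$date == d0]))
  kind <- if (any(classes %in% regimen$classes)) "restart" else "switch"
  list(kind = kind,
       classes = if (kind == "switch") classes
                 else intersect(classes, regimen$classes),
       days_from_initiation = d0 - regimen$start_date,
       days_from_discontinuation = d0 - disc$date)
}

#' Detect treatment augmentation
#'
#' Augmentation is the initiation of a drug class outside the first
#' regimen, starting after the regimen window closes (`regimen start +
#' window` days), with continued use of the original regimen for at least
#' `min_overlap` days of combined use. Overlap is counted against the
#' regimen's exposure spells (regimen-class intervals merged across
#' refill gaps shorter than `gap`), the same regimen-level exposure used
#' by the discontinuation rule. The first qualifying class by start date
#' is reported.
#'
#' @param timeline a [build_exposure_timeline()] result.
#' @param regimen the first regimen.
#' @param min_overlap minimum combined-use days (default 60).
#' @param window regimen inclusion window (default 14).
#' @param gap refill-gap parameter for the regimen spells.
#' @return `NULL` or list with `classes`, `date`, `days_from_initiation`.
#' @export
detect_augmentation <- function(timeline, regimen, min_overlap = 60,
                                window = 14, gap = 60) {
  stopifnot(!is.null(regimen))
  spells <- regimen_spells(timeline, regimen$classes, gap)
  cand <- setdiff(unique(timeline$drug_class), regimen$classes)
  best <- NULL
  for (cl in cand) {
    iv <- timeline[timeline$drug_class == cl, , drop = FALSE]
    cl_start <- min(iv$start)
    if (cl_start <= regimen$start_date + window) next
    ov <- interval_overlap(iv, spells)
    if (ov >= min_overlap && (is.null(best) || cl_start < best$date))
      best <- list(classes = cl, date = cl_start,
                   days_from_initiation = cl_start - regimen$start_date)
  }
  best
}

# total day-count overlap between two sets of disjoint intervals
interval_overlap <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a)))
    tot <- tot + sum(pmax(0, pmin(a$end[i], b$end) - pmax(a$start[i], b$start)))
  tot
}

#' Phase treatment classification for one patient
#'
#' Flags treatment in each study phase and computes the day-count metrics:
#' baseline treated (any fill inside the baseline window, with days from
#' first baseline fill to admission and baseline days with medication),
#' index treated (any inpatient administration during the stay, with days
#' from admission to initiation and inpatient days with medication), and
#' follow-up treated (any outpatient fill inside the follow-up window,
#' with days from discharge to initiation). Inpatient administrations
#' never enter follow-up logic.
#'
#' @param fills all dispensations of one patient (`date`, `drug_class`,
#'   `days_supply`, `setting`, optionally `patient_id`).
#' @param assignment one cohort row (see [build_cohort()]).
#' @param supply_rules per-class default days' supply.
#' @return list of phase flags, class sets and metrics.
#' @export
classify_phase_treatment <- function(fills, assignment, supply_rules = NULL) {
  if (!is.null(fills$patient_id) && length(unique(fills$patient_id)) > 1)
    stop("fills from multiple patients")
  adm <- assignment$index_admission
  dis <- assignment$index_discharge
  res <- list(baseline_treated = FALSE, index_treated = FALSE,
              followup_treated = FALSE, baseline_classes = character(0),
              index_classes = character(0), followup_classes = character(0),
              days_from_treatment_start_to_admission = NA_real_,
              baseline_days_with_medication = NA_real_,
              days_from_admission_to_initiation = NA_real_,
              inpatient_days_with_medication = NA_real_,
              days_from_discharge_to_initiation = NA_real_)
  if (is.null(fills) || nrow(fills) == 0) return(res)

  bl <- fills[fills$date >= assignment$baseline_start &
              fills$date <= assignment$baseline_end, , drop = FALSE]
  if (nrow(bl)) {
    res$baseline_treated <- TRUE
    res$baseline_classes <- sort(unique(bl$drug_class))
    res$days_from_treatment_start_to_admission <- adm - min(bl$date)
    tl <- build_exposure_timeline(bl, supply_rules)
    res$baseline_days_with_medication <- window_coverage(
      tl, assignment$baseline_start, assignment$baseline_end + 1)
  }
  inp <- fills[fills$setting == "inpatient" & fills$date >= adm &
               fills$date <= dis, , drop = FALSE]
  if (nrow(inp)) {
    res$index_treated <- TRUE
    res$index_classes <- sort(unique(inp$drug_class))
    res$days_from_admission_to_initiation <- min(inp$date) - adm
    tl <- build_exposure_timeline(inp, supply_rules)
    res$inpatient_days_with_medication <- window_coverage(tl, adm, dis + 1)
  }
  fu <- fills[fills$setting == "outpatient" &
              fills$date >= assignment$followup_start &
              fills$date <= assignment$followup_end, , drop = FALSE]
  if (nrow(fu)) {
    res$followup_treated <- TRUE
    res$followup_classes <- sort(unique(fu$drug_class))
    res$days_from_discharge_to_initiation <- min(fu$date) - dis
  }
  res
}

# covered days (union over classes) inside [win_start, win_end)
window_coverage <- function(timeline, win_start, win_end) {
  if (nrow(timeline) == 0) return(0)
  iv <- merge_touching(timeline[order(timeline$start), c("start", "end")])
  sum(pmax(0, pmin(iv$end, win_end) - pmax(iv$start, win_start)))
}

# ---------------------------------------------------------------------------
# vector-based internals used by analyze_treatment on large cohorts; the
# exported interval operations above are the reference implementations and
# behave identically (pinned by tests)

iv_stockpile <- function(dates, sups) {
  ord <- order(dates)
  dates <- dates[ord]; sups <- sups[ord]
  m <- length(dates)
  s <- numeric(m); e <- numeric(m)
  run_end <- -Inf
  for (i in seq_len(m)) {
    s[i] <- max(dates[i], run_end)
    e[i] <- s[i] + sups[i]
    run_end <- e[i]
  }
  iv_merge(s, e, 0)
}

iv_merge <- function(s, e, gap) {
  m <- length(s)
  if (m <= 1) return(list(s = s, e = e))
  ord <- order(s)
  s <- s[ord]; e <- e[ord]
  os <- numeric(m); oe <- numeric(m)
  os[1] <- s[1]; oe[1] <- e[1]; k <- 1
  for (i in 2:m) {
    gl <- s[i] - oe[k]
    if (gl <= 0 || gl < gap) {
      if (e[i] > oe[k]) oe[k] <- e[i]
    } else {
      k <- k + 1
      os[k] <- s[i]; oe[k] <- e[i]
    }
  }
  list(s = os[seq_len(k)], e = oe[seq_len(k)])
}

iv_coverage <- function(iv, lo, hi) {
  sum(pmax(0, pmin(iv$e, hi) - pmax(iv$s, lo)))
}

iv_overlap <- function(a, b) {
  tot <- 0
  for (i in seq_along(a$s))
    tot <- tot + sum(pmax(0, pmin(a$e[i], b$e) - pmax(a$s[i], b$s)))
  tot
}

# full episode analysis for one patient from plain vectors; returns the
# values analyze_treatment stores in its row
analyze_patient_fast <- function(date, cls, sup, set, asn, gap, window,
                                 min_overlap, threshold) {
  out <- list()
  adm <- asn$index_admission; dis <- asn$index_discharge
  bl <- set == "outpatient" | set == "inpatient"  # any setting in baseline
  bl <- bl & date >= asn$baseline_start & date <= asn$baseline_end
  if (any(bl)) {
    out$baseline_treated <- TRUE
    out$baseline_classes <- paste(sort(unique(cls[bl])), collapse = "+")
    out$days_start_to_adm <- adm - min(date[bl])
    ivs <- lapply(unique(cls[bl]),
                  function(cc) iv_stockpile(date[bl & cls == cc],
                                            sup[bl & cls == cc]))
    u <- iv_merge(unlist(lapply(ivs, `[[`, "s")),
                  unlist(lapply(ivs, `[[`, "e")), 0)
    out$baseline_days <- iv_coverage(u, asn$baseline_start,
                                     asn$baseline_end + 1)
  }
  inp <- set == "inpatient" & date >= adm & date <= dis
  if (any(inp)) {
    out$index_treated <- TRUE
    out$index_classes <- paste(sort(unique(cls[inp])), collapse = "+")
    out$days_adm_to_init <- min(date[inp]) - adm
    ivs <- lapply(unique(cls[inp]),
                  function(cc) iv_stockpile(date[inp & cls == cc],
                                            sup[inp & cls == cc]))
    u <- iv_merge(unlist(lapply(ivs, `[[`, "s")),
                  unlist(lapply(ivs, `[[`, "e")), 0)
    out$inpatient_days <- iv_coverage(u, adm, dis + 1)
  }
  fu <- set == "outpatient" & date >= dis & date <= asn$followup_end
  fu_in <- fu & date >= asn$followup_start
  if (!any(fu_in)) return(out)
  out$followup_treated <- TRUE
  out$followup_classes <- paste(sort(unique(cls[fu_in])), collapse = "+")
  out$days_dis_to_init <- min(date[fu_in]) - dis
  E <- asn$followup_end + 1

  # MPR over [first follow-up fill, follow-up end)
  t0 <- min(date[fu_in])
  L <- E - t0
  out$mpr <- min(1, sum(pmin(sup[fu_in], E - date[fu_in])) / L)
  out$adherent <- out$mpr >= threshold
  out$mpr_bin <- mpr_bin(out$mpr)

  reg <- fu & date <= dis + window
  if (!any(reg)) return(out)
  reg_classes <- sort(unique(cls[reg]))
  reg_start <- min(date[reg])
  out$first_regimen <- paste(reg_classes, collapse = "+")
  out$regimen_start <- reg_start

  fu_cls <- cls[fu]; fu_date <- date[fu]; fu_sup <- sup[fu]
  tl <- lapply(unique(fu_cls), function(cc) {
    iv <- iv_stockpile(fu_date[fu_cls == cc], fu_sup[fu_cls == cc])
    iv_merge(iv$s, iv$e, gap)
  })
  names(tl) <- unique(fu_cls)

  in_reg <- names(tl) %in% reg_classes
  spells <- iv_merge(unlist(lapply(tl[in_reg], `[[`, "s")),
                     unlist(lapply(tl[in_reg], `[[`, "e")), gap)
  first_end <- spells$e[1]
  tail_gap <- if (length(spells$s) > 1) spells$s[2] - first_end
              else E - first_end
  if (tail_gap >= gap) {
    out$discontinued <- TRUE
    out$disc_date <- first_end
    out$days_to_disc <- first_end - reg_start
    after <- fu_date >= first_end
    if (any(after)) {
      d0 <- min(fu_date[after])
      cls0 <- sort(unique(fu_cls[after & fu_date == d0]))
      restart <- any(cls0 %in% reg_classes)
      out$sr_kind <- if (restart) "restart" else "switch"
      out$sr_classes <- paste(
        if (restart) intersect(cls0, reg_classes) else cls0, collapse = "+")
      out$days_to_sr <- d0 - reg_start
      out$days_disc_to_sr <- d0 - first_end
    }
  } else out$discontinued <- FALSE

  best_date <- Inf; best_cls <- NULL
  for (cc in names(tl)[!in_reg]) {
    cl_start <- min(tl[[cc]]$s)
    if (cl_start <= reg_start + window) next
    if (iv_overlap(tl[[cc]], spells) >= min_overlap && cl_start < best_date) {
      best_date <- cl_start; best_cls <- cc
    }
  }
  out$augmented <- !is.null(best_cls)
  if (out$augmented) {
    out$aug_classes <- best_cls
    out$days_to_aug <- best_date - reg_start
  }
  out
}

#' Full treatment-pattern analysis for every cohort patient
#'
#' Runs phase classification, first-regimen identification, the refill-gap
#' discontinuation rule, switch/restart classification, augmentation
#' detection, and MPR adherence over all dispensations, one row per
#' cohort patient.
#'
#' @param dispensations dispensation table for the whole dataset.
#' @param cohort cohort table from [build_cohort()].
#' @param supply_rules per-class default days' supply.
#' @param gap_days refill gap (default 60).
#' @param regimen_window_days first-regimen window (default 14).
#' @param min_overlap_days augmentation combined-use minimum (default 60).
#' @param mpr_threshold adherence threshold (default 0.80).
#' @return data.frame, one row per cohort patient.
#' @export
analyze_treatment <- function(dispensations, cohort, supply_rules = NULL,
                              gap_days = 60, regimen_window_days = 14,
                              min_overlap_days = 60, mpr_threshold = 0.80) {
  n <- nrow(cohort)
  # preallocated columns (assembled into a data.frame at the end; per-row
  # data.frame assignment would copy the whole table each time)
  col <- list(
    baseline_treated = rep(FALSE, n), index_treated = rep(FALSE, n),
    followup_treated = rep(FALSE, n),
    baseline_classes = rep("", n), index_classes = rep("", n),
    followup_classes = rep("", n),
    days_from_treatment_start_to_admission = rep(NA_real_, n),
    baseline_days_with_medication = rep(NA_real_, n),
    days_from_admission_to_initiation = rep(NA_real_, n),
    inpatient_days_with_medication = rep(NA_real_, n),
    days_from_discharge_to_initiation = rep(NA_real_, n),
    first_regimen = rep(NA_character_, n), regimen_start = rep(NA_real_, n),
    persistent = rep(NA, n), discontinued = rep(NA, n),
    discontinuation_date = rep(NA_real_, n),
    days_to_discontinuation = rep(NA_real_, n),
    switch_restart = rep(NA_character_, n),
    switch_classes = rep(NA_character_, n),
    days_to_switch_restart = rep(NA_real_, n),
    days_disc_to_switch_restart = rep(NA_real_, n),
    augmented = rep(NA, n), augment_classes = rep(NA_character_, n),
    days_to_augmentation = rep(NA_real_, n),
    mpr = rep(NA_real_, n), mpr_bin = rep(NA_character_, n),
    adherent = rep(NA, n))
  assemble <- function()
    cbind(data.frame(patient_id = cohort$patient_id,
                     stringsAsFactors = FALSE),
          as.data.frame(col, stringsAsFactors = FALSE))
  if (n == 0 || is.null(dispensations) || nrow(dispensations) == 0)
    return(assemble())

  supply <- resolve_supply(dispensations, supply_rules)
  d_date <- dispensations$date
  d_cls <- dispensations$drug_class
  d_set <- dispensations$setting
  by_pat <- split(seq_len(nrow(dispensations)), dispensations$patient_id)

  for (i in seq_len(n)) {
    idx <- by_pat[[cohort$patient_id[i]]]
    if (is.null(idx)) next
    asn <- list(index_admission = cohort$index_admission[i],
                index_discharge = cohort$index_discharge[i],
                baseline_start = cohort$baseline_start[i],
                baseline_end = cohort$baseline_end[i],
                followup_start = cohort$followup_start[i],
                followup_end = cohort$followup_end[i])
    r <- analyze_patient_fast(d_date[idx], d_cls[idx], supply[idx],
                              d_set[idx], asn, gap_days,
                              regimen_window_days, min_overlap_days,
                              mpr_threshold)
    if (isTRUE(r$baseline_treated)) {
      col$baseline_treated[i] <- TRUE
      col$baseline_classes[i] <- r$baseline_classes
      col$days_from_treatment_start_to_admission[i] <- r$days_start_to_adm
      col$baseline_days_with_medication[i] <- r$baseline_days
    }
    if (isTRUE(r$index_treated)) {
      col$index_treated[i] <- TRUE
      col$index_classes[i] <- r$index_classes
      col$days_from_admission_to_initiation[i] <- r$days_adm_to_init
      col$inpatient_days_with_medication[i] <- r$inpatient_days
    }
    if (!isTRUE(r$followup_treated)) next
    col$followup_treated[i] <- TRUE
    col$followup_classes[i] <- r$followup_classes
    col$days_from_discharge_to_initiation[i] <- r$days_dis_to_init
    col$mpr[i] <- r$mpr
    col$mpr_bin[i] <- r$mpr_bin
    col$adherent[i] <- r$adherent
    if (is.null(r$first_regimen)) next
    col$first_regimen[i] <- r$first_regimen
    col$regimen_start[i] <- r$regimen_start
    col$discontinued[i] <- r$discontinued
    col$persistent[i] <- !r$discontinued
    if (r$discontinued) {
      col$discontinuation_date[i] <- r$disc_date
      col$days_to_discontinuation[i] <- r$days_to_disc
      if (!is.null(r$sr_kind)) {
        col$switch_restart[i] <- r$sr_kind
        col$switch_classes[i] <- r$sr_classes
        col$days_to_switch_restart[i] <- r$days_to_sr
        col$days_disc_to_switch_restart[i] <- r$days_disc_to_sr
      }
    }
    col$augmented[i] <- r$augmented
    if (r$augmented) {
      col$augment_classes[i] <- r$aug_classes
      col$days_to_augmentation[i] <- r$days_to_aug
    }
  }
  assemble()
}
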