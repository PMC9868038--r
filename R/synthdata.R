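#' Sample patient covariates from the configured marginals
#'
#' Draws `n` independent patients: fracture cohort, record-level
#' covariates (age band and an age inside it, sex, length of stay and its
#' band, previous hospitalization, prior-diagnosis combination, route and
#' admission type, CCI band, discharge destination, medications at
#' discharge, smoking index) from the configured categorical marginals.
#' Every covariate is drawn independently — the source study publishes
#' only marginals, and independence suffices for marginal-rate and
#' injected-OR recovery.
#'
#' @param config a generator configuration.
#' @param n number of patients.
#' @param seed RNG seed for this draw.
#' @return data.frame with one row per patient.
#' @export
sample_covariates <- function(config, n, seed) {
  set.seed(seed)
  cm <- config$covariate_marginals
  draw <- function(mix) {
    if (abs(sum(mix) - 1) > 1e-9)
      stop("configuration error: marginal does not sum to 1")
    if (n == 0) return(character(0))
    sample(names(mix), n, replace = TRUE, prob = mix)
  }
  cov <- data.frame(
    fracture_cohort = draw(config$cohort_mix),
    age_band = draw(cm$age_band),
    sex = draw(cm$sex),
    los_band = draw(cm$los_band),
    previous_hospitalization = draw(cm$previous_hospitalization),
    prior_dx = draw(cm$prior_dx),
    route = draw(cm$route),
    admission_type = draw(cm$admission_type),
    cci_band = draw(cm$cci_band),
    discharge_destination = draw(cm$discharge_destination),
    meds_at_discharge = draw(cm$meds_at_discharge),
    stringsAsFactors = FALSE)
  if (n == 0) {
    cov$age_years <- integer(0); cov$los_days <- integer(0)
    cov$n_meds <- integer(0); cov$smoking_index <- numeric(0)
    return(cov)
  }
  # an age inside the band; the >=90 band reaches past 100 so the reporting
  # cap (age > 100 -> 100) is exercised by real records
  age_lo <- c("50-59" = 50, "60-69" = 60, "70-79" = 70, "80-89" = 80,
              ">=90" = 90)[cov$age_band]
  age_hi <- c("50-59" = 59, "60-69" = 69, "70-79" = 79, "80-89" = 89,
              ">=90" = 102)[cov$age_band]
  cov$age_years <- age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1))
  los <- integer(n)
  b <- cov$los_band == "<15"
  los[b] <- 1L + floor(stats::runif(sum(b)) * 14)
  b <- cov$los_band == "15-30"
  los[b] <- 15L + floor(stats::runif(sum(b)) * 16)
  b <- cov$los_band == ">30"
  los[b] <- pmin(31L + as.integer(floor(stats::rexp(sum(b), 1 / 25))), 120L)
  cov$los_days <- los
  nm <- c("0" = 0L, "1" = 1L, "2" = 2L, ">=3" = 3L)[cov$meds_at_discharge]
  extra <- stats::rpois(n, 0.8)
  cov$n_meds <- ifelse(cov$meds_at_discharge == ">=3", nm + extra, nm)
  smoker <- stats::runif(n) < 0.28
  cov$smoking_index <- ifelse(
    smoker, pmin(round(stats::rlnorm(n, meanlog = 5.5, sdlog = 1)), 9600), 0)
  cov$route_group <- route_group(cov$route)
  cov$admission_type_group <- admission_type_group(cov$admission_type)
  cov$destination_group <- destination_group(cov$discharge_destination)
  cov
}

#' Linear predictor from per-category log-odds
#'
#' Sums, per patient, the configured log-odds of each covariate's
#' category; reference levels (and categories the model excludes, e.g.
#' destination died) contribute 0. Unknown categories are an error.
#'
#' @param covariates covariate data.frame (columns named as in
#'   `treatment_log_odds`).
#' @param log_odds named list: per covariate, named numeric of
#'   non-reference log-odds.
#' @export
linear_predictor <- function(covariates, log_odds) {
  lp <- numeric(nrow(covariates))
  spec <- model_spec()
  for (cov in names(log_odds)) {
    x <- covariates[[cov]]
    if (is.null(x)) stop("covariate missing: ", cov)
    if (!is.null(spec[[cov]])) {
      known <- c(spec[[cov]], if (cov == "destination_group") "died")
      bad <- !x %in% known
      if (any(bad))
        stop("unknown category in ", cov, ": ",
             paste(unique(x[bad]), collapse = ", "))
    }
    beta <- log_odds[[cov]][x]
    beta[is.na(beta)] <- 0
    lp <- lp + beta
  }
  lp
}

#' Bernoulli treatment assignment from the logistic model
#'
#' Each patient's flag is a Bernoulli draw with probability
#' `plogis(intercept + sum of category log-odds)`.
#'
#' @param covariates covariate data.frame.
#' @param log_odds per-covariate named log-odds (see
#'   [linear_predictor()]).
#' @param intercept model intercept.
#' @param seed RNG seed.
#' @return integer 0/1 vector.
#' @export
assign_followup_treatment <- function(covariates, log_odds, intercept, seed) {
  lp <- linear_predictor(covariates, log_odds)
  set.seed(seed)
  stats::rbinom(nrow(covariates), 1, stats::plogis(intercept + lp))
}

# ---------------------------------------------------------------------------
# fill-history synthesis

default_drug_code <- function(classes) {
  map <- drug_class_map()
  map$drug_code[match(classes, map$drug_class)]
}

# deterministic fill-schedule construction for one treated patient.
# classes/supplies: the first regimen; t0: first fill day; E: exclusive end
# of follow-up; target: intended MPR; aux: pre-drawn random quantities.
# Guarantees (under the generator's clamped targets): the realized MPR is
# within +-0.05 of target and on the intended side of `threshold`, and the
# exposure module detects exactly the injected pattern.
build_fill_schedule <- function(classes, supplies, pattern, target, t0, E,
                                aux, gap = 60, threshold = 0.8) {
  k <- length(classes)
  L <- E - t0
  sbar <- mean(supplies)
  adherent <- target >= threshold
  emit <- function(dates, cls, sup)
    data.frame(date = dates, drug_class = cls, days_supply = sup,
               stringsAsFactors = FALSE)
  rr_class <- function(j) classes[(j - 1L) %% k + 1L]
  rr_supply <- function(j) supplies[(j - 1L) %% k + 1L]

  # contiguous stream: first k fills at t0, then extensions back to back;
  # returns dates/classes/supplies and the union coverage end
  contiguous <- function(n) {
    dates <- rep(t0, min(k, n))
    cls <- classes[seq_len(min(k, n))]
    sup <- supplies[seq_len(min(k, n))]
    cover <- t0 + max(sup)
    j <- k
    while (j < n) {
      j <- j + 1
      dates <- c(dates, cover); cls <- c(cls, rr_class(j))
      sup <- c(sup, rr_supply(j))
      cover <- cover + rr_supply(j)
    }
    list(dates = dates, cls = cls, sup = sup, cover = cover)
  }
  # spread stream for persistence: gaps g < gap after each extension so the
  # regimen spell is unbroken and the terminal gap stays < gap
  spread <- function(n) {
    ext <- n - k
    span_contig <- max(supplies) + if (ext > 0)
      sum(vapply((k + 1):n, rr_supply, numeric(1))) else 0
    g <- if (ext > 0)
      max(0, min(gap - 1, ceiling((L - (gap - 1) - span_contig) / ext)))
    else 0
    dates <- rep(t0, k); cls <- classes; sup <- supplies
    cover <- t0 + max(supplies)
    if (ext > 0) for (j in (k + 1):n) {
      d <- cover + g
      dates <- c(dates, d); cls <- c(cls, rr_class(j))
      sup <- c(sup, rr_supply(j))
      cover <- d + rr_supply(j)
    }
    list(dates = dates, cls = cls, sup = sup, cover = cover)
  }
  full_coverage <- function() {
    dates <- rep(t0, k); cls <- classes; sup <- supplies
    cover <- t0 + max(supplies)
    j <- k
    while (cover < E) {
      j <- j + 1
      dates <- c(dates, cover); cls <- c(cls, rr_class(j))
      sup <- c(sup, rr_supply(j))
      cover <- cover + rr_supply(j)
    }
    list(dates = dates, cls = cls, sup = sup, cover = cover)
  }
  realized <- function(st) sum(pmin(st$sup, E - st$dates)) / L
  # smallest fill count whose spread schedule can keep the terminal gap
  # below `gap` (the k initial fills share one date, so only n - k fills
  # extend the span)
  n_floor <- function() {
    need <- L - (gap - 1) - max(supplies)
    k + max(0L, as.integer(ceiling(need / (min(supplies) + gap - 1))))
  }
  # nudge the fill count so the realized MPR lands on the intended side of
  # the adherence threshold (30-day supply granularity can cross it)
  side_fix <- function(n, build, floor_n = k) {
    st <- build(n)
    if (adherent && realized(st) < threshold) st <- build(n + 1)
    if (!adherent && realized(st) >= threshold && n - 1 >= floor_n)
      st <- build(n - 1)
    st
  }

  if (pattern == "persistent") {
    if (target >= 0.97) {
      st <- full_coverage()
    } else {
      n <- max(n_floor(), k, round(target * L / sbar))
      st <- side_fix(n, spread, floor_n = max(n_floor(), k))
    }
    return(emit(st$dates, st$cls, st$sup))
  }
  if (pattern == "augment") {
    s_a <- aux$aug_supply
    n_aug <- 3L
    n <- max(n_floor(), k, round((target * L - n_aug * s_a) / sbar))
    st <- spread(n)
    if (realized(st) + n_aug * s_a / L >= threshold && !adherent &&
        n - 1 >= max(n_floor(), k))
      st <- spread(n - 1)
    if (realized(st) + n_aug * s_a / L < threshold && adherent)
      st <- spread(n + 1)
    span <- st$cover - t0
    off_max <- span - n_aug * s_a
    if (off_max < 16)
      stop("generation error: augmentation incompatible with coverage span")
    off <- 16 + floor(aux$u * (off_max - 16 + 1))
    aug_dates <- t0 + off + s_a * (seq_len(n_aug) - 1)
    return(emit(c(st$dates, aug_dates),
                c(st$cls, rep(aux$aug_class, n_aug)),
                c(st$sup, rep(s_a, n_aug))))
  }
  # discontinuation patterns: contiguous pre-spell, >= gap-day lapse, then
  # (optionally) a switch or restart stream
  n_tot <- max(k, round(target * L / sbar))
  with_post <- pattern %in% c("discontinue_switch", "discontinue_restart")
  if (with_post) n_tot <- max(k + 1L, n_tot)
  n_pre <- if (with_post)
    max(k, min(n_tot - 1L, k + aux$pre_geom)) else n_tot
  repeat {
    pre <- contiguous(n_pre)
    if (E - pre$cover >= gap || n_pre <= k) break
    n_pre <- n_pre - 1L
  }
  if (E - pre$cover < gap)
    stop("generation error: discontinuation incompatible with follow-up length")
  if (!with_post) {
    st <- pre
    if (realized(st) >= threshold && n_pre > k) st <- contiguous(n_pre - 1L)
    return(emit(st$dates, st$cls, st$sup))
  }
  restart <- pattern == "discontinue_restart"
  post_class <- if (restart) classes[1] else aux$switch_class
  s_post <- if (restart) supplies[1] else aux$switch_supply
  n_post <- max(1L, round((target * L - sum(pre$sup)) / s_post))
  gap_min <- if (restart) gap else 2
  gp <- gap_min + aux$gap_extra
  repeat {
    ds <- pre$cover + gp
    if (ds + n_post * s_post <= E) break
    if (gp > gap_min) { gp <- max(gap_min, gp - 30) ; next }
    if (n_post > 1L) { n_post <- n_post - 1L ; next }
    stop("generation error: switch/restart does not fit in follow-up")
  }
  post_dates <- ds + s_post * (seq_len(n_post) - 1)
  emit(c(pre$dates, post_dates),
       c(pre$cls, rep(post_class, n_post)),
       c(pre$sup, rep(s_post, n_post)))
}

#' Synthesize one patient's follow-up fill history
#'
#' Realizes a treated patient's dispensation list so that the exposure
#' module detects exactly the injected pattern (`persistent`,
#' `discontinue`, `discontinue_switch`, `discontinue_restart`, `augment`)
#' and the recomputed MPR lands within 0.05 of `target_mpr` and on the
#' intended side of the adherence threshold. Untreated patients yield an
#' empty list; treated patients receive their first fill within 14 days
#' of discharge.
#'
#' @param treated logical flag.
#' @param regimen character vector of first-regimen classes.
#' @param target_mpr intended MPR in \[0, 1\].
#' @param pattern injected event pattern.
#' @param config generator configuration (supplies, gap rule).
#' @param seed RNG seed for the auxiliary draws.
#' @param discharge index discharge day (default 0).
#' @return data.frame of dispensations (`date`, `drug_class`,
#'   `days_supply`, `setting`).
#' @export
synthesize_fill_history <- function(treated, regimen, target_mpr, pattern,
                                    config, seed, discharge = 0) {
  if (!treated)
    return(data.frame(date = numeric(0), drug_class = character(0),
                      days_supply = numeric(0), setting = character(0),
                      stringsAsFactors = FALSE))
  stopifnot(target_mpr >= 0, target_mpr <= 1,
            pattern %in% c("persistent", "discontinue", "discontinue_switch",
                           "discontinue_restart", "augment"))
  set.seed(seed)
  delay <- 1 + min(13, stats::rgeom(1, 0.5))
  sup <- config$supply_days_by_class
  other <- setdiff(names(config$switch_class_mix), regimen)
  sw_cl <- if (length(other))
    sample(other, 1, prob = config$switch_class_mix[other]) else "denosumab"
  ot2 <- setdiff(names(config$augment_class_mix), regimen)
  ag_cl <- if (length(ot2))
    sample(ot2, 1, prob = config$augment_class_mix[ot2]) else "calcium"
  aux <- list(pre_geom = stats::rgeom(1, 0.5),
              gap_extra = sample(0:90, 1), u = stats::runif(1),
              switch_class = sw_cl, switch_supply = unname(sup[sw_cl]),
              aug_class = ag_cl, aug_supply = unname(sup[ag_cl]))
  t0 <- discharge + delay
  E <- discharge + 366
  fills <- build_fill_schedule(regimen, unname(sup[regimen]), pattern,
                               target_mpr, t0, E, aux,
                               gap = config$gap_days,
                               threshold = config$mpr_threshold)
  fills$setting <- "outpatient"
  fills
}

# pattern-conditional target-MPR draw: the configured decile histogram is
# restricted to the bins each pattern can realize (and split at the
# adherence threshold for non-discontinuers), so the marginal adherent
# share among treated patients equals the configured rate
draw_target_mpr <- function(pattern, adherent, k, sbar, L, config) {
  h <- config$mpr_histogram
  rng <- switch(pattern,
    discontinue = c(k * sbar / L + 0.002, 0.76),
    discontinue_switch = ,
    discontinue_restart = c((k + 1) * sbar / L + 0.002, 0.70),
    persistent = if (adherent) c(0.84, 1) else c(0.45, 0.76),
    augment = if (adherent) c(0.84, 1) else c(0.62, 0.76))
  lo_all <- (seq_len(10) - 1) / 10
  hi_all <- seq_len(10) / 10
  ok <- hi_all > rng[1] & lo_all < rng[2]
  w <- h[ok]
  b <- if (sum(w) > 0) sample(which(ok), 1, prob = w) else which(ok)[1]
  lo <- max(lo_all[b], rng[1]); hi <- min(hi_all[b], rng[2])
  stats::runif(1, lo, hi)
}

#' Generate a synthetic claims dataset
#'
#' Emits the full record set the analysis pipeline consumes — patients,
#' encounters, hospitalizations, diagnoses, dispensations (baseline fills,
#' inpatient administrations, follow-up fills) and ADL assessments — plus
#' a truth table of the generating values that the pipeline never reads.
#' All dates are integer day offsets with day 0 = the patient's index
#' admission. Follow-up treatment receipt is drawn from the configured
#' logistic model with an intercept calibrated so the marginal rate equals
#' `target_followup_rate`; episode patterns and target MPRs are drawn at
#' the configured rates and realized by [synthesize_fill_history()]'s
#' schedule construction. Fixing the seed fixes every emitted record.
#'
#' @param config a validated generator configuration.
#' @return list of class `osteoclaims_dataset`.
#' @export
generate_dataset <- function(config) {
  config <- validate_generator_config(unclass(config))
  n <- config$n_patients
  cov <- sample_covariates(config, n, stage_seed(config$seed, "covariates"))
  pid <- if (n > 0) sprintf("P%06d", seq_len(n)) else character(0)

  # treatment flags -------------------------------------------------------
  lp <- if (n > 0) linear_predictor(cov, config$treatment_log_odds) else numeric(0)
  b0 <- if (n > 0) calibrate_intercept(lp, config$target_followup_rate) else 0
  fu_trt <- if (n > 0)
    assign_followup_treatment(cov, config$treatment_log_odds, b0,
                              stage_seed(config$seed, "treatment")) == 1
  else logical(0)

  set.seed(stage_seed(config$seed, "hospital"))
  idx_p <- config$index_treatment_rate_by_cohort[cov$fracture_cohort]
  idx_trt <- stats::runif(n) < idx_p
  bl_trt <- stats::runif(n) < config$baseline_treatment_rate
  los <- cov$los_days
  discharge <- los - 1L

  # hospitalizations ------------------------------------------------------
  frac_codes <- list(hip = c("S72.0", "S72.1"),
                     vertebrae = c("S22.0", "S32.0"),
                     nvnh = c("S52.5", "S42.2", "S32.1"))
  fr <- vapply(seq_len(n), function(i) {
    ch <- frac_codes[[cov$fracture_cohort[i]]]
    ch[1 + (stats::runif(1) < 0.35)]
  }, character(1))
  outcome <- ifelse(cov$discharge_destination == "died", "death",
                    sample(c("healed", "remission", "no_change",
                             "exacerbation", "other"), max(n, 1),
                           replace = TRUE,
                           prob = c(0.948, 0.003, 0.028, 0.001, 0.02))[seq_len(n)])
  hosp <- data.frame(
    patient_id = pid, admission_date = rep(0L, n), discharge_date = discharge,
    route = cov$route, admission_type = cov$admission_type,
    discharge_destination = cov$discharge_destination, outcome = outcome,
    fracture_codes = fr, n_meds_at_discharge = cov$n_meds,
    stringsAsFactors = FALSE)

  # encounters ------------------------------------------------------------
  set.seed(stage_seed(config$seed, "encounters"))
  enc <- list(
    data.frame(patient_id = pid, date = -365L - sample(0:200, n, TRUE),
               setting = rep("outpatient", n), stringsAsFactors = FALSE),
    data.frame(patient_id = pid,
               date = discharge + 365L + sample(0:60, n, TRUE),
               setting = rep("outpatient", n), stringsAsFactors = FALSE))
  ph <- cov$previous_hospitalization == "yes"
  if (any(ph))
    enc[[3]] <- data.frame(patient_id = pid[ph],
                           date = -sample(30:300, sum(ph), TRUE),
                           setting = "inpatient", stringsAsFactors = FALSE)
  encounters <- do.call(rbind, enc)

  # diagnoses: Charlson codes realizing the sampled CCI band, prior
  # osteoporosis / fracture codes realizing the prior-dx combination ------
  set.seed(stage_seed(config$seed, "diagnoses"))
  cci_codes <- list("0" = character(0), "1" = "I50.0",
                    "2" = c("I50.0", "I63.9"),
                    "3" = c("I50.0", "I63.9", "F03"),
                    ">3" = c("C80", "I50.0"))
  dx <- vector("list", n)
  for (i in seq_len(n)) {
    codes <- cci_codes[[cov$cci_band[i]]]
    if (cov$prior_dx[i] != "neither") codes <- c(codes, "M81.9")
    if (cov$prior_dx[i] == "osteo_and_fracture") codes <- c(codes, "S52.5")
    if (length(codes))
      dx[[i]] <- data.frame(patient_id = pid[i],
                            date = -sample(30:330, length(codes), TRUE),
                            code = codes, stringsAsFactors = FALSE)
  }
  diagnoses <- if (any(!vapply(dx, is.null, logical(1))))
    do.call(rbind, dx[!vapply(dx, is.null, logical(1))])
  else data.frame(patient_id = character(0), date = integer(0),
                  code = character(0), stringsAsFactors = FALSE)

  # follow-up fill histories ----------------------------------------------
  set.seed(stage_seed(config$seed, "fills_followup"))
  sup <- config$supply_days_by_class
  p_disc <- config$discontinuation_rate
  p_sr <- config$switch_restart_given_disc
  p_aug <- min(1, config$augmentation_rate / max(1e-9, 1 - p_disc))
  p_adh <- min(1, config$adherent_rate_treated / max(1e-9, 1 - p_disc))
  reg_names <- names(config$regimen_mix$followup)

  trt_idx <- which(fu_trt)
  pattern <- rep("none", n)
  target <- rep(NA_real_, n)
  fills_fu <- vector("list", length(trt_idx))
  if (length(trt_idx)) {
    u_disc <- stats::runif(length(trt_idx))
    u_sr <- stats::runif(length(trt_idx))
    u_restart <- stats::runif(length(trt_idx))
    u_aug <- stats::runif(length(trt_idx))
    u_adh <- stats::runif(length(trt_idx))
    reg_draw <- sample(reg_names, length(trt_idx), TRUE,
                       prob = config$regimen_mix$followup)
    delay <- 1L + pmin(13L, stats::rgeom(length(trt_idx), 0.5))
    pre_geom <- stats::rgeom(length(trt_idx), 0.5)
    gap_extra <- sample(0:90, length(trt_idx), TRUE)
    u_off <- stats::runif(length(trt_idx))
    u_cls <- stats::runif(length(trt_idx))

    for (j in seq_along(trt_idx)) {
      i <- trt_idx[j]
      regimen <- strsplit(reg_draw[j], "+", fixed = TRUE)[[1]]
      k <- length(regimen)
      pat <- if (u_disc[j] < p_disc) {
        if (u_sr[j] < p_sr) {
          if (u_restart[j] < config$restart_share) "discontinue_restart"
          else "discontinue_switch"
        } else "discontinue"
      } else if (u_aug[j] < p_aug) "augment" else "persistent"
      adh <- pat %in% c("persistent", "augment") && u_adh[j] < p_adh
      if (pat == "augment" && length(regimen) > 1) {
        # augmented regimens start single-class: a second original class
        # plus the added one cannot stay persistent at feasible MPR targets
        regimen <- regimen[1]
        k <- 1L
      }
      t0 <- discharge[i] + delay[j]
      E <- discharge[i] + 366L
      L <- E - t0
      sbar <- mean(sup[regimen])
      tg <- draw_target_mpr(pat, adh, k, sbar, L, config)
      other <- setdiff(names(config$switch_class_mix), regimen)
      w <- config$switch_class_mix[other] / sum(config$switch_class_mix[other])
      sw_cl <- other[findInterval(u_cls[j], cumsum(w)) + 1L]
      ot2 <- setdiff(names(config$augment_class_mix), regimen)
      w2 <- config$augment_class_mix[ot2] / sum(config$augment_class_mix[ot2])
      ag_cl <- ot2[findInterval(u_cls[j], cumsum(w2)) + 1L]
      aux <- list(pre_geom = pre_geom[j], gap_extra = gap_extra[j],
                  u = u_off[j], switch_class = sw_cl,
                  switch_supply = unname(sup[sw_cl]),
                  aug_class = ag_cl, aug_supply = unname(sup[ag_cl]))
      f <- build_fill_schedule(regimen, unname(sup[regimen]), pat, tg, t0, E,
                               aux, gap = config$gap_days,
                               threshold = config$mpr_threshold)
      f$patient_id <- pid[i]
      f$setting <- "outpatient"
      fills_fu[[j]] <- f
      pattern[i] <- pat
      target[i] <- tg
    }
  }

  # inpatient administrations during the index stay ------------------------
  set.seed(stage_seed(config$seed, "fills_index"))
  idx_i <- which(idx_trt)
  fills_idx <- vector("list", length(idx_i))
  if (length(idx_i)) {
    reg_i <- sample(names(config$regimen_mix$index), length(idx_i), TRUE,
                    prob = config$regimen_mix$index)
    start_d <- pmin(stats::rgeom(length(idx_i), 0.16), discharge[idx_i])
    dur <- 1L + stats::rgeom(length(idx_i), 0.04)
    for (j in seq_along(idx_i)) {
      i <- idx_i[j]
      cls <- strsplit(reg_i[j], "+", fixed = TRUE)[[1]]
      d <- min(start_d[j], discharge[i])
      fills_idx[[j]] <- data.frame(
        patient_id = pid[i], date = d, drug_class = cls,
        days_supply = max(1, min(dur[j], discharge[i] - d + 1)),
        setting = "inpatient", stringsAsFactors = FALSE)
    }
  }

  # baseline fills ---------------------------------------------------------
  set.seed(stage_seed(config$seed, "fills_baseline"))
  bl_i <- which(bl_trt)
  fills_bl <- vector("list", length(bl_i))
  if (length(bl_i)) {
    reg_b <- sample(names(config$regimen_mix$baseline), length(bl_i), TRUE,
                    prob = config$regimen_mix$baseline)
    long <- stats::runif(length(bl_i)) < 0.6
    D <- ifelse(long, 270L + sample(0:95, length(bl_i), TRUE),
                1L + sample(0:268, length(bl_i), TRUE))
    u_stop <- stats::runif(length(bl_i))
    for (j in seq_along(bl_i)) {
      i <- bl_i[j]
      cls <- strsplit(reg_b[j], "+", fixed = TRUE)[[1]]
      s <- max(sup[cls])
      d0 <- -D[j]
      dates <- seq(d0, -1L, by = s)
      # most baseline users lapse before admission (partial coverage)
      keep <- seq_len(max(1, min(length(dates),
                                 1 + stats::rgeom(1, 1 - 0.75^(1 / 1)))))
      dates <- dates[keep]
      fills_bl[[j]] <- data.frame(
        patient_id = pid[i], date = rep(dates, each = length(cls)),
        drug_class = rep(cls, length(dates)),
        days_supply = rep(unname(sup[cls]), length(dates)),
        setting = "outpatient", stringsAsFactors = FALSE)
    }
  }

  all_fills <- c(fills_fu, fills_idx, fills_bl)
  all_fills <- all_fills[!vapply(all_fills, is.null, logical(1))]
  dispensations <- if (length(all_fills)) {
    d <- do.call(rbind, all_fills)
    d$drug_code <- default_drug_code(d$drug_class)
    d <- d[order(d$patient_id, d$date, d$drug_class),
           c("patient_id", "date", "drug_code", "drug_class", "days_supply",
             "setting")]
    rownames(d) <- NULL
    d
  } else data.frame(patient_id = character(0), date = numeric(0),
                    drug_code = character(0), drug_class = character(0),
                    days_supply = numeric(0), setting = character(0),
                    stringsAsFactors = FALSE)

  # ADL assessments --------------------------------------------------------
  set.seed(stage_seed(config$seed, "adl"))
  adl <- data.frame(patient_id = pid, stringsAsFactors = FALSE)
  for (item in names(config$adl_marginals)) {
    mix <- config$adl_marginals[[item]]
    lev <- names(mix)
    x <- if (n > 0) sample(lev, n, TRUE, prob = mix) else character(0)
    adl[[item]] <- suppressWarnings(as.integer(ifelse(x == "missing", NA, x)))
  }

  patients <- data.frame(
    patient_id = pid, sex = cov$sex,
    birth_year = config$index_year - cov$age_years,
    smoking_index = cov$smoking_index, stringsAsFactors = FALSE)

  truth <- data.frame(
    patient_id = pid, followup_treated = fu_trt, index_treated = idx_trt,
    baseline_treated = bl_trt, pattern = pattern, target_mpr = target,
    linear_predictor = lp, stringsAsFactors = FALSE)

  structure(list(patients = patients, encounters = encounters,
                 hospitalizations = hosp, diagnoses = diagnoses,
                 dispensations = dispensations, adl = adl, truth = truth,
                 intercept = b0, config = config),
            class = "osteoclaims_dataset")
}

#' Write / read a dataset as delimited text tables
#'
#' One CSV per record type (`patients`, `encounters`, `hospitalizations`,
#' `diagnoses`, `dispensations`, `adl`, `truth`); dates are integer day
#' offsets from each patient's index admission.
#'
#' @param dataset an `osteoclaims_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("patients", "encounters", "hospitalizations", "diagnoses",
               "dispensations", "adl", "truth"))
    utils::write.csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  out <- list()
  for (nm in c("patients", "encounters", "hospitalizations", "diagnoses",
               "dispensations", "adl", "truth"))
    out[[nm]] <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                 stringsAsFactors = FALSE,
                                 colClasses = c(patient_id = "character"))
  structure(out, class = "osteoclaims_dataset")
}
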