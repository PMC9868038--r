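# Brute-force day-grid simulator of the episode rules, used as an
# independent oracle against the package's interval arithmetic. Coverage is
# materialized as boolean day vectors; bridging, spells and overlaps are
# computed by run-length scanning.

oracle_patient <- function(date, cls, sup, discharge, followup_end,
                           gap = 60, window = 14, threshold = 0.8,
                           min_overlap = 60) {
  E <- followup_end + 1          # exclusive end of follow-up
  H <- E + 800                   # horizon past any supply end
  off <- discharge               # grid index 1 == day `discharge`
  ndays <- H - off

  bridge_vec <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (q in seq_along(r$values))
      if (!r$values[q] && q > 1 && q < length(r$values) && r$lengths[q] < gap)
        v[starts[q]:ends[q]] <- TRUE
    v
  }

  out <- list(followup_treated = FALSE, mpr = NA_real_,
              adherent = NA, first_regimen = NA_character_,
              discontinued = NA, disc_date = NA_real_,
              sr_kind = NA_character_, augmented = NA,
              aug_date = NA_real_)
  fu_in <- date >= discharge + 1 & date <= followup_end
  if (!any(fu_in)) return(out)
  out$followup_treated <- TRUE

  # MPR by per-day counting over the observation period
  t0 <- min(date[fu_in])
  num <- 0L
  for (j in which(fu_in))
    for (d in date[j]:(date[j] + sup[j] - 1))
      if (d < E) num <- num + 1L
  out$mpr <- min(1, num / (E - t0))
  out$adherent <- out$mpr >= threshold

  # per-class coverage: day-by-day stockpiling, then gap bridging
  classes <- unique(cls)
  cov <- list()
  for (cc in classes) {
    v <- rep(FALSE, ndays)
    sel <- which(cls == cc)
    sel <- sel[order(date[sel])]
    run_end <- -Inf
    for (j in sel) {
      s <- max(date[j], run_end)
      for (d in s:(s + sup[j] - 1))
        if (d >= off && d < H) v[d - off + 1] <- TRUE
      run_end <- s + sup[j]
    }
    cov[[cc]] <- bridge_vec(v)
  }

  reg_sel <- date >= discharge & date <= discharge + window
  if (!any(reg_sel)) return(out)
  reg_classes <- sort(unique(cls[reg_sel]))
  reg_start <- min(date[reg_sel])
  out$first_regimen <- paste(reg_classes, collapse = "+")

  # regimen exposure spells: union of regimen coverage with < gap lapses
  # filled in; a spell boundary is a true >= gap-day lapse
  b <- bridge_vec(Reduce(`|`, cov[reg_classes]))
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bl <- which(r$values)
  first_end <- off + ends[bl[1]]               # exclusive end day of spell 1
  tail_gap <- if (length(bl) > 1) (off + starts[bl[2]] - 1) - first_end
              else E - first_end
  if (tail_gap >= gap) {
    out$discontinued <- TRUE
    out$disc_date <- first_end
    after <- which(date >= first_end & date <= followup_end)
    if (length(after)) {
      d0 <- min(date[after])
      cls0 <- unique(cls[date == d0 & date >= first_end])
      out$sr_kind <- if (any(cls0 %in% reg_classes)) "restart" else "switch"
    }
  } else out$discontinued <- FALSE

  best <- Inf
  for (cc in setdiff(classes, reg_classes)) {
    cdays <- which(cov[[cc]])
    if (!length(cdays)) next
    cl_start <- off + cdays[1] - 1
    if (cl_start <= reg_start + window) next
    if (sum(cov[[cc]] & b) >= min_overlap && cl_start < best) best <- cl_start
  }
  out$augmented <- is.finite(best)
  if (out$augmented) out$aug_date <- best
  out
}

# random follow-up fill history of up to max_fills fills
random_fill_history <- function(max_fills = 6, discharge = 0) {
  n <- sample(1:max_fills, 1)
  data.frame(
    patient_id = "P1",
    date = discharge + sample(0:365, n, replace = TRUE),
    drug_class = sample(c("bisphosphonate", "active_vitamin_D3",
                          "teriparatide", "denosumab"), n, replace = TRUE),
    days_supply = sample(c(7, 14, 28, 30, 60, 90, 180), n, replace = TRUE),
    setting = "outpatient",
    stringsAsFactors = FALSE)
}
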