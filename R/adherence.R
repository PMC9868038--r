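#' Observation period for adherence
#'
#' A half-open day interval `[start, end)`; the default pipeline anchors
#' it at the first post-discharge fill and ends it one day past the last
#' follow-up day, so `length = end - start` is the number of observation
#' days.
#'
#' @param start,end integer day indices, `end > start`.
#' @export
observation_period <- function(start, end) {
  if (end - start <= 0) stop("observation period must have positive length")
  list(start = start, end = end, length = end - start)
}

#' Medication possession ratio
#'
#' The MPR is the sum of the days' supply dispensed inside the observation
#' period divided by the period length. Each fill's supply is truncated at
#' the period end; fills dated outside the period contribute nothing; the
#' ratio is capped at 1.0 (stockpiled supply is never discarded before the
#' cap, so overlapping fills can reach the cap).
#'
#' @param fills data.frame with `date` and `days_supply` (resolved).
#' @param period an [observation_period()].
#' @return MPR in \[0, 1\].
#' @export
compute_mpr <- function(fills, period) {
  if (is.null(period$length) || period$length <= 0)
    stop("observation period must have positive length")
  if (is.null(fills) || nrow(fills) == 0) return(0)
  inside <- fills$date >= period$start & fills$date < period$end
  num <- sum(pmin(fills$days_supply[inside],
                  period$end - fills$date[inside]))
  min(1, num / period$length)
}

#' Dichotomous adherence and MPR decile bin
#'
#' An MPR of at least the threshold (default 0.80) is adherent. Decile
#' bins follow the reporting convention `0.00-0.10`, `>0.10-0.20`, ...,
#' `>0.90-1.00`: each bin is left-open except the first, so the boundary
#' value 0.80 falls in `>0.70-0.80` yet is adherent.
#'
#' @param mpr value in \[0, 1\].
#' @param threshold adherence cutoff.
#' @return list `mpr`, `decile_bin`, `adherent`.
#' @export
classify_adherence <- function(mpr, threshold = 0.80) {
  if (is.na(mpr) || mpr < 0 || mpr > 1)
    stop("mpr must lie in [0, 1]")
  list(mpr = mpr, decile_bin = mpr_bin(mpr), adherent = mpr >= threshold)
}

mpr_bin_levels <- function() {
  c("0.00-0.10", paste0(">0.", seq(10, 90, 10), "-",
                        c(paste0("0.", seq(20, 90, 10)), "1.00")))
}

mpr_bin <- function(mpr) {
  lev <- mpr_bin_levels()
  idx <- pmax(1, ceiling(round(mpr * 10, 9)))  # 0.80 -> bin 8
  lev[pmin(idx, 10)]
}
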