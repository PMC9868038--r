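#' Covariate specification for the treatment-receipt model
#'
#' Covariates and reference levels of the multivariable logistic
#' regression of treatment receipt at follow-up: age band (ref 50-59),
#' sex (ref male), length-of-stay band (ref <15), previous hospitalization
#' (ref no), prior diagnosis combination (ref neither), route group (ref
#' home), admission-type group (ref planned), CCI band (ref 0), discharge
#' destination group (ref nursing/geriatric/social-welfare facility), and
#' medications-at-discharge band (ref 0).
#'
#' @return named list: per covariate, the level vector with the reference
#'   first.
#' @export
model_spec <- function() {
  list(
    age_band = c("50-59", "60-69", "70-79", "80-89", ">=90"),
    sex = c("male", "female"),
    los_band = c("<15", "15-30", ">30"),
    previous_hospitalization = c("no", "yes"),
    prior_dx = c("neither", "osteo_only", "osteo_and_fracture"),
    route_group = c("home", "other"),
    admission_type_group = c("planned", "unplanned_nonemergency", "emergency"),
    cci_band = c("0", "1", "2", "3", ">3"),
    destination_group = c("facility", "hospital", "home", "other_missing"),
    meds_at_discharge = c("0", "1", "2", ">=3"))
}

#' Design matrix for the logistic model
#'
#' One indicator column per non-reference category plus an intercept;
#' reference-level patients are all-zero on their covariate's columns.
#' Patients whose destination group is `died` are excluded (the shipped
#' default for the regression denominator) unless `keep_died`.
#'
#' @param profiles baseline-profile data.frame holding every spec
#'   covariate (see [build_baseline_profiles()]).
#' @param spec a [model_spec()].
#' @param keep_died keep destination-died patients in the frame.
#' @return list with `frame` (factor data.frame), `design` (model matrix)
#'   and `kept` (logical row filter applied to `profiles`).
#' @export
encode_design <- function(profiles, spec = model_spec(), keep_died = FALSE) {
  kept <- rep(TRUE, nrow(profiles))
  if (!keep_died && !is.null(profiles$destination_group))
    kept <- profiles$destination_group != "died"
  frame <- list()
  for (cov in names(spec)) {
    x <- profiles[[cov]][kept]
    if (is.null(x)) stop("covariate missing from profiles: ", cov)
    bad <- !x %in% spec[[cov]]
    if (any(bad))
      stop("unseen category in ", cov, ": ",
           paste(unique(x[bad]), collapse = ", "))
    frame[[cov]] <- factor(x, levels = spec[[cov]])
  }
  frame <- as.data.frame(frame, stringsAsFactors = FALSE)
  design <- stats::model.matrix(~ ., data = frame)
  list(frame = frame, design = design, kept = kept)
}

#' Fit the logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binomial fit (IRLS via [stats::glm()]), converging
#' when the relative deviance change drops below 1e-8 or after 100
#' iterations. Rank-deficient designs and (quasi-)separation are errors
#' naming the offending columns.
#'
#' @param frame factor data.frame from [encode_design()].
#' @param outcome binary outcome vector (0/1), same length.
#' @return object of class `osteoclaims_fit`: the glm fit plus
#'   bookkeeping.
#' @export
fit_logistic <- function(frame, outcome) {
  stopifnot(nrow(frame) == length(outcome))
  if (length(unique(outcome)) < 2)
    stop("need at least one case and one non-case")
  dat <- cbind(frame, .y = outcome)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  if (!fit$converged)
    stop("IRLS did not converge (possible separation)")
  big <- abs(cf) > 15
  if (any(big[-1]))
    stop("possible complete separation in columns: ",
         paste(names(cf)[-1][big[-1]], collapse = ", "))
  structure(list(glm = fit, coefficients = cf, vcov = stats::vcov(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, n_iterations = fit$iter),
            class = "osteoclaims_fit")
}

#' Odds ratios with Wald 95% confidence intervals
#'
#' For every non-intercept coefficient: OR = exp(beta), CI =
#' exp(beta +- 1.96 se), and the Wald p-value.
#'
#' @param fit an [fit_logistic()] result.
#' @return data.frame `term`, `odds_ratio`, `ci95_low`, `ci95_high`,
#'   `p_value`.
#' @export
estimate_effects <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge")
  cf <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  keep <- names(cf) != "(Intercept)"
  z <- cf / se
  data.frame(
    term = names(cf)[keep],
    odds_ratio = exp(cf[keep]),
    ci95_low = exp(cf[keep] - 1.96 * se[keep]),
    ci95_high = exp(cf[keep] + 1.96 * se[keep]),
    p_value = 2 * stats::pnorm(-abs(z[keep])),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Concordance statistic (AUC)
#'
#' The probability that a randomly chosen case receives a higher fitted
#' probability than a randomly chosen non-case, ties counted 1/2 —
#' computed by the rank-sum identity.
#'
#' @param fitted_probabilities numeric score vector.
#' @param outcome binary vector of the same length.
#' @export
compute_auc <- function(fitted_probabilities, outcome) {
  stopifnot(length(fitted_probabilities) == length(outcome))
  y <- as.integer(outcome)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one non-case")
  r <- rank(fitted_probabilities)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibrate the generator intercept to a target marginal rate
#'
#' Finds the intercept `b0` such that the mean of
#' `plogis(b0 + linear_predictor)` over the supplied sample equals the
#' target rate to within 1e-6, by monotone bisection.
#'
#' @param linear_predictor per-patient sum of category log-odds.
#' @param target_rate desired marginal event rate, in (0, 1).
#' @export
calibrate_intercept <- function(linear_predictor, target_rate) {
  if (target_rate <= 0 || target_rate >= 1)
    stop("target rate must lie strictly inside (0, 1)")
  f <- function(b0) mean(stats::plogis(b0 + linear_predictor)) - target_rate
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) stop("target rate unreachable")
  mid <- (lo + hi) / 2
  for (i in 1:200) {
    fm <- f(mid)
    if (abs(fm) < 1e-10) break
    if (fm < 0) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
  }
  if (abs(f(mid)) > 1e-6) stop("bisection failed to reach target rate")
  mid
}
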