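#' Configuration for the synthetic TBI cohort generator
#'
#' Builds and validates the full parameter set controlling
#' [generate_cohort()], [apply_untestability()] and [apply_missingness()].
#' The generator emulates the structure of an emergency-phase TBI registry:
#' a latent injury severity drives correlated Glasgow Coma Scale (GCS)
#' component and pupil observations at up to four time points
#' (pre-hospital, referring-hospital ED arrival for secondary transfers,
#' study-hospital ED arrival, ED discharge), baseline covariates of the
#' IMPACT prognostic family, and an ordinal 8-category GOSE outcome at
#' 3, 6 and 12 months.
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort at every stage.
#' @param p_transfer probability of a secondary transfer (only transferred
#'   patients have a referring-hospital arrival assessment).
#' @param stratum_probs named probabilities for the `ed` / `hosp` / `icu`
#'   enrolment strata; must sum to 1. Defaults put just under half the
#'   cohort in the ICU stratum, as in large European TBI studies.
#' @param noise_sd_by_timepoint standard deviation of the assessment noise
#'   on the latent neurological scale at each of the four time points.
#'   The default `c(1.0, 0.6, 0.5, 0.4)` encodes "pre-hospital least
#'   reliable, post-stabilisation most reliable".
#' @param resuscitation_drift mean improvement in the latent neurological
#'   state per successive time point (resuscitation effect).
#' @param missing_prob_by_timepoint probability that any given assessment
#'   cell (eye/verbal/motor/pupils) at each time point is not recorded.
#'   Missingness depends only on always-observed fields, so downstream
#'   imputation faces a missing-at-random mechanism by construction.
#' @param intubation,sedation length-2 numeric `c(intercept, slope)` for the
#'   logistic link `plogis(intercept + slope * severity)` giving the
#'   per-time-point probability of endotracheal intubation (verbal
#'   untestable) and deep sedation/paralysis (motor untestable). Slopes
#'   must be non-negative so untestability is monotone in severity.
#' @param outcome_coefficients named weights of the linear predictor of the
#'   GOSE-generating proportional-odds model (see Details).
#' @param gose_cutpoints increasing cutpoints (length 7) of the
#'   proportional-odds outcome model over GOSE categories 1..8.
#' @param recovery_drift shift of the 3-month (minus) and 12-month (plus)
#'   GOSE linear predictor relative to 6 months, on the logit scale.
#' @param gose_copy_sd SD of the noise added to the 3/12-month linear
#'   predictors, making them informative but imperfect auxiliaries.
#' @param covariate_params list of marginal parameters for the baseline
#'   covariates (means, SDs and severity loadings for age, glucose,
#'   haemoglobin; logistic links for tSAH, EDH, hypoxia, hypotension;
#'   Marshall CT class cutpoints). See Details for fields.
#' @param covariate_missing named per-covariate missingness probabilities
#'   (age is never masked).
#' @param gose_missing named missingness probabilities for the 3/6/12-month
#'   GOSE outcomes.
#' @param stratum_missing_shift named additive shift (on the probability
#'   scale) of assessment missingness per stratum; defaults to zero so the
#'   marginal per-time-point missing fraction equals
#'   `missing_prob_by_timepoint`.
#' @param mnar_shift additive shift of the assessment missingness
#'   probability per unit of (unobserved) latent severity. Zero (default)
#'   keeps the mechanism missing-at-random; positive values provide a
#'   missing-not-at-random sensitivity switch.
#'
#' @details
#' The 6-month GOSE is drawn from a proportional-odds model
#' `P(GOSE <= k) = plogis(cutpoint_k - lp)` with linear predictor
#' `lp = -(severity * b_severity) - b_age*(age-45)/10 - b_glucose*(glucose-8)
#'  + b_hb*(hb-13.5) - b_marshall*(marshall-2) - b_tsah*tsah - b_edh*edh`,
#' so higher severity and worse CT findings push probability mass towards
#' low (bad) GOSE categories. `covariate_params` fields: `age_mean`,
#' `age_sd` (truncated to 16..95 and rounded), `glucose_mean`, `glucose_sd`,
#' `glucose_loading` (mmol/L per severity SD), `hb_mean`, `hb_sd`,
#' `hb_loading` (g/dL), `marshall_cutpoints` (length 5, on the
#' severity-plus-noise scale), and `c(intercept, slope)` logistic links
#' `tsah`, `edh`, `hypoxia`, `hypotension`.
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 1)
#' cfg
#' @export
cohort_config <- function(n_patients,
                          seed,
                          p_transfer = 0.30,
                          stratum_probs = c(ed = 0.30, hosp = 0.23, icu = 0.47),
                          noise_sd_by_timepoint = c(1.0, 0.6, 0.5, 0.4),
                          resuscitation_drift = 0.05,
                          missing_prob_by_timepoint = c(0.40, 0.10, 0.05, 0.05),
                          intubation = c(intercept = -2.0, slope = 1.2),
                          sedation = c(intercept = -2.4, slope = 1.0),
                          outcome_coefficients = c(
                            b_severity = 1.6, b_age = 0.30, b_glucose = 0.03,
                            b_hb = 0.03, b_marshall = 0.12, b_tsah = 0.20,
                            b_edh = 0.10),
                          gose_cutpoints = c(-2.6, -1.9, -1.2, -0.5, 0.2,
                                             1.0, 1.9),
                          recovery_drift = 0.30,
                          gose_copy_sd = 0.80,
                          covariate_params = list(
                            age_mean = 45, age_sd = 19,
                            glucose_mean = 8.0, glucose_sd = 2.2,
                            glucose_loading = 0.45,
                            hb_mean = 13.5, hb_sd = 1.7, hb_loading = -0.25,
                            marshall_cutpoints = c(-0.2, 0.6, 1.1, 1.6, 2.1),
                            tsah = c(-1.2, 0.5),
                            edh = c(-2.0, 0.2),
                            hypoxia = c(-1.8, 0.7),
                            hypotension = c(-2.0, 0.7)),
                          covariate_missing = c(
                            glucose = 0.15, hb = 0.12, marshall = 0.08,
                            tsah = 0.08, edh = 0.08,
                            hypoxia = 0.20, hypotension = 0.20),
                          gose_missing = c(gose_3mo = 0.25, gose_6mo = 0.12,
                                           gose_12mo = 0.30),
                          stratum_missing_shift = c(ed = 0, hosp = 0, icu = 0),
                          mnar_shift = 0) {
  n_patients <- check_pos_int(n_patients, "n_patients")
  seed <- check_pos_int(seed, "seed", min = 0L)
  check_prob(p_transfer, "p_transfer")

  if (!is.numeric(stratum_probs) || length(stratum_probs) != 3L)
    config_error("stratum_probs", "must be 3 probabilities named ed/hosp/icu")
  if (is.null(names(stratum_probs)) || !setequal(names(stratum_probs), STRATA))
    config_error("stratum_probs", "must be named ed/hosp/icu")
  stratum_probs <- stratum_probs[STRATA]
  check_prob(unname(stratum_probs), "stratum_probs", 3L)
  if (abs(sum(stratum_probs) - 1) > 1e-12)
    config_error("stratum_probs", "must sum to 1 (within 1e-12)")

  if (!is.numeric(noise_sd_by_timepoint) || length(noise_sd_by_timepoint) != 4L ||
      anyNA(noise_sd_by_timepoint) || any(noise_sd_by_timepoint < 0))
    config_error("noise_sd_by_timepoint", "must be 4 non-negative SDs")
  if (!is.numeric(resuscitation_drift) || length(resuscitation_drift) != 1L ||
      is.na(resuscitation_drift))
    config_error("resuscitation_drift", "must be a single real number")
  check_prob(missing_prob_by_timepoint, "missing_prob_by_timepoint", 4L)

  for (nm in c("intubation", "sedation")) {
    lk <- get(nm)
    if (!is.numeric(lk) || length(lk) != 2L || anyNA(lk))
      config_error(nm, "must be numeric c(intercept, slope)")
    if (lk[[2L]] < 0)
      config_error(nm, "slope must be non-negative (monotone in severity)")
  }

  need <- c("b_severity", "b_age", "b_glucose", "b_hb", "b_marshall",
            "b_tsah", "b_edh")
  if (!all(need %in% names(outcome_coefficients)))
    config_error("outcome_coefficients",
                 paste("must contain", paste(need, collapse = ", ")))
  if (length(gose_cutpoints) != 7L || any(diff(gose_cutpoints) <= 0))
    config_error("gose_cutpoints", "must be 7 strictly increasing cutpoints")

  cm_need <- c("glucose", "hb", "marshall", "tsah", "edh",
               "hypoxia", "hypotension")
  if (!all(cm_need %in% names(covariate_missing)))
    config_error("covariate_missing",
                 paste("must name", paste(cm_need, collapse = ", ")))
  check_prob(unname(covariate_missing[cm_need]), "covariate_missing", 7L)
  if (!all(c("gose_3mo", "gose_6mo", "gose_12mo") %in% names(gose_missing)))
    config_error("gose_missing", "must name gose_3mo, gose_6mo, gose_12mo")
  check_prob(unname(gose_missing[c("gose_3mo", "gose_6mo", "gose_12mo")]),
             "gose_missing", 3L)

  cp <- covariate_params
  cp_need <- c("age_mean", "age_sd", "glucose_mean", "glucose_sd",
               "glucose_loading", "hb_mean", "hb_sd", "hb_loading",
               "marshall_cutpoints", "tsah", "edh", "hypoxia", "hypotension")
  miss <- setdiff(cp_need, names(cp))
  if (length(miss))
    config_error("covariate_params",
                 paste("missing fields:", paste(miss, collapse = ", ")))
  if (any(c(cp$age_sd, cp$glucose_sd, cp$hb_sd) < 0))
    config_error("covariate_params", "SDs must be non-negative")
  if (length(cp$marshall_cutpoints) != 5L || any(diff(cp$marshall_cutpoints) <= 0))
    config_error("covariate_params",
                 "marshall_cutpoints must be 5 strictly increasing values")

  if (!setequal(names(stratum_missing_shift), STRATA))
    config_error("stratum_missing_shift", "must be named ed/hosp/icu")
  if (!is.numeric(mnar_shift) || length(mnar_shift) != 1L || is.na(mnar_shift))
    config_error("mnar_shift", "must be a single real number")

  structure(
    list(n_patients = n_patients, seed = seed, p_transfer = p_transfer,
         stratum_probs = stratum_probs,
         noise_sd_by_timepoint = noise_sd_by_timepoint,
         resuscitation_drift = resuscitation_drift,
         missing_prob_by_timepoint = missing_prob_by_timepoint,
         intubation = unname(intubation), sedation = unname(sedation),
         outcome_coefficients = outcome_coefficients,
         gose_cutpoints = gose_cutpoints,
         recovery_drift = recovery_drift, gose_copy_sd = gose_copy_sd,
         covariate_params = cp,
         covariate_missing = covariate_missing,
         gose_missing = gose_missing,
         stratum_missing_shift = stratum_missing_shift[STRATA],
         mnar_shift = mnar_shift),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic TBI cohort configuration\n")
  cat(sprintf("  n_patients: %d   seed: %d\n", x$n_patients, x$seed))
  cat(sprintf("  strata (ed/hosp/icu): %s   P(transfer): %.2f\n",
              paste(sprintf("%.2f", x$stratum_probs), collapse = "/"),
              x$p_transfer))
  cat(sprintf("  assessment noise SD by time point: %s\n",
              paste(sprintf("%.2f", x$noise_sd_by_timepoint), collapse = ", ")))
  cat(sprintf("  missingness by time point: %s\n",
              paste(sprintf("%.2f", x$missing_prob_by_timepoint),
                    collapse = ", ")))
  cat(sprintf("  resuscitation drift: %.2f per time point; MNAR shift: %.2f\n",
              x$resuscitation_drift, x$mnar_shift))
  invisible(x)
}
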