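#' Generate a synthetic TBI cohort
#'
#' Simulates a patient-level emergency-phase TBI cohort. A standard-normal
#' latent injury severity (higher = worse) drives everything: enrolment
#' stratum, baseline covariates, per-time-point neurological state, and the
#' ordinal GOSE outcome. The latent neurological state at time point `t` is
#' `-severity + resuscitation_drift * (t-1) + noise_t`; GCS eye/verbal/motor
#' components and the number of unreactive pupils are obtained by
#' thresholding it, which guarantees the monotone severity-to-GCS
#' relationship the downstream strategy comparison assumes. The 6-month
#' GOSE is drawn from a proportional-odds model on severity and covariates;
#' 3- and 12-month GOSE are noisy ordinal copies of its linear predictor
#' (shifted by a recovery drift) so they carry auxiliary signal for
#' imputation. Survival is defined as GOSE > 1.
#'
#' The returned data frame carries the latent truth (severity, per-time-point
#' latent neurological values, outcome linear predictor) in
#' `attr(cohort, "truth")`; [write_cohort()] writes it as a separate sidecar
#' so masking recovery can be tested.
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` of class `tbi_cohort` with one row per patient:
#'   `id`, `stratum` (`ed`/`hosp`/`icu`), `transfer`, IMPACT covariates
#'   (`age`, `glucose`, `hb`, `marshall`, `tsah`, `edh`, `hypoxia`,
#'   `hypotension`), outcomes `gose_3mo`/`gose_6mo`/`gose_12mo`, and per
#'   time point `tp` in `preh`, `ref_arr`, `study_arr`, `ed_disch` the
#'   columns `gcs_e_<tp>`, `gcs_v_<tp>`, `gcs_m_<tp>`, `pupils_<tp>` plus
#'   untestability flags `ut_v_<tp>`, `ut_m_<tp>`. The referring-arrival
#'   assessment exists only for secondarily transferred patients
#'   (structurally `NA` otherwise).
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 1))
#' range(gcs_sum_by_timepoint(coh, "ed_disch"), na.rm = TRUE)
#' @seealso [apply_untestability()], [apply_missingness()], [write_cohort()]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  set.seed(stage_seeds(config)[1L])

  severity <- stats::rnorm(n)

  # Stratum: ordinal probit on severity + unit noise, thresholds chosen so
  # the marginal mixture matches stratum_probs; ICU collects the worst.
  z <- severity + stats::rnorm(n)
  thr <- stats::qnorm(cumsum(config$stratum_probs)[1:2], sd = sqrt(2))
  stratum <- factor(STRATA[1L + findInterval(z, thr)], levels = STRATA)

  transfer <- stats::runif(n) < config$p_transfer

  cp <- config$covariate_params
  age <- round(pmin(95, pmax(16, stats::rnorm(n, cp$age_mean, cp$age_sd))))
  glucose <- cp$glucose_mean + cp$glucose_loading * severity +
    stats::rnorm(n, 0, cp$glucose_sd)
  hb <- cp$hb_mean + cp$hb_loading * severity + stats::rnorm(n, 0, cp$hb_sd)
  marshall <- 1L + findInterval(severity + stats::rnorm(n, 0, 0.9),
                                cp$marshall_cutpoints)
  bern <- function(link) {
    as.integer(stats::runif(n) < stats::plogis(link[[1L]] + link[[2L]] * severity))
  }
  tsah <- bern(cp$tsah); edh <- bern(cp$edh)
  hypoxia <- bern(cp$hypoxia); hypotension <- bern(cp$hypotension)

  # Latent neurological state per time point: higher = better neurology.
  drift <- config$resuscitation_drift
  sds <- config$noise_sd_by_timepoint
  neuro <- vapply(seq_along(TIMEPOINTS), function(t) {
    -severity + drift * (t - 1L) + stats::rnorm(n, 0, sds[t])
  }, numeric(n))
  colnames(neuro) <- TIMEPOINTS

  b <- config$outcome_coefficients
  lp <- -(b[["b_severity"]] * severity) -
    b[["b_age"]] * (age - 45) / 10 -
    b[["b_glucose"]] * (glucose - cp$glucose_mean) +
    b[["b_hb"]] * (hb - cp$hb_mean) -
    b[["b_marshall"]] * (marshall - 2) -
    b[["b_tsah"]] * tsah - b[["b_edh"]] * edh

  gose_6mo <- draw_prop_odds(lp, config$gose_cutpoints)
  lp3 <- lp - config$recovery_drift + stats::rnorm(n, 0, config$gose_copy_sd)
  lp12 <- lp + config$recovery_drift + stats::rnorm(n, 0, config$gose_copy_sd)
  gose_3mo <- draw_prop_odds(lp3, config$gose_cutpoints)
  gose_12mo <- draw_prop_odds(lp12, config$gose_cutpoints)

  cohort <- data.frame(
    id = seq_len(n), stratum = stratum, transfer = transfer, age = age,
    glucose = glucose, hb = hb, marshall = marshall, tsah = tsah, edh = edh,
    hypoxia = hypoxia, hypotension = hypotension,
    gose_3mo = gose_3mo, gose_6mo = gose_6mo, gose_12mo = gose_12mo,
    stringsAsFactors = FALSE
  )

  for (t in seq_along(TIMEPOINTS)) {
    tp <- TIMEPOINTS[t]
    applicable <- if (tp == "ref_arr") transfer else rep(TRUE, n)
    nv <- neuro[, t]
    e <- 1L + findInterval(nv, GCS_E_CUTS)
    v <- 1L + findInterval(nv, GCS_V_CUTS)
    m <- 1L + findInterval(nv, GCS_M_CUTS)
    pup <- 2L - findInterval(nv, PUPIL_CUTS)
    e[!applicable] <- NA_integer_; v[!applicable] <- NA_integer_
    m[!applicable] <- NA_integer_; pup[!applicable] <- NA_integer_
    cohort[[paste0("gcs_e_", tp)]] <- e
    cohort[[paste0("gcs_v_", tp)]] <- v
    cohort[[paste0("gcs_m_", tp)]] <- m
    cohort[[paste0("pupils_", tp)]] <- pup
    cohort[[paste0("ut_v_", tp)]] <- rep(FALSE, n)
    cohort[[paste0("ut_m_", tp)]] <- rep(FALSE, n)
  }

  attr(cohort, "truth") <- data.frame(
    id = seq_len(n), severity = severity,
    neuro_preh = neuro[, "preh"], neuro_ref_arr = neuro[, "ref_arr"],
    neuro_study_arr = neuro[, "study_arr"], neuro_ed_disch = neuro[, "ed_disch"],
    lp_gose = lp,
    neuroworsening = apply(neuro, 1L, function(x) any(diff(x) < -0.5)),
    gcs_sum_preh = pmin(pmax(
      (1L + findInterval(neuro[, 1], GCS_E_CUTS)) +
        (1L + findInterval(neuro[, 1], GCS_V_CUTS)) +
        (1L + findInterval(neuro[, 1], GCS_M_CUTS)), 3L), 15L)
  )
  attr(cohort, "config") <- config
  class(cohort) <- c("tbi_cohort", "data.frame")
  cohort
}

# Threshold maps from the latent neurological value to ordinal components.
# Chosen so a well patient (latent ~ +1) scores E4 V5 M6 and a moribund one
# (latent ~ -2.5) scores E1 V1 M1 with both pupils unreactive.
GCS_E_CUTS <- c(-1.4, -0.6, 0.3)
GCS_V_CUTS <- c(-1.4, -0.75, -0.1, 0.7)
GCS_M_CUTS <- c(-1.7, -1.1, -0.45, 0.25, 1.0)
PUPIL_CUTS <- c(-2.0, -1.55)  # below first: 2 unreactive; between: 1; above: 0

stage_seeds <- function(config) derive_seeds(config$seed, 3L)

#' Mask verbal/motor components that could not be tested
#'
#' Emulates clinical untestability: an endotracheally intubated patient has
#' no verbal response to score, and a deeply sedated or pharmacologically
#' paralysed patient has no motor response. Intubation and sedation are
#' drawn independently at each time point with probability
#' `plogis(intercept + slope * severity)` (non-decreasing in severity), and
#' the affected component is flagged untestable — a state distinct from
#' "not recorded", carried in the `ut_v_*` / `ut_m_*` columns and written
#' as the sentinel `"UT"` by [write_cohort()].
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param config the same [cohort_config()] used to generate it.
#' @return the cohort with verbal/motor cells masked and flags set.
#' @export
apply_untestability <- function(cohort, config) {
  stopifnot(inherits(cohort, "tbi_cohort"), inherits(config, "cohort_config"))
  set.seed(stage_seeds(config)[2L])
  truth <- attr(cohort, "truth")
  severity <- truth$severity
  n <- nrow(cohort)
  for (tp in TIMEPOINTS) {
    applicable <- if (tp == "ref_arr") cohort$transfer else rep(TRUE, n)
    p_int <- stats::plogis(config$intubation[1L] +
                             config$intubation[2L] * severity)
    p_sed <- stats::plogis(config$sedation[1L] + config$sedation[2L] * severity)
    intub <- stats::runif(n) < p_int & applicable
    sed <- stats::runif(n) < p_sed & applicable
    vcol <- paste0("gcs_v_", tp); mcol <- paste0("gcs_m_", tp)
    cohort[[vcol]][intub] <- NA_integer_
    cohort[[paste0("ut_v_", tp)]][intub] <- TRUE
    cohort[[mcol]][sed] <- NA_integer_
    cohort[[paste0("ut_m_", tp)]][sed] <- TRUE
  }
  cohort
}

#' Mask assessment cells and covariates at random
#'
#' Applies cell-level not-recorded missingness. For each assessment cell
#' (eye, verbal, motor, pupils) the masking probability is
#' `missing_prob_by_timepoint[t] + stratum_missing_shift[stratum] +
#' mnar_shift * severity` (clamped to `[0, 1]`); with the default zero
#' shifts the mechanism depends only on the time point — fully observed —
#' so it is missing at random by construction, and the marginal missing
#' fraction per time point equals the configured probability. Covariate and
#' GOSE cells are masked with their own per-variable probabilities.
#' `stratum`, `transfer` and `age` are never masked. A cell masked here
#' loses its record entirely: an untestable flag on it is cleared, since an
#' unrecorded assessment carries no untestability information.
#'
#' @inheritParams apply_untestability
#' @return the cohort with `NA`s introduced.
#' @export
apply_missingness <- function(cohort, config) {
  stopifnot(inherits(cohort, "tbi_cohort"), inherits(config, "cohort_config"))
  set.seed(stage_seeds(config)[3L])
  n <- nrow(cohort)
  severity <- attr(cohort, "truth")$severity
  shift <- config$stratum_missing_shift[as.character(cohort$stratum)]

  for (t in seq_along(TIMEPOINTS)) {
    tp <- TIMEPOINTS[t]
    applicable <- if (tp == "ref_arr") cohort$transfer else rep(TRUE, n)
    p <- pmin(1, pmax(0, config$missing_prob_by_timepoint[t] + shift +
                        config$mnar_shift * severity))
    for (var in c("gcs_e_", "gcs_v_", "gcs_m_", "pupils_")) {
      col <- paste0(var, tp)
      mask <- stats::runif(n) < p & applicable
      cohort[[col]][mask] <- NA_integer_
      if (var == "gcs_v_") cohort[[paste0("ut_v_", tp)]][mask] <- FALSE
      if (var == "gcs_m_") cohort[[paste0("ut_m_", tp)]][mask] <- FALSE
    }
  }
  for (cov in names(config$covariate_missing)) {
    mask <- stats::runif(n) < config$covariate_missing[[cov]]
    cohort[[cov]][mask] <- NA
  }
  for (g in names(config$gose_missing)) {
    mask <- stats::runif(n) < config$gose_missing[[g]]
    cohort[[g]][mask] <- NA_integer_
  }
  cohort
}

#' Simulate a complete synthetic cohort (generate, untestability, masking)
#'
#' Convenience wrapper running [generate_cohort()],
#' [apply_untestability()] and [apply_missingness()] in order.
#'
#' @inheritParams apply_untestability
#' @return a masked `tbi_cohort`.
#' @export
simulate_cohort <- function(config) {
  apply_missingness(apply_untestability(generate_cohort(config), config), config)
}

#' @export
print.tbi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TBI cohort: %d patients (%s)\n", nrow(x),
              paste(sprintf("%s %d", levels(x$stratum), table(x$stratum)),
                    collapse = ", ")))
  cat(sprintf("  secondary transfers: %d; 6-month GOSE observed: %d\n",
              sum(x$transfer), sum(!is.na(x$gose_6mo))))
  cat("First rows:\n")
  print(utils::head(as.data.frame(x)[, 1:14]))
  invisible(x)
}

#' Per-time-point GCS sum under a sub-score policy
#'
#' Vectorised helper returning the (possibly not-calculable) GCS sum at one
#' time point for every patient; see [gcs_sum_at_timepoint()] for the
#' policy semantics.
#'
#' @param cohort a `tbi_cohort` (or any data frame in the standard layout).
#' @param timepoint one of `"preh"`, `"ref_arr"`, `"study_arr"`, `"ed_disch"`.
#' @param policy a sum-score policy, see [sum_policies()].
#' @return integer vector, `NA` where not calculable.
#' @export
gcs_sum_by_timepoint <- function(cohort, timepoint,
                                 policy = "nc_if_either") {
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  gcs_sum_at_timepoint(
    eye = cohort[[paste0("gcs_e_", timepoint)]],
    verbal = cohort[[paste0("gcs_v_", timepoint)]],
    motor = cohort[[paste0("gcs_m_", timepoint)]],
    verbal_untestable = cohort[[paste0("ut_v_", timepoint)]],
    motor_untestable = cohort[[paste0("ut_m_", timepoint)]],
    policy = policy
  )
}

#' Write / read a cohort as CSV with the standard column dictionary
#'
#' One column per component per time point (`gcs_e_preh`, ...,
#' `pupils_ed_disch`). Missing cells are written empty; untestable verbal or
#' motor cells are written as the sentinel `"UT"`. The latent truth sidecar
#' (severity, per-time-point latent values, outcome linear predictor,
#' pre-mask pre-hospital GCS sum) can be written alongside for recovery
#' tests.
#'
#' @param cohort a `tbi_cohort`.
#' @param path output CSV path.
#' @param truth_path optional path for the truth sidecar CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  out <- as.data.frame(cohort)
  for (tp in TIMEPOINTS) {
    for (comp in c("v", "m")) {
      col <- paste0("gcs_", comp, "_", tp)
      ut <- out[[paste0("ut_", comp, "_", tp)]]
      vals <- as.character(out[[col]])
      vals[is.na(out[[col]])] <- ""
      vals[ut] <- "UT"
      out[[col]] <- vals
    }
    out[[paste0("ut_v_", tp)]] <- NULL
    out[[paste0("ut_m_", tp)]] <- NULL
  }
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), "", format(x, digits = 10, trim = TRUE, scientific = FALSE)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(truth_path)) {
    truth <- attr(cohort, "truth")
    if (is.null(truth)) data_error("cohort carries no truth sidecar")
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = FALSE,
                     na = "")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  n <- nrow(raw)
  coh <- data.frame(
    id = as.integer(raw$id),
    stratum = factor(raw$stratum, levels = STRATA),
    transfer = raw$transfer %in% c("TRUE", "true", "1"),
    age = as.numeric(raw$age),
    glucose = as.numeric(raw$glucose), hb = as.numeric(raw$hb),
    marshall = as.integer(raw$marshall),
    tsah = as.integer(raw$tsah), edh = as.integer(raw$edh),
    hypoxia = as.integer(raw$hypoxia),
    hypotension = as.integer(raw$hypotension),
    gose_3mo = as.integer(raw$gose_3mo),
    gose_6mo = as.integer(raw$gose_6mo),
    gose_12mo = as.integer(raw$gose_12mo),
    stringsAsFactors = FALSE
  )
  for (tp in TIMEPOINTS) {
    coh[[paste0("gcs_e_", tp)]] <- as.integer(raw[[paste0("gcs_e_", tp)]])
    for (comp in c("v", "m")) {
      col <- paste0("gcs_", comp, "_", tp)
      ut <- !is.na(raw[[col]]) & raw[[col]] == "UT"
      vals <- raw[[col]]
      vals[ut] <- NA_character_
      coh[[col]] <- as.integer(vals)
      coh[[paste0("ut_", comp, "_", tp)]] <- ut
    }
    coh[[paste0("pupils_", tp)]] <- as.integer(raw[[paste0("pupils_", tp)]])
    # keep the documented column order: flags after the component block
  }
  class(coh) <- c("tbi_cohort", "data.frame")
  coh
}
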