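#' Substitution strategies and sub-score policies
#'
#' `strategies()` lists the five substitution strategies for deriving a
#' single baseline value from multi-time-point assessments:
#' \describe{
#'   \item{impact}{start at ED discharge (the post-stabilisation score) and
#'     work backwards in time: ED discharge, study-hospital arrival,
#'     referring-hospital arrival, pre-hospital.}
#'   \item{tarn}{start at the first ED the patient presented to and move
#'     forward: referring arrival (secondary transfers only),
#'     study-hospital arrival, then pre-hospital as last resort.}
#'   \item{erasmus}{study-hospital arrival first, then referring arrival,
#'     then pre-hospital.}
#'   \item{best}{best neurology over all available time points: highest GCS
#'     sum or motor score, fewest unreactive pupils.}
#'   \item{worst}{worst neurology: lowest GCS sum or motor score, most
#'     unreactive pupils.}
#' }
#' `sum_policies()` lists the four policies for handling a missing or
#' untestable verbal/motor component when forming the GCS sum:
#' `nc_if_either` (not calculable if either is missing), `nc_if_m_v1`
#' (not calculable if motor missing, missing verbal scored 1), `nc_if_v_m1`
#' (the converse), `both_1` (both substituted with 1). `motor_policies()`
#' lists the two motor-score policies `nc_if_m` and `m_1`.
#'
#' @return character vector of identifiers.
#' @export
strategies <- function() c("impact", "tarn", "best", "worst", "erasmus")

#' @rdname strategies
#' @export
sum_policies <- function() c("nc_if_either", "nc_if_m_v1", "nc_if_v_m1",
                             "both_1")

#' @rdname strategies
#' @export
motor_policies <- function() c("nc_if_m", "m_1")

STRATEGY_ORDERS <- list(
  impact  = c("ed_disch", "study_arr", "ref_arr", "preh"),
  tarn    = c("ref_arr", "study_arr", "preh"),
  erasmus = c("study_arr", "ref_arr", "preh")
)

check_component <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
  if (any(bad))
    data_error(sprintf("%s component out of range [%d, %d]: %s",
                       what, lo, hi, paste(unique(x[bad]), collapse = ", ")))
  invisible(x)
}

#' GCS sum at a single time point under a sub-score policy
#'
#' Computes eye + verbal + motor, treating absent and untestable
#' verbal/motor components identically for policy purposes (both count as
#' "missing"). A substituted component contributes exactly 1. An absent eye
#' component makes the sum not calculable under every policy.
#'
#' @param eye integer 1–4 or `NA`.
#' @param verbal integer 1–5 or `NA`.
#' @param motor integer 1–6 or `NA`.
#' @param verbal_untestable,motor_untestable logical; `TRUE` marks a
#'   component recorded as untestable (intubation, sedation/paralysis).
#' @param policy one of [sum_policies()].
#' @return integer GCS sum in 3–15, or `NA` where not calculable.
#' @examples
#' gcs_sum_at_timepoint(3, NA, 5, verbal_untestable = TRUE,
#'                      policy = "nc_if_m_v1")   # 3 + 1 + 5 = 9
#' gcs_sum_at_timepoint(3, NA, 5, verbal_untestable = TRUE,
#'                      policy = "nc_if_either") # NA
#' @export
gcs_sum_at_timepoint <- function(eye, verbal, motor,
                                 verbal_untestable = FALSE,
                                 motor_untestable = FALSE,
                                 policy = sum_policies()) {
  policy <- match.arg(policy)
  check_component(eye, 1L, 4L, "eye")
  check_component(verbal, 1L, 5L, "verbal")
  check_component(motor, 1L, 6L, "motor")
  n <- max(length(eye), length(verbal), length(motor))
  verbal_untestable <- rep_len(verbal_untestable, n)
  motor_untestable <- rep_len(motor_untestable, n)
  v_miss <- is.na(verbal) | verbal_untestable
  m_miss <- is.na(motor) | motor_untestable
  v <- ifelse(v_miss, NA_integer_, verbal)
  m <- ifelse(m_miss, NA_integer_, motor)
  nc <- switch(policy,
    nc_if_either = v_miss | m_miss,
    nc_if_m_v1   = m_miss,
    nc_if_v_m1   = v_miss,
    both_1       = rep(FALSE, n)
  )
  if (policy %in% c("nc_if_m_v1", "both_1")) v[v_miss] <- 1L
  if (policy %in% c("nc_if_v_m1", "both_1")) m[m_miss] <- 1L
  out <- eye + v + m
  out[nc | is.na(eye)] <- NA_integer_
  as.integer(out)
}

#' GCS motor score at a single time point under a motor policy
#'
#' @inheritParams gcs_sum_at_timepoint
#' @param policy `"nc_if_m"` (missing motor stays missing) or `"m_1"`
#'   (missing motor scored 1).
#' @return integer 1–6, or `NA` where not calculable.
#' @export
gcs_motor_at_timepoint <- function(motor, motor_untestable = FALSE,
                                   policy = motor_policies()) {
  policy <- match.arg(policy)
  check_component(motor, 1L, 6L, "motor")
  motor_untestable <- rep_len(motor_untestable, length(motor))
  m_miss <- is.na(motor) | motor_untestable
  out <- ifelse(m_miss, if (policy == "m_1") 1L else NA_integer_, motor)
  as.integer(out)
}

values_by_timepoint <- function(cohort, variable, sum_policy, motor_policy) {
  n <- nrow(cohort)
  vals <- matrix(NA_integer_, n, length(TIMEPOINTS),
                 dimnames = list(NULL, TIMEPOINTS))
  for (tp in TIMEPOINTS) {
    vals[, tp] <- switch(variable,
      gcs = gcs_sum_at_timepoint(
        cohort[[paste0("gcs_e_", tp)]], cohort[[paste0("gcs_v_", tp)]],
        cohort[[paste0("gcs_m_", tp)]], cohort[[paste0("ut_v_", tp)]],
        cohort[[paste0("ut_m_", tp)]], policy = sum_policy),
      gcsm = gcs_motor_at_timepoint(
        cohort[[paste0("gcs_m_", tp)]], cohort[[paste0("ut_m_", tp)]],
        policy = motor_policy),
      pupils = cohort[[paste0("pupils_", tp)]]
    )
  }
  vals
}

#' Derive a single baseline value per patient
#'
#' Applies one substitution strategy to the per-time-point values of one
#' variable (GCS sum, GCS motor score, or unreactive-pupil count), after
#' the sub-score policy has been applied at each time point. A time point
#' whose value is not calculable under the policy is skipped and the
#' fallback continues. For `best`/`worst` the extremum is taken over all
#' available time points (`best` pupils = fewest unreactive, `worst` = most)
#' with ties broken towards the later time point. The source time point
#' actually used is recorded; it is `NA` exactly when the derived value is
#' missing.
#'
#' @param cohort a `tbi_cohort` or data frame in the standard column layout.
#' @param strategy one of [strategies()].
#' @param variable `"gcs"`, `"gcsm"` or `"pupils"`.
#' @param sum_policy policy for the GCS sum, see [sum_policies()].
#' @param motor_policy policy for the motor score, see [motor_policies()].
#' @return a data frame with columns `value` (integer, `NA` = missing) and
#'   `source` (factor over the four time points, `NA` = missing).
#' @examples
#' cfg <- cohort_config(n_patients = 20, seed = 3)
#' coh <- simulate_cohort(cfg)
#' derive_baseline(coh, "impact", "gcs")[1:5, ]
#' @export
derive_baseline <- function(cohort, strategy = strategies(),
                            variable = c("gcs", "gcsm", "pupils"),
                            sum_policy = "nc_if_either",
                            motor_policy = "nc_if_m") {
  if (!strategy[[1L]] %in% strategies())
    config_error("strategy", paste("unknown strategy:", strategy[[1L]]))
  strategy <- match.arg(strategy)
  variable <- match.arg(variable)
  sum_policy <- match.arg(sum_policy, sum_policies())
  motor_policy <- match.arg(motor_policy, motor_policies())
  vals <- values_by_timepoint(cohort, variable, sum_policy, motor_policy)
  n <- nrow(vals)

  if (strategy %in% names(STRATEGY_ORDERS)) {
    ord <- STRATEGY_ORDERS[[strategy]]
    value <- rep(NA_integer_, n)
    src <- rep(NA_character_, n)
    for (tp in ord) {
      take <- is.na(value) & !is.na(vals[, tp])
      value[take] <- vals[take, tp]
      src[take] <- tp
    }
  } else {
    # best = highest GCS / fewest unreactive pupils; worst = the reverse.
    maximise <- (strategy == "best") == (variable != "pupils")
    cmp <- if (maximise) function(a, b) b >= a else function(a, b) b <= a
    value <- rep(NA_integer_, n)
    src <- rep(NA_character_, n)
    for (tp in TIMEPOINTS) {  # chronological: later time point wins ties
      v <- vals[, tp]
      take <- !is.na(v) & (is.na(value) | cmp(value, v))
      value[take] <- v[take]
      src[take] <- tp
    }
  }
  data.frame(value = value, source = factor(src, levels = TIMEPOINTS))
}

#' Percent-missing accounting across strategies and policies
#'
#' For every combination of strategy, variable and sub-score policy,
#' reports `100 * (missing after derivation) / n` to two decimals, in the
#' classic layout: GCS sum rows per sum policy, motor rows per motor
#' policy, one pupil row; one column per strategy. Strategies that scan the
#' same availability set (best/worst/impact all consider every time point)
#' produce identical columns by construction.
#'
#' @param cohort a `tbi_cohort`.
#' @param strategies character vector of strategies to include.
#' @return a data frame of class `missingness_table` with columns
#'   `variable`, `policy`, then one column per strategy.
#' @export
missingness_table <- function(cohort, strategies = tbibaseline::strategies()) {
  if (nrow(cohort) == 0L) data_error("empty cohort")
  n <- nrow(cohort)
  rows <- list()
  add_row <- function(variable, policy, sum_policy, motor_policy) {
    pct <- vapply(strategies, function(s) {
      d <- derive_baseline(cohort, s, variable,
                           sum_policy = sum_policy,
                           motor_policy = motor_policy)
      round(100 * sum(is.na(d$value)) / n, 2)
    }, numeric(1L))
    c(list(variable = variable, policy = policy), as.list(pct))
  }
  for (p in sum_policies())
    rows[[length(rows) + 1L]] <- add_row("gcs", p, p, "nc_if_m")
  for (p in motor_policies())
    rows[[length(rows) + 1L]] <- add_row("gcsm", p, "nc_if_either", p)
  rows[[length(rows) + 1L]] <- add_row("pupils", "missing_pupils",
                                       "nc_if_either", "nc_if_m")
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  class(out) <- c("missingness_table", "data.frame")
  out
}

#' @export
print.missingness_table <- function(x, ...) {
  cat("Percent missing after imputation by substitution\n")
  NextMethod()
}

#' Pairwise Spearman correlations among derived baseline variants
#'
#' Derives GCS sum, GCS motor and pupil baselines under every strategy and
#' computes pairwise-complete Spearman correlations among the resulting
#' variables (named `gcs_impact`, `gcsm_best`, `pupils_erasmus`, ...).
#' Pairs with fewer than 3 jointly observed rows are flagged unavailable
#' (`NA`).
#'
#' @param cohort a `tbi_cohort`.
#' @param sum_policy,motor_policy sub-score policies applied before
#'   derivation; the defaults treat untestable components as missing.
#' @return a symmetric correlation matrix with unit diagonal.
#' @export
strategy_correlations <- function(cohort, sum_policy = "nc_if_either",
                                  motor_policy = "nc_if_m") {
  vars <- list()
  for (v in c("gcs", "gcsm", "pupils"))
    for (s in strategies())
      vars[[paste(v, s, sep = "_")]] <-
        derive_baseline(cohort, s, v, sum_policy, motor_policy)$value
  mat <- do.call(cbind, vars)
  k <- ncol(mat)
  rho <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(k)) {
    rho[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      ok <- stats::complete.cases(mat[, c(i, j)])
      # a pair needs >= 3 joint observations and variation on both sides
      if (sum(ok) >= 3L && stats::var(mat[ok, i]) > 0 &&
          stats::var(mat[ok, j]) > 0) {
        r <- stats::cor(mat[ok, i], mat[ok, j], method = "spearman")
        rho[i, j] <- rho[j, i] <- r
      }
    }
  }
  rho
}

#' Distribution of source time points for a derived baseline
#'
#' Fraction of non-missing derived values drawn from each time point
#' (the completeness-weighting picture of the strategies).
#'
#' @inheritParams derive_baseline
#' @return named numeric vector over the four time points, summing to 1
#'   (within 1e-12) over non-missing derived values.
#' @export
source_distribution <- function(cohort, strategy, variable = "gcs",
                                sum_policy = "nc_if_either",
                                motor_policy = "nc_if_m") {
  d <- derive_baseline(cohort, strategy, variable, sum_policy, motor_policy)
  src <- d$source[!is.na(d$value)]
  if (length(src) == 0L)
    return(stats::setNames(rep(NA_real_, length(TIMEPOINTS)), TIMEPOINTS))
  stats::setNames(as.numeric(table(src) / length(src)), TIMEPOINTS)
}

#' Count derived GCS values in mild / moderate / severe bands
#'
#' Bands follow the conventional clinical cut: severe 3–8, moderate 9–12,
#' mild 13–15; they partition the GCS range, and the counts sum to the
#' number of non-missing values.
#'
#' @param gcs integer vector of GCS sums (3–15 or `NA`).
#' @return named integer vector `c(mild, moderate, severe)`.
#' @examples
#' severity_bands(c(15, 13, 8, 3, 14, NA))
#' @export
severity_bands <- function(gcs) {
  check_component(gcs, 3L, 15L, "GCS sum")
  gcs <- gcs[!is.na(gcs)]
  c(mild = sum(gcs >= 13), moderate = sum(gcs >= 9 & gcs <= 12),
    severe = sum(gcs <= 8))
}
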