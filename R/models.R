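#' Dichotomise 6-month GOSE into survival
#'
#' GOSE category 1 is death by the instrument's definition; every other
#' category (including vegetative state) is survival.
#'
#' @param gose integer vector of GOSE values in 1–8.
#' @return integer vector: 1 = alive, 0 = dead (`NA` preserved).
#' @examples
#' dichotomise_survival(c(1, 2, 8))
#' @export
dichotomise_survival <- function(gose) {
  bad <- !is.na(gose) & (gose < 1 | gose > 8 | gose != floor(gose))
  if (any(bad)) data_error("GOSE values must be integers in 1..8")
  ifelse(is.na(gose), NA_integer_, as.integer(gose > 1))
}

#' Outcome model specification
#'
#' Declares one cell of the model grid: the family (logistic regression on
#' dichotomous 6-month survival, or proportional-odds regression on the
#' ordered 6-month GOSE), the fixed IMPACT-style baseline covariates, and
#' exactly one GCS-type candidate variable plus one pupil candidate.
#'
#' @param family `"logistic_survival"` or `"proportional_odds_gose"`.
#' @param gcs_var column name of the GCS sum or motor candidate.
#' @param pupil_var column name of the unreactive-pupil candidate.
#' @param stratum `"all"` or `"icu"` (ICU enrolment stratum only).
#' @param fixed fixed covariate columns.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("logistic_survival",
                                  "proportional_odds_gose"),
                       gcs_var, pupil_var, stratum = c("all", "icu"),
                       fixed = c("age", "glucose", "hb", "marshall",
                                 "tsah", "edh")) {
  family <- match.arg(family)
  stratum <- match.arg(stratum)
  if (length(gcs_var) != 1L || length(pupil_var) != 1L)
    config_error("model_spec",
                 "exactly one GCS candidate and one pupil candidate required")
  structure(list(family = family, gcs_var = gcs_var, pupil_var = pupil_var,
                 stratum = stratum, fixed = fixed),
            class = "model_spec")
}

new_tbi_fit <- function(family, coefficients, loglik, null_loglik, n,
                        converged, separation = FALSE, cutpoints = NULL) {
  if (n <= length(coefficients) + length(cutpoints))
    data_error("more parameters than observations")
  structure(list(family = family, coefficients = coefficients,
                 loglik = loglik, null_loglik = null_loglik, n = n,
                 converged = converged, separation = separation,
                 cutpoints = cutpoints),
            class = "tbi_fit")
}

#' Fit the logistic survival model
#'
#' Maximum-likelihood logistic regression of a binary outcome on the given
#' predictors via iteratively reweighted least squares ([stats::glm()]).
#' Complete separation (non-convergence or divergent coefficients) is
#' flagged and the model is refitted with a small ridge penalty so a finite
#' likelihood is always returned. The null model is intercept-only.
#'
#' @param data a data frame.
#' @param outcome name of the 0/1 outcome column.
#' @param predictors character vector of predictor columns.
#' @return a `tbi_fit` with coefficients, maximised and null log-likelihood,
#'   `n`, and convergence/separation flags.
#' @examples
#' d <- data.frame(y = rbinom(80, 1, 0.6), x = rnorm(80))
#' fit_logistic(d, "y", "x")
#' @export
fit_logistic <- function(data, outcome, predictors) {
  pred_cols <- setdiff(predictors, "1")  # "1" requests an intercept-only fit
  d <- data[stats::complete.cases(data[c(outcome, pred_cols)]), , drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) < 2L)
    data_error("outcome has a single class; logistic model is degenerate")
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(predictors, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separated <- sep_warn || !fit$converged || any(abs(stats::coef(fit)) > 15)
  if (separated) {
    X <- stats::model.matrix(form, d)
    rfit <- ridge_logit_fit(X, y, ridge = 1e-2)
    coefs <- stats::setNames(rfit$coef, colnames(X))
    ll <- rfit$loglik
    converged <- rfit$converged
  } else {
    coefs <- stats::coef(fit)
    ll <- as.numeric(stats::logLik(fit))
    converged <- fit$converged
  }
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + sum(1 - y) * log(1 - p0)
  new_tbi_fit("logistic_survival", coefs, ll, ll0, nrow(d),
              converged, separation = separated)
}

#' Fit the proportional-odds GOSE model
#'
#' Maximum-likelihood cumulative-logit (proportional-odds) regression of an
#' ordered outcome on the given predictors, via [MASS::polr()]. Empty
#' outcome categories are collapsed before fitting (the category labels are
#' retained in the cutpoint names). With exactly two categories the model
#' is analytically a logistic regression and is fitted as such. The null
#' model is cutpoints-only, whose maximised log-likelihood is the
#' multinomial closed form `sum(n_k log(n_k/n))`. Separation or a failed
#' fit falls back to a ridge-stabilised proportional-odds fit and is
#' flagged.
#'
#' @inheritParams fit_logistic
#' @param outcome name of the ordinal outcome column (integer categories).
#' @return a `tbi_fit` with slope coefficients, strictly increasing
#'   cutpoints, log-likelihoods and flags.
#' @export
fit_proportional_odds <- function(data, outcome, predictors) {
  pred_cols <- setdiff(predictors, "1")
  d <- data[stats::complete.cases(data[c(outcome, pred_cols)]), , drop = FALSE]
  yraw <- d[[outcome]]
  lev <- sort(unique(yraw))
  if (length(lev) < 2L)
    data_error("outcome has fewer than 2 categories")
  ycode <- match(yraw, lev)
  K <- length(lev)
  n <- nrow(d)
  nk <- tabulate(ycode, K)
  ll0 <- sum(nk * log(nk / n))

  if (K == 2L) {
    d$.y01 <- as.integer(ycode == 2L)
    lf <- fit_logistic(d, ".y01", predictors)
    cuts <- stats::setNames(-lf$coefficients[["(Intercept)"]],
                            paste(lev[1L], lev[2L], sep = "|"))
    return(new_tbi_fit("proportional_odds_gose",
                       lf$coefficients[-1L], lf$loglik, ll0, n,
                       lf$converged, lf$separation, cutpoints = cuts))
  }

  d$.yord <- factor(ycode, levels = seq_len(K), ordered = TRUE)
  form <- stats::as.formula(paste(".yord ~",
                                  paste(predictors, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(MASS::polr(form, data = d, Hess = FALSE)),
    error = function(e) NULL)
  separated <- is.null(fit) || any(abs(stats::coef(fit)) > 15) ||
    fit$convergence != 0
  if (!separated) {
    zeta <- fit$zeta
    if (any(diff(zeta) <= 0))
      data_error("non-monotone cutpoints at convergence")
    cuts <- stats::setNames(zeta, paste(lev[-K], lev[-1L], sep = "|"))
    return(new_tbi_fit("proportional_odds_gose", stats::coef(fit),
                       as.numeric(stats::logLik(fit)), ll0, n,
                       fit$convergence == 0L, FALSE, cutpoints = cuts))
  }
  X <- build_design(d, predictors, rep(TRUE, n), intercept = FALSE)
  rfit <- ridge_polr_fit(X, ycode, ridge = 1e-2)
  zeta <- theta_to_cutpoints(rfit$theta, K)
  beta <- stats::setNames(rfit$theta[(K - 1L) + seq_len(ncol(X))],
                          colnames(X))
  # unpenalised log-likelihood at the stabilised estimate
  ll <- -po_nll_grad(rfit$theta, X, ycode, K, ridge = 0)$nll
  new_tbi_fit("proportional_odds_gose", beta, ll, ll0, n,
              rfit$converged, TRUE,
              cutpoints = stats::setNames(zeta,
                                          paste(lev[-K], lev[-1L], sep = "|")))
}

#' @export
print.tbi_fit <- function(x, ...) {
  cat(sprintf("%s model: n = %d, logLik = %.3f (null %.3f), McFadden R2 = %.4f\n",
              x$family, x$n, x$loglik, x$null_loglik, mcfadden_r2(x)))
  if (x$separation) cat("  note: separation flagged; ridge-stabilised fit\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$cutpoints)) {
    cat("Cutpoints:\n")
    print(round(x$cutpoints, 4))
  }
  invisible(x)
}

#' @export
coef.tbi_fit <- function(object, ...) object$coefficients

#' @export
logLik.tbi_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              length(object$cutpoints), class = "logLik")
}

#' McFadden's pseudo-R-squared
#'
#' `1 - logLik(model) / logLik(null)`, where the null model is the
#' intercept(s)-only fit. Zero when the model adds no likelihood over the
#' null; approaches 1 only for a near-perfect model. A degenerate
#' single-class outcome (null log-likelihood zero) raises an error.
#'
#' @param fit a `tbi_fit`, or a numeric maximised log-likelihood.
#' @param null_loglik the null log-likelihood when `fit` is numeric.
#' @return a value in `[0, 1)`.
#' @examples
#' mcfadden_r2(-50, -100)  # 0.5
#' @export
mcfadden_r2 <- function(fit, null_loglik = NULL) {
  if (inherits(fit, "tbi_fit")) {
    ll <- fit$loglik; ll0 <- fit$null_loglik
  } else {
    ll <- fit; ll0 <- null_loglik
  }
  if (is.null(ll0) || ll0 == 0)
    data_error("null log-likelihood is zero (degenerate outcome)")
  r2 <- 1 - ll / ll0
  if (r2 < 0 && r2 > -1e-8) r2 <- 0
  r2
}

#' Per-imputation pseudo-R-squared for one model cell
#'
#' Fits the model of a [model_spec()] on every completed dataset of a
#' [mice_impute()] result and returns the distribution of McFadden
#' pseudo-R-squared values across imputations (the box-and-whisker payload;
#' no Rubin combination of R-squared is attempted). Rows whose candidate
#' GCS or pupil value is missing in a given dataset are dropped from that
#' fit (complete-case on the candidate), mirroring how substitution leaves
#' residual missingness. Non-converged fits are excluded with a warning and
#' counted.
#'
#' @param cds a `completed_set`.
#' @param spec a [model_spec()].
#' @return an object of class `r2_dist`: list with `values` (numeric vector
#'   of length at most `m`), `summary` (median, quartiles, min, max, mean),
#'   `n_excluded`, `n_used` (median rows per fit) and the model
#'   specification.
#' @export
per_imputation_r2 <- function(cds, spec) {
  stopifnot(inherits(cds, "completed_set"), inherits(spec, "model_spec"))
  predictors <- c(spec$fixed, spec$gcs_var, spec$pupil_var)
  vals <- rep(NA_real_, cds$m)
  ns <- rep(NA_integer_, cds$m)
  for (k in seq_len(cds$m)) {
    d <- cds$data[[k]]
    if (spec$stratum == "icu") d <- d[d$stratum == "icu", , drop = FALSE]
    if (spec$family == "logistic_survival") {
      d$.surv <- dichotomise_survival(d$gose_6mo)
      fit <- fit_logistic(d, ".surv", predictors)
    } else {
      fit <- fit_proportional_odds(d, "gose_6mo", predictors)
    }
    if (fit$converged) {
      vals[k] <- mcfadden_r2(fit)
      ns[k] <- fit$n
    }
  }
  excluded <- sum(is.na(vals))
  if (excluded > 0L)
    warning(sprintf("%d of %d fits did not converge and were excluded",
                    excluded, cds$m))
  v <- vals[!is.na(vals)]
  structure(list(
    values = v,
    summary = c(median = stats::median(v),
                q1 = unname(stats::quantile(v, 0.25)),
                q3 = unname(stats::quantile(v, 0.75)),
                min = min(v), max = max(v), mean = mean(v)),
    n_excluded = excluded,
    n_used = stats::median(ns, na.rm = TRUE),
    spec = spec), class = "r2_dist")
}

#' @export
print.r2_dist <- function(x, ...) {
  s <- x$spec
  cat(sprintf("McFadden R2 over %d imputations [%s | %s + %s | %s stratum]\n",
              length(x$values), s$family, s$gcs_var, s$pupil_var, s$stratum))
  print(round(x$summary, 4))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d non-converged fits excluded)\n", x$n_excluded))
  invisible(x)
}
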