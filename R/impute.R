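#' Specification of one imputed variable
#'
#' Declares how a single variable enters the chained-equations engine: its
#' conditional model family, its predictors, and (optionally) the row
#' subset on which it is defined and the ordinal support.
#'
#' @param name column name of the variable.
#' @param family `"gaussian_linear"`, `"binary_logistic"` or
#'   `"ordinal_proportional_odds"`.
#' @param predictors character vector of predictor column names (may
#'   include other imputed variables, which act as mutual auxiliaries).
#' @param subset optional name of a logical column restricting the rows on
#'   which the variable exists (e.g. `"transfer"` for referring-arrival
#'   assessments); rows outside the subset are left untouched.
#' @param support for ordinal variables, the full vector of admissible
#'   values (e.g. `3:15` for a GCS sum); draws always fall in the observed
#'   subset of this support.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name,
                          family = c("gaussian_linear", "binary_logistic",
                                     "ordinal_proportional_odds"),
                          predictors, subset = NULL, support = NULL) {
  family <- match.arg(family)
  if (length(predictors) == 0L)
    config_error(name, "imputed variable needs a non-empty predictor list")
  if (name %in% predictors)
    config_error(name, "a variable cannot predict itself")
  structure(list(name = name, family = family,
                 predictors = unique(predictors),
                 subset = subset, support = support),
            class = "variable_spec")
}

#' Fill hypoxia/hypotension by the absent-if-unrecorded convention
#'
#' Missing hypoxia and hypotension indicators are set to 0 (assumed not to
#' have been present when unrecorded). Age must already be complete — it is
#' a required, never-imputed covariate — so a missing age raises a data
#' error.
#'
#' @param cohort a `tbi_cohort` or data frame with `hypoxia`, `hypotension`
#'   and `age` columns.
#' @return the cohort with the two indicator columns completed.
#' @export
default_fill <- function(cohort) {
  if (anyNA(cohort$age))
    data_error("age must be complete (it is never imputed)")
  cohort$hypoxia[is.na(cohort$hypoxia)] <- 0L
  cohort$hypotension[is.na(cohort$hypotension)] <- 0L
  cohort
}

#' Default variable specifications for the imputation model
#'
#' Builds the per-variable conditional-model list in the fixed visit order
#' used throughout the package: continuous and binary covariates first
#' (glucose, haemoglobin, EDH, tSAH), then the Marshall CT class, then —
#' when requested — the per-time-point neurological assessments, then the
#' GOSE outcomes. Haemoglobin and glucose use linear regression; EDH and
#' tSAH logistic regression; Marshall, the assessments and GOSE
#' proportional-odds models. The 6-month GOSE conditional includes the 3-
#' and 12-month GOSE as auxiliaries (and vice versa), so partial outcome
#' information is exploited. Referring-arrival assessments are restricted
#' to secondarily transferred patients via `subset = "transfer"`.
#'
#' @param include_assessments logical; add per-time-point GCS sum, GCS
#'   motor and pupil variables (requires [prepare_assessment_columns()]).
#' @param assessment_vars subset of `c("gcs", "gcsm", "pupils")`.
#' @param timepoints assessment time points to include.
#' @return list of [variable_spec()] objects in visit order.
#' @export
default_specs <- function(include_assessments = FALSE,
                          assessment_vars = c("gcs", "gcsm", "pupils"),
                          timepoints = TIMEPOINTS) {
  sp <- list(
    variable_spec("glucose", "gaussian_linear",
                  c("age", "hb", "marshall", "tsah", "edh", "hypoxia",
                    "hypotension", "gose_6mo")),
    variable_spec("hb", "gaussian_linear",
                  c("age", "glucose", "marshall", "tsah", "edh", "hypoxia",
                    "hypotension", "gose_6mo")),
    variable_spec("edh", "binary_logistic",
                  c("age", "marshall", "tsah", "gose_6mo")),
    variable_spec("tsah", "binary_logistic",
                  c("age", "marshall", "edh", "gose_6mo")),
    variable_spec("marshall", "ordinal_proportional_odds",
                  c("age", "glucose", "tsah", "edh", "gose_6mo"),
                  support = 1:6)
  )
  if (include_assessments) {
    assessment_vars <- match.arg(assessment_vars, several.ok = TRUE)
    for (v in assessment_vars) {
      prefix <- switch(v, gcs = "gcs_", gcsm = "gcsm_", pupils = "pupils_")
      support <- switch(v, gcs = 3:15, gcsm = 1:6, pupils = 0:2)
      for (tp in timepoints) {
        others <- paste0(prefix, setdiff(timepoints, c(tp, "ref_arr")))
        extra <- if (v != "pupils" && "pupils" %in% assessment_vars)
          paste0("pupils_", tp) else character(0)
        sp[[length(sp) + 1L]] <- variable_spec(
          paste0(prefix, tp), "ordinal_proportional_odds",
          c(others, extra, "age", "stratum", "gose_6mo"),
          subset = if (tp == "ref_arr") "transfer" else NULL,
          support = support)
      }
    }
  }
  sp <- c(sp, list(
    variable_spec("gose_3mo", "ordinal_proportional_odds",
                  c("age", "gose_6mo", "gose_12mo"), support = 1:8),
    variable_spec("gose_6mo", "ordinal_proportional_odds",
                  c("age", "glucose", "hb", "marshall", "tsah", "edh",
                    "hypoxia", "hypotension", "gose_3mo", "gose_12mo"),
                  support = 1:8),
    variable_spec("gose_12mo", "ordinal_proportional_odds",
                  c("age", "gose_6mo", "gose_3mo"), support = 1:8)
  ))
  sp
}

#' Add per-time-point GCS sum and motor columns
#'
#' Computes `gcs_<tp>` and `gcsm_<tp>` columns from the stored components
#' under the given sub-score policies (a time point rendered not calculable
#' becomes `NA` and is later imputed on the ordinal scale). The GCS sum is
#' imputed directly as a 13-category ordinal variable rather than
#' component-wise.
#'
#' @inheritParams default_fill
#' @param sum_policy,motor_policy see [sum_policies()], [motor_policies()].
#' @return the cohort with added columns.
#' @export
prepare_assessment_columns <- function(cohort, sum_policy = "nc_if_either",
                                       motor_policy = "nc_if_m") {
  for (tp in TIMEPOINTS) {
    cohort[[paste0("gcs_", tp)]] <-
      gcs_sum_by_timepoint(cohort, tp, sum_policy)
    cohort[[paste0("gcsm_", tp)]] <- gcs_motor_at_timepoint(
      cohort[[paste0("gcs_m_", tp)]], cohort[[paste0("ut_m_", tp)]],
      policy = motor_policy)
  }
  cohort
}

build_design <- function(data, predictors, rows, intercept = TRUE) {
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, sum(rows))
  for (p in predictors) {
    x <- data[[p]]
    if (is.null(x)) data_error(paste("unknown predictor column:", p))
    x <- x[rows]
    if (is.factor(x)) {
      lev <- levels(x)
      for (l in lev[-1L]) cols[[paste0(p, l)]] <- as.numeric(x == l)
    } else if (is.logical(x)) {
      cols[[p]] <- as.numeric(x)
    } else {
      cols[[p]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  if (anyNA(X))
    data_error(paste("predictors", paste(predictors, collapse = ", "),
                     "contain missing values in the working data"))
  # drop constant (non-intercept) columns to keep fits full rank
  keep <- apply(X, 2L, stats::var) > 0
  if (intercept) keep[1L] <- TRUE
  X[, keep, drop = FALSE]
}

impute_one <- function(work, spec, obs, mis, ridge, start_env) {
  Xo <- build_design(work, spec$predictors, obs)
  Xm <- build_design(work, spec$predictors, mis)
  # align columns in case constants differ between the two row sets
  common <- intersect(colnames(Xo), colnames(Xm))
  Xo <- Xo[, common, drop = FALSE]; Xm <- Xm[, common, drop = FALSE]
  y <- work[[spec$name]][obs]
  if (spec$family == "gaussian_linear") {
    return(bayes_lm_draw(Xo, as.numeric(y), Xm, ridge = ridge * 1e-2))
  }
  if (spec$family == "binary_logistic") {
    vals <- sort(unique(as.numeric(y)))
    if (length(vals) == 1L) return(rep(y[1L], sum(mis)))
    yb <- as.integer(as.numeric(y) == max(vals))
    d <- ridge_logit_draw(Xo, yb, Xm, ridge = ridge)
    return(ifelse(d == 1L, max(vals), min(vals)))
  }
  # ordinal: collapse to the observed category set
  lev <- sort(unique(as.numeric(y)))
  if (length(lev) == 1L) return(rep(y[1L], sum(mis)))
  ycode <- match(as.numeric(y), lev)
  Xo2 <- Xo[, -1L, drop = FALSE]; Xm2 <- Xm[, -1L, drop = FALSE]
  key <- paste0(spec$name, ":", ncol(Xo2), ":", length(lev))
  start <- start_env[[key]]
  # reuse the posterior covariance computed on this variable's first sweep
  # of the current dataset; the MLE moves little between sweeps
  vkey <- paste0(key, ":vcov")
  res <- ridge_polr_draw(Xo2, ycode, Xm2, ridge = ridge, start = start,
                         vcov_cache = start_env[[vkey]])
  start_env[[key]] <- res$fit$theta
  start_env[[vkey]] <- res$fit$vcov
  lev[res$draws]
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort. For each copy, every
#' missing cell of every specified variable is first filled by a random
#' draw from the variable's observed marginal; then `iterations` sweeps are
#' made over the variables in the order given. Each sweep fits the
#' variable's conditional model on the currently complete data (observed
#' rows only), draws parameters from their approximate posterior — the
#' standard conjugate draw for Gaussian conditionals, a normal
#' approximation at the (lightly ridge-penalised) maximum likelihood for
#' logistic and proportional-odds conditionals — and replaces the missing
#' cells with draws from the resulting predictive distribution. Ordinal
#' draws are always from the observed category support. A conditional fit
#' that fails is retried twice with a 100-fold stronger ridge before an
#' error is raised.
#'
#' Observed cells are never altered and are identical across all `m`
#' datasets; given the same cohort, specs and seed the result is
#' bit-identical.
#'
#' @param cohort a `tbi_cohort` (or data frame in the standard layout),
#'   normally after [default_fill()].
#' @param specs list of [variable_spec()]s in visit order; defaults to the
#'   covariate/outcome model of [default_specs()].
#' @param m number of completed datasets (the reference analysis uses 200;
#'   desk-scale runs use 10–20).
#' @param iterations chained-equation sweeps per dataset.
#' @param seed integer seed.
#' @param ridge base ridge penalty for logistic/ordinal conditionals.
#' @return an object of class `completed_set`: list with elements `data`
#'   (list of `m` completed data frames), `original` (the input cohort),
#'   `specs`, `m`, `iterations`, `seed`, `dataset_seeds`.
#' @examples
#' coh <- default_fill(simulate_cohort(cohort_config(300, seed = 2)))
#' cds <- mice_impute(coh, m = 3, iterations = 2, seed = 9)
#' cds
#' @export
mice_impute <- function(cohort, specs = default_specs(), m = 200L,
                        iterations = 5L, seed = 1L, ridge = 1e-4) {
  m <- check_pos_int(m, "m", min = 2L)
  iterations <- check_pos_int(iterations, "iterations", min = 1L)
  seed <- check_pos_int(seed, "seed", min = 0L)
  n <- nrow(cohort)

  miss_mask <- list(); subset_rows <- list()
  for (spec in specs) {
    x <- cohort[[spec$name]]
    if (is.null(x)) data_error(paste("no such column:", spec$name))
    sub <- if (is.null(spec$subset)) rep(TRUE, n) else
      as.logical(cohort[[spec$subset]])
    if (!any(!is.na(x[sub])))
      data_error(paste0("variable '", spec$name,
                        "' has zero observed cases; cannot fit its conditional"))
    miss_mask[[spec$name]] <- is.na(x) & sub
    subset_rows[[spec$name]] <- sub
  }

  dataset_seeds <- derive_seeds(seed, m)
  datasets <- vector("list", m)
  # Warm-start cache shared across datasets: the conditional MLEs (and, to a
  # very good approximation, their information matrices) are dominated by the
  # observed cells, which are identical in every dataset.
  start_env <- new.env(parent = emptyenv())
  for (k in seq_len(m)) {
    set.seed(dataset_seeds[k])
    work <- as.data.frame(cohort)
    # initial fill: draw from the observed marginal
    for (spec in specs) {
      mis <- miss_mask[[spec$name]]
      if (!any(mis)) next
      obs_vals <- work[[spec$name]][subset_rows[[spec$name]] & !mis]
      work[[spec$name]][mis] <- sample(obs_vals, sum(mis), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (spec in specs) {
        mis <- miss_mask[[spec$name]]
        if (!any(mis)) next
        obs <- subset_rows[[spec$name]] & !mis
        drawn <- NULL
        r <- ridge
        for (attempt in 1:3) {
          drawn <- tryCatch(
            impute_one(work, spec, obs, mis, r, start_env),
            error = function(e) NULL)
          if (!is.null(drawn)) break
          r <- r * 100
        }
        if (is.null(drawn))
          data_error(paste0("conditional model for '", spec$name,
                            "' failed after 2 ridge-stabilised retries"))
        if (is.integer(cohort[[spec$name]])) drawn <- as.integer(drawn)
        work[[spec$name]][mis] <- drawn
      }
    }
    datasets[[k]] <- work
  }
  structure(list(data = datasets, original = cohort, specs = specs,
                 miss_mask = miss_mask, m = m, iterations = iterations,
                 seed = seed, dataset_seeds = dataset_seeds),
            class = "completed_set")
}

#' Impute per-time-point neurological assessments
#'
#' Runs [mice_impute()] on the cohort extended with per-time-point GCS sum
#' and motor columns, imputing the assessments as ordinal
#' (proportional-odds) variables over their category support — GCS sum over
#' 3–15, motor over 1–6, pupils over 0–2 — alongside the covariates and
#' GOSE outcomes. Each assessment's predictors are the same variable at the
#' other time points, the same-time-point pupil count, age, stratum, and
#' the 6-month GOSE. Referring-arrival assessments are imputed only for
#' secondarily transferred patients (they do not exist for the rest).
#'
#' @inheritParams mice_impute
#' @param assessment_vars subset of `c("gcs", "gcsm", "pupils")` to impute.
#' @param sum_policy,motor_policy policies used to form the observed
#'   per-time-point scores before imputation.
#' @return a `completed_set` whose datasets carry completed `gcs_<tp>`,
#'   `gcsm_<tp>`, `pupils_<tp>` columns.
#' @export
impute_timepoint_assessments <- function(cohort, m = 200L, iterations = 5L,
                                         seed = 1L,
                                         assessment_vars = c("gcs", "gcsm",
                                                             "pupils"),
                                         sum_policy = "nc_if_either",
                                         motor_policy = "nc_if_m",
                                         ridge = 1e-4) {
  assessment_vars <- match.arg(assessment_vars, several.ok = TRUE)
  ext <- prepare_assessment_columns(cohort, sum_policy, motor_policy)
  specs <- default_specs(include_assessments = TRUE,
                         assessment_vars = assessment_vars)
  mice_impute(ext, specs, m = m, iterations = iterations, seed = seed,
              ridge = ridge)
}

#' @export
print.completed_set <- function(x, ...) {
  n_imp <- sum(vapply(x$miss_mask, sum, integer(1L)))
  cat(sprintf(
    "Chained-equations multiple imputation: %d completed datasets\n", x$m))
  cat(sprintf("  %d patients, %d imputed variables, %d imputed cells, %d sweeps, seed %d\n",
              nrow(x$original), length(x$specs), n_imp, x$iterations, x$seed))
  invisible(x)
}

#' Extract one completed dataset
#' @param x a `completed_set`.
#' @param k dataset index in `1..m`.
#' @return a completed data frame.
#' @export
complete_dataset <- function(x, k = 1L) {
  stopifnot(inherits(x, "completed_set"), k >= 1L, k <= x$m)
  x$data[[k]]
}

#' Combine referring and study arrivals into a presenting-ED assessment
#'
#' Forms `*_present_arr` columns representing the neurological assessment
#' at the first emergency department the patient presented to: the
#' referring-hospital arrival value for secondary transfers, the
#' study-hospital arrival value otherwise. Applied after imputation, so a
#' transferred patient's imputed referring value is used in each completed
#' dataset.
#'
#' @param x a completed `data.frame` or a `completed_set`.
#' @param vars variable prefixes to combine.
#' @return the input with added `<var>_present_arr` columns.
#' @export
combine_presenting_ed <- function(x, vars = c("gcs", "gcsm", "pupils")) {
  if (inherits(x, "completed_set")) {
    x$data <- lapply(x$data, combine_presenting_ed, vars = vars)
    return(x)
  }
  for (v in vars) {
    ref <- x[[paste0(v, "_ref_arr")]]
    study <- x[[paste0(v, "_study_arr")]]
    if (is.null(study)) next
    if (is.null(ref)) ref <- rep(NA, nrow(x))
    x[[paste0(v, "_present_arr")]] <- ifelse(x$transfer, ref, study)
  }
  x
}

#' Drop patients with no observed GOSE at any follow-up
#'
#' Removes, from every completed dataset, the rows whose 3-, 6- and
#' 12-month GOSE were all missing in the original data. These patients
#' contribute to the imputation models but carry no outcome information,
#' so they are deleted after imputation for statistical efficiency. The
#' removed row set is identical across datasets.
#'
#' @param x a `completed_set`.
#' @return the `completed_set` with rows removed.
#' @export
drop_no_outcome <- function(x) {
  stopifnot(inherits(x, "completed_set"))
  orig <- x$original
  drop <- is.na(orig$gose_3mo) & is.na(orig$gose_6mo) & is.na(orig$gose_12mo)
  keep <- which(!drop)
  x$data <- lapply(x$data, function(d) d[keep, , drop = FALSE])
  x$original <- orig[keep, , drop = FALSE]
  x$miss_mask <- lapply(x$miss_mask, function(mm) mm[keep])
  x
}
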