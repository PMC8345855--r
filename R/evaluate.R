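new_r2_grid <- function(rows, values, experiment) {
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  attr(grid, "values") <- values
  attr(grid, "experiment") <- experiment
  class(grid) <- c("r2_grid", "data.frame")
  grid
}

grid_row <- function(labels, r2) {
  cbind(as.data.frame(labels, stringsAsFactors = FALSE),
        as.data.frame(as.list(r2$summary)),
        n_excluded = r2$n_excluded, n_used = r2$n_used)
}

#' Substitution-strategy experiment
#'
#' The first of the two experiments: covariates and outcomes are multiply
#' imputed once (the derived neurological candidates are not), patients
#' with no observed GOSE at any follow-up are dropped, and then for every
#' requested combination of GCS variable (sum or motor), substitution
#' strategy, sub-score policy and pupil strategy, both outcome-model
#' families are fitted per completed dataset and summarised as McFadden
#' pseudo-R-squared distributions. Rows whose derived candidate is missing
#' are dropped per model (complete-case on the candidate): substitution
#' leaves a small residual missingness rather than inventing values. The
#' single covariate imputation is shared across all cells so that cells
#' differ only in the candidate variables.
#'
#' @param cohort a masked `tbi_cohort`.
#' @param m,iterations,seed imputation settings, see [mice_impute()].
#' @param gcs_vars `"gcs"`, `"gcsm"` or both.
#' @param gcs_strategies,pupil_strategies subsets of [strategies()].
#' @param sum_policies,motor_policies policy subsets, see [sum_policies()].
#' @param families model families to fit.
#' @param strata `"all"`, `"icu"` or both.
#' @return an `r2_grid` data frame: one row per cell with the R-squared
#'   summary; per-imputation values in `attr(, "values")`.
#' @export
run_substitution_experiment <- function(cohort, m = 20L, iterations = 5L,
                                        seed = 1L,
                                        gcs_vars = c("gcs", "gcsm"),
                                        gcs_strategies = strategies(),
                                        pupil_strategies = strategies(),
                                        sum_policies =
                                          tbibaseline::sum_policies(),
                                        motor_policies =
                                          tbibaseline::motor_policies(),
                                        families = c("logistic_survival",
                                                     "proportional_odds_gose"),
                                        strata = c("all", "icu")) {
  gcs_vars <- match.arg(gcs_vars, several.ok = TRUE)
  coh <- default_fill(cohort)
  cds <- mice_impute(coh, default_specs(), m = m, iterations = iterations,
                     seed = seed)
  cds <- drop_no_outcome(cds)

  # derive all requested candidate columns once, on the original
  # (post-deletion) assessment data, and attach to every completed dataset
  derived <- list()
  for (v in gcs_vars) {
    pols <- if (v == "gcs") sum_policies else motor_policies
    for (s in gcs_strategies) for (p in pols) {
      col <- paste("d", v, s, p, sep = "_")
      derived[[col]] <- derive_baseline(
        cds$original, s, v,
        sum_policy = if (v == "gcs") p else "nc_if_either",
        motor_policy = if (v == "gcsm") p else "nc_if_m")$value
    }
  }
  for (s in pupil_strategies) {
    derived[[paste0("d_pupils_", s)]] <-
      derive_baseline(cds$original, s, "pupils")$value
  }
  cds$data <- lapply(cds$data, function(d) {
    for (col in names(derived)) d[[col]] <- derived[[col]]
    d
  })

  rows <- list(); values <- list()
  for (v in gcs_vars) {
    pols <- if (v == "gcs") sum_policies else motor_policies
    for (s in gcs_strategies) for (p in pols) for (q in pupil_strategies)
      for (fam in families) for (st in strata) {
        spec <- model_spec(fam, paste("d", v, s, p, sep = "_"),
                           paste0("d_pupils_", q), stratum = st)
        r2 <- per_imputation_r2(cds, spec)
        lab <- list(variable = v, gcs_strategy = s, policy = p,
                    pupil_strategy = q, family = fam, stratum = st)
        rows[[length(rows) + 1L]] <- grid_row(lab, r2)
        values[[length(values) + 1L]] <- r2$values
      }
  }
  new_r2_grid(rows, values, "substitution")
}

#' Fully-imputed time-point experiment
#'
#' The second experiment: the per-time-point GCS/motor/pupil assessments
#' themselves are multiply imputed (ordinal conditionals over their
#' support) together with covariates and outcomes; the referring and
#' study-hospital arrival assessments are then combined into a single
#' presenting-ED-arrival time point, no-outcome patients are dropped, and
#' both model families are fitted per completed dataset for every
#' combination of assessment time point (pre-hospital, presenting ED
#' arrival, ED discharge) and GCS variable, with the pupil candidate taken
#' from its own (by default the same) time point.
#'
#' @inheritParams run_substitution_experiment
#' @param timepoints assessment time points for the GCS candidate, among
#'   `"preh"`, `"present_arr"`, `"ed_disch"`.
#' @param pupil_timepoints pupil time points crossed with each GCS cell;
#'   `NULL` (default) pairs each GCS time point with its own pupils.
#' @param sum_policy,motor_policy policies forming the observed
#'   per-time-point scores before imputation.
#' @return an `r2_grid`, one row per cell.
#' @export
run_timepoint_experiment <- function(cohort, m = 20L, iterations = 5L,
                                     seed = 1L,
                                     gcs_vars = c("gcs", "gcsm"),
                                     timepoints = c("preh", "present_arr",
                                                    "ed_disch"),
                                     pupil_timepoints = NULL,
                                     families = c("logistic_survival",
                                                  "proportional_odds_gose"),
                                     strata = c("all", "icu"),
                                     sum_policy = "nc_if_either",
                                     motor_policy = "nc_if_m") {
  gcs_vars <- match.arg(gcs_vars, several.ok = TRUE)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  coh <- default_fill(cohort)
  cds <- impute_timepoint_assessments(
    coh, m = m, iterations = iterations, seed = seed,
    assessment_vars = unique(c(gcs_vars, "pupils")),
    sum_policy = sum_policy, motor_policy = motor_policy)
  cds <- combine_presenting_ed(cds, vars = unique(c(gcs_vars, "pupils")))
  cds <- drop_no_outcome(cds)

  rows <- list(); values <- list()
  for (v in gcs_vars) for (tp in timepoints) {
    ptps <- pupil_timepoints %||% tp
    for (ptp in ptps) for (fam in families) for (st in strata) {
      spec <- model_spec(fam, paste0(v, "_", tp), paste0("pupils_", ptp),
                         stratum = st)
      r2 <- per_imputation_r2(cds, spec)
      lab <- list(variable = v, timepoint = tp, pupil_timepoint = ptp,
                  family = fam, stratum = st)
      rows[[length(rows) + 1L]] <- grid_row(lab, r2)
      values[[length(values) + 1L]] <- r2$values
    }
  }
  new_r2_grid(rows, values, "timepoint")
}

#' @export
print.r2_grid <- function(x, ...) {
  cat(sprintf("McFadden R2 grid (%s experiment): %d cells\n",
              attr(x, "experiment") %||% "?", nrow(x)))
  NextMethod()
}

#' Box-and-whisker display of an R2 grid
#'
#' One box per cell, grouped by family and stratum, showing the spread of
#' McFadden pseudo-R-squared over imputations.
#'
#' @param x an `r2_grid`.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, `x`.
#' @export
plot.r2_grid <- function(x, ...) {
  vals <- attr(x, "values")
  labcols <- setdiff(names(x),
                     c("median", "q1", "q3", "min", "max", "mean",
                       "n_excluded", "n_used"))
  labs <- apply(as.data.frame(x)[labcols], 1L, paste, collapse = ".")
  graphics::boxplot(stats::setNames(vals, labs), las = 2,
                    ylab = "McFadden pseudo-R2",
                    cex.axis = 0.6, ...)
  invisible(x)
}

grid_values_long <- function(grid) {
  vals <- attr(grid, "values")
  labcols <- setdiff(names(grid),
                     c("median", "q1", "q3", "min", "max", "mean",
                       "n_excluded", "n_used"))
  out <- do.call(rbind, lapply(seq_along(vals), function(i) {
    cbind(as.data.frame(grid)[rep(i, length(vals[[i]])), labcols,
                              drop = FALSE],
          imputation = seq_along(vals[[i]]), r2 = vals[[i]])
  }))
  rownames(out) <- NULL
  out
}

file_sha256 <- function(path) {
  out <- tryCatch(system2("sha256sum", shQuote(path), stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (length(out) >= 1L && nzchar(out[[1L]]))
    return(list(algorithm = "sha256", digest = strsplit(out[[1L]], " ")[[1L]][1L]))
  list(algorithm = "md5", digest = unname(tools::md5sum(path)))
}

#' Write the report bundle for one or both experiments
#'
#' Emits, under `out_dir`: the missingness table (classic layout), the
#' Spearman correlation matrix, the source-time-point distribution, one
#' summary CSV and one long per-imputation-value CSV per grid, optional
#' box-and-whisker figures (regenerable from the long CSVs alone), and a
#' JSON manifest listing every emitted file with its checksum. All CSVs are
#' written deterministically, so a rerun on the same inputs is
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param substitution_grid,timepoint_grid `r2_grid`s (either may be NULL,
#'   not both).
#' @param missingness a [missingness_table()] result.
#' @param correlations a [strategy_correlations()] matrix.
#' @param source_dist a data frame of [source_distribution()] rows.
#' @param figures write PDF boxplots as well.
#' @return the manifest (list), invisibly.
#' @export
report <- function(out_dir, substitution_grid = NULL, timepoint_grid = NULL,
                   missingness = NULL, correlations = NULL,
                   source_dist = NULL, figures = TRUE) {
  grids <- list(substitution = substitution_grid, timepoint = timepoint_grid)
  grids <- grids[!vapply(grids, is.null, logical(1L))]
  if (length(grids) == 0L)
    data_error("no experiment grids supplied")
  for (nm in names(grids))
    if (nrow(grids[[nm]]) == 0L)
      data_error(paste("empty grid for experiment:", nm))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_csv <- function(df, name, rn = FALSE) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = rn)
    files <<- c(files, path)
  }
  if (!is.null(missingness)) emit_csv(missingness, "missingness_table.csv")
  if (!is.null(correlations))
    emit_csv(as.data.frame(correlations), "spearman_correlations.csv",
             rn = TRUE)
  if (!is.null(source_dist)) emit_csv(source_dist, "source_distribution.csv")
  for (nm in names(grids)) {
    emit_csv(as.data.frame(grids[[nm]]), paste0("r2_", nm, "_summary.csv"))
    emit_csv(grid_values_long(grids[[nm]]), paste0("r2_", nm, "_values.csv"))
    if (figures) {
      fig <- file.path(out_dir, paste0("r2_", nm, "_boxplot.pdf"))
      grDevices::pdf(fig, width = 10, height = 6)
      plot(grids[[nm]])
      grDevices::dev.off()
      files <- c(files, fig)
    }
  }
  manifest <- list(files = lapply(files, function(f) {
    c(list(path = basename(f)), file_sha256(f))
  }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
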