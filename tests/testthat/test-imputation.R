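test_that("default fill sets unrecorded hypoxia/hypotension to absent and demands complete age", {
  coh <- simulate_cohort(cohort_config(n_patients = 50, seed = 3))
  coh$hypoxia <- NA_integer_
  out <- default_fill(coh)
  expect_true(all(out$hypoxia == 0L))

  coh2 <- generate_cohort(cfg_complete(10, 1))
  expect_identical(default_fill(coh2), coh2)

  coh3 <- generate_cohort(cfg_complete(10, 1))
  coh3$hypotension <- c(NA, NA, NA, coh3$hypotension[4:10])
  out3 <- default_fill(coh3)
  expect_equal(out3$hypotension[1:3], c(0L, 0L, 0L))
  expect_identical(out3$hypotension[4:10], coh3$hypotension[4:10])

  coh4 <- generate_cohort(cfg_complete(10, 1))
  coh4$age[5] <- NA
  expect_error(default_fill(coh4), "age")
})

test_that("a cohort with no missing cells passes through imputation unchanged", {
  coh <- default_fill(generate_cohort(cfg_complete(150, seed = 6)))
  cds <- mice_impute(coh, m = 3, iterations = 2, seed = 4)
  for (k in 1:3)
    expect_identical(complete_dataset(cds, k), as.data.frame(coh))
})

test_that("observed cells are never altered and are identical across datasets", {
  coh <- default_fill(simulate_cohort(cohort_config(n_patients = 300, seed = 8)))
  cds <- mice_impute(coh, m = 4, iterations = 2, seed = 5)
  for (spec in cds$specs) {
    v <- spec$name
    obs <- !is.na(coh[[v]])
    sub <- if (is.null(spec$subset)) rep(TRUE, nrow(coh)) else coh$transfer
    for (k in 1:4) {
      d <- complete_dataset(cds, k)
      expect_identical(d[[v]][obs], coh[[v]][obs])
      expect_false(anyNA(d[[v]][sub]))
    }
  }
})

test_that("imputation is deterministic given the seed", {
  coh <- default_fill(simulate_cohort(cohort_config(n_patients = 250, seed = 9)))
  a <- mice_impute(coh, m = 3, iterations = 2, seed = 77)
  b <- mice_impute(coh, m = 3, iterations = 2, seed = 77)
  expect_identical(a$data, b$data)
  c2 <- mice_impute(coh, m = 3, iterations = 2, seed = 78)
  expect_false(identical(a$data, c2$data))
})

test_that("ordinal draws respect category support", {
  coh <- default_fill(simulate_cohort(cohort_config(n_patients = 400, seed = 10)))
  cds <- impute_timepoint_assessments(coh, m = 2, iterations = 2, seed = 3,
                                      assessment_vars = c("gcs", "pupils"))
  for (k in 1:2) {
    d <- complete_dataset(cds, k)
    for (tp in c("preh", "study_arr", "ed_disch")) {
      expect_true(all(d[[paste0("gcs_", tp)]] %in% 3:15))
      expect_true(all(d[[paste0("pupils_", tp)]] %in% 0:2))
    }
    # referring-arrival exists only for transfers
    expect_true(all(d$gcs_ref_arr[d$transfer] %in% 3:15))
    expect_true(all(is.na(d$gcs_ref_arr[!d$transfer])))
    expect_true(all(d$gose_6mo %in% 1:8))
    expect_true(all(d$marshall %in% 1:6))
  }
})

test_that("between-imputation variance is positive for imputed continuous cells", {
  coh <- default_fill(simulate_cohort(cohort_config(n_patients = 500, seed = 12)))
  cds <- mice_impute(coh, m = 20, iterations = 3, seed = 6)
  mis <- is.na(coh$glucose)
  imp <- sapply(cds$data, function(d) d$glucose[mis])
  v <- apply(imp, 1L, var)
  expect_gte(mean(v > 0), 0.99)
})

test_that("conditional-model imputation beats marginal draws at recovering masked GCS", {
  cfg <- cfg_no_untestable(1500, seed = 14)
  truthcoh <- prepare_assessment_columns(generate_cohort(cfg))
  masked <- default_fill(apply_missingness(
    apply_untestability(generate_cohort(cfg), cfg), cfg))
  cds <- impute_timepoint_assessments(masked, m = 5, iterations = 3, seed = 15,
                                      assessment_vars = c("gcs", "pupils"))
  mis <- is.na(prepare_assessment_columns(masked)$gcs_preh)
  truth_vals <- truthcoh$gcs_preh[mis]
  imp_mae <- mean(sapply(cds$data, function(d)
    mean(abs(d$gcs_preh[mis] - truth_vals))))
  obs_vals <- prepare_assessment_columns(masked)$gcs_preh[!mis]
  set.seed(16)
  marg_mae <- mean(replicate(5, mean(abs(
    sample(obs_vals, sum(mis), replace = TRUE) - truth_vals))))
  expect_lt(imp_mae, marg_mae)
})

test_that("presenting-ED combination picks referring for transfers, study otherwise", {
  d <- data.frame(transfer = c(TRUE, FALSE, TRUE),
                  gcs_ref_arr = c(9L, NA, 12L),
                  gcs_study_arr = c(11L, 14L, 10L))
  out <- combine_presenting_ed(d, vars = "gcs")
  expect_equal(out$gcs_present_arr, c(9L, 14L, 12L))
})

test_that("patients with no GOSE at any follow-up are dropped from every dataset", {
  coh <- default_fill(simulate_cohort(cfg_no_untestable(10, seed = 18,
    gose_missing = c(gose_3mo = 0, gose_6mo = 0, gose_12mo = 0))))
  coh$gose_3mo[1:2] <- NA; coh$gose_6mo[1:2] <- NA; coh$gose_12mo[1:2] <- NA
  # patient 3 keeps only the 3-month GOSE: retained
  coh$gose_6mo[3] <- NA; coh$gose_12mo[3] <- NA
  cds <- mice_impute(coh, m = 2, iterations = 1, seed = 19)
  out <- drop_no_outcome(cds)
  for (k in 1:2) expect_equal(nrow(complete_dataset(out, k)), 8)
  expect_true(3 %in% out$original$id)
  expect_false(any(c(1, 2) %in% out$original$id))
})

test_that("congeniality under MCAR: pooled and complete-case estimates agree", {
  set.seed(20)
  n <- 1500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x))
  d <- data.frame(x = x, y = y, age = rnorm(n, 45, 10))
  d$x[sample(n, 450)] <- NA  # 30% MCAR
  cc <- glm(y ~ x, data = d, family = binomial())
  cds <- mice_impute(d, list(variable_spec("x", "gaussian_linear",
                                           c("y", "age"))),
                     m = 10, iterations = 3, seed = 21)
  pooled <- mean(sapply(cds$data, function(dd)
    coef(glm(y ~ x, data = dd, family = binomial()))[["x"]]))
  se_cc <- summary(cc)$coefficients["x", "Std. Error"]
  expect_lt(abs(pooled - coef(cc)[["x"]]), 3 * se_cc)
})

test_that("imputation inputs are validated", {
  coh <- default_fill(simulate_cohort(cohort_config(n_patients = 50, seed = 22)))
  expect_error(mice_impute(coh, m = 1, iterations = 2, seed = 1), "m")
  expect_error(mice_impute(coh, m = 2, iterations = 0, seed = 1), "iterations")
  expect_error(variable_spec("x", "gaussian_linear", character(0)), "predictor")
  expect_error(variable_spec("x", "gaussian_linear", c("x", "y")), "itself")
  coh$glucose <- NA_real_
  expect_error(mice_impute(coh, m = 2, iterations = 1, seed = 1),
               "zero observed")
})
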