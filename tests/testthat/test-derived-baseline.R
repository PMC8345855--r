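test_that("GCS sum policies handle missing and untestable components as specified", {
  # complete score: every policy returns 15
  for (p in sum_policies())
    expect_equal(gcs_sum_at_timepoint(4, 5, 6, policy = p), 15L)
  # untestable verbal: substituted with 1 only where the policy allows
  expect_equal(gcs_sum_at_timepoint(3, NA, 5, verbal_untestable = TRUE,
                                    policy = "nc_if_m_v1"), 9L)
  expect_equal(gcs_sum_at_timepoint(3, NA, 5, verbal_untestable = TRUE,
                                    policy = "both_1"), 9L)
  expect_true(is.na(gcs_sum_at_timepoint(3, NA, 5, verbal_untestable = TRUE,
                                         policy = "nc_if_either")))
  expect_true(is.na(gcs_sum_at_timepoint(3, NA, 5, verbal_untestable = TRUE,
                                         policy = "nc_if_v_m1")))
  # absent motor under the converse policy
  expect_equal(gcs_sum_at_timepoint(2, 4, NA, policy = "nc_if_v_m1"), 7L)
  # a recorded-but-untestable component counts as missing, same as absent
  expect_identical(
    gcs_sum_at_timepoint(3, 2, NA, motor_untestable = TRUE, policy = "both_1"),
    gcs_sum_at_timepoint(3, 2, NA, policy = "both_1"))
  # absent eye is never calculable
  for (p in sum_policies())
    expect_true(is.na(gcs_sum_at_timepoint(NA, 5, 6, policy = p)))
  # component validation
  expect_error(gcs_sum_at_timepoint(5, 5, 6), "eye")
  expect_error(gcs_sum_at_timepoint(4, 6, 6), "verbal")
  expect_error(gcs_motor_at_timepoint(7), "motor")
})

test_that("motor policies score an untestable motor as 1 or not calculable", {
  expect_equal(gcs_motor_at_timepoint(4, policy = "nc_if_m"), 4L)
  expect_true(is.na(gcs_motor_at_timepoint(NA, policy = "nc_if_m")))
  expect_equal(gcs_motor_at_timepoint(NA, policy = "m_1"), 1L)
  expect_equal(gcs_motor_at_timepoint(5, motor_untestable = TRUE,
                                      policy = "m_1"), 1L)
})

test_that("the five strategies follow their hand-traced fallback orders", {
  # one patient: GCS sums preh 8, referring absent, study 6, discharge 7
  coh <- blank_cohort(1)
  coh <- set_gcs(coh, 1, "preh", 3, 2, 3)      # 8
  coh <- set_gcs(coh, 1, "study_arr", 2, 2, 2) # 6
  coh <- set_gcs(coh, 1, "ed_disch", 2, 2, 3)  # 7
  got <- sapply(strategies(), function(s)
    derive_baseline(coh, s, "gcs")$value)
  expect_equal(unname(got[c("impact", "erasmus", "tarn", "best", "worst")]),
               c(7L, 6L, 6L, 8L, 6L))
  # sources recorded for the sequential strategies
  expect_equal(as.character(derive_baseline(coh, "impact", "gcs")$source),
               "ed_disch")
  expect_equal(as.character(derive_baseline(coh, "tarn", "gcs")$source),
               "study_arr")
  expect_equal(as.character(derive_baseline(coh, "best", "gcs")$source),
               "preh")
  # all four time points absent: missing value, no source
  empty <- blank_cohort(1)
  d <- derive_baseline(empty, "impact", "gcs")
  expect_true(is.na(d$value) && is.na(d$source))
  # unknown strategy
  expect_error(derive_baseline(coh, "locf", "gcs"), "strategy")
})

test_that("best/worst pupils select fewest/most unreactive", {
  coh <- blank_cohort(1)
  coh$pupils_preh[1] <- 2L
  coh$pupils_study_arr[1] <- 0L
  expect_equal(derive_baseline(coh, "best", "pupils")$value, 0L)
  expect_equal(derive_baseline(coh, "worst", "pupils")$value, 2L)
})

test_that("best/worst ties break towards the later time point", {
  coh <- blank_cohort(1)
  coh <- set_gcs(coh, 1, "preh", 3, 2, 3)      # 8
  coh <- set_gcs(coh, 1, "ed_disch", 2, 3, 3)  # 8
  d <- derive_baseline(coh, "best", "gcs")
  expect_equal(d$value, 8L)
  expect_equal(as.character(d$source), "ed_disch")
})

test_that("missingness table counts a patient with no data anywhere in every all-scanning strategy", {
  coh <- blank_cohort(4)
  for (i in 1:3) {
    coh <- set_gcs(coh, i, "study_arr", 4, 5, 6)
    coh$pupils_study_arr[i] <- 0L
  }
  coh <- set_gcs(coh, 4, "study_arr", 3, 4, 5)  # patient 4 has GCS but no pupils
  tab <- missingness_table(coh)
  pup <- tab[tab$variable == "pupils", ]
  for (s in c("best", "worst", "impact", "tarn", "erasmus"))
    expect_equal(pup[[s]], 25.00)
  # best/worst/impact columns agree everywhere (same availability set)
  expect_equal(tab$best, tab$impact)
  expect_equal(tab$worst, tab$impact)
  expect_error(missingness_table(blank_cohort(0)), "empty")
})

test_that("complete data yields zero missingness and pure source distributions", {
  coh <- generate_cohort(cfg_complete(80, seed = 9))
  tab <- missingness_table(coh)
  for (s in strategies()) expect_true(all(tab[[s]] == 0))
  sd_imp <- source_distribution(coh, "impact")
  expect_equal(unname(sd_imp[["ed_disch"]]), 1)
  sd_era <- source_distribution(coh, "erasmus")
  expect_equal(unname(sd_era[["study_arr"]]), 1)
  expect_equal(sum(sd_imp), 1, tolerance = 1e-12)
})

test_that("source distribution splits by availability", {
  coh <- blank_cohort(10)
  for (i in 1:10) coh <- set_gcs(coh, i, "study_arr", 4, 5, 6)
  for (i in 1:5) coh <- set_gcs(coh, i, "ed_disch", 4, 5, 6)
  sd <- source_distribution(coh, "impact")
  expect_equal(unname(sd[["ed_disch"]]), 0.5)
  expect_equal(unname(sd[["study_arr"]]), 0.5)
})

test_that("policy ordering: substitution can only rescue rows", {
  coh <- simulate_cohort(cohort_config(n_patients = 800, seed = 23))
  tab <- missingness_table(coh)
  g <- function(p) unlist(tab[tab$variable == "gcs" & tab$policy == p,
                              strategies()])
  expect_true(all(g("both_1") <= g("nc_if_m_v1")))
  expect_true(all(g("both_1") <= g("nc_if_v_m1")))
  expect_true(all(g("nc_if_m_v1") <= g("nc_if_either")))
  expect_true(all(g("nc_if_v_m1") <= g("nc_if_either")))
  m <- function(p) unlist(tab[tab$variable == "gcsm" & tab$policy == p,
                              strategies()])
  expect_true(all(m("m_1") <= m("nc_if_m")))
})

test_that("worst <= per-time-point values <= best, reversed for pupils", {
  coh <- simulate_cohort(cohort_config(n_patients = 2000, seed = 29))
  for (v in c("gcs", "gcsm")) {
    best <- derive_baseline(coh, "best", v)$value
    worst <- derive_baseline(coh, "worst", v)$value
    vals <- tbibaseline:::values_by_timepoint(coh, v, "nc_if_either", "nc_if_m")
    for (tp in colnames(vals)) {
      ok <- !is.na(vals[, tp])
      expect_true(all(worst[ok] <= vals[ok, tp] & vals[ok, tp] <= best[ok]))
    }
  }
  bp <- derive_baseline(coh, "best", "pupils")$value
  wp <- derive_baseline(coh, "worst", "pupils")$value
  pv <- tbibaseline:::values_by_timepoint(coh, "pupils", "nc_if_either", "nc_if_m")
  for (tp in colnames(pv)) {
    ok <- !is.na(pv[, tp])
    expect_true(all(bp[ok] <= pv[ok, tp] & pv[ok, tp] <= wp[ok]))
  }
})

test_that("sequential strategies return exactly the value at their recorded source", {
  coh <- simulate_cohort(cohort_config(n_patients = 500, seed = 37))
  vals <- tbibaseline:::values_by_timepoint(coh, "gcs", "nc_if_either", "nc_if_m")
  for (s in c("impact", "tarn", "erasmus")) {
    d <- derive_baseline(coh, s, "gcs")
    ok <- !is.na(d$value)
    picked <- vals[cbind(which(ok), as.integer(d$source[ok]))]
    expect_identical(d$value[ok], picked)
  }
})

test_that("derivation is pure: permuting patients permutes outputs", {
  coh <- simulate_cohort(cohort_config(n_patients = 200, seed = 41))
  perm <- sample(nrow(coh))
  a <- derive_baseline(coh, "impact", "gcs")
  b <- derive_baseline(coh[perm, ], "impact", "gcs")
  expect_identical(a$value[perm], b$value)
})

test_that("strategy correlations are symmetric with unit diagonal and the expected signs", {
  coh <- simulate_cohort(cohort_config(n_patients = 1500, seed = 43))
  rho <- strategy_correlations(coh)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, ncol(rho)))
  # GCS variants strongly positively correlated with each other
  expect_gt(rho["gcs_impact", "gcs_erasmus"], 0.5)
  # derived GCS vs derived unreactive pupils: negative
  expect_lt(rho["gcs_impact", "pupils_impact"], 0)
  # identical selections give rho exactly 1: complete data, impact == best source set?
  coh2 <- blank_cohort(6)
  eyes <- c(2L, 3L, 4L, 2L, 3L, 4L)
  for (i in 1:6) coh2 <- set_gcs(coh2, i, "study_arr", eyes[i], 4, 5)
  r2 <- strategy_correlations(coh2)
  expect_equal(r2["gcs_impact", "gcs_erasmus"], 1)
  # pairs with < 3 joint observations flagged unavailable
  coh3 <- blank_cohort(3)
  coh3 <- set_gcs(coh3, 1, "preh", 4, 5, 6)
  r3 <- strategy_correlations(coh3)
  expect_true(is.na(r3["gcs_impact", "gcsm_impact"]))
})

test_that("severity bands partition the GCS range", {
  expect_equal(severity_bands(c(15, 13)),
               c(mild = 2L, moderate = 0L, severe = 0L))
  expect_equal(severity_bands(c(12, 9)),
               c(mild = 0L, moderate = 2L, severe = 0L))
  expect_equal(severity_bands(c(8, 3, 14)),
               c(mild = 1L, moderate = 0L, severe = 2L))
  x <- c(3:15, NA)
  expect_equal(sum(severity_bands(x)), 13L)
  expect_error(severity_bands(c(2, 10)), "GCS")
})
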