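test_that("survival dichotomisation treats only GOSE 1 as death", {
  expect_equal(dichotomise_survival(1), 0L)
  expect_equal(dichotomise_survival(2), 1L)  # vegetative state survives
  expect_equal(dichotomise_survival(8), 1L)
  expect_equal(dichotomise_survival(c(1, NA, 5)), c(0L, NA, 1L))
  expect_error(dichotomise_survival(0), "GOSE")
  expect_error(dichotomise_survival(9), "GOSE")
})

test_that("intercept-only logistic model fits the observed proportion", {
  d <- data.frame(y = rep(c(0L, 1L), c(30, 70)))
  fit <- fit_logistic(d, "y", "1")
  expect_equal(unname(plogis(fit$coefficients[1])), 0.70, tolerance = 1e-8)
  expect_equal(mcfadden_r2(fit), 0, tolerance = 1e-10)
})

test_that("complete separation is flagged and still yields a finite fit", {
  d <- data.frame(y = c(0L, 0L, 1L, 1L, 0L, 1L),
                  x = c(-2, -1, 1, 2, -1.5, 1.5))
  fit <- fit_logistic(d, "y", "x")
  expect_true(fit$separation)
  expect_true(is.finite(fit$loglik))
  expect_gte(fit$loglik, fit$null_loglik)
})

test_that("logistic fit matches the grid-search likelihood oracle", {
  set.seed(31)
  n <- 50
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.3 + 0.8 * d$x1 - 0.5 * d$x2))
  fit <- fit_logistic(d, "y", c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  ll <- function(b) {
    p <- plogis(drop(X %*% b))
    sum(d$y * log(p) + (1 - d$y) * log(1 - p))
  }
  oracle <- grid_maximise(ll, lower = rep(-4, 3), upper = rep(4, 3))
  expect_lt(abs(fit$loglik - oracle$value), 1e-4)
})

test_that("two-category proportional-odds model equals logistic regression", {
  set.seed(32)
  n <- 120
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 1L + rbinom(n, 1, plogis(-0.2 + 0.9 * d$x))
  po <- fit_proportional_odds(d, "y", c("x", "z"))
  d$y01 <- as.integer(d$y == 2)
  lo <- fit_logistic(d, "y01", c("x", "z"))
  expect_equal(unname(po$coefficients[c("x", "z")]),
               unname(lo$coefficients[c("x", "z")]), tolerance = 1e-6)
  expect_equal(unname(po$cutpoints[1]),
               -unname(lo$coefficients[["(Intercept)"]]), tolerance = 1e-6)
  expect_equal(po$loglik, lo$loglik, tolerance = 1e-8)
})

test_that("cutpoints-only model reproduces observed category frequencies", {
  set.seed(33)
  y <- sample(1:4, 200, replace = TRUE, prob = c(0.1, 0.3, 0.4, 0.2))
  d <- data.frame(y = y)
  nk <- tabulate(y, 4)
  ll0 <- sum(nk * log(nk / length(y)))
  # MASS::polr intercept-only fit as independent confirmation of the
  # closed-form null log-likelihood used by fit_proportional_odds
  m0 <- MASS::polr(factor(y, ordered = TRUE) ~ 1, data = d)
  expect_equal(as.numeric(logLik(m0)), ll0, tolerance = 1e-6)
  expect_equal(unname(plogis(m0$zeta)), cumsum(nk / length(y))[1:3],
               tolerance = 1e-5)
})

test_that("proportional-odds fit matches the grid-search oracle", {
  set.seed(34)
  n <- 60
  x <- rnorm(n)
  u <- 0.9 * x + rlogis(n)
  y <- cut(u, c(-Inf, -0.5, 0.8, Inf), labels = FALSE)
  d <- data.frame(y = y, x = x)
  fit <- fit_proportional_odds(d, "y", "x")
  ll <- function(par) {  # par = (z1, z2, beta), z2 > z1 required
    if (par[2] <= par[1]) return(-Inf)
    eta <- par[3] * x
    cum1 <- plogis(par[1] - eta); cum2 <- plogis(par[2] - eta)
    p <- cbind(cum1, cum2 - cum1, 1 - cum2)
    if (any(p[cbind(seq_len(n), y)] <= 0)) return(-Inf)
    sum(log(p[cbind(seq_len(n), y)]))
  }
  oracle <- grid_maximise(ll, lower = c(-4, -4, -4), upper = c(4, 4, 4))
  expect_lt(abs(fit$loglik - oracle$value), 1e-4)
})

test_that("proportional-odds fitting collapses empty categories", {
  set.seed(35)
  d <- data.frame(y = sample(c(1L, 3L, 7L), 90, replace = TRUE),
                  x = rnorm(90))
  fit <- fit_proportional_odds(d, "y", "x")
  expect_equal(length(fit$cutpoints), 2L)
  expect_true(all(diff(fit$cutpoints) > 0))
  expect_equal(names(fit$cutpoints), c("1|3", "3|7"))
})

test_that("McFadden identities hold", {
  expect_equal(mcfadden_r2(-50, -100), 0.5)
  expect_equal(mcfadden_r2(-100, -100), 0)
  expect_error(mcfadden_r2(0, 0), "null")
  # nested-model monotonicity on random datasets
  set.seed(36)
  for (i in 1:5) {
    n <- 150
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- rbinom(n, 1, plogis(0.2 * d$x1))
    r_small <- mcfadden_r2(fit_logistic(d, "y", "x1"))
    r_big <- mcfadden_r2(fit_logistic(d, "y", c("x1", "x2")))
    expect_gte(r_big, r_small - 1e-10)
    expect_gte(r_small, 0)
    expect_lt(r_big, 1)
  }
})

test_that("pseudo-R2 is invariant to affine rescaling of continuous predictors", {
  set.seed(37)
  n <- 300
  d <- data.frame(x = rnorm(n, 50, 10), z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.1 + 0.05 * (d$x - 50) + 0.4 * d$z))
  r1 <- mcfadden_r2(fit_logistic(d, "y", c("x", "z")))
  d$x <- (d$x - 50) / 10
  r2 <- mcfadden_r2(fit_logistic(d, "y", c("x", "z")))
  expect_equal(r1, r2, tolerance = 1e-8)
  d$yord <- cut(d$z + rlogis(n), c(-Inf, -1, 1, Inf), labels = FALSE)
  p1 <- mcfadden_r2(fit_proportional_odds(d, "yord", c("x", "z")))
  d$x <- d$x * 7 + 3
  p2 <- mcfadden_r2(fit_proportional_odds(d, "yord", c("x", "z")))
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("per-imputation R2 over identical datasets is constant", {
  coh <- default_fill(generate_cohort(cfg_complete(250, seed = 38)))
  cds <- mice_impute(coh, m = 3, iterations = 1, seed = 39)
  cds$data <- lapply(cds$data, prepare_assessment_columns)
  spec <- model_spec("logistic_survival", "gcs_ed_disch", "pupils_ed_disch")
  r2 <- per_imputation_r2(cds, spec)
  expect_equal(length(r2$values), 3L)
  expect_true(all(r2$values == r2$values[1]))
  expect_equal(unname(r2$summary[["median"]]), r2$values[1])
  expect_gt(r2$values[1], 0)  # the generator has a real effect
})

test_that("no-signal null: adding GCS to an outcome it does not drive gains < 0.01 R2", {
  cfg <- cfg_complete(2000, seed = 40,
                      outcome_coefficients = c(b_severity = 0, b_age = 0.3,
                                               b_glucose = 0.03, b_hb = 0.03,
                                               b_marshall = 0, b_tsah = 0,
                                               b_edh = 0))
  d <- prepare_assessment_columns(default_fill(generate_cohort(cfg)))
  d$surv <- dichotomise_survival(d$gose_6mo)
  fixed <- c("age", "glucose", "hb", "marshall", "tsah", "edh")
  base <- mcfadden_r2(fit_logistic(d, "surv", fixed))
  with_gcs <- mcfadden_r2(fit_logistic(d, "surv",
                                       c(fixed, "gcs_ed_disch",
                                         "pupils_ed_disch")))
  expect_lt(with_gcs - base, 0.01)
})

test_that("model-spec invariants are enforced", {
  expect_error(model_spec("logistic_survival", c("a", "b"), "p"), "exactly one")
  f <- fit_logistic(data.frame(y = rep(0:1, 25), x = rnorm(50)), "y", "x")
  expect_gte(f$loglik, f$null_loglik)
  expect_error(fit_logistic(data.frame(y = rep(1L, 20), x = rnorm(20)),
                            "y", "x"), "single class")
})
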