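# Internal conditional-model fitters for the chained-equations engine.
#
# All three return enough to make a proper (Bayesian) imputation draw:
# point estimates plus a posterior (co)variance. Logistic and
# proportional-odds fits carry a small ridge penalty on the slope
# coefficients so that separation in small strata degrades gracefully
# instead of diverging; the penalty default (1e-4 per observation-scaled
# unit) is far below the information content of any non-degenerate fit.

# --- Gaussian: conjugate Bayesian linear regression draw -------------------

# Fit y ~ X (X includes intercept) and draw (beta*, sigma*) from the
# standard noninformative conjugate posterior, then impute X_mis beta* + e.
bayes_lm_draw <- function(X, y, X_mis, ridge = 1e-6) {
  p <- ncol(X)
  XtX <- crossprod(X) + diag(ridge, p)
  Xty <- crossprod(X, y)
  R <- chol(XtX)
  beta_hat <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  res <- y - X %*% beta_hat
  df <- max(length(y) - p, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1L, df)
  # beta* ~ N(beta_hat, sigma2 (X'X)^-1); draw via the Cholesky of XtX.
  z <- stats::rnorm(p)
  beta_star <- beta_hat + sqrt(sigma2) * backsolve(R, z)
  drop(X_mis %*% beta_star) + stats::rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# --- Logistic: ridge-stabilised IRLS ---------------------------------------

ridge_logit_fit <- function(X, y, ridge = 1e-4, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(ridge, p); pen[1L, 1L] <- 0  # intercept unpenalised
  beta <- numeric(p)
  beta[1L] <- stats::qlogis(min(max(mean(y), 1e-3), 1 - 1e-3))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zz <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w) + pen
    XtWz <- crossprod(X, w * zz)
    beta_new <- tryCatch(solve(XtWX, XtWz), error = function(e) NULL)
    if (is.null(beta_new)) {
      pen <- pen + diag(1e-2, p)
      next
    }
    beta <- drop(beta_new)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- tryCatch(solve(crossprod(X, X * w) + pen),
                   error = function(e) diag(1e6, p))
  list(coef = beta, vcov = vcov, converged = converged,
       loglik = sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12))))
}

# Draw beta* ~ N(beta_hat, vcov) and impute Bernoulli outcomes.
ridge_logit_draw <- function(X, y, X_mis, ridge = 1e-4) {
  fit <- ridge_logit_fit(X, y, ridge = ridge)
  beta_star <- draw_mvn(fit$coef, fit$vcov)
  p_mis <- stats::plogis(drop(X_mis %*% beta_star))
  as.integer(stats::runif(nrow(X_mis)) < p_mis)
}

draw_mvn <- function(mean, vcov) {
  p <- length(mean)
  ch <- tryCatch(chol(vcov), error = function(e) {
    chol(vcov + diag(max(diag(vcov)) * 1e-6 + 1e-8, p))
  })
  drop(mean + t(ch) %*% stats::rnorm(p))
}

# --- Proportional odds: penalised MLE on an unconstrained scale ------------

# Parameterisation: theta = (zeta_1, log(zeta_2 - zeta_1), ...,
# log(zeta_{K-1} - zeta_{K-2}), beta). Cutpoints are strictly increasing by
# construction, so posterior draws on the theta scale always map back to a
# valid model. X must NOT contain an intercept column. y must be integer
# codes 1..K with every category present.
po_nll_grad <- function(theta, X, y, K, ridge) {
  nb <- ncol(X)
  z <- theta_to_cutpoints(theta, K)
  beta <- theta[(K - 1L) + seq_len(nb)]
  eta <- if (nb) drop(X %*% beta) else numeric(nrow(X))
  upper <- ifelse(y == K, Inf, z[pmin(y, K - 1L)] - eta)
  lower <- ifelse(y == 1L, -Inf, z[pmax(y - 1L, 1L)] - eta)
  FU <- stats::plogis(upper); FL <- stats::plogis(lower)
  pr <- pmax(FU - FL, 1e-12)
  nll <- -sum(log(pr)) + 0.5 * ridge * sum(beta^2)

  fU <- ifelse(is.finite(upper), stats::dlogis(upper), 0)
  fL <- ifelse(is.finite(lower), stats::dlogis(lower), 0)
  # gradient of -ll wrt each raw cutpoint z_j
  gz <- numeric(K - 1L)
  wU <- fU / pr; wL <- fL / pr
  for (j in seq_len(K - 1L)) {
    gz[j] <- -(sum(wU[y == j]) - sum(wL[y == j + 1L]))
  }
  # map to theta scale: z_j = z_1 + sum_{i<=j-1} exp(theta_{1+i})
  gtheta_cut <- numeric(K - 1L)
  gtheta_cut[1L] <- sum(gz)
  if (K > 2L) {
    for (i in 2L:(K - 1L)) {
      gtheta_cut[i] <- exp(theta[i]) * sum(gz[i:(K - 1L)])
    }
  }
  gbeta <- if (nb) drop(crossprod(X, wU - wL)) + ridge * beta else numeric(0)
  list(nll = nll, grad = c(gtheta_cut, gbeta))
}

theta_to_cutpoints <- function(theta, K) {
  if (K == 2L) return(theta[1L])
  c(theta[1L], theta[1L] + cumsum(exp(theta[2L:(K - 1L)])))
}

ridge_polr_fit <- function(X, y, ridge = 1e-4, start = NULL, maxit = 300L,
                           vcov_cache = NULL, reltol = 1e-10) {
  K <- max(y)
  nb <- ncol(X)
  if (is.null(start)) {
    cum <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / length(y)
    cum <- pmin(pmax(cum, 1e-4), 1 - 1e-4)
    z0 <- stats::qlogis(cum)
    d0 <- if (K > 2L) log(pmax(diff(z0), 1e-3)) else numeric(0)
    start <- c(z0[1L], d0, numeric(nb))
  }
  # optim asks for fn and gr at the same point; share one evaluation
  last_theta <- NULL; last_res <- NULL
  eval_at <- function(th) {
    if (is.null(last_theta) || !identical(th, last_theta)) {
      last_res <<- po_nll_grad(th, X, y, K, ridge)
      last_theta <<- th
    }
    last_res
  }
  fn <- function(th) eval_at(th)$nll
  gr <- function(th) eval_at(th)$grad
  opt <- stats::optim(start, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  if (is.null(vcov_cache)) {
    H <- stats::optimHess(opt$par, fn, gr)
    vcov <- tryCatch(solve(H), error = function(e) {
      tryCatch(solve(H + diag(1e-4, length(opt$par))),
               error = function(e2) diag(1e4, length(opt$par)))
    })
  } else {
    vcov <- vcov_cache
  }
  list(theta = opt$par, vcov = vcov, K = K, nb = nb,
       converged = opt$convergence == 0L, nll = opt$value)
}

# Category probabilities for new rows under parameters theta.
po_predict_probs <- function(theta, X_new, K) {
  nb <- ncol(X_new)
  z <- theta_to_cutpoints(theta, K)
  beta <- theta[(K - 1L) + seq_len(nb)]
  eta <- if (nb) drop(X_new %*% beta) else numeric(nrow(X_new))
  cum <- stats::plogis(outer(eta, z, function(e, zz) zz - e))
  cbind(cum, 1)[, seq_len(K), drop = FALSE] -
    cbind(0, cum)[, seq_len(K), drop = FALSE]
}

# Proper-imputation draw for an ordinal variable: draw theta* from the
# normal approximation at the penalised MLE, then draw categories from the
# implied predictive distribution. Returns integer codes 1..K.
ridge_polr_draw <- function(X, y, X_mis, ridge = 1e-4, start = NULL,
                            vcov_cache = NULL) {
  fit <- ridge_polr_fit(X, y, ridge = ridge, start = start,
                        vcov_cache = vcov_cache)
  theta_star <- draw_mvn(fit$theta, fit$vcov)
  pr <- po_predict_probs(theta_star, X_mis, fit$K)
  cum <- pr
  if (fit$K > 1L)
    for (k in 2L:fit$K) cum[, k] <- cum[, k - 1L] + cum[, k]
  u <- stats::runif(nrow(X_mis))
  draws <- 1L + rowSums(u > cum[, seq_len(fit$K - 1L), drop = FALSE])
  list(draws = as.integer(draws), fit = fit)
}
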