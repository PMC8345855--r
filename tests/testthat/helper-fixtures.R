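# Shared fixtures: small configurations and hand-built cohorts.

# Config with untestability switched off (links pinned at ~0 probability),
# used where tests need full control over which cells are missing.
cfg_no_untestable <- function(n = 200, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed,
                intubation = c(-100, 0), sedation = c(-100, 0), ...)
}

# Fully clean config: no untestability and no missingness anywhere.
cfg_complete <- function(n = 200, seed = 1, ...) {
  cfg_no_untestable(
    n, seed,
    missing_prob_by_timepoint = c(0, 0, 0, 0),
    covariate_missing = c(glucose = 0, hb = 0, marshall = 0, tsah = 0,
                          edh = 0, hypoxia = 0, hypotension = 0),
    gose_missing = c(gose_3mo = 0, gose_6mo = 0, gose_12mo = 0), ...)
}

# An empty standard-layout cohort of n patients, components all NA, to be
# filled by hand in worked-example tests.
blank_cohort <- function(n) {
  coh <- data.frame(id = seq_len(n),
                    stratum = factor(rep("icu", n), levels = c("ed", "hosp", "icu")),
                    transfer = rep(TRUE, n), age = rep(40, n),
                    glucose = rep(8, n), hb = rep(13, n),
                    marshall = rep(2L, n), tsah = rep(0L, n), edh = rep(0L, n),
                    hypoxia = rep(0L, n), hypotension = rep(0L, n),
                    gose_3mo = rep(5L, n), gose_6mo = rep(5L, n),
                    gose_12mo = rep(5L, n))
  for (tp in c("preh", "ref_arr", "study_arr", "ed_disch")) {
    for (col in c("gcs_e_", "gcs_v_", "gcs_m_", "pupils_"))
      coh[[paste0(col, tp)]] <- rep(NA_integer_, n)
    coh[[paste0("ut_v_", tp)]] <- rep(FALSE, n)
    coh[[paste0("ut_m_", tp)]] <- rep(FALSE, n)
  }
  class(coh) <- c("tbi_cohort", "data.frame")
  coh
}

# Set all three GCS components at one time point so the sum is fixed.
set_gcs <- function(coh, row, tp, e, v, m) {
  coh[[paste0("gcs_e_", tp)]][row] <- e
  coh[[paste0("gcs_v_", tp)]][row] <- v
  coh[[paste0("gcs_m_", tp)]][row] <- m
  coh
}

# Coarse-to-fine grid-search maximiser: an independent oracle for
# low-dimensional likelihoods. Refines an 11-point grid per dimension
# around the incumbent, halving the span each round.
grid_maximise <- function(loglik, lower, upper, rounds = 14L, points = 11L) {
  p <- length(lower)
  centre <- (lower + upper) / 2
  span <- (upper - lower) / 2
  best <- centre
  best_ll <- loglik(centre)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j)
      seq(best[j] - span[j], best[j] + span[j], length.out = points))
    cand <- as.matrix(expand.grid(grids))
    lls <- apply(cand, 1L, loglik)
    i <- which.max(lls)
    if (lls[i] > best_ll) { best <- cand[i, ]; best_ll <- lls[i] }
    span <- span * 0.55
  }
  list(par = best, value = best_ll)
}
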