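---
title: "Methods: baseline neurological covariate imputation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: baseline neurological covariate imputation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

# The problem and the two imputation families

A TBI patient's neurological baseline — GCS sum (3–15), GCS motor
component (1–6), and the number of unreactive pupils (0–2) — may be
assessed at four emergency-phase time points: pre-hospital, referring-ED
arrival (secondary transfers only), study-ED arrival, and ED discharge.
Any time point can be *unrecorded*; verbal and motor components can
additionally be *untestable* (endotracheal intubation removes the verbal
response; deep sedation or paralysis the motor response). The package
encodes these two states distinctly — untestable cells carry a `UT`
sentinel in CSV output — because the accounting reports them separately,
but the derivation rules pool them: an untestable component is as
unavailable for scoring as an absent one.

**Substitution** resolves multiplicity by a fallback order
(`impact`: discharge → study arrival → referring arrival → pre-hospital;
`tarn`: referring arrival → study arrival → pre-hospital;
`erasmus`: study arrival → referring arrival → pre-hospital;
`best`/`worst`: extremum over whatever is available), applied after a
sub-score policy has decided, per time point, whether a partially
untestable GCS sum is "not calculable" or completed with 1s. A time point
rendered not calculable is skipped and the fallback continues — this
ordering of policy before strategy is what lets the policy change the
residual missingness under a fixed strategy.

**Chained-equations multiple imputation** completes the dataset `m` times.
Each variable gets a conditional model: Gaussian linear for glucose and
haemoglobin, logistic for EDH and tSAH, proportional-odds for Marshall
class, the ordinal assessments, and GOSE. Hypoxia and hypotension are not
imputed: unrecorded means "assumed absent" (`default_fill()`), and age
must be complete. Patients with no GOSE at 3, 6 or 12 months contribute to
the imputation models and are deleted afterwards (`drop_no_outcome()`).

Strategies are compared through the models they feed — logistic regression
on 6-month survival (GOSE > 1; GOSE 1 is death by the instrument's
definition, including the vegetative state among survivors) and
proportional-odds regression on the ordered GOSE — using McFadden's
pseudo-R² `1 − logL/logL₀`. The per-imputation R² values are reported as a
distribution; Rubin's rules are never applied to R² (they are not defined
for it), only to coefficients where those are requested.

# Decisions where the design was genuinely open

* **TARN order for non-transferred patients.** The referring-arrival slot
  does not exist for them, so the effective order is study arrival →
  pre-hospital. Implemented by leaving the referring slot structurally
  absent, which makes one fallback order serve both groups.
* **`best`/`worst` select each variable independently across time points**
  (the GCS may come from one time point and the pupils from another).
  With components missing at different time points, a jointly-selected
  extremum would discard patients unnecessarily; per-variable selection is
  the only reading consistent with per-variable source reporting.
* **Ties in `best`/`worst` break towards the later time point**, making
  the source distribution deterministic. The tie cannot affect the score,
  and the later assessment is the post-stabilisation one.
* **A time point with pupils recorded but GCS not calculable** contributes
  to pupil selection and is skipped for GCS selection.
* **GCS sum is imputed directly as a 13-category ordinal variable**, not
  component-wise: the strategy comparison operates on sum and motor
  scores, and component-wise imputation would add model complexity the
  comparison never uses.
* **Visit order** (glucose, haemoglobin, EDH, tSAH, Marshall, then the
  assessments, then 3/6/12-month GOSE) is fixed for reproducibility. The
  3- and 12-month GOSE are imputable with the 6-month GOSE as predictor
  and vice versa — mutual auxiliaries.
* **Residual missingness after substitution** (a candidate still missing
  after every fallback) is handled by per-model complete-case deletion of
  that row; the candidate itself is never multiply imputed in the
  substitution arm, otherwise the strategies would converge to the same
  model.
* **Hypoxia and hypotension are excluded from the outcome models** by
  default (they enter the imputation only); the fixed covariate set is
  age, glucose, haemoglobin, Marshall, tSAH, EDH, with GCS/GCSm and
  Marshall entered as linear numeric terms to keep the comparison across
  strategies interpretable.

# The synthetic-cohort generator

The generator exists so that every stage has data with the statistical
structure the analysis assumes. One latent standard-normal injury
severity `s` (higher = worse) drives:

* **stratum**: an ordinal probit on `s` plus unit noise, thresholds set so
  the ED/hospital/ICU mix matches `stratum_probs` (default 0.30 / 0.23 /
  0.47, ICU-heavy as in large European TBI cohorts);
* **neurological state** at time point `t`:
  `n_t = −s + drift·(t−1) + ε_t`, with `ε_t ~ N(0, σ_t)`. The default
  noise SDs `(1.0, 0.6, 0.5, 0.4)` encode decreasing unreliability from
  pre-hospital to post-stabilisation; the resuscitation drift (default
  0.05 per time point, latent-scale units) encodes modest systematic
  improvement. GCS components and pupils are fixed thresholdings of
  `n_t`, which guarantees mean GCS falls monotonically in severity and
  that the rank correlation between observed GCS and outcome grows across
  time points — the construction the time-point comparison relies on;
* **covariates** with deliberately moderate severity loadings (glucose
  +0.45 mmol/L, haemoglobin −0.25 g/dL per severity SD; Marshall class a
  noisy thresholding of `s`; logistic links for tSAH/EDH/hypoxia/
  hypotension). Loadings are kept moderate so the baseline covariates do
  not absorb the severity signal that distinguishes the assessment time
  points;
* **outcomes**: 6-month GOSE from a proportional-odds model whose linear
  predictor is dominated by severity (weight 1.6) with small direct
  covariate effects; 3- and 12-month GOSE are noisy ordinal copies of the
  same linear predictor shifted by a recovery drift (default ±0.30, SD
  0.80), so they are informative but imperfect auxiliaries;
* **untestability**: per-time-point intubation/sedation draws with
  severity-monotone logistic links (slopes constrained non-negative);
* **missingness**: cell-level, with probability depending only on the
  always-observed time point (defaults 0.40 / 0.10 / 0.05 / 0.05), plus
  optional stratum shifts (default 0) — missing at random by
  construction, so the chained-equations assumptions hold exactly. A
  single `mnar_shift` parameter adds severity-dependence for sensitivity
  experiments and defaults off. Stratum, transfer status and age are
  never masked.

What the generator does **not** emulate: real pre-hospital physiology
(hypoxia/hypotension are correlated with severity, not causal confounders
of the GCS), inter-rater GCS noise structure, informative transfer
decisions, loss to follow-up that depends on outcome, and the marginal
covariate distributions of any particular registry — the defaults are
plausible for a mixed European trauma population, not calibrated to one.
Passing tests therefore demonstrate that the *pipeline* behaves correctly
under the assumed structure, not that any particular strategy is best on
real data.

# Numerical choices

* **Outcome fits** use `stats::glm` (IRLS, relative log-likelihood
  tolerance 1e-8) and `MASS::polr`. Complete separation (non-convergence,
  or any |coefficient| > 15) is flagged and refitted with a small ridge
  penalty (1e-2) via the internal fitters, so a finite likelihood is
  always returned; the flag is carried in the result. An empty outcome
  class raises an error rather than a degenerate fit; empty GOSE
  categories are collapsed before ordinal fitting and the labels retained.
  A two-category ordinal outcome is fitted as the analytically equivalent
  logistic regression.
* **Imputation conditionals** are the package's own ridge-stabilised
  fitters (default penalty 1e-4 on slopes only): logistic IRLS, and a
  proportional-odds maximiser on an unconstrained parameterisation
  (first cutpoint plus log-increments), BFGS with analytic gradients, so
  posterior draws always map back to strictly increasing cutpoints.
  Parameter draws use the standard conjugate posterior for Gaussian
  conditionals and a normal approximation at the penalised MLE (inverse
  observed information) for logistic/ordinal ones; predictive draws
  respect the observed category support. A failing conditional is retried
  twice with a 100-fold stronger ridge before erroring.
* **Warm starts and information reuse.** Within one imputation run the
  conditional MLEs are warm-started across sweeps and datasets, and the
  observed-information matrix of each ordinal conditional is computed on
  a variable's first sweep of each run and reused afterwards: observed
  cells — identical in every dataset — dominate the information, so the
  matrix is essentially constant while the fill-ins vary. This is purely
  a cost optimisation; point estimates are refitted every sweep.
* **Determinism.** Every user-facing entry point takes one seed;
  stage-level and per-dataset sub-seeds are derived from it by a fixed
  scheme (all below 2³¹). Identical inputs and seed give bit-identical
  cohorts, completed datasets, grids and CSV output.

# Scales used by the tests and the acceptance script

Simulation-backed checks run at sizes chosen to keep Monte-Carlo error
well below the effects being asserted while remaining desk-scale: binomial
rate checks and bounding properties at n = 10,000; parameter-recovery and
congeniality checks at n = 2,000 with m = 20 completed datasets and 5
sweeps; the qualitative time-point comparison averages 10 independent
cohorts of n = 2,000 at m = 20. The acceptance script uses one cohort of
n = 2,000 with m = 10. The reference configuration for a full analysis
(m = 200, 5 iterations) remains the package default in `mice_impute()`.

# Known limitations

* The proportional-odds conditionals assume proportionality across all
  category contrasts; a badly violated assumption would propagate into
  imputed assessments. No partial-proportional extension is provided.
* McFadden R² distributions are compared descriptively; no inferential
  test of R² differences between cells is offered.
* Predictive-mean matching, random-forest conditionals and MNAR
  imputation models are out of scope; the `mnar_shift` switch affects the
  generator only, enabling sensitivity *data*, not MNAR-aware estimation.
* The substitution arm's complete-case handling of residual candidate
  missingness is principled only when that residual missingness is small
  (it is, by design, for the discharge-anchored strategies under lenient
  policies).
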