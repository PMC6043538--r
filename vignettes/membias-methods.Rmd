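---
title: "Models and methods behind membias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind membias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`membias` analyzes the remember-and-decide paradigm: choices between
options that must be retrieved from memory, followed by cued recall and a
per-option estimate of one's own recall success. This vignette documents
the statistical models, the generative simulator, the numerical choices,
and the design decisions that were genuinely open — in enough detail that
a maintainer can judge every default.

## The two-stage analysis model

All inference is two-stage: regressions are fit **within** each
participant, and the resulting coefficients are tested **across**
participants (one-sample t-tests with Cohen's d = t/√n, or Pearson
correlations). No partial pooling is attempted; the per-participant
regressions are deliberately simple and the group stage treats their
coefficients as data. The pipeline therefore inherits the usual properties
of two-stage summary-statistics approaches: unbiased group means when the
per-participant estimators are unbiased, and group-level SDs that mix true
heterogeneity with estimation noise (which matters for interpreting d, see
*Parameter recovery* below).

Within participant, with z the within-participant z-score of the 0–10
value ratings over the snacks used in the task and q = standardize(z²):

- **Memory bias**: logistic regression of `chose remembered` on the
  remembered option's z, restricted to answered trials in which exactly
  one option was recalled correctly in that block's cued recall. The
  intercept is the bias; an unbiased chooser facing an average remembered
  option (z = 0) and a forgotten option should be indifferent.
- **Corrected bias**: same regression with regressor `z − mean(z of all
  forgotten snack-block instances)`. Because this is an affine shift of a
  single regressor, the corrected intercept equals
  `b0 + b1·mean_forgotten_z` exactly; the package computes it that way in
  the batch driver and verifies the refit/identity agreement to 1e-8 in
  its test suite.
- **Estimation and performance regressions**: the 0–6 memory estimate is
  regressed on z (and optionally q and the actual recall count k) by
  least squares — the estimate is treated as continuous, not ordinal —
  and recall correctness (one row per snack-block) on z and q by
  logistic regression.
- **Model comparisons**: linear-only and quadratic-only fits are compared
  against linear-and-quadratic by summing per-participant deviance gaps
  and referring the sum to chi-square. For the Gaussian models the
  deviance is −2 log-likelihood at the ML variance (RSS/n), so the same
  machinery covers both outcome families. One parameter is freed per
  participant, hence df = number of participants by default; a
  `df_convention = "n_minus_1"` compatibility mode reproduces the
  convention in which the subscript is one less (the chi-square value is
  identical either way, so the choice only moves the reference
  distribution by one df).
- **Path analysis**: performance ~ z + q and estimation ~ performance +
  z + q, all variables standardized within participant. The system is
  recursive and just-identified, so per-equation OLS *is* the ML
  solution — no SEM iteration is needed, and the total-effect
  decomposition (the z coefficient of the reduced regression equals
  c1 + b3·a1) holds to machine precision, which the tests assert at
  1e-10. With the strength mediator included, strength enters as a
  parallel mediator (strength ~ z + q; estimation gains a strength
  term). A mediator chain performance → strength would be equally
  consistent with the data layout; the parallel structure is the simplest
  choice and is configurable by refitting with the exported pieces.

Hypothesis-driven tests (bias > 0, estimation slope > 0, their
correlation > 0) report one-sided p-values; everything else is two-sided.
Normality of the coefficient distributions is checked with a one-sample KS
test of the standardized coefficients against the standard normal. Since
mean and SD are estimated from the same values, this plain KS test is
conservative; a Lilliefors-corrected variant is available behind a flag.

## The logistic fitter

Per-participant logistic regressions are fit by an explicit IRLS/Newton
loop with step-halving. Convergence is declared when the maximum absolute
score falls below 1e-8 or the relative deviance change below 1e-10;
non-convergence after 100 iterations is an error. Separation — fitted
probabilities within 1e-6 of 0/1 together with coefficients beyond ±10 —
is flagged rather than silently returned, and flagged participants enter
the group stage as missing with a logged reason. The test suite holds the
fitter to a brute-force Nelder-Mead maximization of the same likelihood on
100 random problems (max coefficient difference < 1e-5).

The explicit loop exists because the pipeline needs deterministic,
uniform convergence and separation semantics across tens of thousands of
small fits in the simulation studies; standard GLM fits serve as an
independent cross-check in tests.

## The power analysis

`correlation_sample_size()` solves the Fisher-z power equation for the
Pearson correlation test: the critical r implied by the t threshold at
df = n−2, against the alternative's Fisher z with the small-sample bias
correction r/(2(n−1)); the continuous solution is rounded up. At
r = 0.3, α = 0.05, power = 0.80, one-sided, this yields n = 67.

## The generative simulator

`simulate_cohort()` draws, per participant: 48 uniform(0, 10) snack
ratings; a constrained block design; behavioral parameters from the
population model; and then the full task record:

- **Design**: the 6 top-rated snacks are excluded (memory for favorites
  is atypically good), 24 of the remaining 42 snacks are drawn stratified
  over value tertiles (8 each), and a randomized greedy pass with
  restarts assigns each snack to exactly 6 of the 24 blocks with no
  snack in adjacent blocks (relaxed to a minimized repeat count with a
  warning if no repeat-free assignment is found — at the default
  geometry, restarts virtually always succeed). The task arithmetic
  forces exactly 24 used snacks (24 blocks × 6 slots / 6
  occurrences); stratified selection is our choice for
  guaranteeing a mix of high-, middle- and low-rated snacks in every
  block; beyond that mix, which 24 snacks enter is left random. Screen
  locations are re-randomized per block with a fix-up pass guaranteeing
  every snack at least two distinct locations; the resulting mean
  distinct-location count is ≈ 3.99, the value expected from 6
  independent draws of 6 locations. The 9 decision pairs per block are a
  uniformly random balanced 3-regular pairing (sampled exactly as the
  complement of a uniform 2-regular graph on 6 vertices); balance
  equalizes per-snack decision exposure, which keeps the one-remembered
  trial counts comparable across snacks.
- **Recall**: correctness of a snack with terms (z, q) is Bernoulli with
  log-odds `alpha_mem + beta1_mem·z + beta2_mem·q`. Strength ratings are
  `lambda_corr·correct + lambda1·z + noise`, recentred and clipped to
  [0, 1].
- **Decisions**: both-remembered pairs follow log-odds
  `b_val·(z_a − z_b)`; one-remembered pairs choose the remembered option
  with log-odds `b0_choice + b1_choice·z_rem` (so `b0_choice` is the
  generative memory bias); both-forgotten pairs are a fair coin; each
  trial is missed with probability `p_miss` (the task has a 5 s
  deadline).
- **Estimation**: the estimate of a snack recalled k times is
  `gamma0_est + gamma_perf·k + gamma1_est·z + gamma2_est·q` plus Gaussian
  noise, rounded and clipped to 0–6 — driven jointly by actual recall
  and by value, which is precisely the structure the analyses probe.

Parameters vary across participants as independent normals, except
(`b0_choice`, `gamma1_est`), which are bivariate normal with correlation
`rho_bias_belief` — the population-level link between bias and belief
that the H3 correlation estimates.

### Default population values

Defaults were picked once, as a plausible regime for this task, and are
not fitted to any data set: recall near 50% (`alpha_mem` ≈ 0, where
binary recall is most informative), a clear memory bias
(`b0_choice` 0.5 ± 0.6, giving group d around 0.6–0.8), value effects on
actual performance (`beta1_mem` 0.2, `beta2_mem` 0.15) weaker than the
value dependence of estimation, `gamma_perf` 0.5 so that estimation
tracks actual recall strongly, `rho_bias_belief` 0.4, and a small miss
rate (0.02). Simulated cohorts at these defaults land near the intended
regime (bias d ≈ 0.6–0.8; performance-effect d ≈ 0.4–0.5; mean forgotten
z ≈ −0.1).

### What the simulator does and does not emulate

It reproduces the statistical structure the analyses assume: the trial
counts and design constraints, value-dependent recall with linear and
quadratic components, choice shifted toward remembered options, and
estimation driven by both recall count and value. It does **not** model
reaction times, learning across blocks, intrusion errors, the retention
tasks (their effect is absorbed into `alpha_mem`), or any systematic
deviation from the assumed regression forms. Passing simulation-based
tests therefore establishes that the pipeline is correct and calibrated
*under its own assumptions* — not that those assumptions hold in any real
data set.

Two consequences are worth stating explicitly. First, the observed H3
correlation is attenuated relative to `rho_bias_belief`, because both
coefficients carry estimation noise and the marginal estimation slope
additionally absorbs the recall-mediated value effect
(`gamma_perf × dE[k]/dz`), which is unrelated to the belief parameter;
the recovery report measures this attenuation empirically rather than
assuming it away. Second, the default generator couples the bias to the
*belief* parameter only — it does not build in a coupling between the
bias and `beta1_mem` — so the correlation pattern of path coefficients
with the bias in simulated data need not match the pattern in real data;
populations with such couplings can be constructed by modifying
`population_params()`.

## Calibration and recovery studies

- `type_i_error()` simulates null cohorts and reports one-sided rejection
  rates. A test's rate is only expected to equal alpha when the
  *corresponding* effect is null: with `b0_choice` centered at 0 the H1
  rate calibrates at ≈ 0.05, while H2 would still reject often if
  `beta1_mem > 0`, since the marginal estimation slope inherits the
  recall-mediated effect — a true effect, not a false positive.
- `parameter_recovery()` compares cohort-mean estimates against the
  generative truth. `gamma1_est` is recovered from the
  performance-controlled regression (its actual estimand); the marginal
  H2 slope estimates `gamma1_est` plus the mediated component.
- The summed-LRT null calibration generates per-participant recall tables
  under `beta2_mem = 0` and checks the summed statistic against its
  chi-square reference by KS. The logistic (performance) model is used
  for this check because at 144 Bernoulli observations per participant
  the LRT is close to its asymptotic law, whereas the Gaussian estimation
  model at 24 observations per participant has a known finite-sample
  inflation (E[n·log(RSS_r/RSS_f)] ≈ 1.15 per participant) that is a
  property of small-n Gaussian LRTs generally, not of this
  implementation.

Problem sizes in the shipped tests — 500 cohorts of 30 for type-I error,
100 cohorts of 90 for recovery, 500 cohorts of 20 for the LRT null —
were chosen so that Monte-Carlo error is small against the asserted
bands (e.g. binomial SE ≈ 0.01 against a ±0.02 band at 500 cohorts).

## Numerical choices and degenerate inputs

- Sample SD (n−1) everywhere, including standardization.
- Standardization uses the snacks used in the task (all regressors are
  task-level); participants with zero rating variance are degenerate and
  surface as exclusions/missing rows, never silent drops.
- Per-participant bias fits require a configurable minimum (default 10)
  of answered one-remembered trials.
- Missed decisions are stored explicitly (`choice = "missed"`) and
  filtered at analysis time; they never count as choices.
- Estimates are validated to the integer range 0–6; strength ratings to
  [0, 1] (the continuous strength scale has no canonical units, so [0, 1]
  is a normalization choice).
- Value tertiles break ties by stable snack order, so designs are
  reproducible under a seed.

## Known limitations

- No mixed-effects alternative to the two-stage procedure, no ordinal
  treatment of the 0–6 estimate, no bootstrap CIs for indirect effects.
- Pre-registered exclusion criteria are study-specific;
  `exclusion_criteria()` exposes the thresholds but defaults to excluding
  nobody, so restricted-sample analyses require the criteria as
  configuration.
- Ingesting an existing data deposit requires a converter written
  against that deposit's own file layout, which is outside the core
  package.
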