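---
title: "Models and methods in skillcurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in skillcurve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

skillcurve analyses single-session motor sequence learning experiments in
which participants repeatedly execute a short, fixed, looped key sequence
— for example a four-key pattern played on a piano keyboard and, as a
music-independent control, on a response pad — over 20 trials of 20 s,
while a cognito-motor test battery measures working memory (WM),
processing speed (PS), psychomotor speed (PM) and dexterity (DX). This
vignette documents each model in the pipeline, its assumptions, the
tunable parameters with defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## 1. Key-press scoring

The dependent performance variable is the number of correct key presses
per trial. A press stream is scored by a pointer automaton that walks the
looped four-element sequence:

* a press equal to the expected key counts as **correct** and advances the
  pointer (wrapping after the fourth element);
* a press of a key outside the sequence is a **wrong key** error and
  leaves the pointer unchanged;
* a press of an in-sequence key out of turn is a **wrong order** error,
  after which the pointer resynchronizes to the position *after* the
  pressed key.

The resynchronization rule is a design choice: treating the slip as a
skip prevents one error from cascading into a long run of mismatches. No
published rule fixes this behaviour, so the scorer is validated against
an independently written brute-force simulation of the same rules (1000
random logs in the test suite) rather than against an external reference.
Presses with identical timestamps keep file order, so scoring is
deterministic. The error rate is errors divided by total presses; for an
empty trial it is *undefined* (propagated as `NA`), not zero, to avoid
biasing trial-level averages.

## 2. Measurement model (CFA)

Latent abilities are extracted by confirmatory factor analysis with
maximum likelihood: the implied covariance is
$\Sigma(\theta) = \Lambda \Phi \Lambda^\top + \Theta$ with standardized
factors (unit-diagonal correlation matrix $\Phi$), and the discrepancy
$F = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$ is minimized
with `nlminb`. The retained battery structure is: WM from the three digit
spans and the reversed Corsi block span; PS from coding, symbol search,
the number connection test and trail-making A; PM from the three clicking
conditions; DX from the four Purdue Pegboard conditions; the sequential
digit span cross-loads on WM and PS.

Numerical choices:

* **Orientation and scaling.** Timed scores (ZVT, TMT_A) are negated —
  not reciprocated — before z-standardization, preserving the linearity
  the factor model assumes. Standardization uses the sample (n−1) SD, the
  covariance-based SEM convention.
* **Missing data.** The reversed Corsi span is missing for a fraction of
  participants (the test could not be administered to everyone). The
  sample covariance is computed from pairwise-available cases and enters
  the normal-theory discrepancy; with a single dominant missingness
  pattern this matches the spirit of full-information ML without
  requiring a saturated-model EM step. Factor scores use the
  regression method $\hat F = \Phi\Lambda^\top\Sigma^{-1}x$ restricted to
  each participant's observed indicators; a factor with no observed
  indicator for a participant is scored missing.
* **Residual variances** are optimized on the log scale (stable when they
  approach zero) and floored at 1e-4; solutions at the floor are flagged
  as Heywood cases.
* **Factor correlations** are box-bounded in (−0.995, 0.995) with a
  positive-definiteness penalty; all six correlations are estimated
  freely by default. Fixing the WM–PM and WM–DX correlations to zero is
  available (`battery_model(constrain_wm = TRUE)`) but not the default:
  a non-significant estimate is not a constraint.
* **Convergence** is declared when `nlminb` reports success or the free
  gradient norm falls below 1e-4 after a polishing restart; otherwise the
  best iterate is returned with a warning.

Fit indices use the conventional formulas (CFI, TLI, IFI clipped to
[0, 1]; RMSEA from the noncentrality estimate; SRMR as the RMS
standardized residual), with $\chi^2 = (n-1)F$ and the independence model
as baseline; the test suite checks them against an independently coded
closed-form oracle to 1e-8.

## 3. Hierarchical exponential learning curves

Performance $y_{it}$ follows a Gaussian likelihood around
$$\eta_{it} = \beta_i + (\alpha_i - \beta_i)\,e^{-e^{\gamma_i}(t-1)},$$
so $\alpha_i$ is exactly the trial-1 mean (baseline), $\beta_i$ the
asymptote, and $\gamma_i$ an unconstrained log learning rate (more
negative = slower learning; $\beta_i < \alpha_i$ is admissible and
signals non-learning). The Gaussian likelihood is appropriate because
correct-press counts are large (roughly 10–60 per 20 s trial).

All three parameters vary across participants and correlate. Sampling is
MCMC via JAGS, and the correlated triple uses a **triangular
(Cholesky-regression) parameterization**: $\alpha_i$ is drawn marginally,
$\beta_i$ conditions on $\alpha_i$, and $\gamma_i$ on both. This spans
exactly the set of trivariate normal population distributions while
keeping every node scalar and conjugate-friendly for Gibbs/slice
sampling; the population SDs and the 3×3 correlation matrix are derived
per draw from the conditional scales and slopes. (In an HMC sampler one
would instead non-center the random effects under an LKJ prior; the
triangular scheme is the Gibbs-idiomatic equivalent, and JAGS has no LKJ
distribution.)

Priors are weakly informative and scale-adapted: the baseline and
asymptote means are centred on the empirical trial-1 and last-trial means
with twice their SD; $\mu_\gamma \sim N(0, 1.5^2)$; SDs are half-normal
with the same scales; the triangular slopes are normal with scales
matched to the expected SD ratios; the residual SD is half-normal scaled
to the data SD. The headline MCMC profile is 4 chains × 5000 iterations
with 2000 warm-up; `reduced_config()` (2 × 1500, 500 warm-up) is the
desk-scale profile used in tests, simulation studies and the acceptance
script. Convergence is monitored by split-Rhat with a 1.01 warning
threshold; JAGS is not a Hamiltonian sampler, so divergent-transition
counts do not apply and are reported as zero with sampler metadata.

Polynomial alternatives (linear, quadratic, cubic) share the
random-effects structure — each participant has a correlated coefficient
vector (multivariate normal with a Wishart prior on the precision) on a
standardized trial index — and are compared by PSIS-LOO elpd. The
Pareto-smoothed importance sampling estimator (including the
Zhang–Stephens generalized-Pareto tail fit with the usual
weakly-informative shrinkage of the shape) is implemented in the package
and cross-checked in the tests against exact leave-one-out on a conjugate
normal model; comparisons are flagged unreliable when more than 10% of
observations have tail shape k > 0.7. The exponential family is the
headline model on parsimony and interpretability grounds even where a
cubic can edge it in elpd.

## 4. Trial-wise performance–ability associations

Fitted (posterior-mean) performance $\eta_{it}$ — not the raw counts —
is standardized within each task × trial (1 unit = 1 between-participant
SD), making coefficients comparable across the learning phase; raw-count
standardization is available via the `value` argument for sensitivity
analysis. Each predictor (a latent factor score, musical sophistication,
or cumulative practice hours) is tested in its own model:

$$z_{it} = \delta_t + b_t x_i + c_t g_i + u_i + \varepsilon_{it},$$

with trials as factors (one $b_t$ per trial with a 95% credible
interval), the individual posterior-mean log learning rate $g_i$ as a
control with its own trial-indexed coefficient $c_t$ (a single global
coefficient is config-gated), and a participant random intercept $u_i$ —
without it, repeated measures across 20 trials make the intervals
anti-conservative. Predictors are standardized so $b_t$ is in SD-per-SD
units. Factor-score uncertainty is ignored (two-stage estimation); this
is a known limitation shared with the two-stage design the pipeline
mirrors. Scale parameters carry a 0.01 lower truncation so the precision
cannot degenerate.

`association_profile()` summarizes a trajectory by its trial-1 value, its
minimum (value and trial), the plateau (mean of the last three trials)
and a dip–rebound flag (minimum after trial 1 that is later exceeded);
ties in the minimum resolve to the earliest trial, so a constant profile
is classified as no dip.

## 5. Gaze change points

Gaze changes between display and keys are counted per trial; their
decline is modelled piecewise: a linear decline on the count scale that
reaches zero at an individual change point $\tau_i$ and stays zero
afterwards, with zero-truncated Gaussian noise. The hinge is the minimal
piecewise-nonlinear shape with an interpretable change point; an
exponential-decline variant was considered and rejected because its
"reaching zero" trial is not a model parameter. $\tau_i$ is continuous
via a logit-scaled hierarchical prior on $[\tau_{\min}, T]$ with
$\tau_{\min} = 1.1$ — the guard keeps the hinge denominator $\tau_i - 1$
away from zero. The noise SD is truncated below at 0.05 counts: counts
are integers, so a smaller SD is below the rounding resolution, and
without the bound all-zero data (a participant who never looks down)
would send the likelihood into a spike at zero variance. All-zero
participants are therefore handled gracefully: their $\tau_i$ posterior
concentrates at the lower bound and they are flagged, not dropped.
Participants without usable gaze video are excluded from this module
only, never from the performance analyses.

## 6. The synthetic-study generator

`synth_config()` encodes the study conditions the pipeline expects: 86
participants, two tasks, 20 trials; battery scores from the four-factor
measurement model (default loadings 0.7, the sequential digit span
cross-loading 0.5/0.4, factor correlations with WM–PS at 0.44 and the
three motor-factor correlations at 0.55–0.60); exponential performance
with population log learning rates −1.98 (piano) and −1.10 (response
pad), baselines/asymptotes of 21/47 and 28/58 correct presses, and
individual parameters correlated within task (0.25–0.5) and across tasks
(0.44/0.69/0.37 for baseline/asymptote/rate); error rates declining from
15.0% to 6.7% (piano) and 10.5% to 2.4% (pad) with logit-scale
overdispersion, split 40/60 into wrong-key and wrong-order presses;
gaze change points averaging 7.06 and 4.92 trials; missing reversed
Corsi spans for 22/86 and missing gaze for 12/86 participants; and
musicality covariates (Gold-MSI 56.8 ± 17.1, practice hours for 37/86)
generated independent of everything else, encoding the null. The curve
means, change points, error rates, sample sizes and missingness
fractions encode the documented study conditions; scales that no source
states (baseline/asymptote levels, SDs, battery raw-score scales,
overdispersion, the wrong-key share) were chosen once at values a
practitioner would call realistic for older adults and are documented in
`synth_config()`.

The ability→curve coupling places effects mainly on the asymptote and
learning rate, with a modest direct baseline effect, sized so that the
implied trial-wise association profile is dip-then-rise: relatively
strong at trial 1, weakest in the early trials, then rising to a plateau
(working memory weakest throughout, the motor factors around 0.3–0.4).
With the study's slow learning rates the rate-heterogeneity dilution
that causes the dip peaks around trials 3–6; `association_dip_config()`
provides a faster-learning scenario (log rate −0.3, rate SD 1.0) whose
dilution peaks exactly at trial 2, used to validate shape recovery.
`true_association_profile()` computes the large-sample truth any
estimator of the trial-wise coefficients is chasing.

Counts are produced by rounding a Gaussian latent floored at zero,
consistent with the Gaussian likelihood of the curve module. The
key-press log generator is the exact inverse of the scorer (a
round-trip property tested on hundreds of random targets). What the
generator does **not** emulate: within-trial timing dynamics, fatigue or
consolidation across the session, non-Gaussian performance noise,
floor/ceiling artifacts in battery tests, and any dependence of
musicality on ability. Passing recovery tests therefore demonstrates
that the estimators recover the truth under the assumed data-generating
mechanisms at the study size — not that real data satisfy those
mechanisms.

## 7. Reproducibility and problem sizes

All randomness flows from explicit integer seeds: generators take a root
seed and derive fixed per-stage sub-seeds; every MCMC chain gets a
deterministic RNG seed, so fits are bit-reproducible under a fixed
configuration. The test suite and the acceptance script run at the
desk-scale profile: the coverage study uses 20 replications of the full
86 × 20 design, the null calibration 50 replications, and the CFA
recovery n = 500; these sizes give the property checks adequate power
while keeping a full run in minutes on one CPU. The headline 4 × 5000
profile is available throughout via `mcmc_config()` and the pipeline's
`--full` flag.

## 8. Known limitations

* The exponential-curve scale of $\gamma$ depends on the declared
  parameterization ($t-1$ in the exponent, rate $e^\gamma$); estimates
  from verbally-specified models elsewhere are comparable only up to
  that declaration.
* Factor scores are treated as observed in the association stage;
  coefficient intervals do not carry measurement-model uncertainty.
* The pairwise-covariance treatment of missing battery cells is an
  approximation to casewise full-information ML; with a single
  missingness pattern the difference is negligible, with richer patterns
  a dedicated FIML/EM step would be preferable.
* The gaze hinge assumes visual control declines linearly on the count
  scale; the change-point estimate is robust to mild curvature but the
  decline-segment parameters are not interpretable under strong
  curvature.
* JAGS's Gibbs/slice sampling has no divergence diagnostic; convergence
  assessment rests on split-Rhat and effective mixing, which the reduced
  profile occasionally flags (warnings, not errors) for variance
  components.
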