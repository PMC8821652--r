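---
title: "Predicting long-term treatment effects from short-term risk marker changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long-term treatment effects from short-term risk marker changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cardiovascular and kidney outcome trials take years and thousands of
patients.  Many drugs, however, move a panel of established risk markers —
glycaemia, blood pressure, albuminuria, haemoglobin, body weight, lipids,
uric acid, potassium — within months.  The parameter response efficacy
(PRE) approach asks: if we know, from an independent cohort, how each
marker relates to long-term hazard, what relative risk reduction (RRR)
should the observed short-term multi-marker changes translate into?

`prescore` implements that pipeline end to end:

1. fit a multivariable Cox proportional hazards model on a *background*
   cohort, giving coefficients $\beta_l$ per transformed marker;
2. push each trial patient's marker vector at baseline and at month 6
   through the fitted risk function to get absolute risks at a horizon $T$;
3. contrast the treated arm's risk change with the placebo arm's to obtain
   a predicted RRR, with a parametric coefficient-resampling confidence
   interval;
4. compare against the RRR observed from the trial's own outcomes, score
   subgroups and single markers, and simulate responder enrichment.

Because the patient-level data of the motivating trials are not public,
the package ships a first-class synthetic-cohort generator whose defaults
are calibrated to published population summaries, and every claim the
package makes is tested against that generator's known truth.

## The risk model

For a subject with transformed marker vector $x$ (UACR enters as
$\log \mathrm{UACR}$, all other markers on their natural scale), the hazard
is

$$h(t \mid x) = h_0(t)\, e^{\beta^\top (x - \bar{x})},$$

with $\bar{x}$ the covariate means of the fitting cohort.  `fit_cox()`
estimates $\beta$ by maximum partial likelihood (Efron tie handling by
default, Breslow selectable) and `baseline_survival()` computes the
Breslow baseline cumulative hazard at the centring covariates, so that
the absolute risk at horizon $T$ is

$$r(x) = 1 - S_0(T)^{\exp(\beta^\top (x - \bar{x}))}.$$

Mean-centring is stored inside the model object, making predictions
invariant to the centring choice; predictions beyond the observed
follow-up are refused rather than extrapolated.  The horizon $T$ defaults
to the median follow-up of the background cohort — the source publications
do not state the horizon they used, so it is exposed as a configuration
knob rather than asserted.

## The PRE score

Let $r_a(\mathrm{tp})$ be the mean predicted risk of arm $a$ at timepoint
$\mathrm{tp}$.  Two translations of "the mean difference in predicted risk
in the treated arm, adjusted for the mean difference in the placebo arm"
into an RRR are implemented, because the verbal definition admits both:

* **ratio of ratios** (default):
  $\mathrm{RRR} = 100\left(1 - \dfrac{r_T(m6)/r_T(\mathrm{base})}{r_P(m6)/r_P(\mathrm{base})}\right)$
* **adjusted difference**:
  $\mathrm{RRR} = 100\left(-\dfrac{(r_T(m6)-r_T(\mathrm{base})) - (r_P(m6)-r_P(\mathrm{base}))}{r_T(\mathrm{base})}\right)$

The two agree to first order in the effect size when risks are small; the
divergence is second order and is exercised in the test suite.  The ratio
form is the default because it is invariant to the baseline risk level of
each arm and therefore more robust to chance baseline imbalance.

Single-marker attributions (`single_marker_rrr()`) hold all other markers
at baseline and reuse the full multivariable coefficients.  Refitting
univariable models per marker would confound attribution with
between-marker correlation; keeping one coefficient vector makes the
attributions commensurable, and in the rare-event limit the single-marker
log relative risks add up to the full-model log relative risk.

### Confidence intervals

`ci_resample()` draws `n_draws = 100` coefficient vectors, each component
independently from $N(\hat\beta_l, \mathrm{SE}_l^2)$, recomputes the RRR
per draw and reports percentile bounds (2.5/97.5 at the default 95%
level).  Three deliberate properties, all configurable or documented:

* the between-coefficient covariance is ignored — the draws are
  independent per coefficient by construction;
* the baseline survival function is held fixed across draws;
* the interval reflects *coefficient* uncertainty only.  It does not
  propagate the trial-level sampling error of the observed marker changes,
  so it should not be read as a repeated-sampling interval for the trial:
  under a null treatment effect the interval straddles zero exactly when
  the coefficient draws straddle zero.  The test suite checks the
  nominal-coverage property in the regime where it genuinely holds (a
  marker whose fitted coefficient is consistent with zero).

100 draws give a CI whose endpoints jitter by a few tenths of a
percentage point between seeds; `n_draws` can be raised for stability
studies.

## The synthetic cohorts

`generate_trial()` draws nine-marker baselines through a Gaussian copula:
marginals are normal, except UACR which is log-normal with log-scale
location $\ln 17.7$ and scale $(\ln 74.3 - \ln 17.7)/z_{0.75} = 2.127$,
calibrated to the published median and upper quartile.  That calibration
analytically implies $P(\mathrm{UACR} \ge 30) = 1 - \Phi((\ln 30 - \ln
17.7)/2.127) \approx 0.402$, matching the published 40% elevated-
albuminuria fraction — a consistency check the acceptance suite performs
empirically.  No between-marker correlations are published; the default is
an exchangeable $\rho = 0.2$ block among the metabolic markers, identity
elsewhere, exposed via `default_correlation()`.

Month-6 values are baseline + placebo drift + treated-arm effect +
within-subject noise, additively on the log scale for UACR (so the
configured percent effect is multiplicative on the natural scale).  The
default effect profile is the published placebo-corrected profile (HbA1c
−0.6%, SBP −4.2 mmHg, UACR −13%, haemoglobin +6.6 g/L, weight −2.1 kg,
HDL +0.04 and LDL +0.1 mmol/L, uric acid −20.4 µmol/L, potassium
unchanged).  Within-subject six-month change SDs are not published;
the defaults (HbA1c 1.0%, SBP 14 mmHg, log-UACR 1.0, haemoglobin 10 g/L,
weight 3.5 kg, HDL 0.15 and LDL 0.6 mmol/L, uric acid 60 µmol/L,
potassium 0.4 mmol/L) are fixed once at magnitudes typical of change
distributions in diabetes outcome trials.

Event times are exponential with hazard $\lambda_0 e^{\beta^{*\top}(x -
\bar{x})}$ computed from the **month-6** marker values in both arms, so
the simulated treatment effect is wholly marker-mediated — the regime in
which the PRE score should be unbiased.  A `direct_log_hr` option adds a
treated-arm hazard term that bypasses the markers; the test suite uses it
to reproduce the qualitative finding that motivates the method's
validation: when part of the benefit is not marker-mediated, the
prediction systematically underestimates the observed effect.  The true
coefficient vectors $\beta^*$ of the default cardiovascular and kidney
generators are package inventions with clinically plausible gradients
(the strongest kidney predictor being log-UACR, the strongest CV
predictors HbA1c and haemoglobin); $\lambda_0$ is calibrated by
`calibrate_lambda0()` so that a background cohort of 6355 reproduces
event fractions of 12.5% (CV) and 17.8% (kidney) over the default 3.1
years of follow-up.  `true_rrr()` evaluates the generator's true RRR in
closed form under paired Monte Carlo and serves as the oracle for
parameter-recovery tests.

What the generator does **not** emulate: visit schedules and dropout,
competing risks, non-proportional hazards, measurement error distinct
from biological variability, and treatment effects that alter marker
*variability* rather than location.  Passing tests therefore demonstrate
internal validity of the scoring machinery, not that the published
coefficient estimates or effect sizes are correct.

## Missing data

`inject_missingness()` produces MCAR or MAR blanks (MAR via a logistic
link on a chosen covariate with the intercept solved to hit the marginal
rate).  `impute_pmm()` is multiple imputation by chained equations with
predictive mean matching: visit order is ascending missingness,
initialisation is random draws from observed marginals, each target is
regressed on all other columns of the chained system, and the imputed
value is the observed value of a donor sampled from the `k = 5` nearest
predicted means.  UACR is imputed on the log scale, consistent with its
model entry.  Defaults `m = 5`, `k = 5`, `n_iter = 10` are standard
practice; none are stated by the source publications.  The pipeline
imputes before scoring and pools by averaging the per-dataset RRR point
estimates and CI bounds; `pool_estimates()` additionally provides Rubin's
rules for estimate/variance pairs.

## Enrichment simulations

A *responder* is a treated patient whose marker improvement (oriented by
the marker's harm direction, log scale for UACR) is at least the
treated-arm median improvement; the rule is inclusive, so ties at the
median respond.  `shift_responders()` re-draws treated-arm changes from
the empirical responder stratum with probability $p$ (stratified
bootstrap — a parametric location shift was considered and rejected
because it extrapolates beyond the observed response distribution), and
`enrichment_curve()` maps $p \mapsto \mathrm{RRR}$ over a grid.
`required_effect()` inverts the effect-to-RRR map by bisection to 0.1
percentage point, answering "how large a mean reduction is needed for a
target RRR".

## Numerical choices

* Cox convergence: `coxph` with `eps = 1e-11`, up to 100 iterations;
  collinear covariates and suspected monotone likelihood raise errors
  rather than warnings.
* All randomness derives from one global seed through per-operation
  sub-streams (`derive_seed()`), so re-running any stage — including
  imputation — is byte-identical, and changing one stage's draws never
  perturbs another's.
* Model serialisation uses 17 significant digits, which round-trips
  doubles exactly.
* Risk-model evaluation refuses horizons beyond the observed follow-up;
  non-positive UACR values are an error at transform time, identifying
  the offending records.

## Problem sizes

The test and acceptance suites run the headline parameter-recovery study
at the full published scale (background 6355, trial 7020) and the
supporting property checks at 200–7020 subjects with Monte-Carlo oracles
of $2\times10^5$ draws — sizes at which the Monte-Carlo error of each
assertion is well below the tolerance it asserts.

## Known limitations

* The score inherits every limitation of the background Cox model:
  proportional hazards, log-linear marker effects, and a marker panel
  assumed to carry the treatment's whole mechanism.  The direct-effect
  simulations quantify what happens when the last assumption fails.
* The resampling CI understates total uncertainty (see above).
* The generator's correlation structure and change SDs are package
  defaults, not estimates; conclusions that depend on them (e.g. exact CI
  widths) should be read accordingly.
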