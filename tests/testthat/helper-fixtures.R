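# Shared fixtures, built once per test run.  Sizes are kept moderate: large
# enough for the statistical assertions, small enough that the whole suite
# runs in a few minutes.

# Two-marker toy system with known coefficients: one normal marker ("a") and
# one log-normal ("uacr"), used wherever a hand-checkable Cox system is
# needed.
toy_specs <- function() {
  list(
    a = marker_spec("a", "unit", "normal", 0, 1, +1),
    uacr = marker_spec("uacr", "mg/g", "lognormal", log(20), 1, +1)
  )
}

toy_beta <- c(a = 0.3, log_uacr = -0.2)

toy_outcome <- function(lambda0 = 0.08, followup = 4, direct = 0) {
  outcome_config("toy", toy_beta, lambda0 = lambda0,
                 followup_years = followup, direct_log_hr = direct)
}

toy_background <- function(n = 6355, seed = 101) {
  cfg <- cohort_config(n, c(0, 1), toy_specs(), diag(2), seed = seed)
  generate_background(cfg, toy_outcome())
}

# Default-panel fixtures (memoised: generating and fitting once is enough).
.fx <- new.env()

fx_background <- function() {
  if (is.null(.fx$bg)) {
    cfg <- cohort_config(6355, c(0, 1), background_marker_specs(), seed = 2024)
    .fx$bg <- generate_background(cfg, default_cv_outcome())
  }
  .fx$bg
}

fx_cv_fit <- function() {
  if (is.null(.fx$fit)) .fx$fit <- fit_cox(fx_background(), "cv")
  .fx$fit
}

fx_cv_model <- function() {
  if (is.null(.fx$model)) {
    .fx$model <- risk_model(fx_cv_fit(), empareg_marker_specs())
  }
  .fx$model
}

fx_trial <- function() {
  if (is.null(.fx$trial)) {
    cfg <- cohort_config(7020, c(2, 1), seed = 2025)
    .fx$trial <- generate_trial(cfg, empagliflozin_effect_profile(),
                                default_cv_outcome())
  }
  .fx$trial
}

# A minimal hand-built risk model: one covariate "a" with coefficient b,
# centring 0, and a two-knot baseline survival, for closed-form checks.
manual_model <- function(b = 0.3, s0T = 0.99, horizon = 1) {
  structure(
    list(coef = c(a = b), se = c(a = 0.05),
         vcov = matrix(0.0025, 1, 1, dimnames = list("a", "a")),
         center = c(a = 0), ties = "efron", endpoint = "toy",
         s0_time = c(0.5, horizon), s0_surv = c(sqrt(s0T), s0T),
         tmax = horizon, horizon = horizon,
         specs = list(a = marker_spec("a", "u", "normal", 0, 1, +1))),
    class = "risk_model")
}

# Tiny two-arm table builder on the manual model's single marker.
tiny_trial <- function(base_t, m6_t, base_p = base_t, m6_p = base_p) {
  tibble::tibble(
    id = seq_len(length(base_t) + length(base_p)),
    arm = rep(c("treated", "placebo"), c(length(base_t), length(base_p))),
    a_base = c(base_t, base_p), a_m6 = c(m6_t, m6_p))
}
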