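#' Configure PRE scoring
#'
#' @param horizon Risk horizon in years; `NULL` uses the risk model's.
#' @param n_draws Coefficient resampling draws for the CI (default 100).
#' @param level CI level in (0, 1) (default 0.95).
#' @param rrr_form `"ratio_of_ratios"` (default) or `"adjusted_difference"`;
#'   see [compute_pre_rrr()].
#' @param seed Integer seed for the resampling stream.
#' @return An object of class `score_config`.
#' @export
score_config <- function(horizon = NULL, n_draws = 100L, level = 0.95,
                         rrr_form = c("ratio_of_ratios", "adjusted_difference"),
                         seed = 1L) {
  if (n_draws < 2) stop("score_config: n_draws must be >= 2")
  if (level <= 0 || level >= 1) stop("score_config: level must be in (0, 1)")
  structure(list(horizon = horizon, n_draws = as.integer(n_draws),
                 level = level, rrr_form = match.arg(rrr_form),
                 seed = as.integer(seed)),
            class = "score_config")
}

#' Mean predicted risk of one arm at one timepoint
#'
#' Pushes each patient's marker vector at the requested timepoint through
#' the risk model and averages the predicted absolute risks.
#'
#' @param model A [risk_model()].
#' @param trial Trial tibble with `arm` and `<marker>_base` /
#'   `<marker>_m6` columns.
#' @param arm `"treated"` or `"placebo"`.
#' @param timepoint `"base"` or `"m6"`.
#' @param horizon Risk horizon; defaults to the model's.
#' @param coef Optional coefficient override (resampling machinery).
#' @return Mean predicted risk (scalar in (0, 1)).
#' @export
mean_arm_risk <- function(model, trial, arm, timepoint = c("base", "m6"),
                          horizon = model$horizon, coef = model$coef) {
  timepoint <- match.arg(timepoint)
  sub <- trial[trial$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) stop("mean_arm_risk: arm '", arm, "' is empty")
  x <- marker_matrix(sub, model$specs, timepoint)
  if (anyNA(x)) stop("mean_arm_risk: missing markers at timepoint '",
                     timepoint, "'; impute first")
  mean(predict_risk(model, x, horizon = horizon, coef = coef))
}

# RRR (percent) from the four arm x timepoint mean risks.
rrr_from_means <- function(rT0, rT1, rP0, rP1, form) {
  if (rT0 <= 0 || rP0 <= 0) stop("zero baseline mean risk")
  switch(form,
    ratio_of_ratios = 100 * (1 - (rT1 / rT0) / (rP1 / rP0)),
    adjusted_difference = 100 * (-((rT1 - rT0) - (rP1 - rP0)) / rT0),
    stop("unknown rrr_form: ", form))
}

# Point RRR for a given coefficient vector (shared by the point estimate,
# the resampling CI and the single-marker attribution).
pre_point <- function(model, trial, config, coef = model$coef) {
  horizon <- config$horizon %||% model$horizon
  rrr_from_means(
    mean_arm_risk(model, trial, "treated", "base", horizon, coef),
    mean_arm_risk(model, trial, "treated", "m6",   horizon, coef),
    mean_arm_risk(model, trial, "placebo", "base", horizon, coef),
    mean_arm_risk(model, trial, "placebo", "m6",   horizon, coef),
    config$rrr_form)
}

#' Parametric coefficient-resampling confidence interval
#'
#' Draws `n_draws` coefficient vectors, each component independently from
#' `Normal(coef, se^2)` -- the between-coefficient covariance is deliberately
#' ignored -- recomputes the predicted RRR for every draw, and returns
#' percentile bounds.  The baseline survival function is held fixed across
#' draws.
#'
#' @inheritParams mean_arm_risk
#' @param config A [score_config()].
#' @return List with `lower`, `upper` (percent), and `draws` (the resampled
#'   RRRs).
#' @export
ci_resample <- function(model, trial, config = score_config()) {
  stopifnot(inherits(model, "risk_model"))
  if (config$n_draws < 2) stop("ci_resample: n_draws must be >= 2")
  draws <- with_subseed(config$seed, "ci_resample", {
    vapply(seq_len(config$n_draws), function(i) {
      b <- rnorm(length(model$coef), model$coef, model$se)
      names(b) <- names(model$coef)
      pre_point(model, trial, config, coef = b)
    }, numeric(1))
  })
  alpha <- (1 - config$level) / 2
  q <- unname(quantile(draws, c(alpha, 1 - alpha), type = 7))
  list(lower = q[1], upper = q[2], draws = draws)
}

#' Predicted relative risk reduction (the PRE score)
#'
#' Translates the trial's arm-level baseline to month-6 marker changes into
#' a predicted long-term relative risk reduction.  With `r_a(tp)` the mean
#' predicted risk of arm `a` at timepoint `tp`:
#'
#' * `ratio_of_ratios`: `RRR = 100 (1 - (r_T(m6)/r_T(base)) / (r_P(m6)/r_P(base)))`
#'   -- the treated arm's proportional risk change adjusted by the placebo
#'   arm's, robust to regression to the mean and secular drift.
#' * `adjusted_difference`: `RRR = 100 (-((r_T(m6)-r_T(base)) - (r_P(m6)-r_P(base))) / r_T(base))`
#'   -- the placebo-adjusted absolute risk change relative to baseline risk.
#'
#' The two agree to first order when risks are small.
#'
#' @inheritParams ci_resample
#' @param ci Compute the resampling CI (default `TRUE`).
#' @param single_markers Also compute per-marker attributions via
#'   [single_marker_rrr()] (point estimates only).
#' @return A `pre_result`: `rrr` (percent), `ci_lower`/`ci_upper`,
#'   `marker_rrr` (named vector or `NULL`), `form`, `horizon`, `n_draws`,
#'   `seed`, and per-arm sample sizes.
#' @export
compute_pre_rrr <- function(model, trial, config = score_config(),
                            ci = TRUE, single_markers = FALSE) {
  stopifnot(inherits(model, "risk_model"), inherits(config, "score_config"))
  if (!all(c("treated", "placebo") %in% trial$arm)) {
    stop("compute_pre_rrr: both arms must be non-empty")
  }
  point <- pre_point(model, trial, config)
  bounds <- if (ci) ci_resample(model, trial, config) else NULL
  marker_rrr <- NULL
  if (single_markers) {
    marker_rrr <- vapply(names(model$specs), function(nm) {
      single_marker_rrr(model, trial, nm, config, ci = FALSE)$rrr
    }, numeric(1))
  }
  structure(
    list(rrr = point,
         ci_lower = bounds$lower %||% NA_real_,
         ci_upper = bounds$upper %||% NA_real_,
         marker_rrr = marker_rrr, form = config$rrr_form,
         horizon = config$horizon %||% model$horizon,
         n_draws = if (ci) config$n_draws else 0L, level = config$level,
         seed = config$seed, endpoint = model$endpoint,
         n_treated = sum(trial$arm == "treated"),
         n_placebo = sum(trial$arm == "placebo")),
    class = "pre_result"
  )
}

#' @export
print.pre_result <- function(x, ...) {
  cat(sprintf("<pre_result> endpoint '%s' (%s, T=%.2f y)\n", x$endpoint,
              x$form, x$horizon))
  cat(sprintf("  predicted RRR %.1f%% (%.0f%% CI %.1f to %.1f), %d draws\n",
              x$rrr, 100 * x$level, x$ci_lower, x$ci_upper, x$n_draws))
  if (!is.null(x$marker_rrr)) {
    cat("  single-marker RRR (%):\n")
    print(round(x$marker_rrr, 2))
  }
  invisible(x)
}

#' Predicted RRR attributable to a single marker
#'
#' Rebuilds the month-6 marker matrix as the baseline matrix with only the
#' chosen marker updated to its observed month-6 value, then scores as
#' [compute_pre_rrr()].  The full multivariable coefficients are reused
#' (other markers held at baseline), so attributions are comparable within
#' one scoring framework.
#'
#' @inheritParams compute_pre_rrr
#' @param marker Marker name (must be in the model).
#' @return A `pre_result`.
#' @export
single_marker_rrr <- function(model, trial, marker, config = score_config(),
                              ci = TRUE) {
  if (!marker %in% names(model$specs)) {
    stop("single_marker_rrr: unknown marker '", marker, "'")
  }
  mod <- trial
  for (nm in setdiff(names(model$specs), marker)) {
    mod[[paste0(nm, "_m6")]] <- mod[[paste0(nm, "_base")]]
  }
  compute_pre_rrr(model, mod, config, ci = ci)
}

#' Observed relative risk reduction from trial outcomes
#'
#' Fits a Cox model with a single treatment indicator and reports
#' `RRR = 100 (1 - HR)` with a Wald CI transformed from the log-HR scale.
#'
#' @param trial Trial tibble with `arm`, `time_<endpoint>` and
#'   `event_<endpoint>` columns.
#' @param endpoint Endpoint name.
#' @param level CI level.
#' @return List with `rrr`, `ci_lower`, `ci_upper` (percent), `hr`,
#'   `log_hr_se`, and event counts per arm.
#' @export
observed_rrr <- function(trial, endpoint, level = 0.95) {
  tcol <- paste0("time_", endpoint)
  ecol <- paste0("event_", endpoint)
  if (!all(c(tcol, ecol) %in% names(trial))) {
    stop("observed_rrr: outcome columns for endpoint '", endpoint,
         "' not present")
  }
  ev <- tapply(trial[[ecol]], trial$arm, sum)
  if (any(ev == 0)) {
    stop("observed_rrr: zero events in arm(s): ",
         paste(names(ev)[ev == 0], collapse = ", "))
  }
  df <- data.frame(time = trial[[tcol]], event = trial[[ecol]],
                   treated = as.integer(trial$arm == "treated"))
  fit <- survival::coxph(survival::Surv(time, event) ~ treated, data = df)
  b <- unname(coef(fit)["treated"])
  se <- sqrt(vcov(fit)["treated", "treated"])
  z <- qnorm(1 - (1 - level) / 2)
  list(rrr = 100 * (1 - exp(b)),
       ci_lower = 100 * (1 - exp(b + z * se)),
       ci_upper = 100 * (1 - exp(b - z * se)),
       hr = exp(b), log_hr_se = se,
       events_treated = unname(ev["treated"]),
       events_placebo = unname(ev["placebo"]))
}
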