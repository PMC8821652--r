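#' Configure a cohort to simulate
#'
#' @param n Number of patients.
#' @param allocation Treated:placebo allocation ratio as a length-2 numeric
#'   vector, e.g. `c(2, 1)`; `c(0, 1)` gives a single-arm (background) cohort.
#' @param specs Named list of [marker_spec()]s.
#' @param correlation Between-marker correlation matrix on the transformed
#'   scale (symmetric, positive semi-definite, unit diagonal).  Defaults to
#'   [default_correlation()].
#' @param seed Integer seed; every draw made from this config is a
#'   deterministic function of it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, allocation = c(2, 1),
                          specs = empareg_marker_specs(),
                          correlation = default_correlation(specs),
                          seed = 1L) {
  if (!is.numeric(n) || n <= 0) stop("cohort_config: n must be > 0")
  stopifnot(length(allocation) == 2L, all(allocation >= 0), sum(allocation) > 0)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-8))) {
    stop("cohort_config: correlation matrix must be symmetric")
  }
  if (!isTRUE(all.equal(unname(diag(correlation)), rep(1, nrow(correlation))))) {
    stop("cohort_config: correlation matrix must have unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("cohort_config: correlation matrix is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  }
  if (nrow(correlation) != length(specs)) {
    stop("cohort_config: correlation dimension does not match number of markers")
  }
  structure(list(n = as.integer(n), allocation = allocation, specs = specs,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Configure the placebo-corrected treatment-effect profile
#'
#' Per marker: the placebo-arm mean drift from baseline to month 6, the
#' additional treated-arm effect (for UACR a multiplicative percent change on
#' the natural scale, applied on the log scale), and the within-subject SD of
#' the 6-month change (log-scale SD for UACR).
#'
#' @param effects Named numeric vector of treated-arm placebo-corrected
#'   effects; UACR in percent (e.g. `-13` for a 13\% reduction), others in
#'   the marker's natural unit.
#' @param drift Named numeric vector of placebo-arm mean drifts (same units
#'   and conventions); defaults to zero for every marker in `effects`.
#' @param change_sd Named numeric vector of within-subject change SDs; must
#'   be positive.
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(effects, drift = NULL, change_sd) {
  stopifnot(!is.null(names(effects)), !is.null(names(change_sd)))
  if (is.null(drift)) drift <- setNames(rep(0, length(effects)), names(effects))
  if (any(change_sd <= 0)) stop("effect_profile: change SDs must be > 0")
  missing_sd <- setdiff(names(effects), names(change_sd))
  if (length(missing_sd)) {
    stop("effect_profile: no change SD for marker(s): ",
         paste(missing_sd, collapse = ", "))
  }
  structure(list(effects = effects, drift = drift, change_sd = change_sd),
            class = "effect_profile")
}

#' Treatment-effect profile of an SGLT2 inhibitor over six months
#'
#' Placebo-corrected mean changes of the calibrated generator: HbA1c -0.6\%,
#' SBP -4.2 mmHg, UACR -13\% (multiplicative), haemoglobin +6.6 g/L, weight
#' -2.1 kg, HDL +0.04 mmol/L, LDL +0.1 mmol/L, uric acid -20.4 umol/L,
#' potassium unchanged.  Within-subject 6-month change SDs are not published
#' and are package defaults chosen for clinical realism.
#'
#' @return An [effect_profile()].
#' @export
empagliflozin_effect_profile <- function() {
  effect_profile(
    effects = c(hba1c = -0.6, sbp = -4.2, uacr = -13.0, hemoglobin = 6.6,
                weight = -2.1, hdl = 0.04, ldl = 0.1, uric_acid = -20.4,
                potassium = 0),
    change_sd = c(hba1c = 1.0, sbp = 14.0, uacr = 1.0, hemoglobin = 10.0,
                  weight = 3.5, hdl = 0.15, ldl = 0.6, uric_acid = 60.0,
                  potassium = 0.4)
  )
}

#' Null treatment-effect profile
#'
#' Zero effect and zero drift for every marker, keeping the default change
#' noise; useful for null-calibration checks.
#'
#' @param base Profile whose change SDs to reuse.
#' @return An [effect_profile()].
#' @export
null_effect_profile <- function(base = empagliflozin_effect_profile()) {
  effect_profile(effects = setNames(rep(0, length(base$effects)),
                                    names(base$effects)),
                 change_sd = base$change_sd)
}

#' Configure the outcome-generating hazard
#'
#' Event times are exponential given the covariates: hazard
#' `lambda0 * exp(beta' (x - ref))` where `x` is the transformed marker
#' vector, `ref` the analytic transformed means of the generating specs, and
#' `beta` the true log-hazard-ratio vector per transformed covariate.
#' `direct_log_hr` adds a treated-arm log hazard ratio that bypasses the
#' markers, emulating treatment benefit not captured by the marker panel.
#'
#' @param endpoint Endpoint name (e.g. `"cv"`, `"kidney"`).
#' @param beta Named numeric vector of true coefficients, names being
#'   transformed covariate names (`log_uacr` for UACR).
#' @param lambda0 Baseline hazard rate per year at the reference covariates.
#' @param followup_years Administrative censoring time.
#' @param censor_rate Rate of additional random exponential censoring
#'   (0 = none).
#' @param direct_log_hr Direct (non-marker-mediated) treated-arm log HR.
#' @return An object of class `outcome_config`.
#' @export
outcome_config <- function(endpoint, beta, lambda0, followup_years = 3.1,
                           censor_rate = 0, direct_log_hr = 0) {
  if (!is.numeric(lambda0) || lambda0 <= 0) {
    stop("outcome_config: lambda0 must be > 0")
  }
  if (followup_years <= 0) stop("outcome_config: censoring time must be > 0")
  stopifnot(!is.null(names(beta)))
  structure(list(endpoint = endpoint, beta = beta, lambda0 = lambda0,
                 followup_years = followup_years, censor_rate = censor_rate,
                 direct_log_hr = direct_log_hr),
            class = "outcome_config")
}

# True coefficient vectors for the two default endpoints.  These are
# generator-side ground truth (the quantities a fitted Cox model should
# recover), on the transformed-covariate scale.
default_beta <- function(endpoint = c("cv", "kidney")) {
  endpoint <- match.arg(endpoint)
  switch(endpoint,
    cv = c(hba1c = 0.12, sbp = 0.012, log_uacr = 0.18, hemoglobin = -0.012,
           weight = 0.004, hdl = -0.35, ldl = 0.12, uric_acid = 0.0015,
           potassium = 0.15),
    kidney = c(hba1c = 0.08, sbp = 0.012, log_uacr = 0.45, hemoglobin = -0.02,
               weight = 0.002, hdl = -0.15, ldl = 0.05, uric_acid = 0.001,
               potassium = 0.25))
}

#' Default cardiovascular and kidney outcome generators
#'
#' Coefficient vectors with clinically plausible gradients, with the baseline
#' hazard calibrated (see [calibrate_lambda0()]) so the background cohort
#' reproduces event fractions of 12.5\% (CV) and 17.8\% (kidney) over 3.1
#' years of follow-up.
#'
#' @param direct_log_hr Direct treated-arm log HR passed through.
#' @return An [outcome_config()].
#' @export
default_cv_outcome <- function(direct_log_hr = 0) {
  outcome_config("cv", default_beta("cv"), lambda0 = 0.035318,
                 followup_years = 3.1, direct_log_hr = direct_log_hr)
}

#' @rdname default_cv_outcome
#' @export
default_kidney_outcome <- function(direct_log_hr = 0) {
  outcome_config("kidney", default_beta("kidney"), lambda0 = 0.039982,
                 followup_years = 3.1, direct_log_hr = direct_log_hr)
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' Solves for `lambda0` such that the expected event fraction (before any
#' random censoring) over the follow-up window equals `target`, by Monte
#' Carlo over the marker distribution of `config`.
#'
#' @param config A [cohort_config()] (its marker specs and correlation define
#'   the covariate distribution).
#' @param outcome An [outcome_config()]; its `lambda0` is ignored.
#' @param target Target event fraction in (0, 1).
#' @param n_mc Monte Carlo sample size.
#' @return The calibrated `lambda0` (per year).
#' @export
calibrate_lambda0 <- function(config, outcome, target, n_mc = 200000L) {
  stopifnot(target > 0, target < 1)
  lp <- with_subseed(config$seed, "calibrate", {
    x <- draw_transformed(n_mc, config$specs, config$correlation)
    linear_predictor(x, outcome$beta, spec_transformed_means_cov(config$specs))
  })
  C <- outcome$followup_years
  f <- function(log_l0) mean(1 - exp(-exp(log_l0 + lp) * C)) - target
  exp(uniroot(f, c(log(1e-6), log(10)), tol = 1e-10)$root)
}

# ---- internal draw machinery -------------------------------------------

# Gaussian copula draw; returns matrix of transformed-scale values with
# covariate names (log_uacr etc.).
draw_transformed <- function(n, specs, correlation) {
  z <- MASS::mvrnorm(n, mu = rep(0, length(specs)), Sigma = correlation)
  z <- matrix(z, nrow = n)
  x <- sweep(sweep(z, 2, vapply(specs, `[[`, 0, "scale"), `*`),
             2, vapply(specs, `[[`, 0, "location"), `+`)
  colnames(x) <- vapply(specs, covariate_name, "")
  x
}

# Transformed means keyed by covariate name.
spec_transformed_means_cov <- function(specs) {
  setNames(vapply(specs, `[[`, 0, "location"),
           vapply(specs, covariate_name, ""))
}

# lp = beta' (x - ref), matching columns by name; errors on absent covariates.
linear_predictor <- function(x, beta, ref) {
  missing_cov <- setdiff(names(beta), colnames(x))
  if (length(missing_cov)) {
    stop("covariate(s) absent from data: ", paste(missing_cov, collapse = ", "))
  }
  xc <- sweep(x[, names(beta), drop = FALSE], 2, ref[names(beta)], `-`)
  drop(xc %*% beta)
}

# Back-transform a transformed-scale matrix to natural-scale marker columns
# named <marker>_<suffix>.
natural_scale <- function(x, specs, suffix) {
  out <- lapply(specs, function(s) {
    v <- x[, covariate_name(s)]
    if (s$family == "lognormal") exp(v) else v
  })
  names(out) <- paste0(names(specs), "_", suffix)
  out
}

# Demographics: age, sex, eGFR are descriptive covariates (used for
# subgrouping only, never scored).
draw_demographics <- function(n, trial_like = TRUE) {
  if (trial_like) {
    list(age = rnorm(n, 63.1, 8.7), sex = rbinom(n, 1, 0.285),
         egfr_base = rnorm(n, 74.0, 21.4))
  } else {
    list(age = rnorm(n, 61.0, 9.0), sex = rbinom(n, 1, 0.335),
         egfr_base = rnorm(n, 49.8, 23.3))
  }
}

# Exponential event times with administrative + optional random censoring.
draw_outcome <- function(lp, outcome) {
  n <- length(lp)
  t_event <- rexp(n, rate = outcome$lambda0 * exp(lp))
  cens <- rep(outcome$followup_years, n)
  if (outcome$censor_rate > 0) {
    cens <- pmin(cens, rexp(n, rate = outcome$censor_rate))
  }
  list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
}

# ---- exported generators ------------------------------------------------

#' Generate a background (single-arm) cohort with event times
#'
#' Baseline markers are drawn from the config's marginals through a Gaussian
#' copula; event times follow the marker-dependent exponential hazard of the
#' outcome config.  Reproducible given the config seed.
#'
#' @param config A [cohort_config()] (typically with
#'   [background_marker_specs()]).
#' @param outcome An [outcome_config()].
#' @return A tibble with one row per patient: `id`, demographics, baseline
#'   markers `<marker>_base`, and `time_<endpoint>` / `event_<endpoint>`.
#' @export
#' @examples
#' cfg <- cohort_config(500, c(0, 1), background_marker_specs(), seed = 7)
#' bg <- generate_background(cfg, default_cv_outcome())
#' mean(bg$event_cv)
generate_background <- function(config, outcome) {
  stopifnot(inherits(config, "cohort_config"), inherits(outcome, "outcome_config"))
  with_subseed(config$seed, paste0("background_", outcome$endpoint), {
    n <- config$n
    x <- draw_transformed(n, config$specs, config$correlation)
    ref <- spec_transformed_means_cov(config$specs)
    lp <- linear_predictor(x, outcome$beta, ref)
    oc <- draw_outcome(lp, outcome)
    dem <- draw_demographics(n, trial_like = FALSE)
    tab <- c(list(id = seq_len(n)), dem, natural_scale(x, config$specs, "base"))
    tab[[paste0("time_", outcome$endpoint)]] <- oc$time
    tab[[paste0("event_", outcome$endpoint)]] <- oc$event
    tibble::as_tibble(tab)
  })
}

#' Generate a two-arm trial cohort with marker-mediated outcomes
#'
#' Baseline markers come from the config's marginals; month-6 values are
#' baseline + placebo drift + treated-arm effect + within-subject noise (all
#' on the log scale for UACR).  Event hazards are computed from the
#' *month-6* marker values, so the treatment effect on outcomes is wholly
#' marker-mediated unless `direct_log_hr` is set in the outcome config.
#'
#' @param config A [cohort_config()] with a two-arm allocation.
#' @param effects An [effect_profile()].
#' @param outcome An [outcome_config()], or `NULL` to skip outcome columns.
#' @return A tibble with `id`, `arm` (`"treated"`/`"placebo"`), demographics,
#'   `<marker>_base`, `<marker>_m6`, and (if `outcome` is given)
#'   `time_<endpoint>` / `event_<endpoint>` columns.
#' @export
#' @examples
#' cfg <- cohort_config(600, c(2, 1), seed = 11)
#' tr <- generate_trial(cfg, empagliflozin_effect_profile(), default_cv_outcome())
#' table(tr$arm)
generate_trial <- function(config, effects, outcome = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(effects, "effect_profile"))
  unknown <- setdiff(names(effects$effects), names(config$specs))
  if (length(unknown)) {
    stop("effect specified for unknown marker(s): ",
         paste(unknown, collapse = ", "))
  }
  with_subseed(config$seed, "trial", {
    n <- config$n
    n_treat <- round(n * config$allocation[1] / sum(config$allocation))
    arm <- rep(c("treated", "placebo"), c(n_treat, n - n_treat))
    treated <- arm == "treated"

    xb <- draw_transformed(n, config$specs, config$correlation)
    xm6 <- xb
    for (nm in names(config$specs)) {
      s <- config$specs[[nm]]
      cv <- covariate_name(s)
      eff <- effects$effects[nm]; if (is.na(eff)) eff <- 0
      dr <- effects$drift[nm]; if (is.na(dr)) dr <- 0
      sdc <- effects$change_sd[nm]
      if (is.na(sdc)) next  # marker untouched if profile omits it
      if (s$family == "lognormal") {
        # percent effects act multiplicatively => additive on the log scale
        delta <- log1p(dr / 100) + treated * log1p(eff / 100)
      } else {
        delta <- dr + treated * eff
      }
      xm6[, cv] <- xb[, cv] + delta + rnorm(n, 0, sdc)
    }

    ref <- spec_transformed_means_cov(config$specs)
    dem <- draw_demographics(n, trial_like = TRUE)
    tab <- c(list(id = seq_len(n), arm = arm), dem,
             natural_scale(xb, config$specs, "base"),
             natural_scale(xm6, config$specs, "m6"))
    if (!is.null(outcome)) {
      stopifnot(inherits(outcome, "outcome_config"))
      lp <- linear_predictor(xm6, outcome$beta, ref) +
        treated * outcome$direct_log_hr
      oc <- draw_outcome(lp, outcome)
      tab[[paste0("time_", outcome$endpoint)]] <- oc$time
      tab[[paste0("event_", outcome$endpoint)]] <- oc$event
    }
    tibble::as_tibble(tab)
  })
}

#' Simulated true relative risk reduction (generator oracle)
#'
#' Monte Carlo estimate of the relative risk reduction the generator truly
#' induces at a horizon: both potential month-6 marker vectors (treated and
#' placebo) are computed for the *same* patients and noise draws, risks are
#' evaluated in closed form under the exponential hazard, and
#' `RRR = 100 * (1 - mean(risk_treated) / mean(risk_placebo))`.
#'
#' @param config A [cohort_config()]; `n` is ignored in favour of `n_mc`.
#' @param effects An [effect_profile()].
#' @param outcome An [outcome_config()].
#' @param horizon Risk horizon in years; must not exceed the outcome's
#'   follow-up window.
#' @param n_mc Monte Carlo sample size.
#' @return List with `rrr` (percent), `se` (Monte Carlo SE, percent), and
#'   `n` (`n_mc`).
#' @export
true_rrr <- function(config, effects, outcome, horizon = outcome$followup_years,
                     n_mc = 200000L) {
  stopifnot(inherits(outcome, "outcome_config"))
  if (horizon > outcome$followup_years) {
    stop("true_rrr: horizon exceeds the outcome's follow-up window")
  }
  with_subseed(config$seed, "true_rrr", {
    xb <- draw_transformed(n_mc, config$specs, config$correlation)
    ref <- spec_transformed_means_cov(config$specs)
    m6 <- function(treated) {
      x <- xb
      for (nm in names(config$specs)) {
        s <- config$specs[[nm]]
        sdc <- effects$change_sd[nm]
        if (is.na(sdc)) next
        eff <- effects$effects[nm]; if (is.na(eff)) eff <- 0
        dr <- effects$drift[nm]; if (is.na(dr)) dr <- 0
        delta <- if (s$family == "lognormal") {
          log1p(dr / 100) + treated * log1p(eff / 100)
        } else {
          dr + treated * eff
        }
        x[, covariate_name(s)] <- xb[, covariate_name(s)] + delta
      }
      x
    }
    # within-subject noise is shared between the two potential outcomes,
    # so the contrast is purely the treatment effect
    noise <- vapply(names(config$specs), function(nm) {
      sdc <- effects$change_sd[nm]
      if (is.na(sdc)) rep(0, n_mc) else rnorm(n_mc, 0, sdc)
    }, numeric(n_mc))
    colnames(noise) <- vapply(config$specs, covariate_name, "")
    risk_at <- function(x) {
      lp <- linear_predictor(x + noise, outcome$beta, ref)
      1 - exp(-outcome$lambda0 * exp(lp) * horizon)
    }
    r1 <- risk_at(m6(TRUE))
    r0 <- risk_at(m6(FALSE))
    if (outcome$direct_log_hr != 0) {
      h1 <- -log(1 - r1) * exp(outcome$direct_log_hr)
      r1 <- 1 - exp(-h1)
    }
    ratio <- mean(r1) / mean(r0)
    # linearised SE of the paired ratio estimator
    infl <- (r1 - ratio * r0) / mean(r0)
    list(rrr = 100 * (1 - ratio), se = 100 * sd(infl) / sqrt(n_mc), n = n_mc)
  })
}

#' Configure missing-data injection
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param proportions Named numeric vector of per-marker missing proportions
#'   in `[0, 1)`; names are marker names.
#' @param timepoint Which measurement to blank: `"m6"` (default), `"base"`,
#'   or `"both"`.
#' @param mar_covariate Column the MAR mechanism conditions on (higher values
#'   of this covariate get higher missingness).
#' @param seed Integer seed.
#' @return An object of class `missingness_config`.
#' @export
missingness_config <- function(mechanism = c("MCAR", "MAR"), proportions,
                               timepoint = c("m6", "base", "both"),
                               mar_covariate = "age", seed = 1L) {
  mechanism <- match.arg(mechanism)
  timepoint <- match.arg(timepoint)
  stopifnot(!is.null(names(proportions)))
  if (any(proportions < 0 | proportions >= 1)) {
    stop("missingness_config: proportions must lie in [0, 1)")
  }
  structure(list(mechanism = mechanism, proportions = proportions,
                 timepoint = timepoint, mar_covariate = mar_covariate,
                 seed = as.integer(seed)),
            class = "missingness_config")
}

#' Blank marker values according to a missingness mechanism
#'
#' MCAR blanks each targeted cell independently with the configured
#' probability.  MAR makes the missingness probability an increasing
#' logistic function of the (standardised) MAR covariate, with the intercept
#' solved so the marginal missing proportion matches the target.  Outcome
#' and demographic columns are never blanked.
#'
#' @param table A cohort/trial tibble.
#' @param mconfig A [missingness_config()].
#' @return The table with `NA`s injected.
#' @export
inject_missingness <- function(table, mconfig) {
  stopifnot(inherits(mconfig, "missingness_config"))
  suffixes <- switch(mconfig$timepoint, m6 = "m6", base = "base",
                     both = c("base", "m6"))
  if (mconfig$mechanism == "MAR") {
    if (!mconfig$mar_covariate %in% names(table)) {
      stop("inject_missingness: MAR dependence covariate '",
           mconfig$mar_covariate, "' absent from table")
    }
    z <- scale(table[[mconfig$mar_covariate]])[, 1]
  }
  with_subseed(mconfig$seed, "missingness", {
    n <- nrow(table)
    for (nm in names(mconfig$proportions)) {
      p <- mconfig$proportions[[nm]]
      if (p == 0) next
      for (sf in suffixes) {
        col <- paste0(nm, "_", sf)
        if (!col %in% names(table)) {
          stop("inject_missingness: column '", col, "' absent from table")
        }
        if (mconfig$mechanism == "MCAR") {
          miss <- runif(n) < p
        } else {
          # logistic-in-z with unit slope; intercept tuned to the target rate
          a <- uniroot(function(a) mean(stats::plogis(a + z)) - p,
                       c(-20, 20), tol = 1e-10)$root
          miss <- runif(n) < stats::plogis(a + z)
        }
        table[[col]][miss] <- NA_real_
      }
    }
    table
  })
}

#' Write a cohort table to CSV
#'
#' One row per patient; missing values are written as empty fields.
#'
#' @param table Cohort/trial tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table written by [write_cohort_csv()]
#'
#' @param path CSV file path.
#' @return A tibble; empty fields become `NA`.
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, na.strings = c("", "NA")))
}
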