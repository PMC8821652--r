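#' Transform raw markers to model covariates
#'
#' UACR enters the Cox model on the natural-log scale (its distribution is
#' heavily right-skewed); every other marker enters untransformed.  Columns
#' are renamed to the covariate convention (`uacr` -> `log_uacr`).
#'
#' @param raw A data frame / tibble or named numeric vector of raw marker
#'   values, names being marker names.
#' @param specs Named list of [marker_spec()]s declaring which markers are
#'   log-transformed.
#' @return Same shape as the input, with transformed values and covariate
#'   names.
#' @export
#' @examples
#' transform_markers(c(uacr = 17.7, hba1c = 8.1))
transform_markers <- function(raw, specs = empareg_marker_specs()) {
  vec <- is.numeric(raw) && !is.null(names(raw))
  if (vec) raw <- as.data.frame(as.list(raw))
  out <- raw
  for (nm in intersect(names(specs), names(out))) {
    if (specs[[nm]]$family == "lognormal") {
      bad <- which(!is.na(out[[nm]]) & out[[nm]] <= 0)
      if (length(bad)) {
        stop("transform_markers: non-positive ", nm, " in record(s) ",
             paste(head(bad, 5), collapse = ", "))
      }
      out[[nm]] <- log(out[[nm]])
      names(out)[names(out) == nm] <- paste0("log_", nm)
    }
  }
  if (vec) setNames(as.numeric(out[1, ]), names(out)) else out
}

# Extract the transformed covariate matrix for one timepoint from a cohort
# table with <marker>_base / <marker>_m6 columns.
marker_matrix <- function(table, specs, timepoint = c("base", "m6")) {
  timepoint <- match.arg(timepoint)
  cols <- paste0(names(specs), "_", timepoint)
  absent <- setdiff(cols, names(table))
  if (length(absent)) {
    stop("marker column(s) absent: ", paste(absent, collapse = ", "))
  }
  raw <- as.data.frame(table[cols])
  names(raw) <- names(specs)
  x <- as.matrix(transform_markers(raw, specs))
  colnames(x) <- vapply(specs, covariate_name, "")
  x
}

#' Fit a Cox proportional hazards model on a background cohort
#'
#' Markers are transformed ([transform_markers()]) and mean-centred, then a
#' Cox model is fitted by maximum partial likelihood (Efron tie handling by
#' default).  The centring means are stored so downstream risk predictions
#' are invariant to the centring choice.
#'
#' @param table Background cohort tibble with `<marker>_base`,
#'   `time_<endpoint>` and `event_<endpoint>` columns.
#' @param endpoint Endpoint name selecting the time/event columns.
#' @param specs Named list of [marker_spec()]s to use as covariates.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`: coefficients, SEs, covariance,
#'   log partial likelihood, centring means, and the underlying
#'   [survival::coxph()] fit.
#' @export
fit_cox <- function(table, endpoint, specs = background_marker_specs(),
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  tcol <- paste0("time_", endpoint)
  ecol <- paste0("event_", endpoint)
  if (!all(c(tcol, ecol) %in% names(table))) {
    stop("fit_cox: no time/event columns for endpoint '", endpoint, "'")
  }
  time <- table[[tcol]]
  event <- table[[ecol]]
  if (sum(event) < 2) stop("fit_cox: fewer than 2 events for endpoint '",
                           endpoint, "'")
  x <- marker_matrix(table, specs, "base")
  if (anyNA(x)) stop("fit_cox: missing covariate values; impute first")
  center <- colMeans(x)
  xc <- sweep(x, 2, center, `-`)
  df <- data.frame(time = time, event = event, xc)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(colnames(xc), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-11, toler.chol = 1e-13, iter.max = 100))
  if (any(is.na(coef(fit)))) {
    stop("fit_cox: collinear covariates (NA coefficients)")
  }
  se <- sqrt(diag(vcov(fit)))
  if (any(!is.finite(se)) || any(abs(coef(fit)) > 50)) {
    stop("fit_cox: monotone likelihood / separation suspected")
  }
  structure(
    list(coef = coef(fit), se = se, vcov = vcov(fit),
         loglik = fit$loglik[2], loglik_null = fit$loglik[1],
         ties = ties, center = center, endpoint = endpoint,
         n = nrow(df), n_events = sum(event), coxph = fit, data = df),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> endpoint '%s': %d subjects, %d events, ties=%s\n",
              x$endpoint, x$n, x$n_events, x$ties))
  print(round(cbind(coef = x$coef, se = x$se, z = x$coef / x$se), 4))
  invisible(x)
}

#' Breslow baseline survival function
#'
#' Baseline survival `S0(t) = exp(-H0(t))` at the centring covariates (i.e.
#' the cohort mean marker profile), with `H0` the Breslow cumulative baseline
#' hazard: a right-continuous step function with steps at event times.
#'
#' @param fit A [fit_cox()] result.
#' @return A list with `time`, `surv` (step knots/values) and `s0`, a
#'   function evaluating S0 at arbitrary `t` within the observed follow-up
#'   (evaluation beyond the last observed time is an error -- no
#'   extrapolation).
#' @export
baseline_survival <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  newd <- as.data.frame(as.list(setNames(rep(0, length(fit$coef)),
                                         names(fit$coef))))
  sf <- survival::survfit(fit$coxph, newdata = newd,
                          stype = 2, ctype = 1)  # exp(-H0), Breslow H0
  tmax <- max(fit$data$time)
  knots <- sf$time
  vals <- sf$surv
  s0 <- function(t) {
    if (any(t > tmax + 1e-12)) {
      stop("baseline_survival: t = ", max(t), " beyond last observed time ",
           signif(tmax, 6), " (no extrapolation)")
    }
    if (any(t < 0)) stop("baseline_survival: negative time")
    idx <- findInterval(t, knots)
    ifelse(idx == 0, 1, vals[pmax(idx, 1)])
  }
  list(time = knots, surv = vals, s0 = s0, tmax = tmax)
}

#' Assemble a risk model from a Cox fit
#'
#' Bundles the fitted coefficients, centring means, Breslow baseline
#' survival and a risk horizon into the object used for all downstream
#' scoring.
#'
#' @param fit A [fit_cox()] result.
#' @param specs The [marker_spec()] list used at fit time (carries the
#'   transform map and harm directions).
#' @param horizon Risk horizon T in years; defaults to the median follow-up
#'   of the fitting cohort.  Must not exceed the observed follow-up.
#' @return An object of class `risk_model`.
#' @export
risk_model <- function(fit, specs = background_marker_specs(),
                       horizon = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  bs <- baseline_survival(fit)
  if (is.null(horizon)) horizon <- median(fit$data$time)
  if (horizon > bs$tmax) {
    stop("risk_model: horizon exceeds observed follow-up")
  }
  structure(
    list(coef = fit$coef, se = fit$se, vcov = fit$vcov, center = fit$center,
         ties = fit$ties, endpoint = fit$endpoint,
         s0_time = bs$time, s0_surv = bs$surv, tmax = bs$tmax,
         horizon = horizon, specs = specs),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> endpoint '%s', %d covariates, horizon %.2f y, S0(T)=%.4f\n",
              x$endpoint, length(x$coef), x$horizon,
              s0_at(x, x$horizon)))
  invisible(x)
}

# S0 evaluated from the stored step function.
s0_at <- function(model, t) {
  if (any(t > model$tmax + 1e-12)) {
    stop("predict_risk: horizon beyond observed follow-up of the risk model")
  }
  idx <- findInterval(t, model$s0_time)
  ifelse(idx == 0, 1, model$s0_surv[pmax(idx, 1)])
}

#' Predict absolute event risk at a horizon
#'
#' `risk = 1 - S0(T)^exp(lp)` with linear predictor
#' `lp = coef' (x - centring means)` on the transformed covariate scale.
#'
#' @param model A [risk_model()].
#' @param x Matrix (or named vector) of *transformed* covariate values with
#'   covariate-named columns, or `NULL` when `markers` is given.
#' @param markers Optional data frame of raw marker values (marker-named
#'   columns); transformed internally.
#' @param horizon Risk horizon; defaults to the model's.
#' @param coef Optional coefficient vector overriding the model's (used by
#'   the resampling CI machinery).
#' @return Numeric vector of risks in (0, 1).
#' @export
predict_risk <- function(model, x = NULL, markers = NULL,
                         horizon = model$horizon, coef = model$coef) {
  stopifnot(inherits(model, "risk_model"))
  if (is.null(x)) {
    if (is.null(markers)) stop("predict_risk: supply x or markers")
    x <- as.matrix(transform_markers(as.data.frame(markers), model$specs))
  }
  if (is.numeric(x) && is.null(dim(x))) x <- t(as.matrix(x))
  lp <- linear_predictor(x, coef, model$center)
  s0 <- s0_at(model, horizon)
  1 - s0^exp(lp)
}

#' Serialise a risk model to a structured text file
#'
#' Writes coefficients, SEs, covariance, centring means, the baseline
#' survival step function, horizon and marker transform map as JSON with
#' full double precision, so a round trip is bit-exact.
#'
#' @param model A [risk_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  payload <- list(
    endpoint = model$endpoint, ties = model$ties,
    coef = as.list(model$coef), se = as.list(setNames(model$se, names(model$coef))),
    vcov = unname(model$vcov),
    center = as.list(model$center),
    s0_time = model$s0_time, s0_surv = model$s0_surv, tmax = model$tmax,
    horizon = model$horizon,
    specs = lapply(model$specs, unclass)
  )
  # digits = I(17): full significant digits, so doubles round-trip exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a risk model serialised by [write_risk_model()]
#'
#' @param path JSON file path.
#' @return A [risk_model()] object.
#' @export
read_risk_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(p$specs, function(s) {
    marker_spec(s$name, s$unit, s$family, s$location, s$scale,
                s$harm_direction)
  })
  names(specs) <- vapply(specs, `[[`, "", "name")
  cf <- unlist(p$coef)
  structure(
    list(coef = cf, se = unlist(p$se), vcov = {
      v <- matrix(as.numeric(p$vcov), length(cf), length(cf))
      dimnames(v) <- list(names(cf), names(cf)); v
    },
    center = unlist(p$center), ties = p$ties, endpoint = p$endpoint,
    s0_time = p$s0_time, s0_surv = p$s0_surv, tmax = p$tmax,
    horizon = p$horizon, specs = specs),
    class = "risk_model"
  )
}
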