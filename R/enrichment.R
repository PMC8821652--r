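#' Responder threshold for a marker
#'
#' A responder is a treated patient whose marker *improvement* from baseline
#' is at least the treated-arm median improvement.  Changes are computed on
#' the log scale for log-normal markers (UACR) and oriented by the marker's
#' harm direction, so "response" always means moving away from harm; the
#' rule is inclusive (ties at the median count as responders).
#'
#' @param trial Trial tibble.
#' @param marker Marker name.
#' @param specs Marker specs (for the transform and harm direction).
#' @return List with `threshold` (median improvement on the oriented,
#'   transformed change scale), `improvement` (per treated patient), and
#'   `is_responder` (logical over treated patients).
#' @export
responder_threshold <- function(trial, marker,
                                specs = empareg_marker_specs()) {
  if (!marker %in% names(specs)) {
    stop("responder_threshold: unknown marker '", marker, "'")
  }
  treated <- trial[trial$arm == "treated", , drop = FALSE]
  if (nrow(treated) == 0) stop("responder_threshold: empty treated arm")
  s <- specs[[marker]]
  b <- treated[[paste0(marker, "_base")]]
  m <- treated[[paste0(marker, "_m6")]]
  if (anyNA(m) || anyNA(b)) {
    stop("responder_threshold: missing marker values; impute first")
  }
  change <- if (s$family == "lognormal") log(m) - log(b) else m - b
  improvement <- -s$harm_direction * change  # positive = moved away from harm
  thr <- median(improvement)
  list(threshold = thr, improvement = improvement,
       is_responder = improvement >= thr)
}

#' Shift the responder proportion of the treated arm
#'
#' Re-draws every treated patient's month-6 change for one marker from the
#' empirical responder stratum with probability `p` and from the
#' non-responder stratum with probability `1 - p` (stratified bootstrap).
#' The placebo arm and all other markers are untouched.
#'
#' @param trial Trial tibble.
#' @param marker Marker name.
#' @param p Target responder proportion in `[0, 1]`.
#' @param specs Marker specs.
#' @param seed Integer seed.
#' @return The modified trial tibble.
#' @export
shift_responders <- function(trial, marker, p,
                             specs = empareg_marker_specs(), seed = 1L) {
  if (p < 0 || p > 1) stop("shift_responders: p must be in [0, 1]")
  rt <- responder_threshold(trial, marker, specs)
  s <- specs[[marker]]
  idx_t <- which(trial$arm == "treated")
  b <- trial[[paste0(marker, "_base")]][idx_t]
  m <- trial[[paste0(marker, "_m6")]][idx_t]
  change <- if (s$family == "lognormal") log(m) - log(b) else m - b
  resp <- change[rt$is_responder]
  nonresp <- change[!rt$is_responder]
  if ((p > 0 && length(resp) == 0) || (p < 1 && length(nonresp) == 0)) {
    stop("shift_responders: required responder/non-responder stratum is empty")
  }
  with_subseed(seed, paste0("shift_", marker), {
    n <- length(idx_t)
    from_resp <- runif(n) < p
    new_change <- numeric(n)
    if (any(from_resp)) {
      new_change[from_resp] <- sample(resp, sum(from_resp), replace = TRUE)
    }
    if (any(!from_resp)) {
      new_change[!from_resp] <- sample(nonresp, sum(!from_resp), replace = TRUE)
    }
    new_m6 <- if (s$family == "lognormal") b * exp(new_change) else b + new_change
    trial[[paste0(marker, "_m6")]][idx_t] <- new_m6
    trial
  })
}

#' Predicted RRR as a function of responder proportion
#'
#' For each marker and each responder proportion on the grid, shifts the
#' treated arm's response distribution ([shift_responders()]) and rescores
#' with [compute_pre_rrr()] (point estimates; CIs optional).
#'
#' @param model A [risk_model()].
#' @param trial Trial tibble.
#' @param markers Character vector of marker names to vary (one at a time).
#' @param grid Ascending responder proportions in `[0, 1]`.
#' @param config A [score_config()].
#' @param ci Compute resampling CIs per grid point (slower).
#' @return A tibble of class `enrichment_curve`: `marker`, `proportion`,
#'   `rrr`, and (if `ci`) `ci_lower`/`ci_upper`.
#' @export
enrichment_curve <- function(model, trial,
                             markers = c("uacr", "hba1c", "sbp", "weight"),
                             grid = seq(0, 1, by = 0.1),
                             config = score_config(), ci = FALSE) {
  if (length(grid) == 0) stop("enrichment_curve: empty grid")
  if (is.unsorted(grid)) stop("enrichment_curve: grid must be ascending")
  unknown <- setdiff(markers, names(model$specs))
  if (length(unknown)) {
    stop("enrichment_curve: marker(s) not scored by model: ",
         paste(unknown, collapse = ", "))
  }
  rows <- list()
  for (mk in markers) {
    for (i in seq_along(grid)) {
      p <- grid[i]
      shifted <- shift_responders(trial, mk, p, model$specs,
                                  seed = derive_seed(config$seed,
                                                     paste0(mk, "_", i)))
      res <- compute_pre_rrr(model, shifted, config, ci = ci)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        marker = mk, proportion = p, rrr = res$rrr,
        ci_lower = res$ci_lower, ci_upper = res$ci_upper)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_curve", class(out))
  out
}

#' Placebo-corrected effect needed to reach a target predicted RRR
#'
#' Bisects over a uniform treated-arm shift of one marker -- multiplicative
#' (percent) for log-normal markers, additive otherwise -- applied on top of
#' the observed placebo-arm changes, until the predicted RRR meets the
#' target within 0.1 percentage point.
#'
#' @param model A [risk_model()].
#' @param trial Trial tibble.
#' @param marker Marker to shift.
#' @param target_rrr Target predicted RRR in percent.
#' @param config A [score_config()].
#' @param bounds Search bounds for the shift: percent reduction in
#'   `[0, 99.9]` for log-normal markers, natural units otherwise
#'   (improvement magnitude; the harm direction supplies the sign).
#' @return List with `effect` (percent reduction for log-normal markers,
#'   natural-unit improvement otherwise) and `achieved_rrr`.
#' @export
required_effect <- function(model, trial, marker, target_rrr,
                            config = score_config(), bounds = NULL) {
  if (!marker %in% names(model$specs)) {
    stop("required_effect: unknown marker '", marker, "'")
  }
  s <- model$specs[[marker]]
  if (is.null(bounds)) {
    bounds <- if (s$family == "lognormal") c(0, 99.9) else {
      c(0, 10 * stats::sd(trial[[paste0(marker, "_base")]]))
    }
  }
  idx_t <- which(trial$arm == "treated")
  base_m6 <- trial[[paste0(marker, "_m6")]]
  rrr_at <- function(effect) {
    t2 <- trial
    # replace the treated arm's change with baseline + placebo-like drift 0
    # + the candidate uniform improvement
    if (s$family == "lognormal") {
      fac <- (1 - effect / 100)^(s$harm_direction)
      t2[[paste0(marker, "_m6")]][idx_t] <-
        trial[[paste0(marker, "_base")]][idx_t] * fac
    } else {
      t2[[paste0(marker, "_m6")]][idx_t] <-
        trial[[paste0(marker, "_base")]][idx_t] - s$harm_direction * effect
    }
    compute_pre_rrr(model, t2, config, ci = FALSE)$rrr
  }
  lo <- bounds[1]; hi <- bounds[2]
  r_lo <- rrr_at(lo); r_hi <- rrr_at(hi)
  if (target_rrr < min(r_lo, r_hi) - 0.1 || target_rrr > max(r_lo, r_hi) + 0.1) {
    stop(sprintf(
      "required_effect: target %.1f%% outside achievable range [%.1f, %.1f]",
      target_rrr, min(r_lo, r_hi), max(r_lo, r_hi)))
  }
  increasing <- r_hi >= r_lo
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    r_mid <- rrr_at(mid)
    if (abs(r_mid - target_rrr) < 0.1) {
      return(list(effect = mid, achieved_rrr = r_mid))
    }
    if ((r_mid < target_rrr) == increasing) lo <- mid else hi <- mid
  }
  # converged in effect but not to within the RRR tolerance: report midpoint
  list(effect = (lo + hi) / 2, achieved_rrr = rrr_at((lo + hi) / 2))
}
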