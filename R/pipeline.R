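#' Per-marker change table with placebo-corrected differences
#'
#' For each marker: mean baseline-to-month-6 change per arm, the
#' placebo-corrected difference (treated minus placebo), a normal-
#' approximation CI, and a two-sided p-value.  Log-normal markers (UACR) are
#' analysed on the log scale and additionally reported as a percent change
#' via back-transform (`pct_change = 100 (exp(diff) - 1)`).
#'
#' @param trial Trial tibble with both arms and complete markers.
#' @param specs Marker specs.
#' @param level CI level.
#' @return A tibble: `marker`, `unit`, `scale` (`"natural"`/`"log"`),
#'   `mean_change_placebo`, `mean_change_treated`, `placebo_corrected`,
#'   `ci_lower`, `ci_upper`, `p_value`, `pct_change` (NA for natural-scale
#'   markers).
#' @export
marker_change_table <- function(trial, specs = empareg_marker_specs(),
                                level = 0.95) {
  arms <- unique(trial$arm)
  if (!all(c("treated", "placebo") %in% arms)) {
    stop("marker_change_table: need both arms")
  }
  z <- qnorm(1 - (1 - level) / 2)
  rows <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    b <- trial[[paste0(nm, "_base")]]
    m <- trial[[paste0(nm, "_m6")]]
    if (is.null(b) || is.null(m)) return(NULL)
    ch <- if (s$family == "lognormal") log(m) - log(b) else m - b
    tr <- trial$arm == "treated"
    if (anyNA(ch)) stop("marker_change_table: missing values for '", nm,
                        "'; impute first")
    d <- mean(ch[tr]) - mean(ch[!tr])
    se <- sqrt(var(ch[tr]) / sum(tr) + var(ch[!tr]) / sum(!tr))
    tibble::tibble(
      marker = nm, unit = s$unit,
      scale = if (s$family == "lognormal") "log" else "natural",
      mean_change_placebo = mean(ch[!tr]),
      mean_change_treated = mean(ch[tr]),
      placebo_corrected = d, se = se,
      ci_lower = d - z * se, ci_upper = d + z * se,
      p_value = 2 * pnorm(-abs(d / se)),
      pct_change = if (s$family == "lognormal") 100 * (exp(d) - 1) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Define a baseline subgroup filter
#'
#' @param name Subgroup label.
#' @param predicate Function taking the trial tibble and returning a logical
#'   vector; must use baseline fields only.
#' @return An object of class `subgroup_filter`.
#' @export
subgroup_filter <- function(name, predicate) {
  stopifnot(is.function(predicate))
  structure(list(name = name, predicate = predicate),
            class = "subgroup_filter")
}

#' Standard subgroup filters
#'
#' * `uacr_high` / `uacr_low`: baseline UACR at/above vs below 30 mg/g
#'   (elevated albuminuria).
#' * `empa_kidney_like`: a chronic-kidney-disease subset defined as eGFR
#'   20-45, or eGFR 45-90 with UACR >= 200 mg/g -- a configurable default
#'   for emulating a dedicated kidney-outcome trial population.
#'
#' @return Named list of [subgroup_filter()]s.
#' @export
default_subgroups <- function() {
  list(
    uacr_high = subgroup_filter("UACR >= 30 mg/g",
                                function(d) d$uacr_base >= 30),
    uacr_low = subgroup_filter("UACR < 30 mg/g",
                               function(d) d$uacr_base < 30),
    empa_kidney_like = subgroup_filter(
      "eGFR 20-45, or eGFR 45-90 with UACR >= 200 mg/g",
      function(d) (d$egfr_base >= 20 & d$egfr_base < 45) |
        (d$egfr_base >= 45 & d$egfr_base < 90 & d$uacr_base >= 200))
  )
}

#' Apply a baseline subgroup filter
#'
#' @param trial Trial tibble.
#' @param filter A [subgroup_filter()].
#' @return The subtable of rows satisfying the predicate, with attributes
#'   `n_retained` and `fraction_retained`.
#' @export
apply_subgroup <- function(trial, filter) {
  stopifnot(inherits(filter, "subgroup_filter"))
  keep <- filter$predicate(trial)
  if (anyNA(keep)) stop("apply_subgroup: predicate returned NA")
  out <- trial[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("apply_subgroup: subgroup '", filter$name, "' is empty")
  }
  attr(out, "n_retained") <- nrow(out)
  attr(out, "fraction_retained") <- nrow(out) / nrow(trial)
  out
}

#' Run the full scoring pipeline
#'
#' Orchestrates: optional imputation of missing markers; Cox fit on the
#' background cohort per endpoint; risk-model construction; PRE scoring of
#' the full trial, of each subgroup, and of each single marker; observed RRR
#' from trial outcomes when present; optional enrichment curves.  Entirely
#' deterministic given `seed`.
#'
#' When markers have been imputed (`m` completed datasets), the reported RRR
#' is the mean of the per-dataset point estimates and the CI bounds are the
#' means of the per-dataset percentile bounds.
#'
#' @param background Background cohort tibble (with outcome columns).
#' @param trial Trial tibble.
#' @param endpoints Character vector of endpoint names to score.
#' @param background_specs,trial_specs Marker specs for the two tables.
#' @param subgroups Named list of [subgroup_filter()]s (may be empty).
#' @param impute An [imputation_config()] or `NULL` to require complete data.
#' @param score A [score_config()].
#' @param enrichment_markers Markers for enrichment curves, or `NULL` to
#'   skip.
#' @param seed Global seed; stage sub-seeds derive from it.
#' @param out_dir Optional directory to write the report (JSON) and tables
#'   (CSV) to.
#' @return An `analysis_report` list: one entry per endpoint with fit
#'   summary, overall / subgroup / single-marker predicted RRRs, observed
#'   RRR, the marker change table, and the configuration echo.
#' @export
run_pipeline <- function(background, trial, endpoints = "cv",
                         background_specs = background_marker_specs(),
                         trial_specs = empareg_marker_specs(),
                         subgroups = default_subgroups(),
                         impute = NULL, score = NULL,
                         enrichment_markers = NULL,
                         seed = 1L, out_dir = NULL) {
  marker_cols <- c(paste0(names(trial_specs), "_base"),
                   paste0(names(trial_specs), "_m6"))
  marker_cols <- intersect(marker_cols, names(trial))
  has_blanks <- anyNA(trial[marker_cols])
  trials <- if (has_blanks) {
    if (is.null(impute)) {
      impute <- imputation_config(seed = derive_seed(seed, "impute"))
    }
    impute_pmm(trial, impute)
  } else {
    list(trial)
  }
  m <- length(trials)

  report <- list(seed = seed, n_trial = nrow(trial),
                 n_background = nrow(background), m_imputations = m,
                 endpoints = list())
  for (ep in endpoints) {
    fit <- fit_cox(background, ep, background_specs)
    model <- risk_model(fit, trial_specs)
    cfg <- score %||% score_config(seed = derive_seed(seed, paste0("score_", ep)))

    pool_pre <- function(tabs, scorer) {
      res <- lapply(tabs, scorer)
      out <- res[[1]]
      if (length(res) > 1) {
        out$rrr <- mean(vapply(res, `[[`, 0, "rrr"))
        out$ci_lower <- mean(vapply(res, `[[`, 0, "ci_lower"))
        out$ci_upper <- mean(vapply(res, `[[`, 0, "ci_upper"))
        if (!is.null(out$marker_rrr)) {
          out$marker_rrr <- rowMeans(vapply(res, `[[`,
                                            numeric(length(out$marker_rrr)),
                                            "marker_rrr"))
        }
      }
      out
    }

    overall <- pool_pre(trials, function(t) {
      compute_pre_rrr(model, t, cfg, single_markers = TRUE)
    })
    sub_res <- lapply(subgroups, function(f) {
      pool_pre(trials, function(t) {
        st <- apply_subgroup(t, f)
        if (nrow(st) == 0) return(list(rrr = NA_real_, ci_lower = NA_real_,
                                       ci_upper = NA_real_))
        compute_pre_rrr(model, st, cfg)
      })
    })

    tcol <- paste0("time_", ep)
    obs <- if (tcol %in% names(trial)) observed_rrr(trial, ep) else NULL

    enr <- NULL
    if (!is.null(enrichment_markers)) {
      enr <- enrichment_curve(model, trials[[1]], enrichment_markers,
                              config = cfg)
    }

    report$endpoints[[ep]] <- list(
      endpoint = ep,
      n_events_background = fit$n_events,
      coef = fit$coef, se = fit$se, horizon = model$horizon,
      changes = marker_change_table(trials[[1]], trial_specs),
      predicted = overall, subgroups = sub_res, observed = obs,
      enrichment = enr)
  }
  class(report) <- "analysis_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ep in names(report$endpoints)) {
      e <- report$endpoints[[ep]]
      write.csv(e$changes, file.path(out_dir, paste0("changes_", ep, ".csv")),
                row.names = FALSE)
      if (!is.null(e$enrichment)) {
        write.csv(e$enrichment,
                  file.path(out_dir, paste0("enrichment_", ep, ".csv")),
                  row.names = FALSE)
      }
    }
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# Flatten an analysis_report into JSON-friendly lists.
report_to_json <- function(report) {
  list(
    schema_version = "1.0",
    seed = report$seed, n_trial = report$n_trial,
    n_background = report$n_background, m_imputations = report$m_imputations,
    endpoints = lapply(report$endpoints, function(e) {
      list(endpoint = e$endpoint,
           n_events_background = e$n_events_background,
           coef = as.list(e$coef), se = as.list(setNames(e$se, names(e$coef))),
           horizon = e$horizon,
           predicted_rrr = e$predicted$rrr,
           predicted_ci = c(e$predicted$ci_lower, e$predicted$ci_upper),
           single_marker_rrr = as.list(e$predicted$marker_rrr),
           subgroups = lapply(e$subgroups, function(s) {
             list(rrr = s$rrr, ci = c(s$ci_lower, s$ci_upper))
           }),
           observed = if (is.null(e$observed)) NULL else {
             e$observed[c("rrr", "ci_lower", "ci_upper", "hr")]
           })
    }))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> trial n=%d, background n=%d, m=%d imputation(s)\n",
              x$n_trial, x$n_background, x$m_imputations))
  for (e in x$endpoints) {
    cat(sprintf("  endpoint '%s': predicted RRR %.1f%% (CI %.1f to %.1f)",
                e$endpoint, e$predicted$rrr, e$predicted$ci_lower,
                e$predicted$ci_upper))
    if (!is.null(e$observed)) {
      cat(sprintf("; observed %.1f%% (CI %.1f to %.1f)", e$observed$rrr,
                  e$observed$ci_lower, e$observed$ci_upper))
    }
    cat("\n")
  }
  invisible(x)
}
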