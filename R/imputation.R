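#' Configure multiple imputation
#'
#' @param m Number of completed datasets (default 5).
#' @param k Donor pool size for predictive mean matching (default 5).
#' @param n_iter Chained-equation sweeps per imputation (default 10).
#' @param seed Integer seed.
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(m = 5L, k = 5L, n_iter = 10L, seed = 1L) {
  if (m < 1) stop("imputation_config: m must be >= 1")
  if (k < 1) stop("imputation_config: k must be >= 1")
  if (n_iter < 1) stop("imputation_config: n_iter must be >= 1")
  structure(list(m = as.integer(m), k = as.integer(k),
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "imputation_config")
}

# One PMM draw for one target variable: regress observed y on predictors,
# predict everywhere, and for each missing case copy the observed value of a
# donor drawn at random from the k observed cases with closest predictions.
pmm_step <- function(y, X, miss, k) {
  obs <- !miss
  fitdf <- data.frame(y = y[obs], X[obs, , drop = FALSE])
  fit <- lm(y ~ ., data = fitdf)
  pred_obs <- fit$fitted.values
  pred_mis <- predict(fit, newdata = data.frame(X[miss, , drop = FALSE]))
  y_obs <- y[obs]
  imputed <- vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    pool <- order(d)[seq_len(min(k, length(d)))]
    y_obs[sample(pool, 1L)]
  }, numeric(1))
  y[miss] <- imputed
  y
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' For each of `m` independent streams: missing cells are initialised by
#' random draws from the observed marginal of their column, then `n_iter`
#' sweeps visit the incomplete variables in order of ascending missingness;
#' each visit regresses the variable on all other imputation columns
#' (current completions) and replaces its missing entries by the observed
#' value of a donor sampled from the `k` cases with closest predicted means.
#' Every imputed value is therefore an observed value of its column.
#'
#' Markers listed in `log_columns` (UACR by default, matching its entry into
#' the risk model) are imputed on the log scale and back-transformed.
#'
#' @param table Tibble with `NA`s in some numeric columns.
#' @param config An [imputation_config()].
#' @param columns Columns to use in the chained system (imputed and/or used
#'   as predictors); defaults to all numeric columns except `id` and
#'   time/event columns.
#' @param log_columns Columns imputed on the log scale; defaults to all
#'   `uacr_*` columns present.
#' @return A list of `m` completed tibbles.
#' @export
impute_pmm <- function(table, config = imputation_config(),
                       columns = NULL, log_columns = NULL) {
  stopifnot(inherits(config, "imputation_config"))
  if (is.null(columns)) {
    num <- names(table)[vapply(table, is.numeric, TRUE)]
    columns <- setdiff(num, c("id", grep("^(time|event)_", num, value = TRUE)))
  }
  if (is.null(log_columns)) {
    log_columns <- grep("^uacr_", columns, value = TRUE)
  }
  work <- as.data.frame(table[columns])
  for (lc in intersect(log_columns, columns)) work[[lc]] <- log(work[[lc]])

  n_miss <- vapply(work, function(v) sum(is.na(v)), 0L)
  incomplete <- names(n_miss)[n_miss > 0]
  if (!length(incomplete)) {
    return(replicate(config$m, table, simplify = FALSE))
  }
  if (any(n_miss == nrow(work))) {
    stop("impute_pmm: all-missing column(s): ",
         paste(names(n_miss)[n_miss == nrow(work)], collapse = ", "))
  }
  if (!any(n_miss == 0)) {
    stop("impute_pmm: need at least one fully observed column")
  }
  n_obs <- nrow(work) - n_miss
  if (any(n_obs[incomplete] < config$k)) {
    stop("impute_pmm: donor pool size k exceeds observed count for: ",
         paste(incomplete[n_obs[incomplete] < config$k], collapse = ", "))
  }
  visit <- incomplete[order(n_miss[incomplete])]
  miss_idx <- lapply(work, is.na)

  lapply(seq_len(config$m), function(stream) {
    with_subseed(config$seed, paste0("pmm_", stream), {
      cur <- work
      for (v in incomplete) {  # initialise from observed marginals
        obs_vals <- cur[[v]][!miss_idx[[v]]]
        cur[[v]][miss_idx[[v]]] <- sample(obs_vals, n_miss[[v]], replace = TRUE)
      }
      for (it in seq_len(config$n_iter)) {
        for (v in visit) {
          X <- as.matrix(cur[setdiff(columns, v)])
          cur[[v]] <- pmm_step(ifelse(miss_idx[[v]], NA, work[[v]]),
                               X, miss_idx[[v]], config$k)
        }
      }
      out <- table
      for (v in columns) {
        val <- cur[[v]]
        if (v %in% log_columns) val <- exp(val)
        out[[v]] <- val
      }
      out
    })
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate is the mean of the per-dataset estimates; total variance
#' is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance.
#'
#' @param estimates Numeric vector of per-dataset point estimates.
#' @param variances Numeric vector of per-dataset squared standard errors.
#' @return List with `estimate`, `within`, `between`, `total_variance`, `se`.
#' @export
#' @examples
#' pool_estimates(c(1, 3), c(0, 0))  # pooled 2, total variance 3
pool_estimates <- function(estimates, variances) {
  m <- length(estimates)
  if (m < 2) stop("pool_estimates: need m >= 2 imputations")
  if (length(variances) != m) {
    stop("pool_estimates: estimates and variances differ in length")
  }
  qbar <- mean(estimates)
  within <- mean(variances)
  between <- var(estimates)
  list(estimate = qbar, within = within, between = between,
       total_variance = within + (1 + 1 / m) * between,
       se = sqrt(within + (1 + 1 / m) * between))
}
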