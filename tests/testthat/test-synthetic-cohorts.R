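test_that("generation is byte-identical under the same seed", {
  cfg <- cohort_config(300, c(2, 1), seed = 7)
  t1 <- generate_trial(cfg, empagliflozin_effect_profile(), default_cv_outcome())
  t2 <- generate_trial(cfg, empagliflozin_effect_profile(), default_cv_outcome())
  expect_identical(t1, t2)
  cfg2 <- cohort_config(300, c(2, 1), seed = 8)
  t3 <- generate_trial(cfg2, empagliflozin_effect_profile(), default_cv_outcome())
  expect_false(identical(t1$hba1c_base, t3$hba1c_base))

  bcfg <- cohort_config(400, c(0, 1), background_marker_specs(), seed = 7)
  expect_identical(generate_background(bcfg, default_cv_outcome()),
                   generate_background(bcfg, default_cv_outcome()))
})

test_that("baseline marginals are calibrated to the marker specs", {
  tr <- fx_trial()
  n <- nrow(tr)
  for (nm in c("hba1c", "sbp", "hemoglobin", "weight", "uric_acid")) {
    s <- empareg_marker_specs()[[nm]]
    x <- tr[[paste0(nm, "_base")]]
    expect_lt(abs(mean(x) - s$location), 3 * s$scale / sqrt(n))
    expect_lt(abs(sd(x) - s$scale), 3 * s$scale / sqrt(2 * n))
  }
  # log-normal UACR: median and elevated-albuminuria fraction
  u <- tr$uacr_base
  s <- empareg_marker_specs()$uacr
  expect_lt(abs(median(log(u)) - log(17.7)), 3 * 1.2533 * s$scale / sqrt(n))
  p30 <- 1 - pnorm((log(30) - s$location) / s$scale)  # analytic ~0.402
  expect_equal(p30, 0.402, tolerance = 0.002)
  expect_lt(abs(mean(u >= 30) - p30), 3 * sqrt(p30 * (1 - p30) / n))
})

test_that("background event fraction matches the configured target", {
  bg <- fx_background()
  p <- mean(bg$event_cv)
  expect_lt(abs(p - 0.125), 3 * sqrt(0.125 * 0.875 / nrow(bg)) + 0.005)
  kcfg <- cohort_config(6355, c(0, 1), background_marker_specs(), seed = 31)
  bgk <- generate_background(kcfg, default_kidney_outcome())
  expect_lt(abs(mean(bgk$event_kidney) - 0.178),
            3 * sqrt(0.178 * 0.822 / 6355) + 0.005)
})

test_that("null coefficients make event times independent of markers", {
  specs <- toy_specs()
  cfg <- cohort_config(4000, c(0, 1), specs, diag(2), seed = 5)
  oc <- outcome_config("toy", c(a = 0, log_uacr = 0), lambda0 = 0.1,
                       followup_years = 50)
  bg <- generate_background(cfg, oc)
  expect_lt(abs(cor(bg$time_toy, bg$a_base)), 3 / sqrt(4000))
  expect_lt(abs(cor(bg$time_toy, log(bg$uacr_base))), 3 / sqrt(4000))
})

test_that("a log-2 hazard coefficient doubles the empirical event rate", {
  # binary covariate, beta = ln 2, no censoring: exponential group rates
  # differ by exactly 2, so the mean event times have ratio 2
  set.seed(99)
  lp <- c(rep(0, 5000), rep(log(2), 5000))
  oc <- outcome_config("x", c(z = log(2)), lambda0 = 0.05,
                       followup_years = Inf)
  d <- with(prescore:::draw_outcome(lp, oc), data.frame(time, event))
  expect_true(all(d$event == 1))
  hr <- mean(d$time[1:5000]) / mean(d$time[5001:10000])
  expect_equal(hr, 2, tolerance = 0.1)
  expect_equal(1 / mean(d$time[1:5000]), 0.05, tolerance = 0.05 * 0.05)
})

test_that("trial generator reproduces the configured treatment effects", {
  tr <- fx_trial()
  mc <- marker_change_table(tr)
  n_eff <- 1 / (1 / sum(tr$arm == "treated") + 1 / sum(tr$arm == "placebo"))
  prof <- empagliflozin_effect_profile()
  for (nm in c("hba1c", "sbp", "hemoglobin", "weight", "uric_acid")) {
    row <- mc[mc$marker == nm, ]
    se <- prof$change_sd[[nm]] / sqrt(n_eff)
    expect_lt(abs(row$placebo_corrected - prof$effects[[nm]]), 3.5 * se)
  }
  # UACR: -13% multiplicative effect means log-change difference ln(0.87)
  row <- mc[mc$marker == "uacr", ]
  expect_lt(abs(row$placebo_corrected - log(0.87)),
            3.5 * prof$change_sd[["uacr"]] / sqrt(n_eff))
})

test_that("a null effect profile gives null changes and hazard ratio 1", {
  cfg <- cohort_config(7020, c(2, 1), seed = 77)
  tr <- generate_trial(cfg, null_effect_profile(), default_cv_outcome())
  mc <- marker_change_table(tr)
  expect_true(all(abs(mc$placebo_corrected / mc$se) < 3.5))
  obs <- observed_rrr(tr, "cv")
  expect_lt(abs(log(obs$hr)), 3 * obs$log_hr_se)
})

test_that("effects for unknown markers are rejected by name", {
  cfg <- cohort_config(50, c(2, 1), seed = 1)
  bad <- effect_profile(c(banana = 1), change_sd = c(banana = 1))
  expect_error(generate_trial(cfg, bad), "banana")
})

test_that("non-PSD or malformed correlation matrices are rejected", {
  specs <- toy_specs()
  R <- matrix(c(1, 2, 2, 1), 2)  # correlation > 1 => not PSD
  expect_error(cohort_config(10, c(1, 1), specs, R, seed = 1),
               "positive semi-definite")
  R2 <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(cohort_config(10, c(1, 1), specs, R2, seed = 1), "symmetric")
})

test_that("true_rrr oracle: null effects give zero, scaling is monotone", {
  specs <- toy_specs()
  cfg <- cohort_config(100, c(2, 1), specs, diag(2), seed = 3)
  oc <- toy_outcome()
  null_p <- effect_profile(c(a = 0, uacr = 0), change_sd = c(a = 1, uacr = 0.5))
  expect_equal(true_rrr(cfg, null_p, oc, horizon = 2, n_mc = 20000)$rrr, 0,
               tolerance = 1e-9)
  p1 <- effect_profile(c(a = -0.5, uacr = -10),
                       change_sd = c(a = 1, uacr = 0.5))
  p2 <- effect_profile(c(a = -1.0, uacr = -20),
                       change_sd = c(a = 1, uacr = 0.5))
  r1 <- true_rrr(cfg, p1, oc, horizon = 2, n_mc = 50000)$rrr
  r2 <- true_rrr(cfg, p2, oc, horizon = 2, n_mc = 50000)$rrr
  expect_gt(r1, 0)
  expect_gt(r2, r1)
  expect_error(true_rrr(cfg, p1, oc, horizon = 10), "horizon")
})

test_that("true_rrr matches the rare-event closed form for a uniform shift", {
  specs <- list(a = marker_spec("a", "u", "normal", 0, 1, +1))
  cfg <- cohort_config(100, c(1, 1), specs, diag(1), seed = 4)
  oc <- outcome_config("toy", c(a = 0.3), lambda0 = 0.001, followup_years = 1)
  prof <- effect_profile(c(a = -0.8), change_sd = c(a = 0.3))
  r <- true_rrr(cfg, prof, oc, horizon = 1, n_mc = 200000)$rrr
  expect_equal(r, 100 * (1 - exp(0.3 * -0.8)), tolerance = 0.5)
})

test_that("missingness injection hits target rates and respects mechanisms", {
  tr <- head(fx_trial(), 7020)
  # zero proportion: identical table
  mc0 <- missingness_config("MCAR", c(hba1c = 0), seed = 9)
  expect_identical(inject_missingness(tr, mc0), tr)
  # MCAR 0.2: realized fraction within binomial 3 sigma
  mc1 <- missingness_config("MCAR", c(hba1c = 0.2), seed = 9)
  out <- inject_missingness(tr, mc1)
  f <- mean(is.na(out$hba1c_m6))
  expect_lt(abs(f - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(tr)))
  expect_false(anyNA(out$hba1c_base))      # only m6 targeted by default
  expect_false(anyNA(out$time_cv))         # outcomes never blanked
  expect_false(anyNA(out$event_cv))
  # MAR on age: missingness increases across age tertiles
  mc2 <- missingness_config("MAR", c(sbp = 0.3), mar_covariate = "age",
                            seed = 9)
  out2 <- inject_missingness(tr, mc2)
  ter <- cut(tr$age, quantile(tr$age, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = FALSE)
  rates <- tapply(is.na(out2$sbp_m6), ter, mean)
  expect_lt(rates[1], rates[3])
  expect_lt(abs(mean(is.na(out2$sbp_m6)) - 0.3),
            3 * sqrt(0.3 * 0.7 / nrow(tr)))
  # MAR without its covariate is an error
  mc3 <- missingness_config("MAR", c(sbp = 0.3), mar_covariate = "nope")
  expect_error(inject_missingness(tr, mc3), "nope")
})

test_that("cohort CSV round trip preserves values and blanks", {
  tr <- head(fx_trial(), 50)
  tr$hba1c_m6[c(3, 7)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(tr, path)
  back <- read_cohort_csv(path)
  expect_equal(back$sbp_base, tr$sbp_base, tolerance = 1e-12)
  expect_true(all(is.na(back$hba1c_m6[c(3, 7)])))
  expect_equal(back$arm, tr$arm)
})
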