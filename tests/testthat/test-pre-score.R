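test_that("mean arm risk is computable by hand on a 3-patient table", {
  m <- manual_model(b = 0.3, s0T = 0.95, horizon = 1)
  tr <- tiny_trial(base_t = c(0, 1, 2), m6_t = c(0, 0, 0),
                   base_p = c(0, 1), m6_p = c(0, 1))
  expected <- mean(1 - 0.95^exp(0.3 * c(0, 1, 2)))
  expect_equal(mean_arm_risk(m, tr, "treated", "base"), expected,
               tolerance = 1e-12)
  # month-6 identical to baseline => identical mean risks
  expect_equal(mean_arm_risk(m, tr, "placebo", "base"),
               mean_arm_risk(m, tr, "placebo", "m6"))
  # uniform reduction of a harmful marker lowers risk
  expect_lt(mean_arm_risk(m, tr, "treated", "m6"),
            mean_arm_risk(m, tr, "treated", "base"))
  expect_error(mean_arm_risk(m, tr[tr$arm == "treated", ], "placebo"),
               "empty")
})

test_that("no treatment contrast gives zero RRR under both forms", {
  m <- manual_model()
  bt <- rnorm(40); bp <- rnorm(30)
  tr <- tiny_trial(base_t = bt, m6_t = bt, base_p = bp, m6_p = bp)
  for (form in c("ratio_of_ratios", "adjusted_difference")) {
    cfg <- score_config(rrr_form = form, seed = 2)
    expect_equal(compute_pre_rrr(m, tr, cfg, ci = FALSE)$rrr, 0,
                 tolerance = 1e-12)
  }
  # identical change *distributions* in both arms: RRR ~ 0
  set.seed(40)
  base <- rnorm(4000); chg <- rnorm(4000, -0.3, 0.2)
  tr2 <- tiny_trial(base_t = base[1:2000], m6_t = (base + chg)[1:2000],
                    base_p = base[2001:4000], m6_p = (base + chg)[2001:4000])
  r2 <- compute_pre_rrr(m, tr2, score_config(seed = 2), ci = FALSE)$rrr
  expect_lt(abs(r2), 1.0)
})

test_that("rare-event uniform shift reproduces the closed-form RRR", {
  b <- 0.3; delta <- -0.8
  m <- manual_model(b = b, s0T = 0.999, horizon = 1)
  set.seed(8)
  base <- rnorm(6000)
  tr <- tiny_trial(base_t = base[1:4000], m6_t = base[1:4000] + delta,
                   base_p = base[4001:6000], m6_p = base[4001:6000])
  r <- compute_pre_rrr(m, tr, score_config(seed = 3), ci = FALSE)$rrr
  expect_equal(r, 100 * (1 - exp(b * delta)), tolerance = 0.01)
})

test_that("the two RRR forms agree to first order when risks are small", {
  m <- manual_model(b = 0.3, s0T = 0.999)
  set.seed(9)
  base <- rnorm(3000)
  score <- function(m6_shift_t, m6_shift_p, form) {
    tr <- tiny_trial(base_t = base[1:2000], m6_t = base[1:2000] + m6_shift_t,
                     base_p = base[2001:3000],
                     m6_p = base[2001:3000] + m6_shift_p)
    compute_pre_rrr(m, tr, score_config(rrr_form = form, seed = 1),
                    ci = FALSE)$rrr
  }
  # moderate effects: divergence is second order in the effect size
  r1 <- score(-0.5, -0.1, "ratio_of_ratios")
  r2 <- score(-0.5, -0.1, "adjusted_difference")
  expect_equal(r1, r2, tolerance = 0.05)
  # small effects: near-exact agreement
  s1 <- score(-0.05, -0.01, "ratio_of_ratios")
  s2 <- score(-0.05, -0.01, "adjusted_difference")
  expect_equal(s1, s2, tolerance = 0.005)
  # divergence shrinks with the effect size
  expect_lt(abs(s1 - s2) / abs(s1), abs(r1 - r2) / abs(r1))
})

test_that("predicted RRR recovers the generator oracle", {
  model <- fx_cv_model()
  tr <- fx_trial()
  cfg <- score_config(seed = 6)
  res <- compute_pre_rrr(model, tr, cfg)
  tcfg <- cohort_config(7020, c(2, 1), seed = 2025)
  oracle <- true_rrr(tcfg, empagliflozin_effect_profile(),
                     default_cv_outcome(), horizon = model$horizon,
                     n_mc = 100000)
  se_pred <- sd(ci_resample(model, tr, cfg)$draws)
  expect_lt(abs(res$rrr - oracle$rrr),
            3 * sqrt(se_pred^2 + oracle$se^2 + 1))
})

test_that("single-marker attribution isolates each marker's contribution", {
  m <- manual_model(b = 0.3, s0T = 0.99)
  m$specs <- list(a = marker_spec("a", "u", "normal", 0, 1, +1),
                  b = marker_spec("b", "u", "normal", 0, 1, +1))
  m$coef <- c(a = 0.3, b = 0.2); m$se <- c(a = 0.05, b = 0.05)
  m$center <- c(a = 0, b = 0)
  set.seed(10)
  base_a <- rnorm(3000); base_b <- rnorm(3000)
  tr <- tibble::tibble(
    id = 1:3000, arm = rep(c("treated", "placebo"), c(2000, 1000)),
    a_base = base_a, a_m6 = base_a + ifelse(seq_len(3000) <= 2000, -0.5, 0),
    b_base = base_b, b_m6 = base_b)  # b unchanged in both arms
  cfg <- score_config(seed = 4)
  full <- compute_pre_rrr(m, tr, cfg, ci = FALSE)$rrr
  only_a <- single_marker_rrr(m, tr, "a", cfg, ci = FALSE)$rrr
  only_b <- single_marker_rrr(m, tr, "b", cfg, ci = FALSE)$rrr
  expect_equal(only_b, 0, tolerance = 1e-10)
  expect_equal(only_a, full, tolerance = 1e-10)
  expect_error(single_marker_rrr(m, tr, "zz", cfg), "unknown marker")
})

test_that("single-marker log relative risks decompose multiplicatively", {
  # uniform shifts, rare events: sum of single-marker log RRs ~ full log RR
  m <- manual_model(s0T = 0.999)
  m$specs <- list(a = marker_spec("a", "u", "normal", 0, 1, +1),
                  b = marker_spec("b", "u", "normal", 0, 1, +1))
  m$coef <- c(a = 0.3, b = -0.2); m$se <- c(a = 0.05, b = 0.05)
  m$center <- c(a = 0, b = 0)
  set.seed(11)
  n <- 4000; tre <- seq_len(n) <= 2 * n / 3
  tr <- tibble::tibble(
    id = 1:n, arm = ifelse(tre, "treated", "placebo"),
    a_base = rnorm(n), b_base = rnorm(n))
  tr$a_m6 <- tr$a_base + ifelse(tre, -0.4, 0)
  tr$b_m6 <- tr$b_base + ifelse(tre, 0.6, 0)
  cfg <- score_config(seed = 4)
  lrr <- function(r) log(1 - r / 100)
  full <- lrr(compute_pre_rrr(m, tr, cfg, ci = FALSE)$rrr)
  parts <- lrr(single_marker_rrr(m, tr, "a", cfg, ci = FALSE)$rrr) +
    lrr(single_marker_rrr(m, tr, "b", cfg, ci = FALSE)$rrr)
  expect_equal(full, parts, tolerance = 0.01)
})

test_that("coefficient-resampling CI behaves like a parametric bootstrap", {
  m <- manual_model(b = 0.3, s0T = 0.95)
  set.seed(12)
  base <- rnorm(900)
  tr <- tiny_trial(base_t = base[1:600], m6_t = base[1:600] - 0.5,
                   base_p = base[601:900], m6_p = base[601:900])
  cfg <- score_config(n_draws = 100, seed = 13)
  # zero SEs: the CI collapses onto the point estimate
  m0 <- m; m0$se[] <- 0
  ci0 <- ci_resample(m0, tr, cfg)
  pt <- compute_pre_rrr(m0, tr, cfg, ci = FALSE)$rrr
  expect_equal(ci0$lower, pt, tolerance = 1e-12)
  expect_equal(ci0$upper, pt, tolerance = 1e-12)
  # doubling SEs cannot shrink the interval (same seed, same draws)
  ci1 <- ci_resample(m, tr, cfg)
  m2 <- m; m2$se <- 2 * m$se
  ci2 <- ci_resample(m2, tr, cfg)
  expect_gte(ci2$upper - ci2$lower, ci1$upper - ci1$lower)
  expect_error(score_config(n_draws = 1), "n_draws")
})

test_that("resampling CIs cover the null when the coefficient is null", {
  # the CI reflects coefficient uncertainty only, so it straddles zero
  # exactly when the coefficient draws do; with a marker unrelated to the
  # outcome the fitted coefficient is null and coverage is ~nominal
  specs <- list(a = marker_spec("a", "u", "normal", 0, 1, +1))
  covered <- vapply(1:20, function(i) {
    cfg <- cohort_config(600, c(0, 1), specs, diag(1), seed = 500 + i)
    oc <- outcome_config("toy", c(a = 0), lambda0 = 0.1, followup_years = 3)
    bg <- generate_background(cfg, oc)
    model <- risk_model(fit_cox(bg, "toy", specs), specs)
    set.seed(700 + i)
    base <- rnorm(400); chg <- rnorm(400, -0.2, 0.3)
    tr <- tiny_trial(base_t = base[1:250], m6_t = (base + chg)[1:250],
                     base_p = base[251:400], m6_p = (base + chg)[251:400])
    res <- compute_pre_rrr(model, tr, score_config(seed = i))
    res$ci_lower <= 0 && 0 <= res$ci_upper
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("observed RRR recovers the generating hazard ratio", {
  tr <- fx_trial()
  obs <- observed_rrr(tr, "cv")
  oracle <- true_rrr(cohort_config(7020, c(2, 1), seed = 2025),
                     empagliflozin_effect_profile(), default_cv_outcome(),
                     n_mc = 100000)
  true_hr <- 1 - oracle$rrr / 100    # rare-ish events: RR ~ HR
  expect_lt(abs(log(obs$hr) - log(true_hr)), 3 * obs$log_hr_se + 0.03)
  # permuting arm labels flips the sign of the log relative risk
  flip <- tr
  flip$arm <- ifelse(tr$arm == "treated", "placebo", "treated")
  obs_f <- observed_rrr(flip, "cv")
  expect_equal(log(1 - obs_f$rrr / 100), -log(1 - obs$rrr / 100),
               tolerance = 1e-8)
  none <- tr; none$event_cv[none$arm == "placebo"] <- 0
  expect_error(observed_rrr(none, "cv"), "zero events")
})

test_that("RRR is invariant to affine rescaling of a marker's units", {
  bspecs <- toy_specs()
  bg <- toy_background(n = 3000, seed = 61)
  tre <- rep(c("treated", "placebo"), c(1200, 600))
  set.seed(62)
  ab <- rnorm(1800); ub <- exp(log(20) + rnorm(1800))
  tr <- tibble::tibble(
    id = 1:1800, arm = tre,
    a_base = ab, a_m6 = ab + ifelse(tre == "treated", -0.4, -0.1) + rnorm(1800, 0, 0.2),
    uacr_base = ub, uacr_m6 = ub * exp(ifelse(tre == "treated", -0.2, 0)))
  score_it <- function(bg, tr, specs) {
    fit <- fit_cox(bg, "toy", specs)
    compute_pre_rrr(risk_model(fit, specs), tr,
                    score_config(seed = 5), ci = FALSE)$rrr
  }
  r1 <- score_it(bg, tr, bspecs)
  # rescale marker "a" by 1000 (e.g. kg -> g) everywhere and refit
  bg2 <- bg; bg2$a_base <- 1000 * bg$a_base
  tr2 <- tr; tr2$a_base <- 1000 * tr$a_base; tr2$a_m6 <- 1000 * tr$a_m6
  specs2 <- bspecs
  specs2$a <- marker_spec("a", "u", "normal", 0, 1000, +1)
  r2 <- score_it(bg2, tr2, specs2)
  expect_equal(r1, r2, tolerance = 1e-6)
})
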