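test_that("fir_proportions computes arm and pooled fractions", {
  rec <- records_from_counts(fir_prp = 108, n_prp = 578,
                             fir_soc = 49, n_soc = 251)
  props <- fir_proportions(rec)
  expect_equal(props$proportion[props$arm == "PRP"], 108 / 578)
  expect_equal(props$proportion[props$arm == "SOC"], 49 / 251)
  expect_equal(props$proportion[props$arm == "pooled"], 157 / 829)

  none <- records_from_counts(0, 50, 0, 30)
  expect_true(all(fir_proportions(none)$proportion == 0))

  single <- tibble::tibble(arm = rep("PRP", 10), fir = rbinom(10, 1, 0.5))
  expect_error(fir_proportions(single), "both a PRP and a SOC arm")
})

test_that("odds_ratio_2x2 matches the closed form and handles zero cells", {
  or <- odds_ratio_2x2(108, 470, 49, 202)
  expect_equal(or$estimate, (108 * 202) / (470 * 49), tolerance = 1e-12)
  se <- sqrt(1 / 108 + 1 / 470 + 1 / 49 + 1 / 202)
  expect_equal(or$conf.low, exp(log(or$estimate) - qnorm(0.975) * se))
  expect_equal(or$conf.high, exp(log(or$estimate) + qnorm(0.975) * se))

  expect_equal(odds_ratio_2x2(10, 10, 10, 10)$estimate, 1)

  expect_warning(corr <- odds_ratio_2x2(0, 10, 5, 5), "Haldane")
  expect_equal(corr$estimate, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(odds_ratio_2x2(0, 10, 5, 5, haldane = FALSE), "zero cell")
  expect_error(odds_ratio_2x2(-1, 10, 5, 5), "non-negative")
})

test_that("OR(PRP vs SOC) x OR(SOC vs PRP) = 1 and CIs shrink with counts", {
  a <- 108; b <- 470; c <- 49; d <- 202
  forward <- odds_ratio_2x2(a, b, c, d)
  backward <- odds_ratio_2x2(c, d, a, b)
  expect_equal(forward$estimate * backward$estimate, 1, tolerance = 1e-12)

  widths <- vapply(c(1, 2, 4), function(k) {
    o <- odds_ratio_2x2(k * a, k * b, k * c, k * d)
    log(o$conf.high) - log(o$conf.low)
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("crude_or reproduces the 2x2 arithmetic from records", {
  rec <- records_from_counts(108, 578, 49, 251)
  out <- crude_or(rec)
  expect_equal(c(out$a, out$b, out$c, out$d), c(108, 470, 49, 202))
  expect_equal(out$estimate, 0.9472862, tolerance = 1e-6)
})

test_that("logistic arm-only fit equals the crude odds ratio exactly", {
  rec <- records_from_counts(108, 578, 49, 251)
  fit <- fit_fir_logistic(rec, adjusted = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$odds_ratios[["arm_prp"]]),
               crude_or(rec)$estimate, tolerance = 1e-6)
  # Wald SEs agree with the 1/a+1/b+1/c+1/d formula in the saturated model
  expect_equal(unname(fit$std_errors[["arm_prp"]]),
               crude_or(rec)$se_log_or, tolerance = 1e-6)
})

test_that("intercept-only fit recovers the logit of the prevalence", {
  y <- c(rep(1L, 19), rep(0L, 81))
  fit <- logistic_fit(y, design = NULL)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), qlogis(0.19),
               tolerance = 1e-6)
})

test_that("logistic_fit validates its inputs and flags separation", {
  y <- rbinom(50, 1, 0.5)
  constant <- cbind(x = rep(1, 50))
  expect_error(logistic_fit(y, constant), "zero-variance")
  expect_error(logistic_fit(c(0, 1, 2), cbind(x = 1:3)), "binary")

  # perfectly separated covariate
  ysep <- c(rep(0L, 25), rep(1L, 25))
  xsep <- cbind(x = c(rep(0, 25), rep(1, 25)))
  expect_warning(fsep <- logistic_fit(ysep, xsep), "separation")
  expect_false(fsep$converged)
})

test_that("tidy and glance expose the fit; CI bounds bracket the OR", {
  cohort <- generate_cohort(cohort_config(seed = 21))
  fit <- fit_fir_logistic(cohort)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "odds.ratio", "conf.low",
                    "conf.high", "p.value") %in% names(td)))
  expect_true(all(td$conf.low <= td$odds.ratio &
                    td$odds.ratio <= td$conf.high))
  expect_equal(td$odds.ratio, exp(td$estimate))
  gl <- glance(fit)
  expect_equal(gl$n_used, nrow(cohort))
  expect_true(gl$converged)
})

test_that("records with missing adherence are dropped from the fit", {
  cohort <- generate_cohort(cohort_config(seed = 31,
                                          adherence_missing_frac = 0.05))
  fit <- fit_fir_logistic(cohort)
  expect_equal(fit$n_used, sum(!is.na(cohort$adherence_optimal)))
})
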