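test_that("generation is reproducible and respects arm sizes", {
  cfg <- cohort_config(n_prp = 300, n_soc = 150, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(sum(a$arm == "PRP"), 300)
  expect_equal(sum(a$arm == "SOC"), 150)
  c2 <- generate_cohort(cohort_config(n_prp = 300, n_soc = 150, seed = 43))
  expect_false(identical(a, c2))
})

test_that("fir is recomputed from the follow-up CD4 count", {
  cohort <- generate_cohort(cohort_config(n_prp = 500, n_soc = 200, seed = 7))
  expect_identical(cohort$fir, as.integer(cohort$cd4_followup > 500))
  expect_true(all(cohort$cd4_followup >= 0))
  expect_true(all(cohort$cd4_art_start >= 0))
  expect_true(all(cohort$age_years > 0))
})

test_that("continuous covariate moments match the truncated-normal oracle at n = 10,000", {
  # selection off so arm moments are unconditional
  cfg <- cohort_config(n_prp = 10000, n_soc = 10000, seed = 101,
                       constrain_prp = FALSE)
  cohort <- generate_cohort(cfg)
  for (arm in c("PRP", "SOC")) {
    sub <- cohort[cohort$arm == arm, ]
    for (v in c("age_years", "art_duration_months", "cd4_baseline",
                "followup_months")) {
      spec <- cfg$continuous[cfg$continuous$variable == v &
                               cfg$continuous$arm == arm, ]
      oracle <- truncnorm_moments(spec$mean, spec$sd, spec$min)
      se <- oracle[["sd"]] / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[v]]) - oracle[["mean"]]), 3 * se)
    }
  }
})

test_that("categorical frequencies converge to the configured values", {
  cfg <- cohort_config(n_prp = 10000, n_soc = 10000, seed = 202,
                       constrain_prp = FALSE)
  cohort <- generate_cohort(cfg)
  for (arm in c("PRP", "SOC")) {
    sub <- cohort[cohort$arm == arm, ]
    spec <- cfg$categorical
    f_female <- spec$freq[spec$variable == "gender" & spec$arm == arm &
                            spec$level == "female"]
    se <- sqrt(f_female * (1 - f_female) / nrow(sub))
    expect_lt(abs(mean(sub$gender == "female") - f_female), 3 * se)
    f_oi <- spec$freq[spec$variable == "oi_baseline" & spec$arm == arm]
    se <- sqrt(f_oi * (1 - f_oi) / nrow(sub))
    expect_lt(abs(mean(sub$oi_baseline) - f_oi), 3 * se)
  }
})

test_that("arm-level FIR prevalence matches the logistic model's implied marginal", {
  cfg <- cohort_config(n_prp = 20000, n_soc = 20000, seed = 303,
                       constrain_prp = FALSE)
  cohort <- generate_cohort(cfg)
  # oracle: average model probability over an independent covariate draw
  oracle_cfg <- cohort_config(n_prp = 20000, n_soc = 20000, seed = 904,
                              constrain_prp = FALSE)
  oracle <- generate_cohort(oracle_cfg)
  lp <- refillcea:::fir_linear_predictor(oracle,
                                         cfg$outcome_coefficients)
  for (arm in c("PRP", "SOC")) {
    implied <- mean(plogis(lp[oracle$arm == arm]))
    observed <- mean(cohort$fir[cohort$arm == arm])
    se <- sqrt(implied * (1 - implied) / sum(cohort$arm == arm)) +
      sqrt(implied * (1 - implied) / sum(oracle$arm == arm))
    expect_lt(abs(observed - implied), 3 * se)
  }
})

test_that("an intercept-only outcome model yields the intercept's prevalence", {
  beta <- c(intercept = qlogis(0.19), arm_prp = 0)
  cfg <- cohort_config(n_prp = 20000, n_soc = 10000, seed = 11,
                       outcome_coefficients = beta, constrain_prp = FALSE)
  cohort <- generate_cohort(cfg)
  pooled <- fir_proportions(cohort)$proportion[3]
  expect_lt(abs(pooled - 0.19), 3 * sqrt(0.19 * 0.81 / 30000))
})

test_that("selection constrains the PRP arm to eligible records", {
  cohort <- generate_cohort(cohort_config(n_prp = 800, n_soc = 300,
                                          seed = 5))
  flagged <- apply_prp_eligibility(cohort)
  expect_true(all(flagged$eligible_prp[flagged$arm == "PRP"]))
  # SOC is not constrained: with these covariates some SOC members fail
  expect_true(any(!flagged$eligible_prp[flagged$arm == "SOC"]))
})

test_that("eligibility thresholds behave at the boundaries", {
  rec <- tibble::tibble(
    arm = "SOC",
    cd4_baseline = c(150, 250, 250, 250),
    art_duration_months = c(24, 24, 6, 24),
    adherence_optimal = c(1L, 1L, 1L, 0L)
  )
  out <- apply_prp_eligibility(rec)
  expect_identical(out$eligible_prp, c(FALSE, TRUE, FALSE, FALSE))
  # latent unobservable criteria exclude everyone at pass probability 0
  none <- apply_prp_eligibility(rec, latent_pass_prob = 0, seed = 1)
  expect_false(any(none$eligible_prp))
})

test_that("invalid configurations are rejected", {
  bad_cat <- default_categorical()
  bad_cat$freq[bad_cat$variable == "gender" & bad_cat$level == "male"] <- 0.9
  expect_error(cohort_config(categorical = bad_cat), "sum to 1")
  expect_error(cohort_config(outcome_coefficients = c(intercept = 0)),
               "arm_prp")
})

test_that("adherence masking produces missing values at the requested rate", {
  cfg <- cohort_config(n_prp = 5000, n_soc = 2000, seed = 8,
                       adherence_missing_frac = 22 / 829)
  cohort <- generate_cohort(cfg)
  frac <- mean(is.na(cohort$adherence_optimal))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.05)
})
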