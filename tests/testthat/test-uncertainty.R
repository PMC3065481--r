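test_that("se_from_range treats the range as a 95% CI", {
  expect_equal(se_from_range(0.1568, 0.2352),
               0.0784 / (2 * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(se_from_range(0.1568, 0.2352), 0.02, tolerance = 1e-4)
  expect_equal(se_from_range(121.5, 486), 364.5 / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  # translation invariance
  expect_equal(se_from_range(10, 20), se_from_range(110, 120))
  expect_error(se_from_range(2, 2), "exceed")
  expect_error(se_from_range(3, 2), "exceed")
})

test_that("fit_beta moment-matches and enforces its variance constraint", {
  p <- fit_beta(0.196, 0.02)
  expect_equal(unname(p), c(77.02016, 315.93984), tolerance = 1e-6)
  # fitted mean and sd equal the inputs exactly (moment identities)
  expect_equal(p[["alpha"]] / sum(p), 0.196, tolerance = 1e-12)
  expect_equal(sqrt(prod(p) / (sum(p)^2 * (sum(p) + 1))), 0.02,
               tolerance = 1e-9)

  sym <- fit_beta(0.5, 0.1)
  expect_equal(sym[["alpha"]], sym[["beta"]])

  expect_error(fit_beta(0.5, 0.6), "variance too large")
  expect_error(fit_beta(1.2, 0.1), "in \\(0, 1\\)")
})

test_that("fit_gamma moment-matches with shape*scale = mean exactly", {
  se <- se_from_range(121.5, 486)
  g <- fit_gamma(243, se)
  expect_equal(unname(g), c(243^2 / se^2, se^2 / 243), tolerance = 1e-12)
  expect_equal(g[["shape"]] * g[["scale"]], 243, tolerance = 1e-12)
  expect_equal(fit_gamma(243, 243)[["shape"]], 1)  # exponential limit
  expect_error(fit_gamma(-1, 2), "positive")
})

test_that("ranges follow the halved/doubled and +/-20% rules", {
  params <- build_uncertain_params(quiet_model())
  art <- params[params$name == "cost_art", ]
  expect_equal(c(art$low, art$high), c(121.5, 486))
  expect_equal(art$arm, "both")
  p_soc <- params[params$name == "p_fir_SOC", ]
  expect_equal(c(p_soc$low, p_soc$high), c(0.1568, 0.2352))
  expect_equal(p_soc$dist, "beta")
  expect_true(all(params$dist[params$role == "cost"] == "gamma"))
  expect_true(all(params$low <= params$mean & params$mean <= params$high))
  expect_true(all(params$se > 0))

  # probability ranges are capped at 1
  high_p <- quiet_model()
  high_p$comparator$p_fir <- 0.9
  capped <- build_uncertain_params(high_p)
  expect_equal(capped$high[capped$name == "p_fir_SOC"], 1)

  # zero-valued costs are excluded with a warning
  zero_model <- quiet_model()
  zero_model$comparator$costs$category_costs[["radiology"]] <- 0
  zero_model$intervention$costs$category_costs[["radiology"]] <- 0
  expect_warning(pz <- build_uncertain_params(zero_model), "zero-valued")
  expect_false(any(grepl("radiology", pz$name)))
})

test_that("arm-specific and shared parameters are classified by value equality", {
  params <- build_uncertain_params(quiet_model(), include_residual = TRUE)
  shared <- params$category[params$arm == "both"]
  expect_setequal(shared, c("art", "other_drugs", "radiology", "laboratory",
                            "overhead_capital", "transport"))
  specific <- unique(params$category[params$arm %in% c("SOC", "PRP") &
                                       params$role == "cost"])
  expect_setequal(specific, c("personnel", "lost_patient_time", "residual"))
  # MoH perspective drops the direct non-medical categories
  moh <- build_uncertain_params(quiet_model(), perspective = "moh",
                                include_residual = TRUE)
  expect_false(any(moh$category %in% c("transport", "lost_patient_time"),
                   na.rm = TRUE))
})

test_that("every fitted distribution reproduces its mean and SE in sample moments", {
  params <- build_uncertain_params(quiet_model(), include_residual = TRUE)
  withr::local_seed(99)
  for (i in seq_len(nrow(params))) {
    draws <- if (params$dist[i] == "beta") {
      rbeta(1e6, params$par1[i], params$par2[i])
    } else {
      rgamma(1e6, shape = params$par1[i], scale = params$par2[i])
    }
    expect_lt(abs(mean(draws) - params$mean[i]) / params$mean[i], 0.005)
    expect_lt(abs(stats::sd(draws) - params$se[i]) / params$se[i], 0.005)
  }
})

test_that("tornado: shared parameters cancel in the cost difference, p_fir never moves it", {
  model <- quiet_model()
  torn_cost <- one_way(model, target = "delta_cost")
  expect_equal(torn_cost$outcome_base[1], -135)
  expect_true(all(diff(torn_cost$swing) <= 0))  # sorted by swing
  shared <- grepl("^cost_(art|other_drugs|radiology|laboratory|overhead_capital|transport)$",
                  torn_cost$parameter)
  expect_true(all(torn_cost$swing[shared] == 0))
  expect_true(all(torn_cost$swing[grepl("^p_fir", torn_cost$parameter)] == 0))

  torn_eff <- one_way(model, target = "delta_effect")
  expect_true(all(torn_eff$swing[!grepl("^p_fir", torn_eff$parameter)] == 0))
  expect_true(all(torn_eff$swing[grepl("^p_fir", torn_eff$parameter)] > 0))
})

test_that("tornado with independent per-arm costs is most sensitive to ART cost", {
  model <- quiet_model()
  params <- build_uncertain_params(model, shared = FALSE,
                                   include_residual = TRUE)
  torn <- one_way(model, target = "delta_cost", params = params)
  expect_match(torn$parameter[1], "^cost_art_")
  expect_equal(torn$swing[1], 364.5)

  # arm-total mode: the largest swing is an arm total
  totals <- build_uncertain_params(model, component_mode = "total")
  torn_tot <- one_way(model, target = "delta_cost", params = totals)
  expect_match(torn_tot$parameter[1], "^total_cost_")
})

test_that("PSA is reproducible, unbiased for the increments, and respects base offsets", {
  model <- quiet_model()
  d1 <- run_psa(model, n_iter = 4000, seed = 77)
  d2 <- run_psa(model, n_iter = 4000, seed = 77)
  expect_identical(d1, d2)
  d3 <- run_psa(model, n_iter = 4000, seed = 78)
  expect_false(identical(d1, d3))

  # increments equal per-strategy differences exactly
  expect_equal(d1$delta_cost, d1$cost_intervention - d1$cost_comparator)
  expect_equal(d1$delta_effect,
               d1$effect_intervention - d1$effect_comparator)

  # law of large numbers against the deterministic component-level model
  mc_se_cost <- stats::sd(d1$delta_cost) / sqrt(nrow(d1))
  expect_lt(abs(mean(d1$delta_cost) - (-135)), 3 * mc_se_cost)
  mc_se_eff <- stats::sd(d1$delta_effect) / sqrt(nrow(d1))
  expect_lt(abs(mean(d1$delta_effect) - (-0.010)), 3 * mc_se_eff)
})

test_that("PSA collapses to the base case in the degenerate-variance limit", {
  model <- quiet_model()
  params <- build_uncertain_params(model)
  params$se <- 1e-9 * params$mean
  params <- fit_uncertain_dists(params)
  d <- run_psa(model, n_iter = 50, seed = 5, params = params)
  expect_equal(d$delta_cost, rep(-135, 50), tolerance = 1e-4)
  expect_equal(d$delta_effect, rep(-0.010, 50), tolerance = 1e-4)
})

test_that("unfitted parameters are rejected", {
  model <- quiet_model()
  params <- build_uncertain_params(model)
  params$par1[1] <- NA_real_
  expect_error(run_psa(model, n_iter = 10, seed = 1, params = params),
               "unfitted")
})

test_that("plane_summary fractions sum to one and label quadrants correctly", {
  one_each <- draws_tbl(delta_cost = c(1, 1, -1, -1),
                        delta_effect = c(1, -1, 1, -1))
  ps <- plane_summary(one_each)
  expect_equal(sum(ps$fraction), 1)
  expect_equal(ps$fraction[ps$quadrant %in% c("NE", "NW", "SE", "SW")],
               rep(0.25, 4))

  d <- run_psa(quiet_model(), n_iter = 2000, seed = 13)
  ps2 <- plane_summary(d)
  expect_equal(sum(ps2$fraction), 1)
  expect_error(plane_summary(d[0, ]), "empty")
})

test_that("ceac probabilities are complementary and zero-WTP equals the cost-saving fraction", {
  d <- run_psa(quiet_model(), n_iter = 2000, seed = 17)
  cc <- ceac(d)
  expect_true(all(abs(cc$p_prp + cc$p_soc - 1) < 1e-12))
  expect_true(all(cc$p_prp >= 0 & cc$p_prp <= 1))
  expect_equal(cc$p_prp[cc$wtp == 0], mean(d$delta_cost < 0))
  expect_error(ceac(d, wtp = c(100, 50)), "ascending")
})

test_that("ceac is non-increasing when every draw is in the SW quadrant", {
  d <- run_psa(quiet_model(), n_iter = 3000, seed = 19)
  sw <- d[d$quadrant == "SW", ]
  cc <- ceac(sw)
  expect_true(all(diff(cc$p_prp) <= 0))
})

test_that("degenerate draws give a step CEAC dropping at the deterministic ICER", {
  point <- draws_tbl(delta_cost = -135, delta_effect = -0.010)
  cc <- ceac(point)
  expect_true(all(cc$p_prp[cc$wtp < 13500] == 1))
  expect_true(all(cc$p_prp[cc$wtp >= 13500] == 0))
  # interpolated crossover lies inside the step's grid interval
  cross <- ceac_crossover(cc)
  expect_gte(cross, 13400)
  expect_lte(cross, 13500)
})

test_that("ceac_crossover warns and returns NA when there is no crossing", {
  always <- draws_tbl(delta_cost = c(-10, -20), delta_effect = c(0.1, 0.2))
  expect_warning(na <- ceac_crossover(ceac(always)), "does not cross")
  expect_true(is.na(na))
})
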