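# Synthetic retrospective-cohort generator: patient-level covariates with
# the observed per-arm structure, confounded arm assignment mimicking the
# refill-program eligibility criteria, and a logistic favourable-immune-
# response (FIR) outcome driving the follow-up CD4 count.

.arm_levels <- c("SOC", "PRP")
.regimen_initial_levels <- c("d4T-3TC-NVP", "ZDV-3TC-EFV", "other")
.regimen_current_levels <- c("ZDV-3TC-NVP", "ZDV-3TC-EFV",
                             "ZDV-TDF-FTC-LPV/r", "other")

#' Default covariate structure and outcome model of the synthetic cohort
#'
#' The per-arm truncated-normal parameters, category frequencies and
#' logistic outcome coefficients used by [cohort_config()] when not
#' overridden. Continuous parameters follow the published running text
#' (the refill-program arm is older, longer on ART, with lower baseline CD4
#' and shorter follow-up); categorical frequencies are derived from the
#' published per-arm counts.
#'
#' @return `default_continuous()`: a tibble `variable, arm, mean, sd, min`;
#'   `default_categorical()`: a tibble `variable, arm, level, freq`;
#'   `default_outcome_coefficients()`: a named numeric vector of log-odds
#'   coefficients.
#' @name cohort_defaults
NULL

#' @rdname cohort_defaults
#' @export
default_continuous <- function() {
  tibble::tribble(
    ~variable,             ~arm,  ~mean, ~sd,  ~min,
    "age_years",           "PRP", 38.8,  7.5,  18,
    "age_years",           "SOC", 35.9,  7.5,  18,
    "art_duration_months", "PRP", 41.8,  16.2, 0,
    "art_duration_months", "SOC", 30.9,  13.0, 0,
    "followup_months",     "PRP", 12.8,  1.6,  0,
    "followup_months",     "SOC", 15.1,  1.3,  0,
    "cd4_art_start",       "PRP", 124,   103,  0,
    "cd4_art_start",       "SOC", 121,   131,  0,
    "cd4_baseline",        "PRP", 218,   160,  0,
    "cd4_baseline",        "SOC", 292,   145,  0
  )
}

#' @rdname cohort_defaults
#' @export
default_categorical <- function() {
  dplyr::bind_rows(
    tibble::tibble(variable = "gender", arm = "PRP",
                   level = c("male", "female"),
                   freq = c(253, 325) / 578),
    tibble::tibble(variable = "gender", arm = "SOC",
                   level = c("male", "female"),
                   freq = c(100, 151) / 251),
    tibble::tibble(variable = "initial_regimen", arm = "PRP",
                   level = .regimen_initial_levels,
                   freq = c(362, 194, 22) / 578),
    tibble::tibble(variable = "initial_regimen", arm = "SOC",
                   level = .regimen_initial_levels,
                   freq = c(160, 51, 40) / 251),
    tibble::tibble(variable = "current_regimen", arm = "PRP",
                   level = .regimen_current_levels,
                   freq = c(167, 154, 165, 92) / 578),
    tibble::tibble(variable = "current_regimen", arm = "SOC",
                   level = .regimen_current_levels,
                   freq = c(52, 37, 33, 129) / 251),
    tibble::tibble(variable = "oi_baseline", arm = c("PRP", "SOC"),
                   level = "1", freq = c(34 / 578, 35 / 251)),
    tibble::tibble(variable = "oi_followup", arm = c("PRP", "SOC"),
                   level = "1", freq = c(38 / 578, 31 / 251)),
    tibble::tibble(variable = "adherence_optimal", arm = c("PRP", "SOC"),
                   level = "1", freq = c(564 / 573, 208 / 234))
  )
}

# Adjusted log odds ratios of the reference analysis; age is centred at the
# cohort mean (36.8 years). The intercept is calibrated so the pooled
# marginal FIR prevalence under the default covariate structure is 0.189
# (see calibrate_fir_intercept()).

#' @rdname cohort_defaults
#' @export
default_outcome_coefficients <- function() {
  c(
    intercept            = -1.5363,
    arm_prp              = log(0.93),
    age_centred          = log(1.02),
    female               = log(0.47),
    followup_gt1y        = log(1.98),
    art_2_3y             = log(0.84),
    art_gt3y             = log(0.34),
    cd4s_200_300         = log(0.44),
    cd4s_gt300           = log(0.39),
    oi_baseline          = log(1.68),
    oi_followup          = log(0.83),
    adherence_optimal    = log(1.37),
    init_zdv3tc_efv      = log(2.45),
    init_other           = log(1.09),
    curr_zdv3tc_efv      = log(0.62),
    curr_zdvtdfftc_lpvr  = log(1.03),
    curr_other           = log(1.68)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the covariate structure of the Kampala refill-program
#' cohort: arm sizes 578 (PRP) and 251 (SOC); continuous covariates as
#' truncated normals at the published per-arm means and SDs (the PRP arm is
#' older, longer on ART, with lower baseline CD4 and shorter follow-up);
#' categorical covariates at the published per-arm frequencies; and a
#' logistic FIR model whose default coefficients are the published adjusted
#' log odds ratios (arm effect `log(0.93)`), with the intercept calibrated
#' so pooled FIR prevalence is 18.9%.
#'
#' @param n_prp,n_soc Arm sizes.
#' @param seed Optional integer seed; fixed seed gives identical cohorts.
#' @param continuous Tibble `variable, arm, mean, sd, min` of truncated
#'   normal parameters for the continuous covariates.
#' @param categorical Tibble `variable, arm, level, freq`. Within each
#'   `variable`-`arm` cell the frequencies must sum to 1; binary variables
#'   may list only the positive level.
#' @param outcome_coefficients Named numeric vector of log-odds
#'   coefficients (intercept plus one per design term) for the FIR model.
#' @param cd4_followup_meanlog,cd4_followup_sdlog Lognormal parameters of
#'   the latent follow-up CD4 distribution, truncated above/below 500
#'   cells/uL according to the drawn FIR status.
#' @param constrain_prp Rejection-sample PRP members so all satisfy the
#'   database-observable program eligibility criteria (baseline CD4 > 200,
#'   at least 12 months of ART, optimal self-reported adherence). This is
#'   the selection bias of the program; `FALSE` reproduces the raw marginal
#'   frequencies instead.
#' @param adherence_missing_frac Fraction of records whose adherence is
#'   masked to `NA` (the source analysis lost 22/829 records this way);
#'   default 0.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_prp = 578, n_soc = 251, seed = NULL,
                          continuous = default_continuous(),
                          categorical = default_categorical(),
                          outcome_coefficients = default_outcome_coefficients(),
                          cd4_followup_meanlog = log(350),
                          cd4_followup_sdlog = 0.55,
                          constrain_prp = TRUE,
                          adherence_missing_frac = 0) {
  stopifnot(n_prp >= 1, n_soc >= 1,
            adherence_missing_frac >= 0, adherence_missing_frac < 1)
  if (any(categorical$freq < 0) || any(categorical$freq > 1)) {
    stop("categorical frequencies must lie in [0, 1]", call. = FALSE)
  }
  sums <- categorical |>
    dplyr::group_by(.data$variable, .data$arm) |>
    dplyr::summarise(total = sum(.data$freq), n_lev = dplyr::n(),
                     .groups = "drop")
  invalid <- sums$n_lev > 1 & abs(sums$total - 1) > 1e-6
  if (any(invalid)) {
    stop("categorical frequencies must sum to 1 within ",
         paste(unique(sums$variable[invalid]), collapse = ", "),
         call. = FALSE)
  }
  required <- c("intercept", "arm_prp")
  if (!all(required %in% names(outcome_coefficients))) {
    stop("outcome_coefficients must include at least ",
         paste(required, collapse = " and "), call. = FALSE)
  }
  structure(
    list(n_prp = as.integer(n_prp), n_soc = as.integer(n_soc), seed = seed,
         continuous = continuous, categorical = categorical,
         outcome_coefficients = outcome_coefficients,
         cd4_followup_meanlog = cd4_followup_meanlog,
         cd4_followup_sdlog = cd4_followup_sdlog,
         constrain_prp = isTRUE(constrain_prp),
         adherence_missing_frac = adherence_missing_frac),
    class = "cohort_config"
  )
}

# Truncated-normal draws via inverse CDF; lower truncation only.
rtruncnorm_lower <- function(n, mean, sd, min) {
  p_lo <- pnorm(min, mean, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mean, sd)
}

draw_continuous <- function(n, spec) {
  rtruncnorm_lower(n, spec$mean, spec$sd, spec$min)
}

draw_categorical <- function(n, levels, freqs) {
  sample(levels, n, replace = TRUE, prob = freqs)
}

cont_spec <- function(config, variable, arm) {
  row <- dplyr::filter(config$continuous, .data$variable == !!variable,
                       .data$arm == !!arm)
  if (nrow(row) != 1L) {
    stop("continuous spec missing for ", variable, " / ", arm, call. = FALSE)
  }
  row
}

cat_freq <- function(config, variable, arm) {
  rows <- dplyr::filter(config$categorical, .data$variable == !!variable,
                        .data$arm == !!arm)
  if (nrow(rows) == 0) {
    stop("categorical spec missing for ", variable, " / ", arm,
         call. = FALSE)
  }
  rows
}

draw_arm <- function(config, arm, n) {
  cont <- lapply(
    c("age_years", "art_duration_months", "followup_months",
      "cd4_art_start", "cd4_baseline"),
    function(v) draw_continuous(n, cont_spec(config, v, arm))
  )
  out <- tibble::tibble(
    arm = rep(arm, n),
    age_years = cont[[1]],
    art_duration_months = cont[[2]],
    followup_months = cont[[3]],
    cd4_art_start = cont[[4]],
    cd4_baseline = cont[[5]]
  )
  g <- cat_freq(config, "gender", arm)
  out$gender <- draw_categorical(n, g$level, g$freq)
  ir <- cat_freq(config, "initial_regimen", arm)
  out$initial_regimen <- draw_categorical(n, ir$level, ir$freq)
  cr <- cat_freq(config, "current_regimen", arm)
  out$current_regimen <- draw_categorical(n, cr$level, cr$freq)
  out$oi_baseline <- rbinom(n, 1L, cat_freq(config, "oi_baseline", arm)$freq)
  out$oi_followup <- rbinom(n, 1L, cat_freq(config, "oi_followup", arm)$freq)
  out$adherence_optimal <-
    rbinom(n, 1L, cat_freq(config, "adherence_optimal", arm)$freq)
  out
}

prp_eligible_rows <- function(df) {
  df$cd4_baseline > 200 & df$art_duration_months >= 12 &
    df$adherence_optimal == 1L
}

# FIR linear predictor for generated covariates under the configured
# logistic model; age centred at the pooled cohort mean (36.8 years).
fir_linear_predictor <- function(df, beta) {
  b <- function(name) if (name %in% names(beta)) beta[[name]] else 0
  b("intercept") +
    b("arm_prp") * (df$arm == "PRP") +
    b("age_centred") * (df$age_years - 36.8) +
    b("female") * (df$gender == "female") +
    b("followup_gt1y") * (df$followup_months > 12) +
    b("art_2_3y") * (df$art_duration_months >= 24 &
                       df$art_duration_months < 36) +
    b("art_gt3y") * (df$art_duration_months >= 36) +
    b("cd4s_200_300") * (df$cd4_art_start >= 200 & df$cd4_art_start < 300) +
    b("cd4s_gt300") * (df$cd4_art_start >= 300) +
    b("oi_baseline") * df$oi_baseline +
    b("oi_followup") * df$oi_followup +
    b("adherence_optimal") * df$adherence_optimal +
    b("init_zdv3tc_efv") * (df$initial_regimen == "ZDV-3TC-EFV") +
    b("init_other") * (df$initial_regimen == "other") +
    b("curr_zdv3tc_efv") * (df$current_regimen == "ZDV-3TC-EFV") +
    b("curr_zdvtdfftc_lpvr") *
      (df$current_regimen == "ZDV-TDF-FTC-LPV/r") +
    b("curr_other") * (df$current_regimen == "other")
}

rlnorm_band <- function(fir, meanlog, sdlog) {
  # lognormal truncated above 500 (FIR) or at/below 500 (non-FIR)
  p500 <- plnorm(500, meanlog, sdlog)
  n <- length(fir)
  u <- runif(n)
  p <- ifelse(fir == 1L, p500 + u * (1 - p500), u * p500)
  qlnorm(p, meanlog, sdlog)
}

#' Generate a synthetic patient cohort
#'
#' Draws one record per patient with the configured covariate structure,
#' applies the program's selection bias (PRP members are rejection-sampled
#' to satisfy the observable eligibility criteria when
#' `constrain_prp = TRUE`), draws a latent FIR indicator from the logistic
#' outcome model, and realises the follow-up CD4 count from a lognormal
#' truncated on the corresponding side of 500 cells/uL. The stored `fir`
#' column is recomputed from `cd4_followup > 500`, never stored
#' independently.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per patient: `id`, `arm`, covariates,
#'   `cd4_followup`, `followup_months` and `fir` (0/1).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_prp = 200, n_soc = 100, seed = 1))
#' fir_proportions(cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  soc <- draw_arm(config, "SOC", config$n_soc)
  prp <- draw_arm(config, "PRP", config$n_prp)
  if (config$constrain_prp) {
    for (iter in seq_len(1000)) {
      bad <- which(!prp_eligible_rows(prp))
      if (length(bad) == 0) break
      redraw <- draw_arm(config, "PRP", length(bad))
      prp[bad, names(redraw)] <- redraw
    }
    if (any(!prp_eligible_rows(prp))) {
      stop("could not satisfy PRP eligibility by rejection sampling; ",
           "check the covariate configuration", call. = FALSE)
    }
  }
  cohort <- dplyr::bind_rows(soc, prp)
  lp <- fir_linear_predictor(cohort, config$outcome_coefficients)
  fir_latent <- rbinom(nrow(cohort), 1L, plogis(lp))
  cohort$cd4_followup <- rlnorm_band(fir_latent, config$cd4_followup_meanlog,
                                     config$cd4_followup_sdlog)
  cohort$fir <- as.integer(cohort$cd4_followup > 500)
  if (config$adherence_missing_frac > 0) {
    mask <- runif(nrow(cohort)) < config$adherence_missing_frac
    cohort$adherence_optimal[mask] <- NA_integer_
  }
  cohort |>
    dplyr::mutate(id = dplyr::row_number(), .before = 1) |>
    dplyr::relocate("arm", .after = "id") |>
    dplyr::relocate("cd4_followup", "followup_months", "fir",
                    .after = dplyr::last_col())
}

#' Flag records satisfying the refill-program eligibility criteria
#'
#' The database-observable criteria are: baseline CD4 count above 200
#' cells/uL, at least 12 months on ART, and optimal (>95%) self-reported
#' adherence. The remaining program criteria (visit adherence, disclosure,
#' pregnancy, recent clinical events) are not recorded in the database and
#' are collapsed into a single latent pass probability.
#'
#' @param records Cohort tibble from [generate_cohort()].
#' @param latent_pass_prob Probability that a record passes the
#'   unobservable criteria (default 1, i.e. they never exclude anyone).
#' @param seed Optional seed for the latent Bernoulli draw.
#' @return `records` with a logical `eligible_prp` column appended
#'   (`NA` when adherence is missing).
#' @export
apply_prp_eligibility <- function(records, latent_pass_prob = 1,
                                  seed = NULL) {
  stopifnot(latent_pass_prob >= 0, latent_pass_prob <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  observable <- records$cd4_baseline > 200 &
    records$art_duration_months >= 12 &
    records$adherence_optimal == 1L
  latent <- if (latent_pass_prob < 1) {
    runif(nrow(records)) < latent_pass_prob
  } else {
    TRUE
  }
  dplyr::mutate(records, eligible_prp = observable & latent)
}

#' Calibrate the FIR model intercept to a target pooled prevalence
#'
#' Solves for the intercept that makes the marginal (covariate-averaged)
#' pooled FIR prevalence of the generator equal to `target`, by Monte Carlo
#' integration over a large simulated covariate draw.
#'
#' @param config A [cohort_config()]; its intercept is ignored.
#' @param target Target pooled FIR prevalence.
#' @param n_mc Monte Carlo sample size per arm-weighting (default 2e5).
#' @param seed Seed for the integration draw.
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_fir_intercept <- function(config = cohort_config(),
                                    target = 0.189, n_mc = 2e5,
                                    seed = 1L) {
  stopifnot(target > 0, target < 1)
  big <- cohort_config(
    n_prp = round(n_mc * config$n_prp / (config$n_prp + config$n_soc)),
    n_soc = round(n_mc * config$n_soc / (config$n_prp + config$n_soc)),
    seed = seed,
    continuous = config$continuous, categorical = config$categorical,
    outcome_coefficients = config$outcome_coefficients,
    constrain_prp = config$constrain_prp
  )
  if (!is.null(big$seed)) withr::local_seed(big$seed)
  soc <- draw_arm(big, "SOC", big$n_soc)
  prp <- draw_arm(big, "PRP", big$n_prp)
  if (big$constrain_prp) {
    for (iter in seq_len(1000)) {
      bad <- which(!prp_eligible_rows(prp))
      if (length(bad) == 0) break
      redraw <- draw_arm(big, "PRP", length(bad))
      prp[bad, names(redraw)] <- redraw
    }
  }
  covariates <- dplyr::bind_rows(soc, prp)
  beta <- config$outcome_coefficients
  beta[["intercept"]] <- 0
  lp0 <- fir_linear_predictor(covariates, beta)
  f <- function(b0) mean(plogis(b0 + lp0)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}
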