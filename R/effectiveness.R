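# Effectiveness estimation from patient-level records: FIR proportions,
# crude odds ratio from the 2x2 table, and the covariate-adjusted odds
# ratio from multivariate logistic regression.

#' Favourable-immune-response proportions by arm and pooled
#'
#' @param records Cohort tibble with columns `arm` (`"PRP"`/`"SOC"`) and
#'   `fir` (0/1).
#' @return A tibble with one row per arm plus a pooled row: `n`, `n_fir`,
#'   `proportion`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_prp = 200, n_soc = 100, seed = 1))
#' fir_proportions(cohort)
fir_proportions <- function(records) {
  stopifnot(all(c("arm", "fir") %in% names(records)))
  if (anyNA(records$fir)) stop("fir must be defined for every record",
                               call. = FALSE)
  arms <- unique(records$arm)
  if (!setequal(arms, .arm_levels)) {
    stop("records must contain both a PRP and a SOC arm (non-empty)",
         call. = FALSE)
  }
  by_arm <- records |>
    dplyr::group_by(arm = as.character(.data$arm)) |>
    dplyr::summarise(n = dplyr::n(), n_fir = sum(.data$fir),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$arm, .arm_levels))
  pooled <- tibble::tibble(arm = "pooled", n = sum(by_arm$n),
                           n_fir = sum(by_arm$n_fir))
  dplyr::bind_rows(by_arm, pooled) |>
    dplyr::mutate(proportion = .data$n_fir / .data$n)
}

#' Odds ratio of a 2x2 table with a Wald confidence interval
#'
#' Cells follow the convention `a` = events in the exposed (PRP) arm,
#' `b` = non-events exposed, `c` = events unexposed (SOC), `d` = non-events
#' unexposed; `OR = (a d)/(b c)`. With a zero cell and
#' `haldane = TRUE` (default) 0.5 is added to every cell
#' (Haldane-Anscombe) with a warning; with `haldane = FALSE` a zero cell is
#' an error.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param conf_level Confidence level of the Wald interval (default 0.95).
#' @param haldane Apply the continuity correction when a cell is zero.
#' @return A one-row tibble: `estimate`, `conf.low`, `conf.high`,
#'   `log_or`, `se_log_or`, `p.value` (Wald).
#' @export
#' @examples
#' odds_ratio_2x2(108, 470, 49, 202)
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95, haldane = TRUE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in the 2x2 table; set haldane = TRUE to apply the ",
           "0.5 continuity correction", call. = FALSE)
    }
    warning("zero cell: applying the Haldane-Anscombe correction ",
            "(+0.5 to every cell)", call. = FALSE)
    cells <- cells + 0.5
  }
  log_or <- log(cells[["a"]]) - log(cells[["b"]]) -
    log(cells[["c"]]) + log(cells[["d"]])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    estimate = exp(log_or),
    conf.low = exp(log_or - z * se),
    conf.high = exp(log_or + z * se),
    log_or = log_or,
    se_log_or = se,
    p.value = 2 * pnorm(-abs(log_or / se))
  )
}

#' Crude (unadjusted) odds ratio of FIR, PRP versus SOC
#'
#' Builds the 2x2 table from patient records and applies
#' [odds_ratio_2x2()].
#'
#' @inheritParams fir_proportions
#' @inheritParams odds_ratio_2x2
#' @return A one-row tibble with the cell counts and the odds-ratio
#'   estimate, Wald CI and p value.
#' @export
crude_or <- function(records, conf_level = 0.95, haldane = TRUE) {
  props <- fir_proportions(records)
  prp <- props[props$arm == "PRP", ]
  soc <- props[props$arm == "SOC", ]
  counts <- tibble::tibble(
    a = prp$n_fir, b = prp$n - prp$n_fir,
    c = soc$n_fir, d = soc$n - soc$n_fir
  )
  dplyr::bind_cols(
    counts,
    odds_ratio_2x2(counts$a, counts$b, counts$c, counts$d,
                   conf_level = conf_level, haldane = haldane)
  )
}

#' Maximum-likelihood logistic regression on a design matrix
#'
#' Fits by iteratively reweighted least squares (convergence when the
#' relative deviance change is below `1e-8`, at most `maxit` iterations)
#' with Wald standard errors from the inverse observed information. A
#' diverging coefficient (absolute value above 15 on the log-odds scale)
#' is treated as evidence of separation: the fit is flagged non-converged
#' with a warning rather than silently returned.
#'
#' @param outcome Binary (0/1) response vector.
#' @param design Numeric design matrix with named columns. An
#'   `(Intercept)` column is prepended unless `intercept = FALSE` or one is
#'   already present.
#' @param intercept Add an intercept column (default `TRUE`).
#' @param maxit Maximum IRLS iterations (default 100).
#' @param conf_level Confidence level of the Wald intervals.
#' @return An object of class `logistic_fit`; see [tidy.logistic_fit()].
#' @export
logistic_fit <- function(outcome, design, intercept = TRUE, maxit = 100,
                         conf_level = 0.95) {
  if (is.null(design)) {
    design <- matrix(numeric(0), nrow = length(outcome), ncol = 0)
  }
  design <- as.matrix(design)
  if (ncol(design) > 0 && is.null(colnames(design))) {
    stop("design must have named columns", call. = FALSE)
  }
  keep <- !is.na(outcome)
  if (ncol(design) > 0) keep <- keep & stats::complete.cases(design)
  design <- design[keep, , drop = FALSE]
  outcome <- outcome[keep]
  if (!all(outcome %in% c(0, 1))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  if (intercept && !"(Intercept)" %in% colnames(design)) {
    design <- cbind(`(Intercept)` = 1, design)
  }
  non_icpt <- setdiff(colnames(design), "(Intercept)")
  variances <- apply(design[, non_icpt, drop = FALSE], 2, stats::var)
  if (any(variances == 0)) {
    stop("zero-variance design column(s): ",
         paste(non_icpt[variances == 0], collapse = ", "), call. = FALSE)
  }
  if (nrow(design) <= ncol(design)) {
    stop("more terms than observations", call. = FALSE)
  }
  fit <- glm.fit(design, outcome, family = binomial(),
                 control = glm.control(epsilon = 1e-8, maxit = maxit))
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  coef <- fit$coefficients[seq_len(p)]
  converged <- isTRUE(fit$converged)
  if (any(abs(coef) > 15)) {
    warning("possible separation: coefficient(s) beyond 15 on the ",
            "log-odds scale; fit flagged non-converged", call. = FALSE)
    converged <- FALSE
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      coefficients = coef,
      std_errors = stats::setNames(se, names(coef)),
      odds_ratios = exp(coef),
      ci_low = exp(coef - z * se),
      ci_high = exp(coef + z * se),
      p_values = 2 * pnorm(-abs(coef / se)),
      n_used = nrow(design),
      converged = converged,
      deviance = fit$deviance,
      null_deviance = fit$null.deviance,
      df_residual = fit$df.residual,
      conf_level = conf_level
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, converged = %s\n",
              x$n_used, x$converged))
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic fit
#'
#' @param x A [logistic_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate` (log-odds),
#'   `std.error`, `statistic`, `p.value`, `odds.ratio`, `conf.low`,
#'   `conf.high` (CI on the odds-ratio scale).
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$std_errors),
    statistic = unname(x$coefficients / x$std_errors),
    p.value = unname(x$p_values),
    odds.ratio = unname(x$odds_ratios),
    conf.low = unname(x$ci_low),
    conf.high = unname(x$ci_high)
  )
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(
    n_used = x$n_used,
    converged = x$converged,
    deviance = x$deviance,
    null.deviance = x$null_deviance,
    df.residual = x$df_residual
  )
}

# Design matrix mirroring the published adjusted model: follow-up
# dichotomised at one year, ART duration in three bands, CD4 at ART start
# in three bands, regimen reference levels as published.
fir_design_matrix <- function(records, adjusted = TRUE) {
  m <- cbind(arm_prp = as.numeric(records$arm == "PRP"))
  if (!adjusted) return(m)
  cbind(
    m,
    followup_gt1y = as.numeric(records$followup_months > 12),
    art_2_3y = as.numeric(records$art_duration_months >= 24 &
                            records$art_duration_months < 36),
    art_gt3y = as.numeric(records$art_duration_months >= 36),
    age_years = records$age_years,
    female = as.numeric(records$gender == "female"),
    init_zdv3tc_efv = as.numeric(records$initial_regimen == "ZDV-3TC-EFV"),
    init_other = as.numeric(records$initial_regimen == "other"),
    curr_zdv3tc_efv = as.numeric(records$current_regimen == "ZDV-3TC-EFV"),
    curr_zdvtdfftc_lpvr =
      as.numeric(records$current_regimen == "ZDV-TDF-FTC-LPV/r"),
    curr_other = as.numeric(records$current_regimen == "other"),
    oi_baseline = as.numeric(records$oi_baseline == 1),
    oi_followup = as.numeric(records$oi_followup == 1),
    adherence_optimal = as.numeric(records$adherence_optimal == 1),
    cd4s_200_300 = as.numeric(records$cd4_art_start >= 200 &
                                records$cd4_art_start < 300),
    cd4s_gt300 = as.numeric(records$cd4_art_start >= 300)
  )
}

#' Logistic regression of FIR on arm, crude or covariate-adjusted
#'
#' Fits the favourable-immune-response outcome on the exposure arm alone
#' (`adjusted = FALSE`, equivalent to the crude odds ratio) or on arm plus
#' the full published covariate set: follow-up duration dichotomised at one
#' year, ART duration in three bands, age, gender, initial and current
#' regimen, opportunistic infections at baseline and follow-up, adherence,
#' and CD4 at ART start in three bands. Records with missing adherence are
#' dropped (reflected in `n_used`).
#'
#' @inheritParams fir_proportions
#' @param adjusted Include the covariate set (default `TRUE`).
#' @param conf_level Confidence level of the Wald intervals.
#' @return A [logistic_fit()] object.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' fit <- fit_fir_logistic(cohort)
#' tidy(fit)
fit_fir_logistic <- function(records, adjusted = TRUE, conf_level = 0.95) {
  design <- fir_design_matrix(records, adjusted = adjusted)
  logistic_fit(records$fir, design, conf_level = conf_level)
}
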