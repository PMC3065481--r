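# Decision-model data types: cost categories, perspectives, strategy
# parameters and the two-strategy model, plus YAML configuration I/O.

# Canonical category order; also the order cost parameters are sampled in.
.cost_categories <- c(
  "art", "other_drugs", "radiology", "laboratory", "personnel",
  "overhead_capital", "transport", "lost_patient_time", "residual"
)
.direct_nonmedical <- c("transport", "lost_patient_time")
.perspectives <- c("limited_societal", "moh")

#' Cost categories of the decision model
#'
#' The per-patient annual cost of each strategy is split into fixed
#' categories. `transport` and `lost_patient_time` are direct non-medical
#' costs and are excluded under the Ministry-of-Health perspective;
#' `residual` carries the gap between a strategy's published total and the
#' sum of its published components, so that totals and component-level
#' sensitivity analysis coexist.
#'
#' @return A tibble with columns `category` and `direct_nonmedical`.
#' @export
#' @examples
#' cost_categories()
cost_categories <- function() {
  tibble::tibble(
    category = .cost_categories,
    direct_nonmedical = .cost_categories %in% .direct_nonmedical
  )
}

#' Analysis perspectives
#'
#' `limited_societal` includes every cost category (direct medical and
#' direct non-medical, but no productivity losses); `moh` keeps direct
#' medical costs only.
#'
#' @return Character vector of the supported perspective names.
#' @export
perspectives <- function() .perspectives

included_categories <- function(perspective) {
  perspective <- match.arg(perspective, .perspectives)
  if (perspective == "moh") {
    setdiff(.cost_categories, .direct_nonmedical)
  } else {
    .cost_categories
  }
}

#' Build a per-strategy cost profile
#'
#' @param strategy_name Strategy label, e.g. `"PRP"` or `"SOC"`.
#' @param category_costs Named numeric vector of annual per-patient costs in
#'   2009 US$. All categories listed by [cost_categories()] except
#'   `residual` are required; `residual` defaults to 0.
#' @param totals Optional named numeric vector of published per-perspective
#'   totals (`limited_societal`, `moh`). When present, a total overrides the
#'   category sum in [perspective_total()].
#' @return An object of class `cost_profile`.
#' @export
#' @examples
#' prof <- cost_profile("PRP", c(
#'   art = 243, other_drugs = 35, radiology = 2, laboratory = 34,
#'   personnel = 10, overhead_capital = 141, transport = 20,
#'   lost_patient_time = 4, residual = 31
#' ))
#' perspective_total(prof, "limited_societal")
cost_profile <- function(strategy_name, category_costs, totals = NULL) {
  stopifnot(is.character(strategy_name), length(strategy_name) == 1L)
  required <- setdiff(.cost_categories, "residual")
  missing_cats <- setdiff(required, names(category_costs))
  if (length(missing_cats) > 0) {
    stop("cost profile for '", strategy_name, "' is missing categories: ",
         paste(missing_cats, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(category_costs), .cost_categories)
  if (length(unknown) > 0) {
    stop("unknown cost categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  costs <- stats::setNames(numeric(length(.cost_categories)), .cost_categories)
  costs[names(category_costs)] <- as.numeric(category_costs)
  if (anyNA(costs) || any(costs < 0)) {
    stop("category costs must be non-negative and non-missing", call. = FALSE)
  }
  if (!is.null(totals)) {
    unknown_t <- setdiff(names(totals), .perspectives)
    if (length(unknown_t) > 0) {
      stop("unknown perspectives in totals: ",
           paste(unknown_t, collapse = ", "), call. = FALSE)
    }
    totals <- vapply(totals, as.numeric, numeric(1))
    if (anyNA(totals) || any(totals < 0)) {
      stop("perspective totals must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(strategy_name = strategy_name, category_costs = costs,
         totals = totals),
    class = "cost_profile"
  )
}

#' Total annual cost of a strategy under a perspective
#'
#' Sums the cost categories included under `perspective` (the MoH
#' perspective drops patient transport and lost patient time). When the
#' profile carries a published total for the perspective, that total is
#' returned instead; if it differs from the category sum by more than one
#' dollar a reconciliation warning is emitted.
#'
#' @param profile A [cost_profile()].
#' @param perspective `"limited_societal"` or `"moh"`.
#' @param use_override Return the published total when available
#'   (default `TRUE`). Set `FALSE` to force the category sum.
#' @return Annual per-patient cost (2009 US$), a length-one numeric.
#' @export
perspective_total <- function(profile, perspective = "limited_societal",
                              use_override = TRUE) {
  stopifnot(inherits(profile, "cost_profile"))
  perspective <- match.arg(perspective, .perspectives)
  cat_sum <- sum(profile$category_costs[included_categories(perspective)])
  override <- profile$totals[[perspective]]
  if (use_override && !is.null(override)) {
    if (abs(override - cat_sum) > 1) {
      warning(sprintf(
        "'%s' %s total %.0f differs from its category sum %.0f by more than $1",
        profile$strategy_name, perspective, override, cat_sum
      ), call. = FALSE)
    }
    return(override)
  }
  cat_sum
}

#' @export
print.cost_profile <- function(x, ...) {
  cat("<cost_profile> ", x$strategy_name, "\n", sep = "")
  print(tibble::tibble(category = names(x$category_costs),
                       cost = unname(x$category_costs)))
  if (!is.null(x$totals)) {
    cat("published totals:",
        paste(names(x$totals), x$totals, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Strategy parameters
#'
#' @param name Strategy label.
#' @param p_fir Probability of a favourable immune response (follow-up CD4
#'   count above 500 cells/uL), in `[0, 1]`.
#' @param costs A [cost_profile()].
#' @param followup_months Mean follow-up duration in months (> 0).
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(name, p_fir, costs, followup_months) {
  stopifnot(inherits(costs, "cost_profile"))
  p_fir <- as.numeric(p_fir)
  if (length(p_fir) != 1L || is.na(p_fir) || p_fir < 0 || p_fir > 1) {
    stop("p_fir must be a probability in [0, 1]", call. = FALSE)
  }
  followup_months <- as.numeric(followup_months)
  if (length(followup_months) != 1L || is.na(followup_months) ||
      followup_months <= 0) {
    stop("followup_months must be a positive number", call. = FALSE)
  }
  structure(
    list(name = name, p_fir = p_fir, costs = costs,
         followup_months = followup_months),
    class = "strategy_params"
  )
}

#' Two-strategy decision model
#'
#' @param comparator [strategy_params()] for the comparator (standard of
#'   care, SOC).
#' @param intervention [strategy_params()] for the intervention
#'   (pharmacy-only refill program, PRP).
#' @param n_comparator,n_intervention Cohort sizes (positive integers).
#' @param settings Optional list of run settings (`psa`, `sensitivity`) as
#'   read by [load_config()].
#' @return An object of class `decision_model`.
#' @export
decision_model <- function(comparator, intervention,
                           n_comparator, n_intervention, settings = list()) {
  stopifnot(inherits(comparator, "strategy_params"),
            inherits(intervention, "strategy_params"))
  n_comparator <- as.integer(n_comparator)
  n_intervention <- as.integer(n_intervention)
  if (anyNA(c(n_comparator, n_intervention)) ||
      n_comparator <= 0 || n_intervention <= 0) {
    stop("patient counts must be positive integers", call. = FALSE)
  }
  structure(
    list(comparator = comparator, intervention = intervention,
         n_comparator = n_comparator, n_intervention = n_intervention,
         settings = settings),
    class = "decision_model"
  )
}

#' @export
print.decision_model <- function(x, ...) {
  cat("<decision_model>\n")
  cat(sprintf("  comparator   %s: p_fir = %.3f, n = %d\n",
              x$comparator$name, x$comparator$p_fir, x$n_comparator))
  cat(sprintf("  intervention %s: p_fir = %.3f, n = %d\n",
              x$intervention$name, x$intervention$p_fir, x$n_intervention))
  for (p in .perspectives) {
    cat(sprintf(
      "  %-16s cost/person-year: %s %.0f vs %s %.0f\n", p,
      x$intervention$name,
      suppressWarnings(perspective_total(x$intervention$costs, p)),
      x$comparator$name,
      suppressWarnings(perspective_total(x$comparator$costs, p))
    ))
  }
  invisible(x)
}

check_keys <- function(x, required, optional = character(), where) {
  if (!is.list(x)) stop("configuration section '", where,
                        "' must be a mapping", call. = FALSE)
  missing_keys <- setdiff(required, names(x))
  if (length(missing_keys) > 0) {
    stop("configuration is missing key(s) in '", where, "': ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s) in '", where, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Read a decision-model configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) configuration describing the two
#' strategies, their per-category annual costs and published perspective
#' totals, cohort sizes, and probabilistic/one-way sensitivity settings.
#' All keys are validated; unknown keys are rejected.
#'
#' @param path Path to the configuration file. The parameter set of the
#'   Kampala pharmacy-refill evaluation ships with the package; see
#'   [prp_decision_model()].
#' @return A validated [decision_model()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, required = c("strategies", "n_patients"),
             optional = c("psa", "sensitivity"), where = "top level")
  check_keys(cfg$strategies, required = c("soc", "prp"), where = "strategies")
  check_keys(cfg$n_patients, required = c("soc", "prp"), where = "n_patients")

  read_strategy <- function(s, key, label) {
    check_keys(s, required = c("p_fir", "followup_months", "costs"),
               optional = "totals", where = paste0("strategies.", key))
    profile <- cost_profile(label, unlist(s$costs), totals = unlist(s$totals))
    strategy_params(label, s$p_fir, profile, s$followup_months)
  }
  soc <- read_strategy(cfg$strategies$soc, "soc", "SOC")
  prp <- read_strategy(cfg$strategies$prp, "prp", "PRP")

  settings <- list(
    psa = list(n_iter = 10000L, seed = NULL),
    sensitivity = list(cost_low_factor = 0.5, cost_high_factor = 2,
                       prob_delta = 0.2)
  )
  if (!is.null(cfg$psa)) {
    check_keys(cfg$psa, required = character(),
               optional = c("n_iter", "seed"), where = "psa")
    settings$psa <- utils::modifyList(settings$psa, cfg$psa)
  }
  if (!is.null(cfg$sensitivity)) {
    check_keys(cfg$sensitivity, required = character(),
               optional = c("cost_low_factor", "cost_high_factor",
                            "prob_delta"),
               where = "sensitivity")
    settings$sensitivity <- utils::modifyList(settings$sensitivity,
                                              cfg$sensitivity)
  }
  decision_model(soc, prp, cfg$n_patients$soc, cfg$n_patients$prp,
                 settings = settings)
}

#' The bundled Kampala pharmacy-refill parameter set
#'
#' Loads the decision model of the published evaluation: a pharmacy-only
#' refill program (PRP, 578 patients, FIR probability 0.186) versus
#' standard physician-led care (SOC, 251 patients, FIR probability 0.196),
#' with annual per-patient costs of 520 vs 655 US$ (limited societal) and
#' 496 vs 610 US$ (Ministry of Health), in 2009 US$.
#'
#' @return A [decision_model()].
#' @export
#' @examples
#' model <- prp_decision_model()
#' cea(model)
prp_decision_model <- function() {
  load_config(system.file("extdata", "idi_prp_params.yaml",
                          package = "refillcea", mustWork = TRUE))
}
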