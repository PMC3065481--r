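# One-way (tornado) and probabilistic sensitivity analysis: range-to-SE
# conversion, beta/gamma moment matching, Monte Carlo simulation, plane
# summaries and the cost-effectiveness acceptability curve.

#' Standard error from a range treated as a 95% confidence interval
#'
#' `se = (high - low) / (2 * 1.959964)`.
#'
#' @param low,high Range bounds with `high > low`.
#' @return The implied standard error.
#' @export
#' @examples
#' se_from_range(0.1568, 0.2352)  # 0.02
se_from_range <- function(low, high) {
  if (any(high <= low)) stop("high must exceed low", call. = FALSE)
  (high - low) / (2 * qnorm(0.975))
}

#' Moment-matched beta distribution for a probability parameter
#'
#' Method of moments: `nu = mean (1 - mean) / se^2 - 1`,
#' `alpha = mean nu`, `beta = (1 - mean) nu`. Requires
#' `se^2 < mean (1 - mean)`.
#'
#' @param mean Point estimate in (0, 1).
#' @param se Standard error (> 0).
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
#' @examples
#' fit_beta(0.196, 0.02)
fit_beta <- function(mean, se) {
  stopifnot(length(mean) == 1L, length(se) == 1L)
  if (!(mean > 0 && mean < 1)) stop("mean must lie in (0, 1)", call. = FALSE)
  if (se <= 0) stop("se must be positive", call. = FALSE)
  if (se^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "variance too large for a beta distribution: se^2 = %.4g >= mean(1-mean) = %.4g",
      se^2, mean * (1 - mean)), call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Moment-matched gamma distribution for a cost parameter
#'
#' Method of moments: `shape = mean^2 / se^2`, `scale = se^2 / mean`, so
#' that `shape * scale = mean` exactly.
#'
#' @param mean Point estimate (> 0).
#' @param se Standard error (> 0).
#' @return Named numeric vector `c(shape, scale)`.
#' @export
#' @examples
#' fit_gamma(243, 92.99)
fit_gamma <- function(mean, se) {
  stopifnot(length(mean) == 1L, length(se) == 1L)
  if (mean <= 0 || se <= 0) {
    stop("mean and se must be positive", call. = FALSE)
  }
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' (Re)fit sampling distributions of an uncertain-parameter table
#'
#' Computes `se` from the `low`/`high` range and moment-matches a beta
#' (probabilities) or gamma (costs) distribution. Used by
#' [build_uncertain_params()] and after manually editing a parameter table
#' (e.g. shrinking `se` toward a degenerate limit).
#'
#' @param params Tibble with columns `name`, `role`, `mean`, and either
#'   `low`/`high` or `se`.
#' @return `params` with `se`, `dist`, `par1`, `par2` filled in
#'   (`par1`/`par2` are alpha/beta for the beta, shape/scale for the gamma).
#' @export
fit_uncertain_dists <- function(params) {
  if (!"se" %in% names(params) || anyNA(params$se)) {
    params$se <- se_from_range(params$low, params$high)
  }
  fitted <- purrr::pmap_dfr(
    params[, c("role", "mean", "se")],
    function(role, mean, se) {
      if (role == "probability") {
        p <- fit_beta(mean, se)
        tibble::tibble(dist = "beta", par1 = p[["alpha"]], par2 = p[["beta"]])
      } else {
        p <- fit_gamma(mean, se)
        tibble::tibble(dist = "gamma", par1 = p[["shape"]], par2 = p[["scale"]])
      }
    }
  )
  dplyr::bind_cols(dplyr::select(params, -dplyr::any_of(c("dist", "par1", "par2"))),
                   fitted)
}

#' Uncertain-parameter table for sensitivity analysis
#'
#' Builds one row per model parameter with its one-way range (costs halved
#' and doubled; probabilities varied by +/-20%, capped at 1), the standard
#' error implied by treating that range as a 95% confidence interval, and
#' the moment-matched beta (probabilities) or gamma (costs) sampling
#' distribution.
#'
#' Cost categories whose value is identical in both arms (ART, other drugs,
#' radiology, laboratory, overhead and capital, transport in the bundled
#' model) are treated as shared: one parameter moves or is drawn for both
#' arms together. Categories that differ (personnel, lost patient time,
#' residual) and the two FIR probabilities are arm-specific. With
#' `shared = FALSE` every cost category is arm-specific. The accounting
#' `residual` category is included only when `include_residual = TRUE`
#' (the one-way tornado default); the probabilistic analysis leaves it as a
#' fixed per-arm offset. Zero-valued costs have a degenerate range and are
#' excluded with a warning.
#'
#' @param model A [decision_model()].
#' @param perspective Perspective whose categories enter (`"moh"` drops
#'   transport and lost patient time).
#' @param component_mode `"component"` (default) varies per-category costs;
#'   `"total"` varies each arm's total annual cost as a single parameter.
#' @param shared Treat equal-valued categories as shared across arms.
#' @param include_residual Include the residual category as a varied
#'   parameter.
#' @param cost_low_factor,cost_high_factor,prob_delta One-way range rules;
#'   defaults are taken from the model's `sensitivity` settings when
#'   present, else 0.5 / 2 / 0.2.
#' @return A tibble: `name`, `role` (`cost`/`probability`), `arm`
#'   (`both`/`SOC`/`PRP`), `category`, `mean`, `low`, `high`, `se`,
#'   `dist`, `par1`, `par2`. Row order is the documented sampling order of
#'   [run_psa()].
#' @export
#' @examples
#' build_uncertain_params(prp_decision_model())
build_uncertain_params <- function(model,
                                   perspective = "limited_societal",
                                   component_mode = c("component", "total"),
                                   shared = TRUE,
                                   include_residual = FALSE,
                                   cost_low_factor = NULL,
                                   cost_high_factor = NULL,
                                   prob_delta = NULL) {
  stopifnot(inherits(model, "decision_model"))
  perspective <- match.arg(perspective, perspectives())
  component_mode <- match.arg(component_mode)
  sens <- model$settings$sensitivity
  cost_low_factor <- cost_low_factor %||% sens$cost_low_factor %||% 0.5
  cost_high_factor <- cost_high_factor %||% sens$cost_high_factor %||% 2
  prob_delta <- prob_delta %||% sens$prob_delta %||% 0.2

  comp <- model$comparator
  intv <- model$intervention
  prob_rows <- tibble::tibble(
    name = paste0("p_fir_", c(comp$name, intv$name)),
    role = "probability",
    arm = c(comp$name, intv$name),
    category = NA_character_,
    mean = c(comp$p_fir, intv$p_fir)
  ) |>
    dplyr::mutate(low = (1 - prob_delta) * .data$mean,
                  high = pmin(1, (1 + prob_delta) * .data$mean))

  cats <- included_categories(perspective)
  if (!include_residual) cats <- setdiff(cats, "residual")
  cost_rows <- if (component_mode == "total") {
    tibble::tibble(
      name = paste0("total_cost_", c(comp$name, intv$name)),
      role = "cost",
      arm = c(comp$name, intv$name),
      category = "total",
      mean = c(perspective_total(comp$costs, perspective),
               perspective_total(intv$costs, perspective))
    )
  } else {
    purrr::map_dfr(cats, function(category) {
      v_comp <- comp$costs$category_costs[[category]]
      v_intv <- intv$costs$category_costs[[category]]
      if (shared && isTRUE(all.equal(v_comp, v_intv))) {
        tibble::tibble(name = paste0("cost_", category), role = "cost",
                       arm = "both", category = category, mean = v_comp)
      } else {
        tibble::tibble(
          name = paste0("cost_", category, "_", c(comp$name, intv$name)),
          role = "cost", arm = c(comp$name, intv$name),
          category = category, mean = c(v_comp, v_intv)
        )
      }
    })
  }
  cost_rows <- dplyr::mutate(cost_rows,
                             low = cost_low_factor * .data$mean,
                             high = cost_high_factor * .data$mean)
  degenerate <- cost_rows$mean == 0
  if (any(degenerate)) {
    warning("excluding zero-valued cost parameter(s) with degenerate range: ",
            paste(cost_rows$name[degenerate], collapse = ", "),
            call. = FALSE)
    cost_rows <- cost_rows[!degenerate, , drop = FALSE]
  }
  fit_uncertain_dists(dplyr::bind_rows(prob_rows, cost_rows))
}

# Per-arm category cost vectors under a perspective, components only.
component_costs <- function(model, perspective) {
  cats <- included_categories(perspective)
  list(
    comparator = model$comparator$costs$category_costs[cats],
    intervention = model$intervention$costs$category_costs[cats]
  )
}

one_way_outcome <- function(base, target, p_fir) {
  if (target == "delta_cost") {
    sum(base$intervention) - sum(base$comparator)
  } else {
    p_fir[["intervention"]] - p_fir[["comparator"]]
  }
}

#' One-way (tornado) sensitivity analysis
#'
#' Swings each uncertain parameter to its low and high bound with all
#' others at base case and records the resulting incremental cost or
#' incremental effect, sorted by descending swing. Shared cost categories
#' move both arms together (and therefore cancel exactly in the cost
#' difference); arm-specific parameters move one arm only. Pass a parameter
#' table built with `shared = FALSE` to vary every category independently
#' per arm.
#'
#' The base case is computed from the cost components (including the fixed
#' residual category), not from the published totals, so component swings
#' and the base line are mutually consistent.
#'
#' @inheritParams build_uncertain_params
#' @param target `"delta_cost"` or `"delta_effect"`.
#' @param params Uncertain-parameter table; defaults to
#'   [build_uncertain_params()] with `include_residual = TRUE`.
#' @return A tibble of class `tornado`: `parameter`, `arm`, `low`, `high`,
#'   `outcome_at_low`, `outcome_at_high`, `outcome_base`, `swing`,
#'   sorted by descending `swing`.
#' @export
#' @examples
#' one_way(prp_decision_model(), target = "delta_cost")
one_way <- function(model, perspective = "limited_societal",
                    target = c("delta_cost", "delta_effect"),
                    params = build_uncertain_params(
                      model, perspective, include_residual = TRUE)) {
  stopifnot(inherits(model, "decision_model"))
  perspective <- match.arg(perspective, perspectives())
  target <- match.arg(target)
  base_costs <- component_costs(model, perspective)
  base_p <- c(comparator = model$comparator$p_fir,
              intervention = model$intervention$p_fir)
  outcome_base <- one_way_outcome(base_costs, target, base_p)

  arm_key <- c(stats::setNames("comparator", model$comparator$name),
               stats::setNames("intervention", model$intervention$name))

  eval_at <- function(row, value) {
    costs <- base_costs
    p_fir <- base_p
    if (row$role == "probability") {
      p_fir[[arm_key[[row$arm]]]] <- value
    } else if (identical(row$category, "total")) {
      side <- arm_key[[row$arm]]
      costs[[side]] <- costs[[side]] * value / sum(costs[[side]])
    } else if (row$arm == "both") {
      costs$comparator[[row$category]] <- value
      costs$intervention[[row$category]] <- value
    } else {
      side <- arm_key[[row$arm]]
      costs[[side]][[row$category]] <- value
    }
    one_way_outcome(costs, target, p_fir)
  }

  rows <- purrr::map_dfr(seq_len(nrow(params)), function(i) {
    row <- params[i, ]
    tibble::tibble(
      parameter = row$name, arm = row$arm,
      low = row$low, high = row$high,
      outcome_at_low = eval_at(row, row$low),
      outcome_at_high = eval_at(row, row$high)
    )
  })
  out <- rows |>
    dplyr::mutate(outcome_base = outcome_base,
                  swing = abs(.data$outcome_at_high - .data$outcome_at_low)) |>
    dplyr::arrange(dplyr::desc(.data$swing))
  attr(out, "target") <- target
  attr(out, "perspective") <- perspective
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws every uncertain parameter from its moment-matched distribution
#' (beta for probabilities, gamma for costs), once per iteration, in the
#' fixed row order of `params` so that results are reproducible for a given
#' seed. Shared cost parameters use a single draw applied to both arms;
#' arm-specific parameters are drawn independently per arm. Cost categories
#' not present in `params` (by default the accounting residual) enter each
#' iteration at their fixed base value.
#'
#' @inheritParams one_way
#' @param n_iter Number of Monte Carlo iterations (default from the
#'   model's `psa` settings, else 10,000).
#' @param seed Integer seed (default from the model's `psa` settings).
#' @param params Uncertain-parameter table; defaults to
#'   [build_uncertain_params()] with `include_residual = FALSE`.
#' @return A tibble of class `psa_draws`, one row per iteration:
#'   `iteration`, `cost_comparator`, `cost_intervention`,
#'   `effect_comparator`, `effect_intervention`, `delta_cost`,
#'   `delta_effect`, `quadrant`.
#' @export
#' @examples
#' draws <- run_psa(prp_decision_model(), n_iter = 1000, seed = 1)
#' plane_summary(draws)
run_psa <- function(model, perspective = "limited_societal",
                    n_iter = NULL, seed = NULL,
                    params = build_uncertain_params(
                      model, perspective, include_residual = FALSE)) {
  stopifnot(inherits(model, "decision_model"))
  perspective <- match.arg(perspective, perspectives())
  n_iter <- as.integer(n_iter %||% model$settings$psa$n_iter %||% 10000L)
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  if (anyNA(params$par1) || anyNA(params$par2)) {
    stop("unfitted parameter(s) in params; run fit_uncertain_dists()",
         call. = FALSE)
  }
  seed <- seed %||% model$settings$psa$seed
  if (!is.null(seed)) withr::local_seed(seed)

  # fixed draw order = row order of params
  draw_mat <- matrix(NA_real_, n_iter, nrow(params))
  for (j in seq_len(nrow(params))) {
    draw_mat[, j] <- if (params$dist[j] == "beta") {
      rbeta(n_iter, params$par1[j], params$par2[j])
    } else {
      rgamma(n_iter, shape = params$par1[j], scale = params$par2[j])
    }
  }

  base <- component_costs(model, perspective)
  arm_of <- function(nm) {
    c(stats::setNames("comparator", model$comparator$name),
      stats::setNames("intervention", model$intervention$name))[[nm]]
  }
  cost_vec <- function(side_name, side_key) {
    total_row <- which(params$role == "cost" &
                         params$category == "total" &
                         params$arm == side_name)
    if (length(total_row) == 1L) return(draw_mat[, total_row])
    fixed <- sum(base[[side_key]][setdiff(
      names(base[[side_key]]),
      params$category[params$role == "cost" &
                        params$arm %in% c("both", side_name)]
    )])
    idx <- which(params$role == "cost" &
                   params$arm %in% c("both", side_name) &
                   params$category %in% names(base[[side_key]]))
    sampled <- if (length(idx) > 0) {
      rowSums(draw_mat[, idx, drop = FALSE])
    } else 0
    fixed + sampled
  }
  effect_vec <- function(side_name) {
    i <- which(params$role == "probability" & params$arm == side_name)
    stopifnot(length(i) == 1L)
    draw_mat[, i]
  }

  cost_c <- cost_vec(model$comparator$name, "comparator")
  cost_i <- cost_vec(model$intervention$name, "intervention")
  eff_c <- effect_vec(model$comparator$name)
  eff_i <- effect_vec(model$intervention$name)
  out <- tibble::tibble(
    iteration = seq_len(n_iter),
    cost_comparator = cost_c,
    cost_intervention = cost_i,
    effect_comparator = eff_c,
    effect_intervention = eff_i,
    delta_cost = cost_i - cost_c,
    delta_effect = eff_i - eff_c,
    quadrant = plane_quadrant(cost_i - cost_c, eff_i - eff_c)
  )
  attr(out, "perspective") <- perspective
  attr(out, "seed") <- seed
  class(out) <- c("psa_draws", class(out))
  out
}

#' Cost-effectiveness-plane quadrant proportions of PSA draws
#'
#' @param draws A `psa_draws` tibble from [run_psa()].
#' @return A tibble with one row per quadrant (`NE`, `NW`, `SE`, `SW`,
#'   `axis`): `n` and `fraction`; fractions sum to 1.
#' @export
plane_summary <- function(draws) {
  if (nrow(draws) == 0) stop("draws is empty", call. = FALSE)
  quadrants <- c("NE", "NW", "SE", "SW", "axis")
  counts <- table(factor(draws$quadrant, levels = quadrants))
  tibble::tibble(
    quadrant = quadrants,
    n = as.integer(counts),
    fraction = as.integer(counts) / nrow(draws)
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the probability that the
#' intervention is cost-effective is the fraction of draws with positive
#' incremental net monetary benefit, `lambda * delta_effect - delta_cost
#' > 0` (ties count toward the comparator). With two strategies the two
#' acceptability probabilities sum to 1.
#'
#' @param draws A `psa_draws` tibble from [run_psa()].
#' @param wtp Ascending grid of willingness-to-pay values (US$/FIR);
#'   default 0 to 30,000 in steps of 100.
#' @return A tibble of class `ceac`: `wtp`, `p_prp` (intervention
#'   cost-effective), `p_soc`.
#' @export
#' @examples
#' draws <- run_psa(prp_decision_model(), n_iter = 1000, seed = 1)
#' ceac_crossover(ceac(draws))
ceac <- function(draws, wtp = seq(0, 30000, by = 100)) {
  if (nrow(draws) == 0) stop("draws is empty", call. = FALSE)
  if (is.unsorted(wtp, strictly = TRUE)) {
    stop("wtp grid must be sorted ascending", call. = FALSE)
  }
  p_prp <- vapply(
    wtp,
    function(l) mean(l * draws$delta_effect - draws$delta_cost > 0),
    numeric(1)
  )
  out <- tibble::tibble(wtp = wtp, p_prp = p_prp, p_soc = 1 - p_prp)
  class(out) <- c("ceac", class(out))
  out
}

#' Willingness-to-pay at which the acceptability curves cross
#'
#' Finds the first grid interval where the intervention's acceptability
#' probability falls to `threshold` (default 0.5, where the two curves
#' cross) and interpolates linearly between the bracketing grid points.
#'
#' @param ceac_tbl A `ceac` tibble from [ceac()].
#' @param threshold Crossing probability (default 0.5).
#' @return The interpolated willingness-to-pay (US$/FIR), or `NA` with a
#'   warning if the curve never falls to the threshold on the grid.
#' @export
ceac_crossover <- function(ceac_tbl, threshold = 0.5) {
  p <- ceac_tbl$p_prp
  wtp <- ceac_tbl$wtp
  below <- which(p < threshold)
  if (p[1] < threshold || length(below) == 0) {
    warning("acceptability curve does not cross ", threshold,
            " on the grid", call. = FALSE)
    return(NA_real_)
  }
  i <- below[1]
  if (p[i - 1] == threshold) return(wtp[i - 1])
  wtp[i - 1] + (wtp[i] - wtp[i - 1]) *
    (p[i - 1] - threshold) / (p[i - 1] - p[i])
}
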