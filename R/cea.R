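# Deterministic incremental cost-effectiveness analysis: expected costs per
# perspective, incremental cost and effect, ICER with cost-effectiveness
# plane quadrant semantics, and net monetary benefit.

#' Incremental cost and effect between the two strategies
#'
#' Differences are intervention minus comparator (PRP minus SOC). Costs are
#' annual per patient; the effect is the difference in the probability of a
#' favourable immune response over the follow-up period. As in the source
#' evaluation, no time alignment is applied between the annual cost scale
#' and the roughly 13-month effectiveness horizon.
#'
#' @param model A [decision_model()].
#' @param perspective `"limited_societal"` or `"moh"`.
#' @param use_override Use published perspective totals when present
#'   (default `TRUE`); `FALSE` sums the cost categories instead.
#' @return A tibble with one row: per-strategy costs and effects,
#'   `delta_cost` and `delta_effect`.
#' @export
#' @examples
#' incremental(prp_decision_model(), "limited_societal")
incremental <- function(model, perspective = "limited_societal",
                        use_override = TRUE) {
  stopifnot(inherits(model, "decision_model"))
  perspective <- match.arg(perspective, perspectives())
  cost_c <- perspective_total(model$comparator$costs, perspective,
                              use_override = use_override)
  cost_i <- perspective_total(model$intervention$costs, perspective,
                              use_override = use_override)
  tibble::tibble(
    perspective = perspective,
    cost_comparator = cost_c,
    cost_intervention = cost_i,
    delta_cost = cost_i - cost_c,
    p_fir_comparator = model$comparator$p_fir,
    p_fir_intervention = model$intervention$p_fir,
    delta_effect = model$intervention$p_fir - model$comparator$p_fir
  )
}

plane_quadrant <- function(delta_cost, delta_effect) {
  dplyr::case_when(
    delta_cost == 0 | delta_effect == 0 ~ "axis",
    delta_cost > 0 & delta_effect > 0 ~ "NE",
    delta_cost > 0 & delta_effect < 0 ~ "NW",
    delta_cost < 0 & delta_effect > 0 ~ "SE",
    TRUE ~ "SW"
  )
}

quadrant_interpretation <- function(quadrant) {
  switch(quadrant,
    NE = "intervention more effective and more costly; ICER = extra cost per FIR gained",
    NW = "intervention less effective and more costly (dominated by comparator)",
    SE = "intervention more effective and less costly (dominant)",
    SW = "intervention less effective and less costly; ICER = savings per FIR forgone",
    axis = "increments lie on a plane axis; ICER undefined or degenerate"
  )
}

#' Incremental cost-effectiveness ratio with quadrant semantics
#'
#' In the north-west and south-west quadrants a signed ratio is ambiguous,
#' so the ICER is reported as the absolute ratio `|delta_cost/delta_effect|`
#' together with the quadrant label and an interpretation (in the SW
#' quadrant: the savings obtained per favourable immune response forgone).
#' The ICER is undefined exactly when `delta_effect` is zero.
#'
#' @param delta_cost,delta_effect Finite incremental cost and effect
#'   (intervention minus comparator).
#' @return A one-row tibble of class `icer_result`: `delta_cost`,
#'   `delta_effect`, `icer` (`NA` when undefined), `quadrant`
#'   (`NE`/`NW`/`SE`/`SW`/`axis`) and `interpretation`.
#' @export
#' @examples
#' icer(-135, -0.010)  # savings of 13,500 US$ per FIR forgone
icer <- function(delta_cost, delta_effect) {
  stopifnot(length(delta_cost) == 1L, length(delta_effect) == 1L,
            is.finite(delta_cost), is.finite(delta_effect))
  quadrant <- plane_quadrant(delta_cost, delta_effect)
  ratio <- if (delta_effect == 0) NA_real_ else abs(delta_cost / delta_effect)
  out <- tibble::tibble(
    delta_cost = delta_cost,
    delta_effect = delta_effect,
    icer = ratio,
    quadrant = quadrant,
    interpretation = quadrant_interpretation(quadrant)
  )
  class(out) <- c("icer_result", class(out))
  out
}

#' Deterministic cost-effectiveness analysis of a two-strategy model
#'
#' Computes per-strategy expected costs and effects and the incremental
#' cost-effectiveness ratio under one or both perspectives.
#'
#' @param model A [decision_model()].
#' @param perspective Character vector of perspectives to evaluate
#'   (default: both).
#' @param use_override Use published perspective totals when present.
#' @return An object of class `cea_result`. `tidy()` returns one row per
#'   perspective; `glance()` a one-row model summary; `print()` a
#'   publication-style table with costs in whole dollars and ICERs rounded
#'   to the nearest 100.
#' @export
#' @examples
#' cea(prp_decision_model())
cea <- function(model, perspective = perspectives(), use_override = TRUE) {
  stopifnot(inherits(model, "decision_model"))
  perspective <- match.arg(perspective, perspectives(), several.ok = TRUE)
  rows <- purrr::map_dfr(perspective, function(p) {
    inc <- incremental(model, p, use_override = use_override)
    ic <- icer(inc$delta_cost, inc$delta_effect)
    dplyr::bind_cols(inc, ic[, c("icer", "quadrant", "interpretation")])
  })
  structure(list(model = model, table = rows), class = "cea_result")
}

#' @export
tidy.cea_result <- function(x, ...) x$table

#' @export
glance.cea_result <- function(x, ...) {
  tibble::tibble(
    comparator = x$model$comparator$name,
    intervention = x$model$intervention$name,
    n_comparator = x$model$n_comparator,
    n_intervention = x$model$n_intervention,
    delta_effect = x$table$delta_effect[1],
    n_perspectives = nrow(x$table)
  )
}

#' @export
print.cea_result <- function(x, ...) {
  m <- x$model
  cat(sprintf("Incremental cost-effectiveness: %s vs %s\n",
              m$intervention$name, m$comparator$name))
  for (i in seq_len(nrow(x$table))) {
    r <- x$table[i, ]
    cat(sprintf(
      "  %-16s cost %4.0f vs %4.0f (delta %+4.0f); p(FIR) %.3f vs %.3f (delta %+.3f)\n",
      r$perspective, r$cost_intervention, r$cost_comparator, r$delta_cost,
      r$p_fir_intervention, r$p_fir_comparator, r$delta_effect
    ))
    icer_txt <- if (is.na(r$icer)) "undefined" else
      format(round(r$icer / 100) * 100, big.mark = ",")
    cat(sprintf("  %-16s ICER %s US$/FIR [%s] - %s\n",
                "", icer_txt, r$quadrant, r$interpretation))
  }
  invisible(x)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' For each strategy, `NMB = wtp * p_fir - cost`; the strategy with the
#' larger NMB is cost-effective at that threshold. Ties are broken toward
#' the comparator (standard of care).
#'
#' @param model A [decision_model()].
#' @param perspective `"limited_societal"` or `"moh"`.
#' @param wtp Non-negative willingness to pay per favourable immune
#'   response (US$/FIR); may be a vector.
#' @param use_override Use published perspective totals when present.
#' @return A tibble with one row per `wtp` value: `nmb_comparator`,
#'   `nmb_intervention`, `delta_nmb` and the `preferred` strategy name.
#' @export
#' @examples
#' nmb(prp_decision_model(), "limited_societal", wtp = c(0, 13500, 20000))
nmb <- function(model, perspective = "limited_societal", wtp,
                use_override = TRUE) {
  stopifnot(inherits(model, "decision_model"), is.numeric(wtp))
  if (any(!is.finite(wtp)) || any(wtp < 0)) {
    stop("wtp must be non-negative and finite", call. = FALSE)
  }
  inc <- incremental(model, perspective, use_override = use_override)
  nmb_c <- wtp * inc$p_fir_comparator - inc$cost_comparator
  nmb_i <- wtp * inc$p_fir_intervention - inc$cost_intervention
  tibble::tibble(
    perspective = inc$perspective,
    wtp = wtp,
    nmb_comparator = nmb_c,
    nmb_intervention = nmb_i,
    delta_nmb = nmb_i - nmb_c,
    preferred = ifelse(nmb_i > nmb_c, model$intervention$name,
                       model$comparator$name)
  )
}
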