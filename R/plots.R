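# ggplot2 figures for the three result types: cost-effectiveness plane
# scatter, acceptability curves, and the tornado diagram.

#' Cost-effectiveness plane scatter of PSA draws
#'
#' Incremental effect on the horizontal axis, incremental cost on the
#' vertical, one point per Monte Carlo iteration, with the plane axes drawn
#' and an optional willingness-to-pay ray through the origin.
#'
#' @param draws A `psa_draws` tibble from [run_psa()].
#' @param wtp Optional willingness-to-pay (US$/FIR) drawn as a dashed line
#'   of slope `wtp`.
#' @param alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(draws, wtp = NULL, alpha = 0.25) {
  p <- ggplot2::ggplot(draws,
                       ggplot2::aes(.data$delta_effect, .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = alpha, colour = "steelblue", size = 0.8) +
    ggplot2::labs(
      x = "Incremental effect (difference in probability of FIR)",
      y = "Incremental cost (US$/person-year)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = "dashed", colour = "grey30")
  }
  p
}

#' @export
autoplot.psa_draws <- function(object, ...) plot_ce_plane(object, ...)

#' Cost-effectiveness acceptability curves
#'
#' Probability that each strategy is cost-effective as a function of the
#' willingness to pay per favourable immune response.
#'
#' @param ceac_tbl A `ceac` tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl) {
  long <- tidyr::pivot_longer(tibble::as_tibble(ceac_tbl),
                              c("p_prp", "p_soc"),
                              names_to = "strategy", values_to = "p") |>
    dplyr::mutate(strategy = dplyr::recode(.data$strategy,
                                           p_prp = "PRP", p_soc = "SOC"))
  ggplot2::ggplot(long, ggplot2::aes(.data$wtp, .data$p,
                                     colour = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (US$ per FIR)",
      y = "Probability cost-effective",
      colour = NULL,
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ceac <- function(object, ...) plot_ceac(object, ...)

#' Tornado diagram of one-way sensitivity analysis
#'
#' Horizontal bars span the outcome at each parameter's low and high bound
#' (all other parameters at base case), ordered by swing, with a vertical
#' line at the base-case outcome.
#'
#' @param tornado_tbl A `tornado` tibble from [one_way()].
#' @param top Show only the `top` largest-swing parameters (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado_tbl, top = Inf) {
  df <- tibble::as_tibble(tornado_tbl) |>
    dplyr::filter(.data$swing > 0)
  df <- df |>
    dplyr::slice_head(n = min(top, nrow(df))) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  target <- attr(tornado_tbl, "target") %||% "outcome"
  ggplot2::ggplot(df) +
    ggplot2::geom_vline(xintercept = df$outcome_base[1],
                        colour = "grey40") +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$outcome_at_low, xend = .data$outcome_at_high,
                   y = .data$parameter, yend = .data$parameter),
      linewidth = 5, colour = "steelblue", alpha = 0.8
    ) +
    ggplot2::labs(
      x = if (target == "delta_cost") {
        "Incremental cost (US$/person-year)"
      } else {
        "Incremental effect (probability of FIR)"
      },
      y = NULL,
      title = "One-way sensitivity analysis"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tornado <- function(object, ...) plot_tornado(object, ...)
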