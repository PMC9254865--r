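#' Plot a three-state occupancy trace
#'
#' Stacked state occupancy over time: progression-free, progressed, dead.
#'
#' @param trace A [build_trace()] result.
#' @return A ggplot.
#' @export
plot_trace <- function(trace) {
  df <- as_tibble(trace) |>
    select("t_mid_years", "occ_pfs", "occ_pd", "occ_dead") |>
    tidyr::pivot_longer(-"t_mid_years", names_to = "state",
                        values_to = "occupancy") |>
    mutate(state = factor(.data$state,
                          levels = c("occ_dead", "occ_pd", "occ_pfs"),
                          labels = c("Dead", "Progressed",
                                     "Progression-free")))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_mid_years, .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years", y = "State occupancy", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psm_trace <- function(object, ...) plot_trace(object)

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param dsa Tibble from [one_way_dsa()].
#' @param top Show the `top` widest bars (default 12).
#' @return A ggplot.
#' @export
plot_tornado <- function(dsa, top = 12) {
  df <- dsa |>
    slice_head(n = top) |>
    mutate(parameter = factor(.data$parameter,
                              levels = rev(.data$parameter)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base),
                        linetype = 2) +
    ggplot2::labs(x = "ICER (RMB/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param ceac Tibble from [run_psa()]`$ceac` (or `$pairwise_ceac`, using
#'   the `comparator` column for colour).
#' @return A ggplot.
#' @export
plot_ceac <- function(ceac) {
  colour_var <- if ("strategy" %in% names(ceac)) "strategy" else "comparator"
  ggplot2::ggplot(ceac, ggplot2::aes(.data$wtp, .data$probability,
                                     colour = .data[[colour_var]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (RMB/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness plane
#'
#' Scatter of incremental (QALY, cost) pairs against the reference per PSA
#' iteration, with an optional WTP threshold line.
#'
#' @param psa A [run_psa()] result.
#' @param reference Reference strategy (default: from the samples'
#'   quadrant table).
#' @param wtp Optional threshold to draw.
#' @return A ggplot.
#' @export
plot_ce_plane <- function(psa, reference = psa$quadrants$reference[1],
                          wtp = NULL) {
  wide <- psa$samples |>
    tidyr::pivot_wider(names_from = "strategy",
                       values_from = c("cost", "qaly"))
  comps <- setdiff(unique(psa$samples$strategy), reference)
  df <- list_rbind(map(comps, function(cp) {
    tibble(comparator = cp,
           delta_qaly = wide[[paste0("qaly_", cp)]] -
             wide[[paste0("qaly_", reference)]],
           delta_cost = wide[[paste0("cost_", cp)]] -
             wide[[paste0("cost_", reference)]])
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$delta_qaly, .data$delta_cost,
                                        colour = .data$comparator)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (RMB)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2)
  }
  p
}
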