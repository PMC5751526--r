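# ggplot2 displays of solutions and simulations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an optimal intervention policy
#'
#' Tiles control steps against gene states (decimal encoding, MSB = x1);
#' fill marks whether the control is applied, in the style of the usual
#' intervention-policy figures.  Because optimal decisions may differ
#' between contexts sharing a gene state, tiles show the fraction of
#' contexts with control applied.
#'
#' @param object A `pbn_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pbn_solution <- function(object, ...) {
  pt <- extract_policy_table(object)
  df <- pt |>
    dplyr::group_by(.data$t, .data$state_decimal) |>
    dplyr::summarise(applied = mean(.data$control != strrep("0", nchar(.data$control[1]))),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$t), y = factor(.data$state_decimal),
                                   fill = .data$applied)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), name = "control\napplied") +
    ggplot2::labs(x = "time step t", y = "gene state (decimal)",
                  title = sprintf("Optimal policy, expected cost %.4g", object$value)) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of simulated trajectory costs
#'
#' @param object A `pbn_simulation`.
#' @param value Optional reference value (for instance the backward
#'   induction optimum) drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pbn_simulation <- function(object, value = NULL, ...) {
  df <- tibble::tibble(cost = object$samples)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = object$mean, linetype = 2) +
    ggplot2::labs(x = "realized trajectory cost", y = "trajectories",
                  title = sprintf("Monte-Carlo cost, mean %.4g (SE %.3g, n = %d)",
                                  object$mean, object$se, object$n_traj)) +
    ggplot2::theme_minimal()
  if (!is.null(value)) {
    gg <- gg + ggplot2::geom_vline(xintercept = value, color = "firebrick")
  }
  gg
}
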