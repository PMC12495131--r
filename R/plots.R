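#' Plot a hemodynamic trace
#'
#' Three stacked panels (ABP, CVP in mmHg; CO in L/min) against time, with
#' the arrest marked at t = 0.
#'
#' @param object A trace tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zf_trace
#' @export
autoplot.zf_trace <- function(object, ...) {
  plot_trace(object)
}

#' @rdname autoplot.zf_trace
#' @param trace A trace tibble (simulated or synthetic).
#' @export
plot_trace <- function(trace) {
  long <- trace |>
    tidyr::pivot_longer(dplyr::any_of(c("abp_mmhg", "cvp_mmhg", "co_l_min")),
                        names_to = "channel", values_to = "value") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = c("abp_mmhg", "cvp_mmhg", "co_l_min"),
                                   labels = c("ABP (mmHg)", "CVP (mmHg)", "CO (L/min)")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(ggplot2::aes(group = if ("animal" %in% names(trace))
      .data$animal else .data$label), linewidth = 0.3) +
    ggplot2::facet_grid(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time since arrest (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay arterial and venous mean pressures per scenario
#'
#' The study's central picture: MAP and CVP after arrest, one panel per
#' scenario, showing equilibration (reflexes off) versus the dynamic
#' course with a sustained veno-arterial gradient (reflexes on).
#'
#' @param traces Stacked (filtered) trace tibble with a `label` column.
#' @return A ggplot object.
#' @export
plot_study <- function(traces) {
  long <- traces |>
    tidyr::pivot_longer(c("abp_mmhg", "cvp_mmhg"), names_to = "channel",
                        values_to = "value") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel, abp_mmhg = "MAP",
                                          cvp_mmhg = "CVP"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "time since arrest (s)", y = "pressure (mmHg)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
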