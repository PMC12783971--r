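#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-compartment tracer recovery
#'
#' Bar chart of percent-of-added tracer per compartment with SD error bars,
#' faceted by arm.
#'
#' @param object A [percent_recovery()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tracer_recovery <- function(object, ...) {
  tab <- object$compartments
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$compartment_id,
                                    y = .data$percent_of_added,
                                    fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$percent_of_added - .data$percent_sd,
                   ymax = .data$percent_of_added + .data$percent_sd),
      width = 0.3
    ) +
    ggplot2::facet_wrap(~arm_id, scales = "free_x") +
    ggplot2::labs(x = "Sampled compartment",
                  y = "Tracer found (% of total added)",
                  title = paste0("Tracer recovery (", object$element, ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot source-layer contributions to sink enrichment
#'
#' @param object A [partition_sink()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tracer_partition <- function(object, ...) {
  ggplot2::ggplot(object$layers,
                  ggplot2::aes(x = .data$layer,
                               y = .data$contribution_pct,
                               fill = .data$layer)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Labelled layer",
                  y = "Contribution to sink uptake (%)") +
    ggplot2::theme_minimal()
}

#' Plot single-cell isotope enrichment
#'
#' Scatter of per-cell delta 13C against delta 15N coloured by morphotype,
#' with dashed lines at the control-derived +/- 2 SD boundaries; points
#' above the upper lines are the significantly enriched cells.
#'
#' @param object A [nanosims_cells()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.nanosims_cells <- function(object, ...) {
  b13 <- object$boundaries[object$boundaries$isotope == "13C", ]
  b15 <- object$boundaries[object$boundaries$isotope == "15N", ]
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$delta13C, y = .data$delta15N,
                               colour = .data$morphotype,
                               shape = .data$is_control)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(b13$lower, b13$upper),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(b15$lower, b15$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(delta^13 * C ~ "(‰ vs control)"),
                  y = expression(delta^15 * N ~ "(‰ vs control)")) +
    ggplot2::theme_minimal()
}
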