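#' Plot read placements around a circRNA junction
#'
#' Shows each placement of one circRNA unit as a horizontal segment in
#' doubled-unit coordinates, with the back-splice junction as a vertical
#' line; junction-spanning placements are highlighted.
#'
#' @param placements tibble from [assign_to_units()].
#' @param vg the [build_virtual_genome()] object.
#' @param circ_id which circRNA to draw.
#' @return a ggplot object.
#' @export
plot_junction_coverage <- function(placements, vg, circ_id) {
  u <- vg$units[vg$units$circ_id == circ_id, ]
  if (nrow(u) == 0) abort(sprintf("unknown circRNA id: %s", circ_id))
  df <- placements |>
    filter(.data$circ_id == !!circ_id) |>
    mutate(ustart = .data$start - u$offset, uend = .data$end - u$offset) |>
    arrange(.data$ustart) |>
    mutate(y = row_number())
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ustart, xend = .data$uend,
                                       y = .data$y, yend = .data$y,
                                       colour = .data$spans),
                          linewidth = 1.2) +
    ggplot2::geom_vline(xintercept = u$length, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey60"),
                                 name = "spans junction") +
    ggplot2::labs(x = sprintf("position in doubled unit (junction at %d)",
                              u$length),
                  y = "read", title = circ_id) +
    ggplot2::theme_minimal()
}

#' Plot detection sensitivity against junction read depth
#'
#' @param df tibble with columns `depth` and `sensitivity` (e.g. from a
#'   depth-titration experiment on simulated bundles).
#' @return a ggplot object.
#' @export
plot_depth_sensitivity <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth, y = .data$sensitivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(trans = "log2", breaks = unique(df$depth)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "junction-spanning reads per translated circRNA",
                  y = "sensitivity") +
    ggplot2::theme_minimal()
}
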