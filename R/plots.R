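#' Fitness trajectories over generations of MA
#'
#' Plots per-line mean fitness (absolute `W` or relative `w`) of the
#' ancestral controls (Gmax = 0) and the MA sublines (Gmax = t), one
#' trajectory per line x assay, colored by fitness group.
#'
#' @param records Fitness records from [relative_fitness()] (or row-bound
#'   over assays).
#' @param measure `"w"` (default) or `"W"`.
#' @return A ggplot object.
#' @export
plot_fitness_trajectories <- function(records, measure = c("w", "W")) {
  measure <- match.arg(measure)
  if (!"assay_id" %in% names(records)) records$assay_id <- "assay1"
  d <- records |>
    dplyr::filter(.data$fitness_class != "ancestor") |>
    dplyr::group_by(.data$assay_id, .data$line_id, .data$fitness_class,
                    .data$gmax) |>
    dplyr::summarise(fitness = mean(.data[[measure]]), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gmax, y = .data$fitness,
                                  group = paste(.data$assay_id, .data$line_id),
                                  colour = .data$fitness_class)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Generations of MA (Gmax)",
                  y = paste0("Mean ", measure),
                  colour = "Fitness group") +
    ggplot2::theme_minimal()
}

#' Forest plot of per-line mutational decay
#'
#' @param object An [estimate_lines()] table (or the `line_estimates`
#'   element of a pipeline result).
#' @param quantity Column to plot with its CI: `"delta_m"` (default) or
#'   `"v_m_star"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ma_line_estimates
#' @export
autoplot.ma_line_estimates <- function(object, quantity = "delta_m", ...) {
  plot_line_estimates(object, quantity)
}

#' @rdname autoplot.ma_line_estimates
#' @export
plot_line_estimates <- function(object, quantity = c("delta_m", "v_m_star")) {
  quantity <- match.arg(quantity)
  lo <- paste0(quantity, "_lo"); hi <- paste0(quantity, "_hi")
  d <- dplyr::mutate(as_tibble(object),
                     label = paste(.data$line_id, .data$assay_id, sep = " / "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[quantity]], y = .data$label,
                                  colour = .data$fitness_class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data[[lo]],
                                          xmax = .data[[hi]])) +
    ggplot2::labs(x = quantity, y = NULL, colour = "Fitness group") +
    ggplot2::theme_minimal()
}
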