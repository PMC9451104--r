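#' Plot a simulated trajectory
#'
#' Four-panel summary of a run: population levels, carrying capacities,
#' coevolution coefficients (with the classification threshold) and
#' dependency coefficients, all against time. Vertical dashed lines mark
#' the registered timing of the human and plant type shifts, when they
#' occurred.
#'
#' @param object A `coevo_run` object from [run_coevo()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.coevo_run <- function(object, ...) {
  tr <- object$trajectory
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      tr[c("time", "humans", "plants")],
      -"time", names_to = "population", values_to = "value") |>
      dplyr::mutate(panel = "population"),
    tidyr::pivot_longer(
      tr[c("time", "carrying_capacity_humans", "carrying_capacity_plants")],
      -"time", names_to = "population", values_to = "value") |>
      dplyr::mutate(population = sub("carrying_capacity_", "", .data$population),
                    panel = "carrying capacity"),
    tidyr::pivot_longer(
      tr[c("time", "coevolution_coefficient_humans",
           "coevolution_coefficient_plants")],
      -"time", names_to = "population", values_to = "value") |>
      dplyr::mutate(population = sub("coevolution_coefficient_", "",
                                     .data$population),
                    panel = "coevolution coefficient"),
    tidyr::pivot_longer(
      tr[c("time", "dependency_coefficient_humans",
           "dependency_coefficient_plants")],
      -"time", names_to = "population", values_to = "value") |>
      dplyr::mutate(population = sub("dependency_coefficient_", "",
                                     .data$population),
                    panel = "dependency coefficient")
  )
  long$panel <- factor(long$panel,
                       levels = c("population", "carrying capacity",
                                  "coevolution coefficient",
                                  "dependency coefficient"))
  timings <- tibble::tibble(
    population = c("humans", "plants"),
    timing = c(object$timing_humans, object$timing_plants))
  timings <- timings[!is.na(timings$timing), ]

  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL, colour = NULL,
                  title = paste("end-state:", object$end_state_class)) +
    ggplot2::theme_minimal()
  if (nrow(timings) > 0) {
    p <- p + ggplot2::geom_vline(
      data = timings,
      ggplot2::aes(xintercept = .data$timing, colour = .data$population),
      linetype = "dashed", show.legend = FALSE)
  }
  p
}

#' @rdname autoplot.coevo_run
#' @param run A `coevo_run` object.
#' @export
plot_trajectory <- function(run, ...) autoplot.coevo_run(run, ...)

#' Plot the evolution of a type distribution
#'
#' Heatmap of the type-proportion vector over time for one population;
#' requires a run with `keep_proportions = TRUE` (the default).
#'
#' @param run A `coevo_run` object.
#' @param population `"humans"` or `"plants"`.
#' @return A ggplot object.
#' @export
plot_type_distribution <- function(run, population = c("humans", "plants")) {
  population <- match.arg(population)
  prefix <- paste0("type_proportions_", population, "_")
  cols <- grep(prefix, names(run$trajectory), value = TRUE)
  if (length(cols) == 0) {
    stop("run was simulated without stored type proportions", call. = FALSE)
  }
  long <- tidyr::pivot_longer(run$trajectory[c("time", cols)], -"time",
                              names_to = "type", values_to = "proportion")
  long$type <- as.integer(sub(prefix, "", long$type))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$type,
                                     fill = .data$proportion)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "time step", y = paste(population, "type"),
                  fill = "share") +
    ggplot2::theme_minimal()
}
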