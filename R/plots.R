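# ggplot2 displays for prediction sets and change maps. These are point maps
# at reef centroids — the package works on centroid evidence, so there are no
# polygons to draw.

#' Map per-reef decline probabilities
#'
#' Plots reef centroids coloured by predicted decline probability. Supply the
#' reef table for coordinates.
#'
#' @param object A `reefbn_predictions` tibble.
#' @param reefs Reef tibble with `reef_id`, `lon`, `lat`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.reefbn_predictions <- function(object, reefs, ...) {
  df <- dplyr::inner_join(
    tibble::as_tibble(object),
    tibble::as_tibble(reefs)[c("reef_id", "lon", "lat")],
    by = "reef_id"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, colour = .data$p_decline)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 1), name = "P(decline)") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      title = sprintf(
        "10-year decline probability: %s (%s)",
        attr(object, "scenario"), attr(object, "parameterization")
      ),
      x = "Longitude", y = "Latitude"
    ) +
    ggplot2::theme_minimal()
}

#' Map relative change between two scenarios
#'
#' Plots reef centroids coloured by the relative change in decline
#' probability, `(b - a) / a`; reefs with an undefined change (reference 0)
#' are dropped with a message.
#'
#' @param object A `reefbn_change_map` tibble.
#' @inheritParams autoplot.reefbn_predictions
#'
#' @return A ggplot object.
#' @export
autoplot.reefbn_change_map <- function(object, reefs, ...) {
  df <- dplyr::inner_join(
    tibble::as_tibble(object),
    tibble::as_tibble(reefs)[c("reef_id", "lon", "lat")],
    by = "reef_id"
  )
  if (any(df$undefined)) {
    inform(sprintf("dropping %d reef(s) with undefined relative change", sum(df$undefined)))
    df <- df[!df$undefined, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, colour = .data$rel_change)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_gradient2(name = "Relative\nchange") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      title = sprintf(
        "Relative change in decline probability: %s vs %s",
        attr(object, "scenario_b"), attr(object, "scenario_a")
      ),
      x = "Longitude", y = "Latitude"
    ) +
    ggplot2::theme_minimal()
}

#' Compare scenario means across parameterizations
#'
#' Bar chart of mean decline probability per scenario and parameterization,
#' from the `means` table of [run_pipeline()] / [pipeline_report()].
#'
#' @param means Tibble with `scenario`, `parameterization`, `mean_decline`.
#'
#' @return A ggplot object.
#' @export
plot_scenario_means <- function(means) {
  ggplot2::ggplot(
    tibble::as_tibble(means),
    ggplot2::aes(.data$scenario, .data$mean_decline, fill = .data$parameterization)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Mean P(decline over 10 years)", fill = "Parameterization"
    ) +
    ggplot2::theme_minimal()
}
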