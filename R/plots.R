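#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of classifier outcomes
#'
#' Players as rows, features and summary scores as columns; fill is the
#' min-max normalised value and atypical cells are outlined.
#'
#' @param object A `neglect_classification`.
#' @param group `"patient"` or `"control"` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot neglect_classification
#' @export
autoplot.neglect_classification <- function(object, group = c("patient", "control"), ...) {
  group <- match.arg(group)
  hm <- heatmap_table(object)
  tab <- if (group == "patient") hm$patients else hm$controls
  long <- tab %>%
    tidyr::pivot_longer(
      dplyr::all_of(heatmap_feature_cols()),
      names_to = "feature", values_to = "value"
    ) %>%
    dplyr::mutate(feature = factor(.data$feature, levels = heatmap_feature_cols()))
  masks <- tab %>%
    tidyr::pivot_longer(
      dplyr::starts_with("mask_"),
      names_to = "feature", values_to = "atypical"
    ) %>%
    dplyr::mutate(feature = sub("^mask_", "", .data$feature)) %>%
    dplyr::select("player_id", "feature", "atypical")
  long <- dplyr::left_join(long, masks, by = c("player_id", "feature"))
  long$atypical[is.na(long$atypical)] <- FALSE
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$feature, y = .data$player_id, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = dplyr::filter(long, .data$atypical),
      fill = NA, colour = "orange", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "normalised\nvalue",
      title = paste0("Classifier heatmap (", group, "s)")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a raycast attention histogram
#'
#' @param histogram Output of [raycast_histogram()].
#' @return A ggplot of binned attention frequency.
#' @export
plot_raycast_histogram <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(
    x = .data$lat_bin, y = .data$vert_bin, fill = .data$count
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "lateral angle (deg, negative = left)",
      y = "vertical angle (deg)", fill = "frames"
    ) +
    ggplot2::theme_minimal()
}

#' Plot gameplay performance by target position
#'
#' @param map Output of [position_maps()].
#' @param metric `"accuracy_pct"` or `"rt_s"`.
#' @return A ggplot.
#' @export
plot_position_map <- function(map, metric = c("accuracy_pct", "rt_s")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(map, ggplot2::aes(
    x = .data$target_lateral_angle, y = .data$target_vertical_angle,
    fill = .data[[metric]]
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(
      direction = if (metric == "rt_s") -1 else 1,
      na.value = "grey85"
    ) +
    ggplot2::labs(
      x = "target lateral angle (deg)", y = "target vertical angle (deg)",
      fill = if (metric == "rt_s") "RT (s)" else "accuracy (%)"
    ) +
    ggplot2::theme_minimal()
}
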