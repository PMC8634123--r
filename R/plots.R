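#' Plot 2D tracks
#'
#' Draws each track's path, optionally coloured by a per-track label such
#' as group, model or assigned mode.
#'
#' @param tracks A track table.
#' @param colour_by Optional tibble with `track_id` and one label column,
#'   or the name of a column already present in `tracks` (e.g. `"group"`).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, colour_by = "group") {
  tracks <- as_tibble(tracks)
  if (is.data.frame(colour_by)) {
    lab <- colour_by
    names(lab)[2] <- ".label"
    tracks <- left_join(tracks, lab, by = "track_id")
  } else {
    tracks$.label <- tracks[[colour_by]]
  }
  ggplot2::ggplot(tracks,
                  ggplot2::aes(.data$x, .data$y, group = .data$track_id,
                               colour = .data$.label)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot saltatr_lag_curves
#' @export
autoplot.saltatr_lag_curves <- function(object, ...) {
  type <- attr(object, "type") %||% "msd"
  ylab <- if (identical(type, "msd")) "MSD (µm²)" else "VAC"
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(.data$lag, .data$value,
                                    colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "delay (min)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
  if (identical(type, "vac")) {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed")
  }
  p
}

#' Stacked mode-composition plot
#'
#' @param composition A [mode_composition()] tibble.
#' @return A ggplot object (stacked proportions per group).
#' @export
plot_mode_composition <- function(composition) {
  ggplot2::ggplot(as_tibble(composition),
                  ggplot2::aes(.data$group, .data$prop, fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion of tracks", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Control-normalised effect heatmap
#'
#' Tile heatmap of the log2 treatment/control effects from
#' [compare_groups()]; entries that are non-significant after Bonferroni
#' correction (or undefined) are greyed out.
#'
#' @param stats A `saltatr_group_stats` result.
#' @return A ggplot object.
#' @export
plot_effect_heatmap <- function(stats) {
  df <- mutate(as_tibble(stats),
               shown = ifelse(.data$significant & .data$effect_defined,
                              .data$effect_log2, NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$feature,
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", na.value = "grey80",
                                  name = "log2 effect") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   axis.text.y = ggplot2::element_text(size = 6))
}
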