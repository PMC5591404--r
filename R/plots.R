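# Visualization: search path over the board, and heat maps. The y axis is
# reversed everywhere so plots match the screen convention (origin
# top-left, y downward).

#' Plot a search path over the stimulus board
#'
#' Draws the fixation polyline over the board's stimuli; tagged stimuli
#' are highlighted. Fixation point size scales with duration.
#'
#' @param tags tag events from [detect_tags()].
#' @param fixations fixation data frame from [extract_fixations()].
#' @param board an `etnt_board`.
#' @return A ggplot object.
#' @export
plot_search_path <- function(tags, fixations, board) {
  st <- board$stimuli
  st$tagged <- st$id %in% tags$stimulus_id
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(
      data = st,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$kind,
                   colour = .data$tagged),
      size = 3) +
    ggplot2::scale_shape_manual(values = c(target = 15, distractor = 1)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d62728",
                                            `FALSE` = "grey40"))
  if (nrow(fixations)) {
    p <- p +
      ggplot2::geom_path(data = fixations,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "#1f77b4", alpha = 0.6) +
      ggplot2::geom_point(data = fixations,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       size = .data$duration_s),
                          colour = "#1f77b4", alpha = 0.4)
  }
  p +
    ggplot2::scale_y_reverse(limits = c(1, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "x (screen widths)", y = "y (screen heights)",
                  size = "fixation (s)", colour = "tagged") +
    ggplot2::theme_minimal()
}

#' Plot a heat map
#'
#' @param hm an `etnt_heatmap` (cumulative gaze seconds, or a signed
#'   post-minus-pre difference from [diff_heat_map()]).
#' @return A ggplot object.
#' @export
plot_heat_map <- function(hm) {
  stopifnot(inherits(hm, "etnt_heatmap"))
  df <- expand.grid(row = seq_len(hm$bins_y), col = seq_len(hm$bins_x))
  df$value <- as.vector(hm$grid)
  df$x <- (df$col - 0.5) / hm$bins_x
  df$y <- (df$row - 0.5) / hm$bins_y
  signed <- any(df$value < 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (screen widths)", y = "y (screen heights)",
                  fill = "gaze (s)") +
    ggplot2::theme_minimal()
  if (signed) {
    p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                      high = "#b2182b", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}
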