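map_df_for_plot <- function(m, grid, value_name = "value") {
  fp <- fine_pitch(grid)
  d <- dim(m)
  tibble(x_um = (rep(seq_len(d[2]) - 1L, each = d[1]) + 0.5) * fp[["x"]],
         z_um = (rep(seq_len(d[1]) - 1L, d[2]) + 0.5) * fp[["z"]],
         value = as.vector(m))
}

#' Plot a super-resolved ULM map
#'
#' Renders one component of an [accumulate_maps()] result; the flow map is
#' shown through the square-root display transform.
#'
#' @param object an `ulm_maps` object.
#' @param which one of `"mb_flow"`, `"speed"`, `"vz"`, `"backscatter"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ulm_maps <- function(object, which = "mb_flow", ...) {
  m <- object[[which]]
  lab <- which
  if (which == "mb_flow") { m <- display_transform(m); lab <- "sqrt(MB flow)" }
  df <- map_df_for_plot(m, object$grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$z_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "depth (um)")
}

#' Plot microbubble tracks
#'
#' @param tracks a `track_set`.
#' @param max_tracks cap on the number of tracks drawn.
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks, max_tracks = 500) {
  det <- tracks$detections
  ids <- unique(det$track_id)
  if (length(ids) > max_tracks) det <- det[det$track_id %in%
                                             ids[seq_len(max_tracks)], ]
  ggplot2::ggplot(det, ggplot2::aes(.data$x_um, .data$z_um,
                                    group = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.5, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "depth (um)")
}

#' @export
autoplot.cbv_response <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$t_pattern_s, .data$dcbv_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "pattern time (s)", y = expression(Delta * "CBV (%)"))
}

#' @export
autoplot.activation_map <- function(object, ...) {
  df <- tidy.activation_map(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$z_um,
                                   fill = 100 * .data$relative_increase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(name = "MB flow increase (%)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "depth (um)")
}

#' @export
autoplot.activation_signal <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_pattern_s, .data$signal_pct,
                                       colour = .data$band)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::labs(x = "pattern time (s)", y = "MB flow (% of baseline)")
}
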