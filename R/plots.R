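#' Plot a detection-rate map
#'
#' Raster of the per-sniff detection probability with the 10% isoline, in
#' source-relative metres (x downwind).
#'
#' @param object a [detection_rate_map()].
#' @param level isoline level (relative to the map maximum).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.detection_rate_map <- function(object, level = 0.1, ...) {
  df <- map_to_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$rate)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$rate),
                          breaks = level * max(df$rate),
                          colour = "white", linewidth = 0.3) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, colour = "red") +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "downwind distance x (m)", y = "crosswind y (m)",
                  fill = "detection\nrate / sniff",
                  title = sprintf("%s detection-rate map", object$modality))
}

#' Plot a trajectory
#'
#' Path of the agent in source-relative coordinates, coloured by behavioural
#' segment (surge / cast / other), with air sniffs and detections marked.
#'
#' @param object a [run_episode()] trajectory.
#' @param k segmentation run length.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sniff_trajectory <- function(object, k = 3, ...) {
  h <- attr(object, "cell_size") %||% 1
  df <- classify_segments(object, k)
  df$x_m <- df$x * h; df$y_m <- df$y * h
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_m, y = .data$y_m)) +
    ggplot2::geom_path(colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$segment), size = 0.8) +
    ggplot2::geom_point(data = df[df$air_sniff, ], shape = 2, size = 1.5) +
    ggplot2::geom_point(data = df[df$observation == "detection", ],
                        colour = "red", size = 2) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 4, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "downwind distance x (m)", y = "crosswind y (m)",
                  colour = "segment",
                  title = sprintf("trajectory (%s)", attr(object, "outcome")))
}

#' Plot an episode schedule
#'
#' Casting time versus episode index (the final, indefinite cast is
#' omitted).
#'
#' @param object an `episode_schedule`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.episode_schedule <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$cast_time), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$cast_time)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "episode n", y = "optimal casting time t_n (s)")
}

#' Plot a cast plan
#'
#' The zigzag of sniff positions against cumulative time, with the survival
#' probability as point shade.
#'
#' @param object a [plan_cast_sniff()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cast_plan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$pos)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(alpha = .data$survival)) +
    ggplot2::labs(x = "time (s)", y = "sniff position y (m)",
                  alpha = "c(t)")
}

#' Plot a belief over the grid
#'
#' @param spec a [build_spec()] object.
#' @param belief belief vector.
#' @param level air-plume isoline drawn for reference.
#' @return a ggplot.
#' @export
plot_belief <- function(spec, belief, level = 0.25) {
  df <- belief_to_tibble(spec, belief)
  air <- map_to_tibble(spec$air_map)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
    ggplot2::geom_contour(data = air, ggplot2::aes(z = .data$rate),
                          breaks = level * max(air$rate), colour = "white",
                          linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(option = "magma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = "belief")
}
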