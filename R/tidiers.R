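#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy haemodynamic maps
#'
#' Long-format tidy view: one row per wall sample and metric.
#'
#' @param x A [haemodynamic_maps()] object.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `metric`, `value`.
#' @method tidy haemodynamic_maps
#' @export
tidy.haemodynamic_maps <- function(x, ...) {
  df <- tibble::as_tibble(x)[c("sample", "tawss", "osi", "ecap", "pswss")]
  out <- tibble::tibble(
    sample = rep(df$sample, 4L),
    metric = rep(c("tawss", "osi", "ecap", "pswss"), each = nrow(df)),
    value = c(df$tawss, df$osi, df$ecap, df$pswss))
  out
}

#' Summarise haemodynamic maps
#'
#' One-row summary across wall samples: field means and extremes of the
#' risk metrics.
#'
#' @param x A [haemodynamic_maps()] object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance haemodynamic_maps
#' @export
glance.haemodynamic_maps <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    mean_tawss = mean(x$tawss, na.rm = TRUE),
    min_tawss = min(x$tawss, na.rm = TRUE),
    max_osi = max(x$osi, na.rm = TRUE),
    max_ecap = max(x$ecap, na.rm = TRUE),
    max_pswss = max(x$pswss, na.rm = TRUE),
    period = attr(x, "period"))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot haemodynamic maps along the wall
#'
#' Metric value against wall sample position (arc ordering by sample id
#' when no coordinates are joined).
#'
#' @param object A [haemodynamic_maps()] object.
#' @param metric One of `"tawss"`, `"osi"`, `"ecap"`, `"pswss"`, or
#'   `"all"` (facetted).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot haemodynamic_maps
#' @export
autoplot.haemodynamic_maps <- function(object, metric = "all", ...) {
  long <- tidy.haemodynamic_maps(object)
  if (!identical(metric, "all"))
    long <- long[long$metric %in% metric, , drop = FALSE]
  xvar <- if ("x" %in% names(object)) {
    long$xpos <- object$x[match(long$sample, object$sample)]
    "xpos"
  } else "sample"
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xvar]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = if (xvar == "xpos") "wall position (m)" else "sample",
                  y = NULL, title = "Haemodynamic wall maps")
}

#' Plot a particle snapshot
#'
#' Scatter of particle positions coloured by a field, in the style of the
#' usual SPH state plots.
#'
#' @param object A [particle_system()].
#' @param colour Field to colour by: `"speed"`, `"rho"`, `"p"` or `"tag"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot particle_system
#' @export
autoplot.particle_system <- function(object, colour = "speed", ...) {
  df <- as_tibble.particle_system(object)
  df$speed <- sqrt(df$vx^2 + df$vy^2 + if ("vz" %in% names(df)) df$vz^2 else 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data[[colour]])) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Plot the pulsatile inlet waveform
#'
#' @param object An [inlet_profile()].
#' @param n_cycles Number of cardiac cycles to draw (default 2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot inlet_profile
#' @export
autoplot.inlet_profile <- function(object, n_cycles = 2, ...) {
  t <- seq(0, n_cycles * object$period, length.out = 400 * n_cycles)
  df <- tibble::tibble(t = t, u = pulsatile_inlet_velocity(t, object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$u)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "inlet speed (m/s)",
                  title = "Pulsatile inlet waveform")
}

#' @importFrom rlang .data
NULL

#' Coerce to tibble
#' @name as_tibble
#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
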