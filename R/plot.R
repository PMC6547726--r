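#' Plot a theoretical saturation curve
#'
#' Apparent FRET efficiency versus acceptor:donor ratio on a log ratio
#' axis, the standard depiction of a binding saturation series.
#'
#' @param curve A tibble from [saturation_curve()] (columns `ratio`,
#'   `efficiency`).
#' @return A ggplot object.
#' @export
plot_saturation_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$ratio, y = .data$efficiency)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "acceptor : donor ratio",
      y = "apparent FRET efficiency"
    ) +
    ggplot2::theme_classic()
}

#' Plot per-cell DFRET values with the moving-average curve
#'
#' Scatter of per-cell DFRET against acceptor:donor molar ratio with the
#' moving-average saturation curve overlaid in red, the standard population
#' view of a titration series.
#'
#' @param cells Normalized cell table from [normalize_cells()].
#' @param window Moving-average window passed to [aggregate_curve()].
#' @return A ggplot object.
#' @export
plot_dfret_population <- function(cells, window = 25) {
  curve <- aggregate_curve(cells, window = window)
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$ratio, y = .data$DFRET)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(
      data = curve, colour = "red", linewidth = 0.9
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "acceptor : donor ratio", y = "DFRET") +
    ggplot2::theme_classic()
}

#' Autoplot a fitted mass-action DFRET model
#'
#' Observed per-cell DFRET (blue) and the model prediction at the fitted
#' parameters (red) against the acceptor:donor ratio, for the in-window
#' cells used by the fit.
#'
#' @param object A `fret_fit` from [fit_interaction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fret_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$DFRET), colour = "steelblue",
      alpha = 0.3, size = 0.8
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$.fitted), colour = "red",
      alpha = 0.5, size = 0.8
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "acceptor : donor ratio", y = "DFRET",
      title = sprintf(
        "Ka_app = %.3g, z = %.3g, FRET_max = %.3g",
        object$coefficients$estimate[1],
        object$coefficients$estimate[2],
        object$coefficients$estimate[3]
      )
    ) +
    ggplot2::theme_classic()
}

#' Render a pixelwise DFRET map
#'
#' Displays the DFRET map with a fixed display range (default 0-0.4, the
#' conventional range for these maps); values outside the range are clamped
#' in the rendering only, and masked pixels are drawn dark.
#'
#' @param map_result Result of [dfret_map()] (or a bare matrix).
#' @param range Display range for DFRET.
#' @return A ggplot object.
#' @export
plot_dfret_map <- function(map_result, range = c(0, 0.4)) {
  m <- if (is.list(map_result)) map_result$map else map_result
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    dfret = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$dfret)) +
    ggplot2::scale_fill_viridis_c(
      option = "inferno", limits = range, oob = scales::squish,
      na.value = "grey10", name = "DFRET"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
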