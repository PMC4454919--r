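#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a radial tuning shape and its Fisher-information integrand
#'
#' Two stacked panels: the firing-rate profile `Omega(r)` and the
#' integrand `F(r)` that weights each phase distance's contribution to
#' the module's resolution.
#'
#' @param object A `tuning_shape`.
#' @param n Number of radii to evaluate.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tuning_shape <- function(object, n = 400, ...) {
  r <- seq(0, object$support * 1.1, length.out = n)
  df <- dplyr::bind_rows(
    tibble::tibble(r = r, value = object$value(r), panel = "Omega(r)"),
    tibble::tibble(r = r, value = fi_integrand(object, r), panel = "F(r)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "distance to nearest node", y = NULL,
      title = sprintf("%s tuning shape, support %.3g", object$family, object$support)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the realization distributions of a finite-module comparison
#'
#' Overlaid histograms of per-neuron population Fisher-information traces
#' for the two geometries, with the large-`M` averages as vertical lines.
#'
#' @param object A `module_comparison`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_comparison <- function(object, bins = 60, ...) {
  df <- tidy(object)
  avg <- tibble::tibble(
    geometry = c(object$label_a, object$label_b),
    average = c(object$average_a, object$average_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trace, fill = .data$geometry)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.55, position = "identity") +
    ggplot2::geom_vline(
      data = avg,
      ggplot2::aes(xintercept = .data$average, colour = .data$geometry),
      linetype = 2, show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "population trJ / M at the origin", y = "realizations",
      title = sprintf(
        "%s vs %s (M = %d): %s wins %.1f%% of realizations",
        object$label_a, object$label_b, object$M,
        object$label_b, 100 * object$fraction_b_beats_a
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an angle sweep of the average Fisher information
#'
#' In 2D, `trJ` against `phi` with the `1/sin(phi)` law it follows when
#' the tuning support fits in every cell; in 3D, a tile plot over
#' `(phi, psi)`.
#'
#' @param object An `fi_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fi_sweep <- function(object, ...) {
  if (attr(object, "dimension") == 2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$phi, y = .data$trace)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "spanning angle phi (rad)", y = "average trJ per neuron",
        title = "Resolution falls as 1/sin(phi); maximum at the hexagonal lattice"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(
      x = .data$phi, y = .data$psi, fill = .data$trace
    )) +
      ggplot2::geom_tile() +
      ggplot2::labs(
        x = "phi (rad)", y = "psi (rad)", fill = "trJ",
        title = "Resolution falls as 1/(sin phi sin psi)"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot the node set of a planar lattice
#'
#' Scatter of lattice nodes within a window, with the in-circle of the
#' Voronoi cell around the origin.
#'
#' @param L A 2D `grid_lattice`.
#' @param k_max Range of integer coefficients to draw.
#' @return A ggplot object.
#' @export
plot_lattice <- function(L, k_max = 3) {
  stopifnot(inherits(L, "grid_lattice"), L$dim == 2L)
  g <- expand.grid(k1 = -k_max:k_max, k2 = -k_max:k_max)
  pts <- t(L$basis %*% t(as.matrix(g)))
  df <- tibble::tibble(x = pts[, 1], y = pts[, 2])
  R <- packing_radius(L)
  th <- seq(0, 2 * pi, length.out = 200)
  circ <- tibble::tibble(x = R * cos(th), y = R * sin(th))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_path(data = circ, colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf(
      "%s: det %.4g, packing ratio %.4g", L$name, lattice_det(L), packing_ratio(L)
    )) +
    ggplot2::theme_minimal()
}
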