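#' Compare two geometries at finite module size
#'
#' Draws `n_realizations` independent grid modules of `M` uniformly
#' placed phases for each geometry, computes each module's population
#' Fisher-information trace at the origin divided by `M`, and reports the
#' two distributions together with the fraction of realizations in which
#' geometry B strictly outperforms geometry A.  At finite `M` the traces
#' fluctuate around the [average_fi()] values, so a sparser geometry can
#' win a noticeable fraction of the time even when it is worse on
#' average.
#'
#' Phase draws are unpaired by default (independent draws per geometry
#' and realization); `paired = TRUE` reuses the same unit-cube variates
#' for both geometries.  Every realization consumes its own substream of
#' the master seed, so results are reproducible and independent of
#' evaluation order.
#'
#' @param geom_a,geom_b Geometries (`grid_lattice` or `sphere_packing`).
#' @param shape A `tuning_shape`.
#' @param M Module size (phases per realization).
#' @param n_realizations Number of realizations.
#' @param seed Master seed (required).
#' @param paired Reuse phase variates across the two geometries?
#' @inheritParams fi_integrand
#' @return An object of class `module_comparison`: a list with
#'   `realizations` (tibble with columns `realization`, `trace_a`,
#'   `trace_b`, per-neuron normalised), `fraction_b_beats_a`, summary
#'   means/sds, the expected large-`M` traces, and the seed.
#' @examples
#' cmp <- compare_modules(named_lattice("H"), named_lattice("Q"),
#'   bump_shape(1 / 4, 0.4),
#'   M = 50, n_realizations = 200, seed = 7
#' )
#' glance(cmp)
#' @export
compare_modules <- function(geom_a, geom_b, shape, M = 200,
                            n_realizations = 5000, seed,
                            paired = FALSE, noise = poisson_noise(),
                            fmax = 1, tau = 1) {
  if (missing(seed)) stop("a master seed is required")
  stopifnot(M >= 1, n_realizations >= 1)
  ta <- .realization_traces(geom_a, shape, M, n_realizations, seed,
    stream = 0L, noise = noise, fmax = fmax, tau = tau
  )
  tb <- .realization_traces(geom_b, shape, M, n_realizations, seed,
    stream = if (paired) 0L else 1L, noise = noise, fmax = fmax, tau = tau
  )
  realizations <- tibble::tibble(
    realization = seq_len(n_realizations),
    trace_a = ta, trace_b = tb
  )
  avg <- function(g) {
    average_fi(shape, g,
      noise = noise, method = "auto", fmax = fmax, tau = tau,
      mc_points = 2e5, seed = .substream_seed(seed, 999983L)
    )$trace
  }
  structure(
    list(
      realizations = realizations,
      label_a = geom_a$name, label_b = geom_b$name,
      n_realizations = n_realizations, M = M,
      fraction_b_beats_a = mean(tb > ta),
      mean_a = mean(ta), mean_b = mean(tb),
      sd_a = stats::sd(ta), sd_b = stats::sd(tb),
      average_a = avg(geom_a), average_b = avg(geom_b),
      paired = paired, seed = as.integer(seed)
    ),
    class = "module_comparison"
  )
}

# Per-realization population FI traces at the origin, per neuron.  For a
# module evaluated at 0 the trace is the sum of F(||c_i||) over phases,
# so all realizations can be drawn substream-by-substream and reduced in
# one vectorised batch.
.realization_traces <- function(geometry, shape, M, n, seed, stream,
                                noise, fmax, tau) {
  D <- geometry$dim
  B <- if (inherits(geometry, "sphere_packing")) {
    geometry$period$basis
  } else {
    geometry$basis
  }
  U <- matrix(0, nrow = D, ncol = n * M)
  for (i in seq_len(n)) {
    set.seed(.substream_seed(seed, 2L * (i - 1L) + stream))
    U[, (i - 1L) * M + seq_len(M)] <- stats::runif(D * M)
  }
  d <- reduce_points(geometry, t(B %*% U))$distance
  f <- fi_integrand(shape, d, noise, fmax, tau)
  colSums(matrix(f, nrow = M)) / M
}

#' @export
print.module_comparison <- function(x, ...) {
  cat(sprintf(
    "<module_comparison> %s vs %s, M = %d, n = %d%s\n",
    x$label_a, x$label_b, x$M, x$n_realizations,
    if (x$paired) " (paired)" else ""
  ))
  cat(sprintf(
    "  mean trJ/M: %s %.5g (avg %.5g), %s %.5g (avg %.5g)\n",
    x$label_a, x$mean_a, x$average_a, x$label_b, x$mean_b, x$average_b
  ))
  cat(sprintf(
    "  fraction of realizations with %s > %s: %.4f\n",
    x$label_b, x$label_a, x$fraction_b_beats_a
  ))
  invisible(x)
}

#' Monte-Carlo mean versus large-M average
#'
#' Checks how closely the mean of the finite-module per-neuron traces
#' matches the analytic large-`M` average for one geometry.
#'
#' @inheritParams compare_modules
#' @param geometry The geometry to test.
#' @return A one-row tibble with the Monte-Carlo mean, its standard
#'   error, the [average_fi()] value, and the relative gap.
#' @export
mean_vs_average <- function(geometry, shape, M = 200, n_realizations = 5000,
                            seed, noise = poisson_noise(), fmax = 1, tau = 1) {
  if (missing(seed)) stop("a master seed is required")
  tr <- .realization_traces(geometry, shape, M, n_realizations, seed,
    stream = 0L, noise = noise, fmax = fmax, tau = tau
  )
  avg <- average_fi(shape, geometry,
    noise = noise, fmax = fmax, tau = tau,
    mc_points = 2e5, seed = .substream_seed(seed, 999983L)
  )$trace
  tibble::tibble(
    geometry = geometry$name, M = M, n_realizations = n_realizations,
    mc_mean = mean(tr), mc_se = stats::sd(tr) / sqrt(n_realizations),
    average = avg, relative_gap = abs(mean(tr) - avg) / avg
  )
}

#' Sweep the average Fisher information over lattice spanning angles
#'
#' Evaluates [average_fi()] on the unit-basis-vector angle families: in
#' 2D over `phi`, in 3D over the grid of `(phi, psi)`.  With the tuning
#' support inside every in-ball of the sweep, the trace follows the
#' inverse-determinant law exactly — `1/sin(phi)` in 2D and
#' `1/(sin(phi) sin(psi))` in 3D — so the maximum sits at the smallest
#' angles (the hexagonal lattice in 2D).
#'
#' @param dimension 2 or 3.
#' @param phi Vector of in-plane angles in `[pi/3, pi/2]`.
#' @param psi Vector of out-of-plane angles (3D only).
#' @param shape A `tuning_shape` with support at most the minimal packing
#'   radius over the sweep.
#' @inheritParams fi_integrand
#' @return A tibble of class `fi_sweep` with columns `phi` (and `psi`),
#'   `det`, and `trace`.
#' @examples
#' sw <- fi_angle_sweep(2, phi = seq(pi / 3, pi / 2, length.out = 5),
#'   shape = bump_shape(1 / 4, 1 / 4))
#' @export
fi_angle_sweep <- function(dimension = 2, phi, psi = NULL, shape,
                           noise = poisson_noise(), fmax = 1, tau = 1) {
  stopifnot(dimension %in% c(2, 3))
  if (dimension == 2 && !is.null(psi)) stop("psi is only used in 3D")
  if (dimension == 3 && is.null(psi)) stop("the 3D sweep needs psi")
  grid <- if (dimension == 2) {
    tibble::tibble(phi = phi)
  } else {
    tidyr_expand <- expand.grid(phi = phi, psi = psi, KEEP.OUT.ATTRS = FALSE)
    tibble::as_tibble(tidyr_expand)
  }
  lat <- function(i) {
    if (dimension == 2) angle_lattice(grid$phi[i]) else angle_lattice(grid$phi[i], grid$psi[i])
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    L <- lat(i)
    if (shape$support > packing_radius(L) + 1e-12) {
      stop("tuning support exceeds the packing radius at one sweep angle")
    }
    fs <- average_fi(shape, L, noise = noise, fmax = fmax, tau = tau)
    tibble::tibble(det = lattice_det(L), trace = fs$trace)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  class(out) <- c("fi_sweep", class(out))
  attr(out, "dimension") <- dimension
  out
}

#' Packing-density advantage of the best shipped lattice per dimension
#'
#' For each requested dimension, the ratio of the packing ratio of the
#' densest shipped lattice (hexagonal in 2D, FCC in 3D, E8 in 8D) to that
#' of the integer lattice `Z^D`.  The 8D entry equals 16: the gain from
#' choosing the right symmetry grows dramatically with dimension.
#'
#' @param dimensions Subset of `c(2, 3, 8)`.
#' @return A tibble with columns `dimension`, `best`, `ratio_best`,
#'   `ratio_z`, `advantage`.
#' @examples
#' density_report()
#' @export
density_report <- function(dimensions = c(2, 3, 8)) {
  best_of <- list(
    `2` = "H", `3` = "FCC", `8` = "E8"
  )
  rows <- lapply(dimensions, function(D) {
    key <- as.character(D)
    if (!key %in% names(best_of)) {
      stop("no shipped lattices for dimension ", D)
    }
    dense <- named_lattice(best_of[[key]])
    z <- named_lattice("Z", dim = D)
    r_dense <- packing_ratio(dense)
    r_z <- packing_ratio(z)
    tibble::tibble(
      dimension = as.integer(D), best = dense$name,
      ratio_best = r_dense, ratio_z = r_z,
      advantage = r_dense / r_z
    )
  })
  dplyr::bind_rows(rows)
}
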