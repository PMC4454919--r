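#' Fisher-information integrand of a radial tuning shape
#'
#' The trace of the per-neuron Fisher-information matrix contributed by a
#' cell whose phase sits at distance `r` from the decoded position.  The
#' mean count is `s = fmax tau Omega(r)` and its spatial gradient has
#' norm `fmax tau |Omega'(r)|`, so
#' \deqn{F(r) = (f_{max}\tau)^2 \, \Omega'(r)^2 \, N(f_{max}\tau\,\Omega(r)),}
#' where `N` is the noise model's per-observation Fisher factor.  For
#' Poisson spiking `N(s) = 1/s`, giving
#' `F(r) = fmax tau Omega'(r)^2 / Omega(r)`; for the bump family this is
#' `4 theta1^2 r^2 (theta2^2 - r^2)^-4 exp(theta1/theta2^2 -
#' theta1/(theta2^2 - r^2))` inside the support and 0 outside.  The
#' integrand vanishes at `r = 0` (the `r^2` factor of the bump
#' derivative) and in the limit `r -> theta2` (the exponential beats the
#' pole), so it is finite everywhere, and it carries units of inverse
#' squared length — dilating the module by `lambda` divides it by
#' `lambda^2`.
#'
#' @param shape A `tuning_shape`.
#' @param r Vector of nonnegative radii.
#' @param noise A `noise_model`.
#' @param fmax,tau Peak rate and observation window.
#' @return Vector of nonnegative integrand values.
#' @export
fi_integrand <- function(shape, r, noise = poisson_noise(), fmax = 1, tau = 1) {
  stopifnot(inherits(shape, "tuning_shape"))
  om <- shape$value(r)
  dom <- shape$deriv(r)
  out <- numeric(length(r))
  # near the support edge Omega underflows faster than Omega'^2 does;
  # the analytic limit of the integrand there is 0
  pos <- om > 1e-300 & dom != 0
  out[pos] <- (fmax * tau * dom[pos])^2 *
    noise$fisher_factor(fmax * tau * om[pos])
  out[!is.finite(out)] <- 0
  out
}

.new_fisher_summary <- function(J, normalization, method,
                                se = NA_real_, n = NA_real_, seed = NA_integer_,
                                geometry_name = NA_character_) {
  structure(
    list(
      J = J, trace = sum(diag(J)), normalization = normalization,
      method = method, se = se, n = n, seed = seed,
      geometry = geometry_name, dim = nrow(J)
    ),
    class = "fisher_summary"
  )
}

#' @export
print.fisher_summary <- function(x, ...) {
  cat(sprintf(
    "<fisher_summary> %s (%s), dim %d: trJ = %.6g%s\n",
    x$normalization, x$method, x$dim, x$trace,
    if (is.finite(x$se)) sprintf(" (MC se %.3g, n = %g)", x$se, x$n) else ""
  ))
  invisible(x)
}

#' Per-neuron Fisher-information matrix at the origin
#'
#' The Fisher information contributed at position 0 by a single grid cell
#' with phase `c`: a rank-one matrix `F(r) u u^T` where `r` is the
#' distance from the reduced phase to its nearest node and `u` the unit
#' residual direction.  Zero when `r = 0` or when the phase lies outside
#' the tuning support.
#'
#' @param shape A `tuning_shape`.
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @param c Phase (numeric vector of length D).
#' @inheritParams fi_integrand
#' @return A `fisher_summary` with `normalization = "per_neuron"`.
#' @export
neuron_fi <- function(shape, geometry, c, noise = poisson_noise(),
                      fmax = 1, tau = 1) {
  D <- geometry$dim
  red <- reduce_points(geometry, c)
  r <- red$distance[1]
  J <- matrix(0, D, D)
  if (r > 0) {
    f <- fi_integrand(shape, r, noise, fmax, tau)
    u <- red$residual[1, ] / r
    J <- f * tcrossprod(u)
  }
  .new_fisher_summary(J, "per_neuron", "closed_form",
    geometry_name = geometry$name
  )
}

#' Average Fisher information per neuron over a geometry
#'
#' The expected per-neuron Fisher-information matrix for phases uniformly
#' distributed over the Voronoi cell — the large-`M` limit of a grid
#' module's population information divided by `M`.  Two estimators are
#' provided:
#'
#' * `"quadrature"`: when the tuning support fits inside the in-ball of
#'   the cell (`support <= packing_radius`), the average trace reduces
#'   exactly to a 1-D radial integral,
#'   `trJ = S_{D-1} / vol(cell) * int_0^R F(r) r^(D-1) dr`,
#'   evaluated by adaptive quadrature (relative tolerance `rel_tol`).
#'   The matrix is isotropic by symmetry: `diag(trJ / D)`.
#' * `"mc"`: Monte-Carlo average of the rank-one per-neuron matrices over
#'   uniform phases, with a standard error on the trace.  This is the
#'   estimator of record when the support spills over the cell boundary,
#'   where the interplay of tuning shape and cell shape decides which
#'   geometry wins, and it computes the off-diagonal entries rather than
#'   assuming them zero.
#'
#' `method = "auto"` picks quadrature when the support fits, Monte Carlo
#' otherwise.
#'
#' @param shape A `tuning_shape`.
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @param method `"auto"`, `"quadrature"` or `"mc"`.
#' @param mc_points Number of Monte-Carlo phases.
#' @param seed Seed for the Monte-Carlo path (recorded in the result).
#' @param rel_tol Relative tolerance of the radial quadrature.
#' @inheritParams fi_integrand
#' @return A `fisher_summary` (`normalization = "per_neuron"`).
#' @examples
#' om <- bump_shape(1 / 4, 0.4)
#' average_fi(om, named_lattice("FCC"))$trace / average_fi(om, named_lattice("C"))$trace
#' @export
average_fi <- function(shape, geometry, noise = poisson_noise(),
                       method = c("auto", "quadrature", "mc"),
                       mc_points = 2e6, seed = NULL,
                       fmax = 1, tau = 1, rel_tol = 1e-8) {
  stopifnot(inherits(shape, "tuning_shape"))
  method <- match.arg(method)
  fits <- shape$support <= packing_radius(geometry) + 1e-12
  if (method == "auto") method <- if (fits) "quadrature" else "mc"
  if (method == "quadrature") {
    if (!fits) {
      stop("radial quadrature needs the tuning support inside the in-ball; use method = \"mc\"")
    }
    .average_fi_quadrature(shape, geometry, noise, fmax, tau, rel_tol)
  } else {
    .average_fi_mc(shape, geometry, noise, fmax, tau, mc_points, seed)
  }
}

.cell_volume <- function(geometry) {
  if (inherits(geometry, "sphere_packing")) {
    lattice_det(geometry$period) / ncol(geometry$motif)
  } else {
    lattice_det(geometry)
  }
}

.average_fi_quadrature <- function(shape, geometry, noise, fmax, tau, rel_tol) {
  D <- geometry$dim
  R <- shape$support
  integrand <- function(r) fi_integrand(shape, r, noise, fmax, tau) * r^(D - 1)
  q <- stats::integrate(integrand, 0, R * (1 - 1e-10),
    rel.tol = rel_tol, subdivisions = 200L
  )
  tr <- .sphere_area(D) * q$value / .cell_volume(geometry)
  .new_fisher_summary(diag(rep(tr / D, D)), "per_neuron", "radial_quadrature",
    geometry_name = geometry$name
  )
}

.average_fi_mc <- function(shape, geometry, noise, fmax, tau, mc_points, seed) {
  D <- geometry$dim
  n <- as.integer(mc_points)
  ph <- sample_phases(geometry, n, seed = seed) # n x D residuals
  r <- sqrt(rowSums(ph^2))
  f <- fi_integrand(shape, r, noise, fmax, tau)
  U <- ph / pmax(r, 1e-300)
  J <- matrix(0, D, D)
  for (a in seq_len(D)) {
    for (b in a:D) {
      J[a, b] <- J[b, a] <- mean(f * U[, a] * U[, b])
    }
  }
  .new_fisher_summary(J, "per_neuron", "voronoi_mc",
    se = stats::sd(f) / sqrt(n), n = n,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    geometry_name = geometry$name
  )
}

#' Population Fisher information of a finite grid module
#'
#' The exact finite sum over the module's cells: each neuron contributes
#' the rank-one matrix of [neuron_fi()] evaluated at the reduced
#' difference `x - c_i`.  No integration is involved, so the result is
#' deterministic given the phases.  Dividing the trace by `M` gives the
#' per-neuron normalisation that converges to [average_fi()] as `M`
#' grows.
#'
#' @param module A `grid_module`.
#' @param x Position at which the information is evaluated (default the
#'   origin).
#' @return A `fisher_summary` with `normalization = "per_module"`.
#' @export
population_fi <- function(module, x = NULL) {
  stopifnot(inherits(module, "grid_module"))
  D <- module$geometry$dim
  if (is.null(x)) x <- rep(0, D)
  X <- .as_point_matrix(x, D)
  if (ncol(X) != 1L) stop("x must be a single position")
  shifted <- matrix(as.vector(X), nrow = module$M, ncol = D, byrow = TRUE) -
    module$phases
  red <- reduce_points(module$geometry, shifted)
  r <- red$distance
  f <- fi_integrand(module$shape, r, module$noise, module$fmax, module$tau)
  U <- red$residual / pmax(r, 1e-300)
  J <- matrix(0, D, D)
  for (a in seq_len(D)) {
    for (b in a:D) {
      J[a, b] <- J[b, a] <- sum(f * U[, a] * U[, b])
    }
  }
  .new_fisher_summary(J, "per_module", "finite_sum",
    n = module$M, geometry_name = module$geometry$name
  )
}

#' Rescale a Fisher-information summary
#'
#' Dilating a grid module by a factor `lambda` (lattice, phases and
#' tuning support all scaled together) multiplies its Fisher information
#' by `lambda^-2`: finer grids resolve proportionally better.  Scalings
#' compose multiplicatively.
#'
#' @param summary A `fisher_summary`.
#' @param lambda Positive scale factor.
#' @return A `fisher_summary` with matrix and trace multiplied by
#'   `lambda^-2`.
#' @export
scale_fi <- function(summary, lambda) {
  stopifnot(inherits(summary, "fisher_summary"))
  if (!.is_scalar_number(lambda) || lambda <= 0) stop("lambda must be positive")
  out <- summary
  out$J <- summary$J / lambda^2
  out$trace <- summary$trace / lambda^2
  if (is.finite(out$se)) out$se <- summary$se / lambda^2
  out
}
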