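#' Radial bump tuning shape
#'
#' The compactly supported, infinitely smooth radial profile
#' \deqn{\Omega(r) = \exp(\theta_1/\theta_2^2 - \theta_1/(\theta_2^2 - r^2))}
#' for `r < theta2` and 0 otherwise.  `theta2` is the support radius (the
#' firing-field radius); `theta1` controls how steeply the flank falls.
#' `Omega(0) = 1` and the profile, its derivative
#' `Omega'(r) = -2 theta1 r (theta2^2 - r^2)^-2 Omega(r)`, and all higher
#' derivatives vanish continuously at the support boundary.  Evaluations
#' within `1e-12` of the boundary return the analytic limit 0, so the
#' removable singularity never overflows.
#'
#' @param theta1 Flank-slope parameter (positive).
#' @param theta2 Support radius (positive).
#'
#' @return An object of class `tuning_shape` with vectorised functions
#'   `value` and `deriv`, and `support = theta2`.
#' @examples
#' om <- bump_shape(1 / 4, 0.4)
#' om$value(c(0, 0.2, 0.4))
#' @export
bump_shape <- function(theta1, theta2) {
  if (!.is_scalar_number(theta1) || theta1 <= 0) stop("theta1 must be positive")
  if (!.is_scalar_number(theta2) || theta2 <= 0) stop("theta2 must be positive")
  t1 <- theta1
  t2 <- theta2
  value <- function(r) {
    out <- numeric(length(r))
    inside <- r < t2 - 1e-12
    ri <- r[inside]
    out[inside] <- exp(t1 / t2^2 - t1 / (t2^2 - ri^2))
    out
  }
  deriv <- function(r) {
    out <- numeric(length(r))
    inside <- r < t2 - 1e-12
    ri <- r[inside]
    out[inside] <- -2 * t1 * ri * (t2^2 - ri^2)^(-2) *
      exp(t1 / t2^2 - t1 / (t2^2 - ri^2))
    out
  }
  structure(
    list(
      value = value, deriv = deriv, support = t2,
      theta1 = t1, theta2 = t2, family = "bump"
    ),
    class = "tuning_shape"
  )
}

#' General radial tuning shape
#'
#' Wraps arbitrary value/derivative functions into the container used by
#' the Fisher-information machinery.  `value` must map radius to `[0, 1]`
#' with `value(0) = 1` and vanish for `r >= support`.
#'
#' @param value,deriv Vectorised functions of nonnegative radius.
#' @param support Support radius (positive).
#' @param family Label.
#' @return A `tuning_shape`.
#' @export
tuning_shape <- function(value, deriv, support, family = "custom") {
  stopifnot(is.function(value), is.function(deriv))
  if (!.is_scalar_number(support) || support <= 0) stop("support must be positive")
  structure(
    list(
      value = value, deriv = deriv, support = support,
      theta1 = NA_real_, theta2 = NA_real_, family = family
    ),
    class = "tuning_shape"
  )
}

#' @export
print.tuning_shape <- function(x, ...) {
  cat(sprintf(
    "<tuning_shape %s> support radius %.4g%s\n", x$family, x$support,
    if (!is.na(x$theta1)) sprintf(" (theta1 = %.4g, theta2 = %.4g)", x$theta1, x$theta2) else ""
  ))
  invisible(x)
}

#' Poisson spiking observation model
#'
#' Spike counts in a window `tau` are independent Poisson with mean
#' `tau * rate`.  The per-observation Fisher factor — the expectation of
#' the squared score with respect to the mean count `s` — is `1/s`, which
#' is what makes the Fisher-information integrand of a radial tuning
#' shape collapse to `4 r^2 fmax tau Omega'(r)^2 / Omega(r)`.  Other
#' count models can be plugged in through `fisher_factor`.
#'
#' @param fisher_factor Function of the mean count `s` returning the
#'   Fisher factor `N(s) > 0`.
#' @return An object of class `noise_model`.
#' @export
poisson_noise <- function(fisher_factor = function(s) 1 / s) {
  structure(
    list(fisher_factor = fisher_factor, family = "poisson"),
    class = "noise_model"
  )
}

#' Grid module: a population of phase-shifted periodic tuning curves
#'
#' A grid module bundles a geometry (lattice or sphere packing), a radial
#' tuning shape, and `M` spatial phases in the Voronoi cell of the
#' origin.  Cell `i` fires with mean rate
#' `fmax * Omega(||nearest-node residual of (x - c_i)||)`; spike counts
#' in a window `tau` follow the noise model independently across cells.
#' Phases are reduced into the Voronoi cell on construction.
#'
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @param shape A `tuning_shape`.
#' @param phases `n x D` matrix of phases, or `NULL` to draw `M` uniform
#'   phases (requires `seed`).
#' @param M Number of phases to draw when `phases` is `NULL`.
#' @param seed Integer seed for phase sampling.
#' @param fmax Peak firing rate (default 1).
#' @param tau Observation window (default 1).
#' @param noise A `noise_model` (default Poisson).
#'
#' @return An object of class `grid_module`.
#' @examples
#' mod <- grid_module(named_lattice("H"), bump_shape(1 / 4, 0.4), M = 50, seed = 1)
#' @export
grid_module <- function(geometry, shape, phases = NULL, M = NULL, seed = NULL,
                        fmax = 1, tau = 1, noise = poisson_noise()) {
  stopifnot(
    inherits(geometry, c("grid_lattice", "sphere_packing")),
    inherits(shape, "tuning_shape"),
    inherits(noise, "noise_model")
  )
  if (!.is_scalar_number(fmax) || fmax <= 0) stop("fmax must be positive")
  if (!.is_scalar_number(tau) || tau <= 0) stop("tau must be positive")
  D <- geometry$dim
  if (is.null(phases)) {
    if (is.null(M) || M < 1) stop("need phases or M >= 1")
    phases <- t(sample_phases(geometry, M, seed = seed)) # D x M
  } else {
    phases <- .as_point_matrix(phases, D)
    phases <- t(reduce_points(geometry, t(phases))$residual)
  }
  structure(
    list(
      geometry = geometry, shape = shape, phases = t(phases), # n x D
      M = ncol(phases), fmax = fmax, tau = tau, noise = noise
    ),
    class = "grid_module"
  )
}

#' @export
print.grid_module <- function(x, ...) {
  cat(sprintf(
    "<grid_module> %s geometry \"%s\", %d phases, fmax = %g, tau = %g\n",
    class(x$geometry)[1], x$geometry$name, x$M, x$fmax, x$tau
  ))
  invisible(x)
}

#' Sample spatial phases uniformly over the Voronoi cell
#'
#' Draws points uniformly in the basis parallelepiped (the periodic cell
#' for packings) and reduces each to its nearest-node residual.  The
#' reduction is measure preserving, so the result is uniform on the
#' Voronoi cell of the origin; for packings it is uniform on the
#' congruent cell of each motif center, which leaves the distribution of
#' residual norms unchanged.  Identical seeds reproduce identical phases.
#'
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @param M Number of phases (>= 1).
#' @param seed Optional integer seed.
#' @return An `M x D` matrix of phases.
#' @export
sample_phases <- function(geometry, M, seed = NULL) {
  if (!.is_scalar_number(M) || M < 1) stop("M must be >= 1")
  M <- as.integer(M)
  if (!is.null(seed)) set.seed(seed)
  D <- geometry$dim
  B <- if (inherits(geometry, "sphere_packing")) {
    geometry$period$basis
  } else {
    geometry$basis
  }
  U <- matrix(stats::runif(D * M), nrow = D)
  reduce_points(geometry, t(B %*% U))$residual
}

#' Firing rate of one grid cell at given positions
#'
#' The periodified tuning curve of cell `i`:
#' `fmax * Omega(distance from (x - c_i) to its nearest node)`.  The rate
#' is invariant under all lattice translations of `x`.
#'
#' @param module A `grid_module`.
#' @param x Point or `n x D` matrix of positions.
#' @param cell Cell index in `1..M` (default 1).
#' @return Vector of nonnegative rates.
#' @export
grid_rate <- function(module, x, cell = 1L) {
  stopifnot(inherits(module, "grid_module"))
  if (cell < 1L || cell > module$M) stop("cell index out of range")
  X <- .as_point_matrix(x, module$geometry$dim)
  shifted <- t(X - module$phases[cell, ])
  d <- reduce_points(module$geometry, shifted)$distance
  module$fmax * module$shape$value(d)
}

#' Log-likelihood of a spike-count vector at a position
#'
#' Independent Poisson counts: `sum_i [k_i log(tau * rate_i(x)) -
#' tau * rate_i(x) - log(k_i!)]`, with the convention `0 * log(0) = 0`
#' and `-Inf` when a silent cell (rate 0) emitted spikes.  Because every
#' rate is lattice periodic, so is the log-likelihood — the posterior
#' over positions inherits the lattice symmetry and individual firing
#' fields cannot be told apart within a module.
#'
#' @param module A `grid_module`.
#' @param counts Nonnegative integer vector of length `M`.
#' @param x A single position.
#' @return The log-likelihood (possibly `-Inf`).
#' @export
module_loglik <- function(module, counts, x) {
  stopifnot(inherits(module, "grid_module"))
  counts <- as.numeric(counts)
  if (length(counts) != module$M) {
    stop("counts must have length M = ", module$M)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  X <- .as_point_matrix(x, module$geometry$dim)
  if (ncol(X) != 1L) stop("x must be a single position")
  shifted <- matrix(as.vector(X), nrow = module$M, ncol = module$geometry$dim,
                    byrow = TRUE) - module$phases
  d <- reduce_points(module$geometry, shifted)$distance
  mu <- module$tau * module$fmax * module$shape$value(d)
  ll <- -mu - lgamma(counts + 1)
  pos <- counts > 0
  ll[pos] <- ll[pos] + counts[pos] * log(mu[pos]) # log(0) -> -Inf as required
  sum(ll)
}
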