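test_that("the Poisson FI integrand matches the closed form for bumps", {
  om <- bump_shape(1 / 4, 1 / 2)
  expect_equal(fi_integrand(om, 0), 0)
  expect_equal(fi_integrand(om, 1 / 2), 0)
  expect_equal(fi_integrand(om, 0.75), 0)
  r <- c(0.05, 0.1, 0.25, 0.4, 0.49, 0.4999)
  expect_equal(
    fi_integrand(om, r), bump_fi_closed_form(r, 1 / 4, 1 / 2),
    tolerance = 1e-10
  )
  # fmax and tau enter linearly for Poisson noise
  expect_equal(
    fi_integrand(om, 0.25, fmax = 2, tau = 3),
    6 * fi_integrand(om, 0.25),
    tolerance = 1e-12
  )
  # a custom noise model is honoured (Gaussian-like constant factor)
  flat <- poisson_noise(fisher_factor = function(s) rep(1, length(s)))
  expect_equal(
    fi_integrand(om, 0.25, noise = flat),
    om$deriv(0.25)^2
  )
})

test_that("per-neuron FI matrices are rank-one with trace F(r)", {
  om <- bump_shape(1 / 4, 0.4)
  Q <- named_lattice("Q")
  expect_equal(neuron_fi(om, Q, c(0, 0))$J, matrix(0, 2, 2))
  # phase outside the support contributes nothing
  expect_equal(neuron_fi(om, Q, c(0.5, 0.45))$J, matrix(0, 2, 2))

  fs <- neuron_fi(om, Q, c(0.3, 0))
  expect_equal(fs$J[2, 2], 0)
  expect_equal(fs$J[1, 2], 0)
  expect_equal(fs$J[1, 1], fi_integrand(om, 0.3), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:50) {
    c_i <- stats::runif(2, -0.3, 0.3)
    fs <- neuron_fi(om, Q, c_i)
    expect_equal(fs$trace, fi_integrand(om, sqrt(sum(c_i^2))),
      tolerance = 1e-12
    )
    expect_lte(abs(det(fs$J)), 1e-12 * max(1, fs$trace^2)) # rank <= 1
    expect_equal(fs$J, t(fs$J))
  }
})

test_that("average FI follows the inverse-determinant law", {
  om <- bump_shape(1 / 4, 0.4)
  pairs <- list(
    c("H", "Q"), c("FCC", "C"), c("FCC", "BCC"), c("BCC", "C")
  )
  for (p in pairs) {
    L1 <- named_lattice(p[1])
    L2 <- named_lattice(p[2])
    expect_equal(
      average_fi(om, L1)$trace / average_fi(om, L2)$trace,
      lattice_det(L2) / lattice_det(L1),
      tolerance = 1e-7, label = paste(p, collapse = "/")
    )
  }
  expect_equal(
    average_fi(om, named_lattice("H"))$trace /
      average_fi(om, named_lattice("Q"))$trace,
    2 / sqrt(3),
    tolerance = 1e-7
  )
  # quadrature result has an exactly isotropic matrix
  fs <- average_fi(om, named_lattice("H"))
  expect_equal(fs$J[1, 1], fs$J[2, 2])
  expect_equal(fs$J[1, 2], 0)
})

test_that("Monte-Carlo and quadrature estimates agree within 3 standard errors", {
  om <- bump_shape(1 / 4, 0.4)
  for (nm in c("Q", "H", "FCC")) {
    L <- named_lattice(nm)
    quad <- average_fi(om, L, method = "quadrature")
    mc <- average_fi(om, L, method = "mc", mc_points = 2e5, seed = 101)
    expect_lt(abs(mc$trace - quad$trace), 3 * mc$se, label = nm)
    # empirical isotropy: off-diagonals are sampling noise around zero
    off <- mc$J[upper.tri(mc$J)]
    expect_true(all(abs(off) < 5e-3 * mc$trace))
  }
  # quadrature refuses a support that spills over the cell boundary
  wide <- bump_shape(1 / 4, 0.6)
  expect_error(average_fi(wide, named_lattice("Q"), method = "quadrature"), "in-ball")
  # auto falls back to Monte Carlo in that regime
  fs <- average_fi(wide, named_lattice("Q"), mc_points = 1e4, seed = 5)
  expect_identical(fs$method, "voronoi_mc")
  expect_true(is.finite(fs$se))
})

test_that("rescaling a module multiplies the FI by 1/lambda^2", {
  om <- bump_shape(1 / 4, 0.4)
  H <- named_lattice("H")
  base <- average_fi(om, H)
  for (lam in c(1 / 2, 2)) {
    # dilating by lambda: lattice scale lambda, support lambda * theta2,
    # and theta1 * lambda^2 so the flank profile dilates with it
    scaled_shape <- bump_shape(1 / 4 * lam^2, 0.4 * lam)
    scaled <- average_fi(scaled_shape, named_lattice("H", scale = lam))
    expect_equal(scaled$trace, base$trace / lam^2, tolerance = 1e-7)
    expect_equal(scaled$trace, scale_fi(base, lam)$trace, tolerance = 1e-7)
  }
  expect_equal(scale_fi(base, 1)$J, base$J)
  expect_equal(
    scale_fi(scale_fi(base, 2), 3)$trace, scale_fi(base, 6)$trace,
    tolerance = 1e-12
  )
  expect_error(scale_fi(base, -2), "positive")
})

test_that("population FI is the exact finite sum and converges to the average", {
  om <- bump_shape(1 / 4, 0.4)
  H <- named_lattice("H")

  # single phase at the origin contributes nothing at the origin
  mod0 <- grid_module(H, om, phases = matrix(0, 1, 2))
  expect_equal(population_fi(mod0)$J, matrix(0, 2, 2))

  # exactness: hand-placed phases sum their closed-form contributions
  ph <- rbind(c(0.2, 0), c(0, 0.3), c(0.1, -0.1))
  mod <- grid_module(H, om, phases = ph)
  expect_equal(
    population_fi(mod)$trace,
    sum(fi_integrand(om, sqrt(rowSums(ph^2)))),
    tolerance = 1e-12
  )

  # translating phases and evaluation point together changes nothing
  v <- as.vector(H$basis %*% c(1, -2))
  modv <- grid_module(H, om, phases = sweep(ph, 2, v, "+"))
  expect_equal(population_fi(modv, v)$J, population_fi(mod)$J,
    tolerance = 1e-10
  )

  # law of large numbers: trJ/M at M = 1e5 within 1% of the average
  big <- grid_module(H, om, M = 1e5, seed = 55)
  expect_equal(
    population_fi(big)$trace / big$M,
    average_fi(om, H)$trace,
    tolerance = 0.01
  )
})
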