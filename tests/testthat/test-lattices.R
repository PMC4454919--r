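test_that("named lattices follow the unit node-to-node convention", {
  Q <- named_lattice("Q")
  expect_equal(Q$basis, diag(2))

  H <- named_lattice("H")
  expect_equal(sqrt(colSums(H$basis^2)), c(1, 1))
  ang <- acos(sum(H$basis[, 1] * H$basis[, 2]))
  expect_equal(ang, pi / 3)

  expect_equal(lattice_det(named_lattice("FCC")), 1 / sqrt(2))

  for (nm in c("H", "Q", "C", "BCC", "FCC", "E8")) {
    for (s in c(1, 2.5)) {
      expect_equal(
        shortest_vector(named_lattice(nm, scale = s)), s,
        tolerance = 1e-12, label = paste(nm, "scale", s)
      )
    }
  }
  expect_equal(named_lattice("Z", dim = 8)$basis, diag(8))
  expect_equal(named_lattice("Z8")$basis, diag(8))

  expect_error(named_lattice("XYZ"), "unknown")
  expect_error(named_lattice("Q", scale = -1), "positive")
  expect_error(lattice(cbind(c(1, 1), c(2, 2))), "degenerate")
})

test_that("angle lattices reproduce the named ones at the corners", {
  expect_equal(angle_lattice(pi / 2)$basis, named_lattice("Q")$basis,
    tolerance = 1e-12
  )
  expect_equal(angle_lattice(pi / 3)$basis, named_lattice("H")$basis,
    tolerance = 1e-12
  )
  for (phi in c(pi / 3, 0.4 * pi, pi / 2)) {
    expect_equal(lattice_det(angle_lattice(phi)), sin(phi))
  }
  for (phi in c(pi / 3, pi / 2)) {
    for (psi in c(pi / 3, 5 * pi / 12)) {
      L3 <- angle_lattice(phi, psi)
      expect_equal(lattice_det(L3), sin(phi) * sin(psi))
      expect_equal(sqrt(colSums(L3$basis^2)), rep(1, 3))
    }
  }
  expect_error(angle_lattice(pi / 4), "pi/3")
  expect_error(angle_lattice(pi / 2, 1.9), "pi/3")
})

test_that("determinants scale as lambda^D and survive unimodular change", {
  H <- named_lattice("H")
  expect_equal(lattice_det(named_lattice("Q")), 1)
  expect_equal(lattice_det(H), sqrt(3) / 2)
  for (lam in c(0.5, 3)) {
    expect_equal(
      lattice_det(lattice(H$basis * lam)), lam^2 * lattice_det(H)
    )
  }
  # unimodular basis change: v2 -> v2 + 2 v1 spans the same lattice
  U <- matrix(c(1, 0, 2, 1), 2, 2)
  H2 <- lattice(H$basis %*% U)
  expect_equal(lattice_det(H2), lattice_det(H))
  expect_equal(packing_ratio(H2), packing_ratio(H), tolerance = 1e-12)
})

test_that("shortest vectors match plain box enumeration for every shipped lattice", {
  for (nm in names(shipped_lattices())) {
    L <- shipped_lattices()[[nm]]
    expect_equal(
      shortest_vector(L), brute_shortest(L$basis, K = 3L),
      tolerance = 1e-12, label = nm
    )
  }
  # skewed custom basis where naive rounding misleads
  Lskew <- lattice(cbind(c(1, 0), c(0.9, 0.1)))
  expect_equal(shortest_vector(Lskew), brute_shortest(Lskew$basis, K = 6L),
    tolerance = 1e-12
  )
})

test_that("packing radii and ratios reproduce the closed-form values", {
  expect_equal(packing_radius(named_lattice("Q")), 1 / 2)
  expect_equal(packing_radius(named_lattice("H")), 1 / 2)
  expect_equal(packing_radius(named_lattice("H", scale = 3)), 3 / 2)

  expect_equal(packing_ratio(named_lattice("Q")), pi / 4)
  expect_equal(packing_ratio(named_lattice("H")), pi / sqrt(12))
  expect_equal(packing_ratio(named_lattice("FCC")), pi / sqrt(18))
  expect_equal(packing_ratio(named_lattice("C")), pi / 6)
  expect_equal(packing_ratio(named_lattice("BCC")), pi * sqrt(3) / 8)

  # scale invariance
  for (nm in c("H", "FCC", "E8")) {
    expect_equal(
      packing_ratio(named_lattice(nm, scale = 0.37)),
      packing_ratio(named_lattice(nm)),
      tolerance = 1e-12
    )
  }

  # density orderings
  expect_gt(packing_ratio(named_lattice("H")), packing_ratio(named_lattice("Q")))
  expect_gt(packing_ratio(named_lattice("FCC")), packing_ratio(named_lattice("BCC")))
  expect_gt(packing_ratio(named_lattice("BCC")), packing_ratio(named_lattice("C")))

  expect_equal(
    packing_ratio(named_lattice("E8")) / packing_ratio(named_lattice("Z8")),
    16,
    tolerance = 1e-12
  )
})

test_that("reduction finds the true nearest node", {
  r <- reduce_points(named_lattice("Q"), c(0.6, 0.2))
  expect_equal(r$node[1, ], c(1, 0))
  expect_equal(r$residual[1, ], c(-0.4, 0.2))

  H <- named_lattice("H")
  node <- H$basis %*% c(2, -1)
  expect_equal(reduce_points(H, as.vector(node))$distance, 0)

  # midpoint of v1 sits on the Voronoi boundary at the in-radius
  mid <- reduce_points(H, H$basis[, 1] / 2)
  expect_equal(mid$distance, 1 / 2)
  # deterministic tie-break: lexicographically smallest coefficients -> origin
  expect_equal(mid$node[1, ], c(0, 0))

  set.seed(42)
  for (nm in c("H", "Q", "C", "BCC", "FCC")) {
    L <- shipped_lattices()[[nm]]
    D <- L$dim
    X <- matrix(stats::rnorm(200 * D, sd = 3), ncol = D)
    red <- reduce_points(L, X)
    for (i in seq_len(40)) {
      bn <- brute_nearest(L$basis, X[i, ])
      expect_equal(red$distance[i], bn$dist, tolerance = 1e-10, label = nm)
    }
    # never farther than any random lattice point
    kq <- matrix(sample(-5:5, 100 * D, replace = TRUE), ncol = 100)
    qpts <- L$basis %*% kq
    for (i in seq_len(20)) {
      dq <- sqrt(colSums((qpts - X[i, ])^2))
      expect_lte(red$distance[i], min(dq) + 1e-12)
    }
  }
})

test_that("kissing numbers of the classical lattices are correct", {
  expect_identical(kissing_number(named_lattice("Q")), 4L)
  expect_identical(kissing_number(named_lattice("H")), 6L)
  expect_identical(kissing_number(named_lattice("C")), 6L)
  expect_identical(kissing_number(named_lattice("BCC")), 8L)
  expect_identical(kissing_number(named_lattice("FCC")), 12L)
  expect_identical(kissing_number(named_lattice("E8")), 240L)
})

test_that("JSON serialisation round-trips a lattice", {
  path <- withr::local_tempfile(fileext = ".json")
  L <- named_lattice("BCC", scale = 1.5)
  lattice_to_json(L, path)
  L2 <- lattice_from_json(path)
  expect_equal(L2$basis, L$basis, tolerance = 1e-12)
  expect_equal(L2$dim, 3L)
})
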