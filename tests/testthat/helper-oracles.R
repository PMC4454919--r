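# Independent brute-force oracles, kept free of the package's internal
# search strategies: plain integer-box enumeration and direct distance
# minimisation.

# Shortest nonzero vector by enumerating all k in [-K, K]^D, chunked over
# the leading coordinate so the 8D box stays in memory.
brute_shortest <- function(B, K = 3L) {
  D <- ncol(B)
  tail_grid <- t(as.matrix(do.call(
    expand.grid, rep(list(seq.int(-K, K)), D - 1L)
  )))
  best <- Inf
  for (k1 in seq.int(-K, K)) {
    kmat <- rbind(matrix(k1, 1L, ncol(tail_grid)), tail_grid)
    n2 <- colSums((B %*% kmat)^2)
    n2 <- n2[n2 > 1e-18]
    best <- min(best, n2)
  }
  sqrt(best)
}

# Nearest lattice node to x by enumerating the full box around the
# rounded real solution.
brute_nearest <- function(B, x, K = 4L) {
  D <- ncol(B)
  k0 <- round(solve(B, x))
  g <- t(as.matrix(do.call(expand.grid, rep(list(seq.int(-K, K)), D))))
  kk <- g + as.vector(k0)
  pts <- B %*% kk
  d2 <- colSums((pts - x)^2)
  j <- which.min(d2)
  list(node = pts[, j], dist = sqrt(d2[j]))
}

# All centers of a layered packing within `periods` period translates,
# as a 3 x n matrix.
packing_centers <- function(P, periods = 2L) {
  g <- t(as.matrix(do.call(
    expand.grid, rep(list(seq.int(-periods, periods)), 3L)
  )))
  trans <- P$period$basis %*% g
  out <- lapply(seq_len(ncol(P$motif)), function(j) trans + P$motif[, j])
  do.call(cbind, out)
}

brute_nearest_center <- function(P, x, periods = 5L) {
  centers <- packing_centers(P, periods)
  d2 <- colSums((centers - x)^2)
  j <- which.min(d2)
  list(node = centers[, j], dist = sqrt(d2[j]))
}

# The bump-family Fisher-information trace integrand written out in
# closed form, independent of the tuning_shape function objects:
# Omega'(r)^2 / Omega(r) expanded analytically.
bump_fi_closed_form <- function(r, theta1, theta2) {
  ifelse(
    r < theta2,
    4 * theta1^2 * r^2 * (theta2^2 - r^2)^(-4) *
      exp(theta1 / theta2^2 - theta1 / (theta2^2 - r^2)),
    0
  )
}

shipped_lattices <- function() {
  list(
    H = named_lattice("H"), Q = named_lattice("Q"),
    C = named_lattice("C"), BCC = named_lattice("BCC"),
    FCC = named_lattice("FCC"),
    Z2 = named_lattice("Z", dim = 2), Z3 = named_lattice("Z", dim = 3),
    Z8 = named_lattice("Z", dim = 8), E8 = named_lattice("E8")
  )
}
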