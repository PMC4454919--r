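#' Construct a point lattice from a basis matrix
#'
#' A lattice is the set of all integer combinations of `D` linearly
#' independent basis vectors in `R^D`.  The basis is stored as a `D x D`
#' matrix whose *columns* are the basis vectors.  Degenerate (singular)
#' bases are rejected, since they do not tile space.
#'
#' @param basis A square numeric matrix whose columns are the basis vectors.
#' @param name Optional label used in printing and experiment tables.
#'
#' @return An object of class `grid_lattice` with elements `dim`, `basis`,
#'   and `name`.
#' @seealso [named_lattice()], [angle_lattice()], [reduce_points()]
#' @examples
#' L <- lattice(cbind(c(1, 0), c(1 / 2, sqrt(3) / 2)), name = "H")
#' lattice_det(L)
#' @export
lattice <- function(basis, name = NULL) {
  basis <- as.matrix(basis)
  if (nrow(basis) != ncol(basis)) stop("basis must be square")
  if (!all(is.finite(basis))) stop("basis must be finite")
  D <- nrow(basis)
  d <- abs(det(basis))
  if (d < 1e-12) stop("degenerate lattice: basis matrix is singular")
  structure(
    list(dim = D, basis = basis, name = name %||% "custom"),
    class = "grid_lattice"
  )
}

#' @export
print.grid_lattice <- function(x, ...) {
  cat(sprintf(
    "<grid_lattice \"%s\"> dim %d, det %.6g, shortest vector %.6g\n",
    x$name, x$dim, lattice_det(x), shortest_vector(x)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard named lattices
#'
#' Constructs the lattices used throughout the package: the planar
#' hexagonal (`"H"`, equilateral-triangle) and square (`"Q"`) lattices,
#' the cubic (`"C"`), body-centered cubic (`"BCC"`) and face-centered
#' cubic (`"FCC"`) lattices in 3D, the integer lattice `Z^D` (`"Z"`, any
#' dimension), and the `E8` lattice.  Every lattice is scaled so that its
#' minimal node-to-node distance equals `scale` — the unit-distance
#' convention under which packing radii are `scale / 2`.
#'
#' @param name One of `"H"`, `"Q"`, `"C"`, `"BCC"`, `"FCC"`, `"Z"`,
#'   `"E8"`.  `"Z"` requires `dim`; shorthand such as `"Z8"` is accepted.
#' @param scale Minimal node-to-node distance (positive).
#' @param dim Dimension for the `Z` family; ignored otherwise.
#'
#' @return A `grid_lattice`.
#' @examples
#' named_lattice("H")
#' packing_ratio(named_lattice("FCC"))
#' @export
named_lattice <- function(name, scale = 1, dim = NULL) {
  if (!.is_scalar_number(scale) || scale <= 0) stop("scale must be positive")
  name <- toupper(as.character(name)[1])
  if (grepl("^Z[0-9]+$", name)) {
    dim <- as.integer(sub("^Z", "", name))
    name <- "Z"
  }
  basis <- switch(name,
    Q = diag(2),
    H = cbind(c(1, 0), c(1 / 2, sqrt(3) / 2)),
    C = diag(3),
    # conventional cube edge a chosen so the shortest vector has length 1:
    # BCC shortest = a * sqrt(3)/2, FCC shortest = a / sqrt(2)
    BCC = {
      a <- 2 / sqrt(3)
      cbind(a * c(1, 0, 0), a * c(0, 1, 0), (a / 2) * c(1, 1, 1))
    },
    FCC = {
      a <- sqrt(2)
      (a / 2) * cbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
    },
    Z = {
      if (is.null(dim)) stop("the Z family needs an explicit dimension")
      diag(as.integer(dim))
    },
    E8 = .e8_basis(),
    stop("unknown lattice name: ", name)
  )
  lattice(basis * scale, name = if (name == "Z") paste0("Z", nrow(basis)) else name)
}

# Standard E8 generator (rows of the usual generator matrix become
# columns here): the D8 chain plus the all-halves glue vector, rescaled
# so the minimal vector has length 1 (the raw construction has minimal
# norm sqrt(2) and determinant 1).
.e8_basis <- function() {
  G <- rbind(
    c(2, 0, 0, 0, 0, 0, 0, 0),
    c(-1, 1, 0, 0, 0, 0, 0, 0),
    c(0, -1, 1, 0, 0, 0, 0, 0),
    c(0, 0, -1, 1, 0, 0, 0, 0),
    c(0, 0, 0, -1, 1, 0, 0, 0),
    c(0, 0, 0, 0, -1, 1, 0, 0),
    c(0, 0, 0, 0, 0, -1, 1, 0),
    c(1 / 2, 1 / 2, 1 / 2, 1 / 2, 1 / 2, 1 / 2, 1 / 2, 1 / 2)
  )
  t(G) / sqrt(2)
}

#' Planar and 3D lattices parameterised by spanning angles
#'
#' Families of unit-basis-vector lattices used in angle sweeps.  In 2D the
#' basis is `(1, 0)` and `(cos phi, sin phi)`, with determinant `sin phi`.
#' In 3D the third unit vector is lifted out of the plane by `psi`, giving
#' determinant `sin(phi) * sin(psi)`.  Angles below `pi/3` would bring two
#' nodes closer than the unit node-to-node distance and are rejected, as
#' are angles above `pi/2`.
#'
#' @param phi In-plane spanning angle, in `[pi/3, pi/2]`.
#' @param psi Out-of-plane spanning angle for 3D, in `[pi/3, pi/2]`, or
#'   `NULL` for the planar family.
#'
#' @return A `grid_lattice`.
#' @examples
#' angle_lattice(pi / 3) # the hexagonal lattice
#' lattice_det(angle_lattice(pi / 2, pi / 2)) # the cubic lattice
#' @export
angle_lattice <- function(phi, psi = NULL) {
  chk <- function(a, nm) {
    if (!.is_scalar_number(a) || a < pi / 3 - 1e-12 || a > pi / 2 + 1e-12) {
      stop(nm, " must lie in [pi/3, pi/2]")
    }
  }
  chk(phi, "phi")
  if (is.null(psi)) {
    lattice(
      cbind(c(1, 0), c(cos(phi), sin(phi))),
      name = sprintf("L(phi=%.4g)", phi)
    )
  } else {
    chk(psi, "psi")
    lattice(
      cbind(
        c(1, 0, 0),
        c(cos(phi), sin(phi), 0),
        c(cos(psi), 0, sin(psi))
      ),
      name = sprintf("L(phi=%.4g, psi=%.4g)", phi, psi)
    )
  }
}

#' Lattice determinant (volume of the fundamental domain)
#'
#' @param L A `grid_lattice`.
#' @return `abs(det(basis))`, the volume of the Voronoi cell.
#' @export
lattice_det <- function(L) {
  stopifnot(inherits(L, "grid_lattice"))
  abs(det(L$basis))
}

#' Length of the shortest nonzero lattice vector
#'
#' Exact depth-first enumeration over integer coefficient vectors, pruned
#' by the Cholesky factor of the Gram matrix (Fincke-Pohst): at each
#' coordinate only the integers whose partial squared length stays below
#' the best length found so far are visited, starting from the shortest
#' basis vector as the initial bound.  Deterministic and fast for the
#' dimensions shipped here (D <= 8).
#'
#' @param L A `grid_lattice`.
#' @return The minimal Euclidean length over nonzero lattice vectors.
#' @export
shortest_vector <- function(L) {
  stopifnot(inherits(L, "grid_lattice"))
  sqrt(.svp_enumerate(L$basis)$min2)
}

# Shortest-vector enumeration on the Cholesky factor R of the Gram
# matrix: ||B k||^2 = sum_i (R[i,i] k_i + sum_{j>i} R[i,j] k_j)^2.
# Returns the minimal squared norm and the number of lattice vectors
# attaining it (relative tolerance 1e-9).
.svp_enumerate <- function(B) {
  A <- crossprod(B)
  Rm <- chol(A)
  D <- ncol(B)
  tolrel <- 1e-9
  best2 <- min(diag(A)) * (1 + 1e-12) # a basis vector; re-found below
  cnt <- 0L
  rec <- function(level, S, inner) {
    ci <- -inner[level] / Rm[level, level]
    half <- sqrt(max(best2 * (1 + tolrel) - S, 0)) / Rm[level, level]
    lo <- ceiling(ci - half)
    hi <- floor(ci + half)
    if (lo > hi) return(invisible(NULL))
    for (ki in lo:hi) {
      S2 <- S + (Rm[level, level] * (ki - ci))^2
      if (S2 > best2 * (1 + tolrel)) next
      if (level == 1L) {
        if (S2 < 1e-18) next # the zero vector
        if (S2 < best2 * (1 - tolrel)) {
          best2 <<- S2
          cnt <<- 1L
        } else if (abs(S2 - best2) <= tolrel * best2) {
          cnt <<- cnt + 1L
        }
      } else {
        idx <- seq_len(level - 1L)
        inner2 <- inner
        inner2[idx] <- inner[idx] + Rm[idx, level] * ki
        rec(level - 1L, S2, inner2)
      }
    }
    invisible(NULL)
  }
  rec(D, 0, numeric(D))
  list(min2 = best2 / (1 + 1e-12), count = cnt)
}

#' Packing radius: the in-radius of the Voronoi cell
#'
#' Half the shortest nonzero lattice vector — the largest `R` such that
#' balls `B_R` centered on the nodes do not overlap.
#'
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @return Positive real.
#' @export
packing_radius <- function(geometry) UseMethod("packing_radius")

#' @export
packing_radius.grid_lattice <- function(geometry) shortest_vector(geometry) / 2

#' Packing ratio of a lattice
#'
#' The fraction of space covered by non-overlapping balls of the packing
#' radius centered on the nodes: `vol(B_R) / det(L)` with
#' `vol(B_R) = pi^(D/2) R^D / Gamma(D/2 + 1)`.  Scale invariant.
#'
#' @param geometry A `grid_lattice` (see [packing_density()] for sphere
#'   packings).
#' @return A number in `(0, 1]`.
#' @examples
#' packing_ratio(named_lattice("H")) # pi / sqrt(12)
#' packing_ratio(named_lattice("Q")) # pi / 4
#' @export
packing_ratio <- function(geometry) UseMethod("packing_ratio")

#' @export
packing_ratio.grid_lattice <- function(geometry) {
  R <- packing_radius(geometry)
  .ball_volume(geometry$dim, R) / lattice_det(geometry)
}

.ball_volume <- function(D, R) pi^(D / 2) * R^D / gamma(D / 2 + 1)

.sphere_area <- function(D) 2 * pi^(D / 2) / gamma(D / 2) # surface of unit S^(D-1)

#' Reduce points to the nearest lattice node
#'
#' For each point `x`, finds the lattice node `p` minimising `||x - p||`
#' and the residual `x - p`, which lies in the closed Voronoi cell of the
#' origin.  The real-valued coefficient solution is rounded and a bounded
#' window of integer offsets is searched exhaustively, so the result is
#' exact for the shipped bases; ties on Voronoi-cell boundaries go to the
#' lexicographically smallest coefficient vector.
#'
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @param x A point (numeric vector) or an `n x D` matrix of points.
#' @return A list with `node` and `residual` (`n x D` matrices), and
#'   `distance` (length-`n` vector of residual norms).
#' @examples
#' reduce_points(named_lattice("Q"), c(0.6, 0.2))
#' @export
reduce_points <- function(geometry, x) UseMethod("reduce_points")

#' @export
reduce_points.grid_lattice <- function(geometry, x) {
  X <- .as_point_matrix(x, geometry$dim)
  r <- .lattice_reduce(geometry$basis, X)
  list(node = t(r$node), residual = t(r$residual), distance = r$distance)
}

# Core closest-node search; X is D x n.  The +/-1 offset window around the
# rounded coefficients is exact for the (near-reduced) 2D/3D bases here;
# in higher dimension the window is widened to +/-2.
.lattice_reduce <- function(B, X) {
  D <- nrow(B)
  n <- ncol(X)
  Binv <- solve(B)
  K0 <- round(Binv %*% X)
  w <- if (D <= 3L) 1L else 2L
  offs <- .offset_matrix(D, w)
  tol <- 1e-12 * sum(B^2)
  if (D <= 3L) {
    bestd <- rep(Inf, n)
    bestK <- K0
    for (j in seq_len(ncol(offs))) {
      Kj <- K0 + offs[, j]
      d2 <- colSums((X - B %*% Kj)^2)
      upd <- d2 < bestd - tol
      if (any(upd)) {
        bestd[upd] <- d2[upd]
        bestK[, upd] <- Kj[, upd]
      }
    }
  } else {
    cand <- B %*% offs # D x m, reused across points
    bestd <- numeric(n)
    bestK <- K0
    for (i in seq_len(n)) {
      resid0 <- X[, i] - B %*% K0[, i, drop = FALSE]
      d2 <- colSums((cand - as.vector(resid0))^2)
      jbest <- which(d2 <= min(d2) + tol)[1L] # offsets are lex-ordered
      bestd[i] <- d2[jbest]
      bestK[, i] <- K0[, i] + offs[, jbest]
    }
  }
  node <- B %*% bestK
  list(k = bestK, node = node, residual = X - node, distance = sqrt(pmax(bestd, 0)))
}

#' Number of nearest neighbours at the minimal distance
#'
#' The kissing number: how many nodes sit at exactly the minimal
#' node-to-node distance from a reference node (relative tolerance 1e-9).
#' For layered sphere packings the count is verified to be identical
#' around every center in the repeating motif.
#'
#' @param geometry A `grid_lattice` or `sphere_packing`.
#' @return An integer count.
#' @examples
#' kissing_number(named_lattice("FCC")) # 12
#' @export
kissing_number <- function(geometry) UseMethod("kissing_number")

#' @export
kissing_number.grid_lattice <- function(geometry) {
  .svp_enumerate(geometry$basis)$count
}

#' Serialise / deserialise a lattice as JSON
#'
#' Plain-text representation `{"dimension": D, "basis": [[..], ..]}` with
#' basis vectors as rows of the JSON array (columns of the internal basis
#' matrix).
#'
#' @param L A `grid_lattice`.
#' @param path File path; for `lattice_to_json` omit to get a JSON string.
#' @return `lattice_to_json` returns the path (or JSON string);
#'   `lattice_from_json` returns a `grid_lattice`.
#' @export
lattice_to_json <- function(L, path = NULL) {
  stopifnot(inherits(L, "grid_lattice"))
  obj <- list(
    dimension = L$dim,
    basis = lapply(seq_len(L$dim), function(j) L$basis[, j]),
    name = L$name
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lattice_to_json
#' @export
lattice_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  basis <- t(as.matrix(obj$basis)) # rows in file -> columns internally
  lattice(basis, name = obj$name %||% "custom")
}
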