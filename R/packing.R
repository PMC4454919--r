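#' Layered sphere packings from stacking words
#'
#' Close packings of equal spheres in 3D built by stacking hexagonal
#' layers.  Each layer is a planar hexagonal lattice of node-to-node
#' distance `diameter`; consecutive layers sit `diameter * sqrt(2/3)`
#' apart vertically and are shifted laterally to one of the three
#' deep-hollow positions `gamma_0`, `gamma_1`, `gamma_2` of the base
#' layer, encoded by the letters `0`, `1`, `2` (or `A`, `B`, `C`).  The
#' word is applied cyclically, so the structure is periodic with vertical
#' period `length(word) * diameter * sqrt(2/3)`.  Words with equal
#' cyclically-adjacent letters would stack spheres directly on top of one
#' another and are rejected.  The word `ABC` reproduces the FCC lattice;
#' `AB` is the hexagonal close packing (HCP), which is not a lattice.
#'
#' @param word Stacking sequence: an integer/character vector over
#'   `{0,1,2}` or a string such as `"AB"`, `"ABC"`, `"ABAC"`.
#' @param diameter Sphere diameter = minimal center-to-center distance.
#'
#' @return An object of class `sphere_packing` with the period lattice
#'   (`period`, a `grid_lattice`) and the motif of centers within one
#'   period (`motif`, a `3 x n` matrix, one column per layer).
#' @examples
#' hcp <- stacking_packing("AB")
#' packing_density(hcp) # pi / sqrt(18)
#' kissing_number(hcp) # 12
#' @export
stacking_packing <- function(word, diameter = 1) {
  if (!.is_scalar_number(diameter) || diameter <= 0) {
    stop("diameter must be positive")
  }
  w <- .parse_stacking_word(word)
  n <- length(w)
  if (n < 2L) stop("stacking word must have length >= 2")
  adj <- w[c(seq_len(n - 1L) + 1L, 1L)] # cyclic successor
  if (any(w == adj)) {
    stop("invalid stacking word: cyclically adjacent layers must differ")
  }
  d <- diameter
  h <- d * sqrt(2 / 3)
  gam <- cbind(
    c(0, 0),
    d * c(1 / 2, 1 / (2 * sqrt(3))),
    d * c(1 / 2, -1 / (2 * sqrt(3)))
  )
  period <- lattice(
    cbind(
      d * c(1, 0, 0),
      d * c(1 / 2, sqrt(3) / 2, 0),
      c(0, 0, n * h)
    ),
    name = paste0("period[", paste(w, collapse = ""), "]")
  )
  motif <- rbind(gam[, w + 1L, drop = FALSE], (seq_len(n) - 1L) * h)
  structure(
    list(
      dim = 3L, diameter = d, word = w, layer_spacing = h,
      period = period, motif = motif,
      name = paste(c("P[", w, "]"), collapse = "")
    ),
    class = "sphere_packing"
  )
}

.parse_stacking_word <- function(word) {
  if (is.character(word) && length(word) == 1L && nchar(word) > 1L) {
    word <- strsplit(word, "")[[1]]
  }
  if (is.character(word)) {
    map <- c(A = 0L, B = 1L, C = 2L, "0" = 0L, "1" = 1L, "2" = 2L)
    key <- toupper(word)
    if (any(!key %in% names(map))) {
      stop("stacking letters must be in {0,1,2} / {A,B,C}")
    }
    return(unname(map[key]))
  }
  w <- as.integer(word)
  if (any(is.na(w)) || any(!w %in% 0:2)) {
    stop("stacking letters must be in {0,1,2} / {A,B,C}")
  }
  w
}

#' @export
print.sphere_packing <- function(x, ...) {
  cat(sprintf(
    "<sphere_packing %s> %d layers per period, diameter %.6g, density %.6g\n",
    x$name, length(x$word), x$diameter, packing_density(x)
  ))
  invisible(x)
}

#' Density of a layered sphere packing
#'
#' Fraction of space covered by non-overlapping balls of radius
#' `diameter / 2` centered on the packing: ball volume times centers per
#' unit volume, computed from one periodic cell.  Every valid
#' close-stacking has density `pi / sqrt(18)`, equal to the FCC packing
#' ratio.
#'
#' @param P A `sphere_packing`.
#' @return A number in `(0, 1]`.
#' @export
packing_density <- function(P) {
  stopifnot(inherits(P, "sphere_packing"))
  n_centers <- ncol(P$motif)
  .ball_volume(3L, P$diameter / 2) * n_centers / lattice_det(P$period)
}

#' @export
packing_ratio.sphere_packing <- function(geometry) packing_density(geometry)

#' @export
packing_radius.sphere_packing <- function(geometry) geometry$diameter / 2

#' @export
reduce_points.sphere_packing <- function(geometry, x) {
  X <- .as_point_matrix(x, 3L)
  r <- .packing_reduce(geometry, X)
  list(node = t(r$node), residual = t(r$residual), distance = r$distance)
}

# Nearest-center query: reduce (x - m_j) over the period lattice for each
# motif center m_j, keep the best; motif order + lattice lex order give a
# deterministic tie-break.
.packing_reduce <- function(P, X) {
  n <- ncol(X)
  B <- P$period$basis
  tol <- 1e-12 * sum(B^2)
  bestd <- rep(Inf, n)
  bestnode <- matrix(0, 3L, n)
  for (j in seq_len(ncol(P$motif))) {
    m <- P$motif[, j]
    rj <- .lattice_reduce(B, X - m)
    d2 <- rj$distance^2
    upd <- d2 < bestd - tol
    if (any(upd)) {
      bestd[upd] <- d2[upd]
      bestnode[, upd] <- rj$node[, upd, drop = FALSE] + m
    }
  }
  list(
    node = bestnode, residual = X - bestnode,
    distance = sqrt(pmax(bestd, 0))
  )
}

#' @export
kissing_number.sphere_packing <- function(geometry) {
  P <- geometry
  d <- P$diameter
  counts <- vapply(seq_len(ncol(P$motif)), function(i) {
    ref <- P$motif[, i]
    cnt <- 0L
    offs <- .offset_matrix(3L, 2L)
    centers <- P$period$basis %*% offs # period translates
    for (j in seq_len(ncol(P$motif))) {
      pts <- centers + (P$motif[, j] - ref)
      dist <- sqrt(colSums(pts^2))
      cnt <- cnt + sum(abs(dist - d) <= 1e-9 * d)
    }
    cnt
  }, integer(1))
  if (length(unique(counts)) != 1L) {
    stop("packing centers do not share a common kissing number")
  }
  counts[1]
}
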