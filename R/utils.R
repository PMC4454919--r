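# internal helpers shared across modules

# Points are accepted from users as a numeric vector (one point) or an
# n x D matrix (one point per row); internally we work with D x n.
.as_point_matrix <- function(x, D) {
  if (is.null(dim(x))) {
    if (length(x) != D) {
      stop("point has length ", length(x), ", expected dimension ", D)
    }
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != D) {
    stop("points must have ", D, " columns, got ", ncol(x))
  }
  if (!all(is.finite(x))) stop("points must be finite")
  t(x)
}

# Integer offset vectors in {-w, ..., w}^D as a D x (2w+1)^D matrix,
# columns in lexicographic order so that the first strict minimum found
# while scanning is the lexicographically smallest tie-broken candidate.
.offset_matrix <- function(D, w) {
  g <- do.call(expand.grid, rep(list(seq.int(-w, w)), D))
  g <- as.matrix(g[do.call(order, as.data.frame(g)), , drop = FALSE])
  dimnames(g) <- NULL
  t(g)
}

# All integer vectors k in the box prod_alpha [-K_alpha, K_alpha],
# streamed in chunks over the first coordinate(s) so that the 8D lattices
# never materialise hundreds of millions of rows at once.
.for_each_integer_chunk <- function(K, fun) {
  D <- length(K)
  if (D <= 4L) {
    g <- do.call(expand.grid, lapply(K, function(k) seq.int(-k, k)))
    fun(t(as.matrix(g)))
    return(invisible(NULL))
  }
  head_grid <- as.matrix(do.call(
    expand.grid, lapply(K[1:2], function(k) seq.int(-k, k))
  ))
  tail_grid <- t(as.matrix(do.call(
    expand.grid, lapply(K[-(1:2)], function(k) seq.int(-k, k))
  )))
  m <- ncol(tail_grid)
  for (i in seq_len(nrow(head_grid))) {
    chunk <- rbind(
      matrix(head_grid[i, 1L], 1L, m),
      matrix(head_grid[i, 2L], 1L, m),
      tail_grid
    )
    fun(chunk)
  }
  invisible(NULL)
}

# Deterministic substream seeds: a splitmix-style 32-bit mix of a master
# seed and a stream index, so per-realization draws are reproducible and
# order-independent.  Kept below 2^31 for set.seed().
.substream_seed <- function(master, index) {
  m <- (as.double(master) %% 2147483647) + 1
  x <- (m * 69069 + as.double(index) * 2654435761 + 1013904223) %% 2^31
  x <- (x * 1103515245 + 12345) %% 2^31
  as.integer(x %% 2147483629)
}

.is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
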