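#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Fisher-information summary
#'
#' One row per matrix entry, with the trace share of diagonal entries.
#'
#' @param x A `fisher_summary`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `value`, `diagonal`.
#' @export
tidy.fisher_summary <- function(x, ...) {
  D <- x$dim
  idx <- expand.grid(row = seq_len(D), col = seq_len(D), KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    row = idx$row, col = idx$col,
    value = as.vector(x$J),
    diagonal = idx$row == idx$col
  )
}

#' @rdname tidy.fisher_summary
#' @export
glance.fisher_summary <- function(x, ...) {
  tibble::tibble(
    trace = x$trace, dim = x$dim, normalization = x$normalization,
    method = x$method, se = x$se, n = x$n, seed = x$seed,
    geometry = x$geometry
  )
}

#' Tidy a finite-module comparison
#'
#' `tidy()` returns one row per realization and geometry (long format);
#' `glance()` returns the one-row summary with the exceedance fraction.
#'
#' @param x A `module_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.module_comparison <- function(x, ...) {
  r <- x$realizations
  dplyr::bind_rows(
    tibble::tibble(
      realization = r$realization, geometry = x$label_a, trace = r$trace_a
    ),
    tibble::tibble(
      realization = r$realization, geometry = x$label_b, trace = r$trace_b
    )
  )
}

#' @rdname tidy.module_comparison
#' @export
glance.module_comparison <- function(x, ...) {
  tibble::tibble(
    geometry_a = x$label_a, geometry_b = x$label_b,
    M = x$M, n_realizations = x$n_realizations,
    mean_a = x$mean_a, mean_b = x$mean_b,
    sd_a = x$sd_a, sd_b = x$sd_b,
    average_a = x$average_a, average_b = x$average_b,
    fraction_b_beats_a = x$fraction_b_beats_a,
    paired = x$paired, seed = x$seed
  )
}
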