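# Brute-force unit-cell enumeration: the independent oracle for the
# hand-built phase catalog.

#' Enumerate all small periodic patterns
#'
#' Exhaustively enumerates every periodic pattern whose unit cell has at
#' most `max_cell_sites` sites: all sublattices of that index (one Hermite-
#' normal-form basis each) and all `3^n` spin-1 occupancies of the cell.
#' Patterns are reduced to exact integer tuples `(e0, e1, n1, n2, area)`
#' with cell energy `E = e0 + e1*J`, which determine the per-site grand
#' potential at any `(J, mu1, mu2)`; the enumeration is therefore done once
#' and reused for any couplings.
#'
#' @param max_cell_sites cell-area budget, at most 12 (the `3^12`
#'   occupancies of the largest cells dominate the cost).
#' @return object of class `cell_enumeration` wrapping the tuple matrix.
#' @export
enumerate_unit_cells <- function(max_cell_sites = 12) {
  structure(list(tuples = .enumerate_cell_tuples(as.integer(max_cell_sites)),
                 max_cell_sites = as.integer(max_cell_sites)),
            class = "cell_enumeration")
}

#' @export
print.cell_enumeration <- function(x, ...) {
  cat("Exhaustive cell enumeration up to", x$max_cell_sites, "sites:",
      nrow(x$tuples), "distinct (e0, e1, n1, n2, area) tuples\n")
  invisible(x)
}

#' Minimal enumerated grand potential
#'
#' The lowest per-site `h*` over every enumerated pattern (vacuum included)
#' at each chemical-potential point.  Used as the oracle that the phase
#' catalog is never beaten: wherever the true ground state has a unit cell
#' within the budget, this minimum equals the catalog minimum exactly.
#'
#' @param enumeration result of [enumerate_unit_cells()].
#' @param params [interaction_params()] or numeric `J`.
#' @param mu1,mu2 numeric vectors of equal length.
#' @return numeric vector of minimal `h*` values.
#' @export
enumerated_min_h <- function(enumeration, params, mu1, mu2) {
  stopifnot(inherits(enumeration, "cell_enumeration"))
  if (length(mu1) != length(mu2)) stop("mu1 and mu2 must have equal length")
  .min_h_over_tuples(enumeration$tuples, as_J(params),
                     as.numeric(mu1), as.numeric(mu2))
}

#' Minimal catalog grand potential (vectorized)
#'
#' @inheritParams enumerated_min_h
#' @param catalog the phase catalog.
#' @return numeric vector of the catalog's minimal `h*` at each point.
#' @export
catalog_min_h <- function(params, mu1, mu2, catalog = phase_catalog()) {
  J <- as_J(params)
  h <- sapply(catalog, function(p)
    (p$e0 + p$e1 * J - p$n1 * mu1 - p$n2 * mu2) / p$area)
  if (is.null(dim(h))) min(c(h, 0)) else pmin(do.call(pmin, as.data.frame(h)), 0)
}
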