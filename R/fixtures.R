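# Ideal periodic fixtures of the catalog phases.

#' Generate an ideal periodic phase configuration
#'
#' Tiles the unit cell of a catalog phase over an `L` x `L` torus.  The
#' torus must be commensurate with the cell's sublattice (both `(L, 0)` and
#' `(0, L)` must be sublattice vectors); `L = 60`, the standard simulation
#' size, works for the whole catalog.  The grand-potential density of the
#' fixture equals `phase_h()` of the phase exactly.
#'
#' @param phase_name a catalog phase name; `raft_tri` is refused because it
#'   has no explicit periodic cell (see [phase_catalog()]).
#' @param L lattice size.
#' @param catalog the phase catalog.
#' @return a [lattice_config()].
#' @export
generate_fixture <- function(phase_name, L = 60, catalog = phase_catalog()) {
  p <- get_phase(phase_name, catalog)
  if (is.null(p$cell))
    stop("phase '", p$name, "' has no explicit periodic cell; ",
         "it cannot be generated as a fixture")
  a <- p$cell$a; b <- p$cell$b; cs <- p$cell$cshift
  L <- as.integer(L)
  # commensurate iff a | L, b | L and a | (L/b)*cshift
  if (L %% a != 0L || L %% b != 0L || ((L %/% b) * cs) %% a != 0L) {
    valid <- Filter(function(x) x %% a == 0 && x %% b == 0 &&
                      ((x %/% b) * cs) %% a == 0, seq(5L, 120L))
    stop("L = ", L, " is incompatible with the ", p$name,
         " cell; compatible sizes include ",
         paste(utils::head(valid, 8), collapse = ", "))
  }
  S <- .tile_cell(L, a, b, cs, p$cell$i, p$cell$j, p$cell$s)
  lattice_config(L, S)
}
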