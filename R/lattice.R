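#' @useDynLib salrmix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
NULL

#' Triangular lattice with periodic boundary conditions
#'
#' Builds an `L` x `L` triangular lattice in axial coordinates `(i, j)`
#' (0-based, each in `0:(L-1)`), embedded in the plane as `i*a1 + j*a2` with
#' `a1 = (1, 0)` and `a2 = (1/2, sqrt(3)/2)`, in units of the lattice
#' constant.  Minimum-image neighbour shells are precomputed: the six
#' nearest neighbours at distance 1, the six second-shell sites at distance
#' `sqrt(3)` (interaction-free in this model) and the six third-shell sites
#' at distance 2.
#'
#' @param L lateral size (sites per side); must be at least 5 so the
#'   minimum-image shells are unambiguous.
#' @return an object of class `triangular_lattice` with elements `L` and the
#'   1-based neighbour index tables `nn1`, `nn2`, `nn3` (`L^2` x 6).
#' @export
triangular_lattice <- function(L) {
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 5L)
    stop("L must be a single integer >= 5 (minimum-image shells are ambiguous below L = 5)")
  tabs <- .neighbor_tables(L)
  structure(
    list(L = L,
         nn1 = tabs$nn1 + 1L,
         nn2 = tabs$nn2 + 1L,
         nn3 = tabs$nn3 + 1L),
    class = "triangular_lattice")
}

#' @export
print.triangular_lattice <- function(x, ...) {
  cat("Periodic triangular lattice, L =", x$L, "(", x$L^2, "sites )\n")
  invisible(x)
}

#' Interaction parameters of the lattice mixture
#'
#' The model has a single shape parameter, the ratio `J = J2/J1` of the
#' third- to first-neighbour coupling (`J1 = 1` sets the energy unit).  Like
#' pairs attract at distance 1 (`-1`) and repel at distance 2 (`+J`); unlike
#' pairs do the opposite.  The ground-state engine distinguishes the regimes
#' `J < 1/2` (no microphase separation), `1/2 < J < 13/12` (7-particle
#' hexagonal clusters optimal), `13/12 < J < 7/4` (4-particle rhombic
#' clusters optimal) and `J > 7/4` (only small clusters; the full
#' two-component phase catalog applies).
#'
#' @param J positive coupling ratio `J2/J1`.
#' @return an object of class `interaction_params` with elements `J` and
#'   `regime`.
#' @export
interaction_params <- function(J) {
  if (!is.numeric(J) || length(J) != 1L || is.na(J) || J <= 0)
    stop("J must be a single positive number")
  regime <-
    if (J < 1 / 2) "J < 1/2" else
    if (J < 13 / 12) "1/2 < J < 13/12" else
    if (J < 7 / 4) "13/12 < J < 7/4" else "J > 7/4"
  structure(list(J = J, regime = regime), class = "interaction_params")
}

as_J <- function(params) {
  if (inherits(params, "interaction_params")) params$J
  else if (is.numeric(params) && length(params) == 1L && params > 0) params
  else stop("params must be interaction_params() or a positive number J")
}

#' Lattice configuration of the binary mixture
#'
#' A spin-1 occupancy field on the periodic triangular lattice: `S = +1`
#' for a species-1 particle, `-1` for species 2, `0` for an empty site.
#' Single occupancy is automatic in this encoding.
#'
#' @param L lattice size, or a `triangular_lattice`.
#' @param S optional integer vector of length `L^2` with values in
#'   `c(-1, 0, 1)`, indexed as `i + j*L + 1` for axial `(i, j)`; default
#'   empty.
#' @return object of class `lattice_config` with elements `L` and `S`.
#' @export
lattice_config <- function(L, S = NULL) {
  if (inherits(L, "triangular_lattice")) L <- L$L
  L <- as.integer(L)
  if (L < 5L) stop("L must be >= 5")
  if (is.null(S)) S <- integer(L^2)
  S <- as.integer(S)
  if (length(S) != L^2) stop("S must have length L^2")
  if (!all(S %in% c(-1L, 0L, 1L))) stop("S values must be in {-1, 0, 1}")
  structure(list(L = L, S = S), class = "lattice_config")
}

#' Build a configuration from occupied sites
#'
#' @param L lattice size.
#' @param i,j integer axial coordinates (0-based) of occupied sites.
#' @param species species labels, 1 or 2, recycled to `length(i)`.
#' @return a `lattice_config`.
#' @export
config_from_sites <- function(L, i, j, species) {
  L <- as.integer(L)
  i <- as.integer(i) %% L
  j <- as.integer(j) %% L
  species <- rep_len(as.integer(species), length(i))
  if (!all(species %in% c(1L, 2L))) stop("species must be 1 or 2")
  idx <- i + j * L + 1L
  if (anyDuplicated(idx)) stop("duplicate site: single occupancy is required")
  S <- integer(L^2)
  S[idx] <- ifelse(species == 1L, 1L, -1L)
  lattice_config(L, S)
}

#' @export
print.lattice_config <- function(x, ...) {
  n <- particle_counts(x)
  cat("Lattice configuration L =", x$L, ": N1 =", n[1], ", N2 =", n[2],
      ", empty =", x$L^2 - sum(n), "\n")
  invisible(x)
}

#' Particle counts of a configuration
#'
#' @param config a `lattice_config`.
#' @return named integer vector `c(N1, N2)`.
#' @export
particle_counts <- function(config) {
  c(N1 = sum(config$S == 1L), N2 = sum(config$S == -1L))
}

#' Neighbour shells of one site
#'
#' Returns the six first-shell (distance 1) and six third-shell (distance 2)
#' sites of `site`, as axial coordinates under minimum-image periodic
#' boundary conditions.  The interaction-free second shell (distance
#' `sqrt(3)`) is excluded.
#'
#' @param lattice a `triangular_lattice` (or integer size `L >= 5`).
#' @param site integer vector `c(i, j)` of 0-based axial coordinates.
#' @return list with matrices `first` and `third` (6 x 2, columns `i`, `j`).
#' @export
neighbor_shells <- function(lattice, site) {
  if (!inherits(lattice, "triangular_lattice")) lattice <- triangular_lattice(lattice)
  L <- lattice$L
  i <- as.integer(site[1]) %% L
  j <- as.integer(site[2]) %% L
  d1 <- cbind(i = c(1L, -1L, 0L, 0L, 1L, -1L), j = c(0L, 0L, 1L, -1L, -1L, 1L))
  first <- cbind(i = (i + d1[, 1]) %% L, j = (j + d1[, 2]) %% L)
  third <- cbind(i = (i + 2L * d1[, 1]) %% L, j = (j + 2L * d1[, 2]) %% L)
  list(first = first, third = third)
}

#' Pair interaction energy
#'
#' Energy of one occupied pair, in `J1` units: like pairs `-1` on the first
#' shell and `+J` on the third; unlike pairs `+1` and `-J`.
#'
#' @param species_i,species_j species labels (1 or 2).
#' @param shell `"first"` or `"third"`.
#' @param params `interaction_params()` or numeric `J`.
#' @return pair energy in `J1` units.
#' @export
pair_energy <- function(species_i, species_j, shell, params) {
  J <- as_J(params)
  if (!all(c(species_i, species_j) %in% 1:2)) stop("species must be 1 or 2")
  shell <- match.arg(shell, c("first", "third"))
  like <- species_i == species_j
  if (shell == "first") (if (like) -1 else 1) else (if (like) J else -J)
}

#' Exact interaction energy of a configuration
#'
#' Sum of pair energies over all occupied first- and third-shell pairs, each
#' pair counted once.  `total_energy_parts()` returns the exact integer
#' decomposition `c(e0, e1)` with `E = e0 + e1*J`, so the energy is exact
#' whenever `J` is.
#'
#' @param config a `lattice_config`.
#' @param params `interaction_params()` or numeric `J`.
#' @return energy in `J1` units (`total_energy`), or integer vector
#'   `c(e0, e1)` (`total_energy_parts`).
#' @export
total_energy <- function(config, params) {
  p <- total_energy_parts(config)
  unname(p[[1]] + p[[2]] * as_J(params))
}

#' @rdname total_energy
#' @export
total_energy_parts <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  setNames(.energy_parts(config$S, config$L), c("e0", "e1"))
}

#' Per-site thermodynamic Hamiltonian (grand-potential density)
#'
#' `h* = (E - mu1*N1 - mu2*N2) / L^2`, the quantity whose minimum over
#' candidate patterns selects the stable phase at fixed chemical potentials
#' and T = 0.
#'
#' @param config a `lattice_config`.
#' @param params `interaction_params()` or numeric `J`.
#' @param mu1,mu2 dimensionless chemical potentials (in `J1` units).
#' @return `h*` in `J1` units per site.
#' @export
grand_hamiltonian_density <- function(config, params, mu1, mu2) {
  n <- particle_counts(config)
  (total_energy(config, params) - mu1 * n[["N1"]] - mu2 * n[["N2"]]) / config$L^2
}

#' Local fields at one site
#'
#' `Delta1` and `Delta2`, the sums of the spin variable `S` over the six
#' first-shell and six third-shell neighbours of `site` (the site itself is
#' never included).
#'
#' @param config a `lattice_config`.
#' @param site integer vector `c(i, j)`, 0-based axial coordinates.
#' @return named integer vector `c(Delta1, Delta2)`.
#' @export
local_field <- function(config, site) {
  L <- config$L
  f <- .local_field(config$S, L, as.integer(site[1]) %% L, as.integer(site[2]) %% L)
  setNames(f, c("Delta1", "Delta2"))
}

#' Energy change of inserting one particle
#'
#' For insertion of species `s` at an empty site,
#' `dE = -s' * (Delta1 - J*Delta2)` with `s' = +1` (species 1) or `-1`
#' (species 2); this equals the from-scratch energy difference exactly.
#'
#' @param config a `lattice_config`.
#' @param site `c(i, j)` axial coordinates of an empty site.
#' @param species 1 or 2.
#' @param params `interaction_params()` or numeric `J`.
#' @return energy change in `J1` units.
#' @export
insertion_energy_change <- function(config, site, species, params) {
  L <- config$L
  i <- as.integer(site[1]) %% L
  j <- as.integer(site[2]) %% L
  if (config$S[i + j * L + 1L] != 0L)
    stop("site (", i, ", ", j, ") is occupied")
  if (!species %in% 1:2) stop("species must be 1 or 2")
  f <- local_field(config, c(i, j))
  s <- if (species == 1) 1 else -1
  unname(-s * (f[1] - as_J(params) * f[2]))
}

#' Swap the two species of a configuration
#'
#' @param config a `lattice_config`.
#' @return the configuration with `S -> -S`.
#' @export
species_swap <- function(config) {
  lattice_config(config$L, -config$S)
}

#' Translate a configuration on the torus
#'
#' @param config a `lattice_config`.
#' @param di,dj integer axial shifts.
#' @return the translated configuration.
#' @export
translate_config <- function(config, di, dj) {
  L <- config$L
  idx <- which(config$S != 0L) - 1L
  i <- (idx %% L + as.integer(di)) %% L
  j <- (idx %/% L + as.integer(dj)) %% L
  S <- integer(L^2)
  S[i + j * L + 1L] <- config$S[idx + 1L]
  lattice_config(L, S)
}

# axial -> Euclidean embedding (units of the lattice constant)
axial_to_xy <- function(i, j) {
  cbind(x = i + j / 2, y = j * sqrt(3) / 2)
}
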