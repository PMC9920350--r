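# Continuous-space molecular dynamics of the binary mixture in slit or
# adsorption geometry.

#' Pair potential of the continuous model
#'
#' `V11(r) = 6[r^-12 - r^-6 + 0.3 e^{-r/2}/r]`, `V22 = V11/q^2`,
#' `V12(r) = 6[r^-12 + r^-6 - 0.3 e^{-r/2}/r]/q`, truncated (not shifted by
#' default) at `r_cut = 6.75`.  Energies in `epsilon`, lengths in the
#' particle diameter.
#'
#' @param r distance(s), positive.
#' @param species_i,species_j species labels (1 or 2).
#' @param q charge-asymmetry ratio in `(0, 1]`.
#' @param r_cut cutoff distance.
#' @param shifted if `TRUE` the potential is shifted to zero at the cutoff.
#' @return potential energy (vectorized over `r`).
#' @export
pair_potential <- function(r, species_i, species_j, q = 1, r_cut = 6.75,
                           shifted = FALSE) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  .pair_potential_cpp(as.numeric(r), as.integer(species_i),
                      as.integer(species_j), q, r_cut, shifted)
}

#' @rdname pair_potential
#' @return `pair_force()` gives the radial force `-dV/dr` (positive =
#'   repulsive).
#' @export
pair_force <- function(r, species_i, species_j, q = 1, r_cut = 6.75,
                       shifted = FALSE) {
  .pair_force_cpp(as.numeric(r), as.integer(species_i),
                  as.integer(species_j), q, r_cut, shifted)
}

#' Wall potential
#'
#' Repulsive wall: `2 eps/(z - zw)^12`; attractive wall (at `z = 0`):
#' `4 eps [z^-12 - z^-6]`.  `wall_spec` selects the `z = 0` wall type:
#' `"repulsive"`, `"attract-species-1"` (species 2 sees the repulsive
#' wall) or `"attract-both"`; the wall at `z = Lz` is always repulsive.
#'
#' @param z height(s) inside `(0, Lz)`.
#' @param species 1 or 2.
#' @param wall_spec wall type at `z = 0`.
#' @param Lz slab width.
#' @return total wall energy at `z` (both walls).
#' @export
wall_potential <- function(z, species,
                           wall_spec = c("repulsive", "attract-species-1",
                                         "attract-both"),
                           Lz = 4) {
  wall_spec <- match.arg(wall_spec)
  code <- match(wall_spec, c("repulsive", "attract-species-1", "attract-both")) - 1L
  vapply(as.numeric(z), function(zz)
    .wall_terms_cpp(zz, as.integer(species), code, Lz)[1], numeric(1))
}

#' @rdname wall_potential
#' @return `wall_force()` gives the z-component of the wall force.
#' @export
wall_force <- function(z, species,
                       wall_spec = c("repulsive", "attract-species-1",
                                     "attract-both"),
                       Lz = 4) {
  wall_spec <- match.arg(wall_spec)
  code <- match(wall_spec, c("repulsive", "attract-species-1", "attract-both")) - 1L
  vapply(as.numeric(z), function(zz)
    .wall_terms_cpp(zz, as.integer(species), code, Lz)[2], numeric(1))
}

#' Continuous-space particle system
#'
#' Builds an MD system in a box periodic in x and y with confining walls at
#' `z = 0` and `z = Lz`.  When positions are not supplied, particles are
#' inserted at random without overlap (minimum distance 0.9) and velocities
#' drawn from the Maxwell distribution at `T_bar` with zero centre-of-mass
#' motion.
#'
#' @param N1,N2 particle numbers of species 1 and 2.
#' @param box numeric `c(Lx, Ly, Lz)`.
#' @param T_bar dimensionless temperature `kB T / epsilon` for velocity
#'   initialization.
#' @param q charge-asymmetry ratio.
#' @param wall_spec wall type at `z = 0` (see [wall_potential()]).
#' @param positions,velocities optional `N x 3` matrices.
#' @param z_range height band used for random insertion (default keeps
#'   0.8 clear of each wall).
#' @return list of class `md_system`.
#' @export
md_system <- function(N1, N2, box, T_bar, q = 1,
                      wall_spec = c("repulsive", "attract-species-1",
                                    "attract-both"),
                      positions = NULL, velocities = NULL,
                      z_range = NULL) {
  wall_spec <- match.arg(wall_spec)
  N <- N1 + N2
  species <- rep(c(1L, 2L), c(N1, N2))
  if (is.null(positions)) {
    if (is.null(z_range)) z_range <- c(0.8, box[3] - 0.8)
    positions <- matrix(NA_real_, N, 3)
    placed <- 0
    tries <- 0
    while (placed < N) {
      cand <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]),
                stats::runif(1, z_range[1], z_range[2]))
      ok <- TRUE
      if (placed > 0) {
        d <- t(positions[seq_len(placed), , drop = FALSE]) - cand
        d[1, ] <- d[1, ] - box[1] * round(d[1, ] / box[1])
        d[2, ] <- d[2, ] - box[2] * round(d[2, ] / box[2])
        ok <- min(colSums(d^2)) > 0.81
      }
      if (ok) { placed <- placed + 1; positions[placed, ] <- cand }
      tries <- tries + 1
      if (tries > 1e6) stop("could not place particles without overlap; box too small")
    }
  }
  if (is.null(velocities)) {
    velocities <- matrix(stats::rnorm(3 * N, sd = sqrt(T_bar)), N, 3)
    velocities <- sweep(velocities, 2, colMeans(velocities))
  }
  structure(list(positions = positions, velocities = velocities,
                 species = species, box = box, q = q,
                 wall_spec = wall_spec, T_bar = T_bar),
            class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  cat("MD system: N =", nrow(x$positions), "(",
      sum(x$species == 1), "+", sum(x$species == 2),
      "), box =", paste(x$box, collapse = " x "),
      ", q =", x$q, ", wall:", x$wall_spec, "\n")
  invisible(x)
}

wall_code <- function(wall_spec)
  match(wall_spec, c("repulsive", "attract-species-1", "attract-both")) - 1L

#' Advance an MD system
#'
#' Velocity-Verlet integration with cell-list forces; every
#' `rescale_interval` steps particle velocities are scaled so the kinetic
#' temperature matches `T_target` (omit `T_target` for NVE).  Optional
#' `zones` (matrix with columns `z_lo`, `z_hi`, `T`) impose different
#' temperatures in z-bands, as used in the initial stage of adsorption
#' runs.
#'
#' @param system an [md_system()].
#' @param nsteps number of timesteps.
#' @param dt timestep (default 0.004 in reduced time units).
#' @param T_target thermostat temperature; `NA` for NVE.
#' @param rescale_interval steps between velocity rescalings.
#' @param zones optional zoned-thermostat matrix.
#' @param r_cut,shifted pair-potential truncation.
#' @param record_interval steps between time-series records.
#' @return the advanced `md_system`, with the recorded `series` data frame
#'   (`step`, `T_kin`, `PE`, `E_total`, `Px`, `Py`) and final
#'   `potential_energy` attached.
#' @export
md_run <- function(system, nsteps, dt = 0.004, T_target = NA,
                   rescale_interval = 50, zones = NULL, r_cut = 6.75,
                   shifted = FALSE, record_interval = 100) {
  stopifnot(inherits(system, "md_system"))
  res <- .md_run_cpp(system$positions, system$velocities, system$species,
                     system$box[1], system$box[2], system$box[3], system$q,
                     wall_code(system$wall_spec), dt, as.integer(nsteps),
                     as.integer(rescale_interval), as.numeric(T_target),
                     zones, r_cut, shifted, as.integer(record_interval))
  system$positions <- res$positions
  system$velocities <- res$velocities
  system$series <- res$series
  system$potential_energy <- res$potential_energy
  system
}

#' Total potential energy of a configuration
#'
#' All-pairs reference evaluation (independent of any cell decomposition).
#'
#' @param system an [md_system()].
#' @param r_cut,shifted truncation settings.
#' @return potential energy in `epsilon`.
#' @export
md_potential_energy <- function(system, r_cut = 6.75, shifted = FALSE) {
  .md_potential_energy(system$positions, system$species, system$box[1],
                       system$box[2], system$box[3], system$q,
                       wall_code(system$wall_spec), r_cut, shifted, -1)
}

#' Self-assembly in a thin slit
#'
#' The slit study conditions: both walls repulsive, `Lz = 4`,
#' `Lx = Ly = 150`, `N1 = N2 = 200`, symmetric (`q = 1`) or asymmetric
#' (`q = 1/2`) interactions.  The system is annealed from a hot, mixed
#' state down to `T_bar` and then held there until the pattern is
#' stationary (the potential energy fluctuates around a constant value).
#'
#' @param N1,N2 particle numbers.
#' @param q charge-asymmetry ratio.
#' @param T_bar final temperature.
#' @param Lx,Ly,Lz box dimensions.
#' @param anneal_steps steps per annealing stage.
#' @param hold_steps steps of the final constant-temperature stage.
#' @param seed RNG seed.
#' @param dt,rescale_interval,record_interval integration settings.
#' @return the final `md_system` (with attached `series` of the hold
#'   stage).
#' @export
run_slit <- function(N1 = 200, N2 = 200, q = 1, T_bar = 0.12,
                     Lx = 150, Ly = 150, Lz = 4,
                     anneal_steps = 20000, hold_steps = 200000,
                     seed = NULL, dt = 0.004, rescale_interval = 50,
                     record_interval = 1000) {
  if (!is.null(seed)) set.seed(seed)
  sys <- md_system(N1, N2, c(Lx, Ly, Lz), T_bar = 0.5, q = q,
                   wall_spec = "repulsive")
  for (Tstage in c(0.5, 0.3, 0.2, max(T_bar, 0.15))) {
    if (Tstage < T_bar) break
    sys <- md_run(sys, anneal_steps, dt = dt, T_target = Tstage,
                  rescale_interval = rescale_interval,
                  record_interval = record_interval)
  }
  md_run(sys, hold_steps, dt = dt, T_target = T_bar,
         rescale_interval = rescale_interval,
         record_interval = record_interval)
}

#' Scaled-down adsorption run
#'
#' Adsorption of the mixture on the wall at `z = 0` (selective or
#' non-selective), at desk scale: the full-size boxes and particle numbers
#' of the adsorption study are out of scope, and this mode preserves the
#' geometry near the wall only.  The charge-neutrality condition
#' `N1 = q*N2` is enforced.  The initial stage uses the zoned thermostat
#' (three z-bands at scaled heights with temperatures 0.04, 0.13, 0.17);
#' the final stage holds the whole box at `T_final`.
#'
#' @param N2 species-2 particle number; `N1 = q*N2` must be an integer and
#'   `N1 + N2` at most 2000.
#' @param q charge-asymmetry ratio.
#' @param wall_spec `"attract-species-1"` or `"attract-both"`.
#' @param Lx,Ly,Lz box dimensions (desk-scale defaults).
#' @param T_final final uniform temperature.
#' @param stage_steps,hold_steps steps of the zoned and final stages.
#' @param seed RNG seed.
#' @param dt,rescale_interval,record_interval integration settings.
#' @return the final `md_system`.
#' @export
run_adsorption_scaled <- function(N2 = 300, q = 1 / 2,
                                  wall_spec = c("attract-species-1",
                                                "attract-both"),
                                  Lx = 30, Ly = 30, Lz = 40,
                                  T_final = 0.08,
                                  stage_steps = 20000, hold_steps = 100000,
                                  seed = NULL, dt = 0.004,
                                  rescale_interval = 50,
                                  record_interval = 1000) {
  wall_spec <- match.arg(wall_spec)
  N1 <- q * N2
  if (abs(N1 - round(N1)) > 1e-9)
    stop("charge neutrality requires N1 = q*N2 to be an integer")
  N1 <- as.integer(round(N1))
  if (N1 + N2 > 2000)
    stop("N beyond desk budget (N1 + N2 <= 2000); full-scale adsorption ",
         "runs are a non-goal of this package")
  if (!is.null(seed)) set.seed(seed)
  sys <- md_system(N1, N2, c(Lx, Ly, Lz), T_bar = 0.17, q = q,
                   wall_spec = wall_spec,
                   z_range = c(0.8, Lz - 0.8))
  # zoned initial stage; band heights scaled from the full geometry
  # (0-80-320-800) to the desk box
  zb <- Lz * c(0.1, 0.4)
  zones <- rbind(c(0, zb[1], 0.04), c(zb[1], zb[2], 0.13),
                 c(zb[2], Lz, 0.17))
  sys <- md_run(sys, stage_steps, dt = dt, zones = zones,
                rescale_interval = rescale_interval,
                record_interval = record_interval)
  md_run(sys, hold_steps, dt = dt, T_target = T_final,
         rescale_interval = rescale_interval,
         record_interval = record_interval)
}

#' Extract a monolayer slab
#'
#' Particles whose height is within a slab of thickness `thickness`
#' centred at `z_center`, as used to compare adsorbed monolayers with the
#' lattice phases.
#'
#' @param system an `md_system`.
#' @param z_center slab centre.
#' @param thickness slab thickness (default one particle diameter).
#' @return an `md_system` restricted to the slab.
#' @export
extract_monolayer <- function(system, z_center, thickness = 1) {
  keep <- abs(system$positions[, 3] - z_center) <= thickness / 2
  system$positions <- system$positions[keep, , drop = FALSE]
  system$velocities <- system$velocities[keep, , drop = FALSE]
  system$species <- system$species[keep]
  system
}
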