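# Grand-canonical and canonical Monte Carlo with simulated annealing.
#
# The production protocol follows the lattice-model study conditions:
# lateral size L = 60, annealing from T* = 5.0 down to T* = 0.2, an MC step
# being one attempted insertion/removal per lattice site (grand canonical)
# or one attempted displacement per particle (canonical).

#' Default annealing temperature schedule
#'
#' Roughly geometric sequence from the hot start `T* = 5.0` to the final
#' low temperature `T* = 0.2`.
#'
#' @param canonical logical; the canonical schedule cools in more stages
#'   because raft coarsening relies on rare detachment events near the
#'   aggregation temperature.
#' @return decreasing numeric vector of temperatures.
#' @export
default_schedule <- function(canonical = FALSE) {
  if (canonical) c(5.0, 3.0, 2.0, 1.4, 1.0, 0.7, 0.5, 0.35, 0.2)
  else c(5.0, 2.0, 1.0, 0.5, 0.2)
}

#' Parameters for a grand-canonical annealing run
#'
#' @param mu1,mu2 dimensionless chemical potentials.
#' @param J coupling ratio `J2/J1`.
#' @param L lattice size (default 60, the production size).
#' @param T_schedule strictly decreasing temperatures (default
#'   [default_schedule()]).
#' @param equil_steps,prod_steps equilibration and production MC steps per
#'   temperature (paper-scale defaults `1e5` and `1e6`; scale down for
#'   exploratory runs).
#' @param seed RNG seed recorded in the result (`set.seed` is called with
#'   it when not `NULL`).
#' @param record_interval steps between time-series records.
#' @param snapshot_interval production steps between stored snapshots at
#'   the final temperature.
#' @param max_snapshots cap on stored snapshots.
#' @param validate_interval attempted moves between from-scratch
#'   revalidations of the incrementally tracked energy and local fields
#'   (exact integer comparison; any mismatch aborts the run).
#' @return list of class `gcmc_params`.
#' @export
gcmc_params <- function(mu1, mu2, J = 3, L = 60,
                        T_schedule = default_schedule(),
                        equil_steps = 1e5, prod_steps = 1e6,
                        seed = NULL, record_interval = 1000,
                        snapshot_interval = 1000, max_snapshots = 50,
                        validate_interval = 1e6) {
  if (any(diff(T_schedule) >= 0) || any(T_schedule <= 0))
    stop("T_schedule must be strictly decreasing and positive")
  if (equil_steps < 1 || prod_steps < 1) stop("step counts must be positive")
  structure(list(mu1 = mu1, mu2 = mu2, J = J, L = as.integer(L),
                 T_schedule = T_schedule,
                 equil_steps = as.integer(equil_steps),
                 prod_steps = as.integer(prod_steps), seed = seed,
                 record_interval = as.integer(record_interval),
                 snapshot_interval = as.integer(snapshot_interval),
                 max_snapshots = as.integer(max_snapshots),
                 validate_interval = validate_interval),
            class = "gcmc_params")
}

#' Grand-canonical annealing run
#'
#' Starts from an empty lattice at the first (hot) temperature and anneals
#' through the schedule.  At every attempted move a site is picked
#' uniformly; if empty, a species is picked with probability 1/2 and
#' inserted with acceptance `min(1, exp[(u_i + mu_i)/T*])`; if occupied by
#' species `i`, removal is attempted with acceptance
#' `min(1, exp[-(u_i + mu_i)/T*])`, where `u_1 = -u_2 = Delta1 - J*Delta2`
#' from the local fields.  Energy is tracked as exact integers and verified
#' against a from-scratch recomputation every `1e4` moves.
#'
#' @param params a [gcmc_params()].
#' @param initial optional starting [lattice_config()] (default empty).
#' @return list of class `gcmc_result`: final `config`, `series` data frame
#'   (`step`, `T`, `N1`, `N2`, `E`), `snapshots` (final-temperature
#'   production configurations) and the run `params`.
#' @export
anneal_gcmc <- function(params, initial = NULL) {
  stopifnot(inherits(params, "gcmc_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  S0 <- if (is.null(initial)) integer(params$L^2) else {
    stopifnot(inherits(initial, "lattice_config"),
              initial$L == params$L)
    initial$S
  }
  res <- .run_gcmc(S0, params$L, params$J, params$mu1, params$mu2,
                   params$T_schedule, params$equil_steps, params$prod_steps,
                   params$record_interval, params$snapshot_interval,
                   params$max_snapshots, params$validate_interval)
  structure(list(config = lattice_config(params$L, res$S),
                 series = res$series,
                 snapshots = lapply(res$snapshots, function(s)
                   lattice_config(params$L, s)),
                 energy_parts = res$energy_parts,
                 params = params),
            class = "gcmc_result")
}

#' @export
print.gcmc_result <- function(x, ...) {
  n <- particle_counts(x$config)
  cat("GCMC annealing at (mu1, mu2) = (", x$params$mu1, ",", x$params$mu2,
      "), J =", x$params$J, "-> final T* =",
      min(x$params$T_schedule), ": N1 =", n[1], ", N2 =", n[2], "\n")
  invisible(x)
}

#' Parameters for a canonical (fixed-N) annealing run
#'
#' @param N1,N2 particle numbers of the two species (`N1 + N2 <= L^2`).
#' @param J coupling ratio.
#' @param L lattice size.
#' @param T_schedule decreasing temperatures (default the slower canonical
#'   schedule of [default_schedule()]).
#' @param equil_steps,prod_steps MC steps (one attempted displacement per
#'   particle each) per temperature.
#' @param seed RNG seed.
#' @param record_interval steps between records.
#' @return list of class `canonical_params`.
#' @export
canonical_params <- function(N1, N2, J = 3, L = 60,
                             T_schedule = default_schedule(canonical = TRUE),
                             equil_steps = 2e4, prod_steps = 2e5,
                             seed = NULL, record_interval = 1000) {
  if (N1 + N2 > L^2) stop("N1 + N2 must not exceed L^2")
  if (N1 + N2 < 1) stop("need at least one particle")
  if (any(diff(T_schedule) >= 0) || any(T_schedule <= 0))
    stop("T_schedule must be strictly decreasing and positive")
  structure(list(N1 = as.integer(N1), N2 = as.integer(N2), J = J,
                 L = as.integer(L), T_schedule = T_schedule,
                 equil_steps = as.integer(equil_steps),
                 prod_steps = as.integer(prod_steps), seed = seed,
                 record_interval = as.integer(record_interval)),
            class = "canonical_params")
}

#' Canonical annealing run
#'
#' Fixed particle numbers; the stochastic evolution proceeds by
#' displacement moves of a random particle to a random first-shell site,
#' accepted with the Metropolis probability `min(1, exp(-dE/T*))`.
#' Particle counts are conserved exactly.  The default start is a random
#' non-interacting placement (the hot first stage mixes it).
#'
#' @param params a [canonical_params()].
#' @param initial optional starting [lattice_config()] with matching counts.
#' @return list of class `canonical_result` with final `config`, `series`
#'   and `params`.
#' @export
anneal_canonical <- function(params, initial = NULL) {
  stopifnot(inherits(params, "canonical_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(initial)) {
    sites <- sample.int(params$L^2, params$N1 + params$N2) - 1L
    initial <- config_from_sites(
      params$L, sites %% params$L, sites %/% params$L,
      rep(c(1L, 2L), c(params$N1, params$N2)))
  } else {
    n <- particle_counts(initial)
    if (n[1] != params$N1 || n[2] != params$N2 || initial$L != params$L)
      stop("initial configuration does not match (N1, N2, L)")
  }
  res <- .run_canonical(initial$S, params$L, params$J, params$T_schedule,
                        params$equil_steps, params$prod_steps,
                        params$record_interval)
  structure(list(config = lattice_config(params$L, res$S),
                 series = res$series,
                 energy_parts = res$energy_parts,
                 params = params),
            class = "canonical_result")
}

#' Insertion/removal acceptance factor
#'
#' The factor `min(1, exp[+-(u_i + mu_i)/T*])` used by the grand-canonical
#' kernel, exposed for detailed-balance checks.
#'
#' @param params [interaction_params()] or numeric `J`.
#' @param T_star temperature.
#' @param mu1,mu2 chemical potentials.
#' @param Delta1,Delta2 integer local fields at the site.
#' @param species 1 or 2.
#' @param move `"insertion"` or `"removal"`.
#' @return acceptance probability in `[0, 1]`.
#' @export
gcmc_acceptance <- function(params, T_star, mu1, mu2, Delta1, Delta2,
                            species, move = c("insertion", "removal")) {
  move <- match.arg(move)
  .gcmc_acceptance(as_J(params), T_star, mu1, mu2,
                   as.integer(Delta1), as.integer(Delta2),
                   as.integer(species), move)
}
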