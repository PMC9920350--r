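# Order parameters, phase classification and raft structure.
#
# Visual classification of snapshots is subjective; here it is
# operationalized as a fingerprint of intensive order parameters (species
# densities and like/unlike occupied-pair fractions of the two interacting
# shells) compared against the ideal fingerprint of every catalog phase.

#' Order parameters of a lattice configuration
#'
#' @param config a [lattice_config()].
#' @return list of class `order_parameters`: species densities `rho1`,
#'   `rho2`; `f_like_nn`, `f_unlike_nn`, `f_like_3rd`, `f_unlike_3rd`
#'   (occupied like/unlike pairs as a fraction of all `3 L^2` site pairs of
#'   the shell); `cluster_sizes` (histogram of like-species first-shell
#'   connected components); `largest_mixed_fraction` (fraction of particles
#'   in the largest component of the distance-\eqn{\le}2 particle graph).
#' @export
order_parameters <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  L <- config$L
  n <- particle_counts(config)
  np <- sum(n)
  pc <- .pair_counts(config$S, L)
  npairs <- 3 * L^2
  like_comp <- .lattice_components(config$S, L, 1L)
  comp_sizes <- if (np > 0) as.integer(table(like_comp[like_comp > 0L]))
                else integer(0)
  mixed <- .lattice_components(config$S, L, 2L)
  lmf <- if (np > 0) max(table(mixed[mixed > 0])) / np else 0
  structure(list(
    rho1 = n[["N1"]] / L^2, rho2 = n[["N2"]] / L^2,
    f_like_nn = pc[1] / npairs, f_unlike_nn = pc[2] / npairs,
    f_like_3rd = pc[3] / npairs, f_unlike_3rd = pc[4] / npairs,
    cluster_sizes = table(comp_sizes),
    largest_mixed_fraction = unname(lmf)),
    class = "order_parameters")
}

fingerprint <- function(op) {
  c(rho1 = op$rho1, rho2 = op$rho2,
    f_like_nn = op$f_like_nn, f_unlike_nn = op$f_unlike_nn,
    f_like_3rd = op$f_like_3rd, f_unlike_3rd = op$f_unlike_3rd)
}

.fingerprint_cache <- new.env(parent = emptyenv())

#' Ideal fingerprints of the catalog phases
#'
#' Intensive order-parameter vectors of the ideal fixtures (independent of
#' the lattice size used to evaluate them).
#'
#' @param catalog the phase catalog.
#' @return matrix, one row per classifiable phase (phases with explicit
#'   cells), columns the six fingerprint components.
#' @export
catalog_fingerprints <- function(catalog = phase_catalog()) {
  key <- paste(names(catalog), collapse = ",")
  if (!is.null(.fingerprint_cache[[key]])) return(.fingerprint_cache[[key]])
  classifiable <- Filter(function(p) !is.null(p$cell), catalog)
  fp <- t(vapply(classifiable, function(p) {
    # fingerprints are intensive: any commensurate torus gives the same values
    a <- p$cell$a; b <- p$cell$b; cs <- p$cell$cshift
    L <- Filter(function(x) x %% a == 0 && x %% b == 0 &&
                  ((x %/% b) * cs) %% a == 0, 5:120)[1]
    fingerprint(order_parameters(generate_fixture(p$name, L, catalog)))
  }, numeric(6)))
  .fingerprint_cache[[key]] <- fp
  fp
}

#' Classify a configuration into a catalog phase
#'
#' Nearest catalog phase in fingerprint space (Euclidean distance over the
#' six intensive order parameters, each of which lies in `[0, 1]`); when no
#' phase is within `threshold` the configuration is reported as
#' `"disordered/mixed"`.
#'
#' @param config a [lattice_config()].
#' @param catalog the phase catalog.
#' @param threshold maximal fingerprint distance for a phase label.
#' @return list of class `phase_classification`: `label`, `distance` (to
#'   the nearest phase), `confidence` (`1 - distance/threshold`, floored at
#'   0) and the full named `distances` vector.
#' @export
classify <- function(config, catalog = phase_catalog(), threshold = 0.15) {
  fp <- catalog_fingerprints(catalog)
  x <- fingerprint(order_parameters(config))
  d <- sqrt(colSums((t(fp) - x)^2))
  best <- which.min(d)
  label <- if (d[best] <= threshold) rownames(fp)[best] else "disordered/mixed"
  structure(list(label = label,
                 distance = unname(d[best]),
                 nearest = rownames(fp)[best],
                 confidence = max(0, 1 - unname(d[best]) / threshold),
                 distances = d),
            class = "phase_classification")
}

#' @export
print.phase_classification <- function(x, ...) {
  cat("Classified as:", x$label,
      sprintf("(distance %.4f, confidence %.2f)\n", x$distance, x$confidence))
  invisible(x)
}

# unwrap one mixed-graph component across the torus; returns axial
# coordinates relative to an arbitrary member
unwrap_component <- function(config, members) {
  L <- config$L
  offs <- rbind(
    c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1),        # d = 1
    c(1, 1), c(-1, -1), c(2, -1), c(-2, 1), c(1, -2), c(-1, 2),      # sqrt(3)
    c(2, 0), c(-2, 0), c(0, 2), c(0, -2), c(2, -2), c(-2, 2))        # d = 2
  memb <- setNames(rep(NA_real_, length(members)), members)
  pos <- matrix(NA_real_, length(members), 2)
  rownames(pos) <- as.character(members)
  seed <- members[1]
  pos[1, ] <- c(0, 0)
  queue <- seed
  inset <- setNames(seq_along(members), as.character(members))
  visited <- setNames(logical(length(members)), as.character(members))
  visited[1] <- TRUE
  while (length(queue)) {
    s <- queue[1]; queue <- queue[-1]
    si <- (s - 1L) %% L; sj <- (s - 1L) %/% L
    p <- pos[inset[as.character(s)], ]
    for (k in seq_len(nrow(offs))) {
      ni <- (si + offs[k, 1]) %% L
      nj <- (sj + offs[k, 2]) %% L
      t <- ni + nj * L + 1L
      ix <- inset[as.character(t)]
      if (is.na(ix) || visited[ix]) next
      visited[ix] <- TRUE
      pos[ix, ] <- p + offs[k, ]
      queue <- c(queue, t)
    }
  }
  pos
}

point_in_hull <- function(pts, hull_xy, eps = 1e-9) {
  # hull_xy: CCW-ordered hull vertices; pts: matrix of xy
  nh <- nrow(hull_xy)
  inside <- rep(TRUE, nrow(pts))
  for (k in seq_len(nh)) {
    a <- hull_xy[k, ]; b <- hull_xy[if (k == nh) 1 else k + 1, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr >= -eps
  }
  inside
}

#' Raft structure of a fixed-N configuration
#'
#' Connected components ("rafts") of the graph joining all particles within
#' Euclidean distance 2 (shells 1, `sqrt(3)` and 2), with the empty-site
#' fraction inside each component's convex lattice hull as a porosity
#' measure.
#'
#' @param config a [lattice_config()].
#' @return list of class `raft_report`: `n_rafts`, integer vector `sizes`
#'   (decreasing), `porosity` (aligned with `sizes`), and
#'   `largest_fraction` (largest raft size over the particle number).
#' @export
raft_report <- function(config) {
  stopifnot(inherits(config, "lattice_config"))
  comp <- .lattice_components(config$S, config$L, 2L)
  occupied <- which(comp > 0)
  if (!length(occupied))
    return(structure(list(n_rafts = 0L, sizes = integer(0),
                          porosity = numeric(0), largest_fraction = 0),
                     class = "raft_report"))
  ids <- unique(comp[occupied])
  sizes <- vapply(ids, function(id) sum(comp == id), integer(1))
  ord <- order(sizes, decreasing = TRUE)
  ids <- ids[ord]; sizes <- sizes[ord]
  porosity <- vapply(ids, function(id) {
    members <- which(comp == id)
    if (length(members) < 3) return(0)
    ax <- unwrap_component(config, members)
    xy <- axial_to_xy(ax[, 1], ax[, 2])
    hull <- grDevices::chull(xy)
    if (length(hull) < 3) return(0)
    hull <- rev(hull)  # chull is clockwise; point_in_hull wants CCW
    # candidate lattice sites in the bounding box of the unwrapped component
    ir <- range(ax[, 1]); jr <- range(ax[, 2])
    cand <- expand.grid(i = seq(ir[1] - 1, ir[2] + 1),
                        j = seq(jr[1] - 1, jr[2] + 1))
    cxy <- axial_to_xy(cand$i, cand$j)
    inhull <- point_in_hull(cxy, xy[hull, , drop = FALSE])
    n_in <- sum(inhull)
    if (n_in <= 0) return(0)
    max(0, 1 - length(members) / n_in)
  }, numeric(1))
  structure(list(n_rafts = length(ids), sizes = sizes, porosity = porosity,
                 largest_fraction = sizes[1] / length(occupied)),
            class = "raft_report")
}

#' @export
print.raft_report <- function(x, ...) {
  cat("Rafts:", x$n_rafts, "| sizes:",
      paste(utils::head(x$sizes, 10), collapse = ", "),
      "| largest fraction:", round(x$largest_fraction, 3), "\n")
  invisible(x)
}

#' Largest-cluster fraction of a continuous configuration
#'
#' Particles are joined when within `cutoff` (default `1.35a`, between the
#' first and second coordination shells of the dense liquid); returns the
#' fraction of particles in the largest connected cluster.
#'
#' @param system an `md_system` or a list with `positions` and `box`.
#' @param cutoff contact distance.
#' @return numeric in `(0, 1]`.
#' @export
md_largest_cluster_fraction <- function(system, cutoff = 1.35) {
  comp <- .continuous_components(system$positions, system$box[1],
                                 system$box[2], cutoff)
  max(table(comp)) / length(comp)
}
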