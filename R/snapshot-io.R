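# Plain-text snapshot formats: lattice configurations and XYZ trajectories.

#' Write / read a lattice snapshot
#'
#' Plain-text format: header lines `L <int>` and `J <float>`, then one line
#' `i j s` per occupied site with 0-based axial coordinates and species
#' `s` in `{1, 2}`.  The round trip is bit-exact.
#'
#' @param config a [lattice_config()].
#' @param path file path.
#' @param J coupling ratio recorded in the header.
#' @return `write_lattice_snapshot()` returns `path` invisibly;
#'   `read_lattice_snapshot()` returns a list with the `config` and `J`.
#' @export
write_lattice_snapshot <- function(config, path, J = 3) {
  stopifnot(inherits(config, "lattice_config"))
  L <- config$L
  idx <- which(config$S != 0L) - 1L
  lines <- c(paste("L", L),
             paste("J", format(J, digits = 17)),
             sprintf("%d %d %d", idx %% L, idx %/% L,
                     ifelse(config$S[idx + 1L] == 1L, 1L, 2L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lattice_snapshot
#' @export
read_lattice_snapshot <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "L ") ||
      !startsWith(lines[2], "J "))
    stop("malformed lattice snapshot '", path,
         "': expected 'L <int>' and 'J <float>' header lines")
  L <- as.integer(sub("^L ", "", lines[1]))
  J <- as.numeric(sub("^J ", "", lines[2]))
  if (is.na(L) || is.na(J)) stop("malformed lattice snapshot header")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  i <- integer(0); j <- integer(0); sp <- integer(0)
  for (k in seq_along(body)) {
    f <- suppressWarnings(as.integer(strsplit(trimws(body[k]), "[[:space:]]+")[[1]]))
    if (length(f) != 3 || anyNA(f))
      stop("parse error in '", path, "' at line ", k + 2,
           ": expected 'i j s'")
    if (!f[3] %in% 1:2)
      stop("parse error in '", path, "' at line ", k + 2,
           ": species must be 1 or 2")
    i[k] <- f[1]; j[k] <- f[2]; sp[k] <- f[3]
  }
  idx <- (i %% L) + (j %% L) * L
  if (anyDuplicated(idx))
    stop("duplicate site in '", path, "': single occupancy is required")
  list(config = config_from_sites(L, i, j, sp), J = J)
}

#' Write / read an XYZ snapshot of the continuous system
#'
#' Standard XYZ: particle count, a comment line carrying `step`, the
#' dimensionless temperature and the potential energy, then one
#' `label x y z` line per particle with labels `A` (species 1) and `B`
#' (species 2).  Positions are written to 9 significant digits.
#'
#' @param system an `md_system` (see [md_system()]).
#' @param path file path.
#' @param step,T_bar,potential_energy values recorded in the comment line.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` returns a
#'   list with `positions`, `species` and the parsed `comment`.
#' @export
write_xyz <- function(system, path, step = 0, T_bar = NA,
                      potential_energy = NA) {
  pos <- system$positions
  lab <- ifelse(system$species == 1L, "A", "B")
  lines <- c(
    as.character(nrow(pos)),
    sprintf("step=%d T=%s PE=%s", as.integer(step),
            format(T_bar, digits = 9), format(potential_energy, digits = 9)),
    sprintf("%s %.9g %.9g %.9g", lab, pos[, 1], pos[, 2], pos[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  if (is.na(n) || length(lines) < n + 2)
    stop("malformed XYZ file '", path, "'")
  rows <- strsplit(trimws(lines[3:(n + 2)]), "[[:space:]]+")
  lab <- vapply(rows, `[`, character(1), 1)
  if (!all(lab %in% c("A", "B")))
    stop("unknown atom label in '", path, "': expected A or B, got '",
         setdiff(unique(lab), c("A", "B"))[1], "'")
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(pos)) stop("malformed coordinates in '", path, "'")
  list(positions = pos,
       species = ifelse(lab == "A", 1L, 2L),
       comment = lines[2])
}
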