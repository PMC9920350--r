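# small cluster motifs used across tests, in axial coordinates

rhombus_sites <- function(i0 = 0, j0 = 0) {
  cbind(i = i0 + c(0L, 1L, 0L, 1L), j = j0 + c(0L, 0L, 1L, 1L))
}

hexagon_sites <- function(i0 = 0, j0 = 0) {
  # centre + its six first-shell neighbours
  cbind(i = i0 + c(0L, 1L, -1L, 0L, 0L, 1L, -1L),
        j = j0 + c(0L, 0L, 0L, 1L, -1L, -1L, 1L))
}

motif_config <- function(L, sites, species = 1L) {
  config_from_sites(L, sites[, 1], sites[, 2], species)
}

# random sparse configuration for property tests
random_config <- function(L, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(L^2, n) - 1L
  config_from_sites(L, idx %% L, idx %/% L,
                    sample(1:2, n, replace = TRUE))
}

# rotate a configuration by 60 degrees about the origin (axial coords)
rotate_config <- function(config) {
  L <- config$L
  idx <- which(config$S != 0L) - 1L
  i <- idx %% L; j <- idx %/% L
  config_from_sites(L, -j, i + j, ifelse(config$S[idx + 1L] == 1L, 1L, 2L))
}
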