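test_that("neighbour shells have the triangular-lattice geometry", {
  lat <- triangular_lattice(10)
  sh <- neighbor_shells(lat, c(0, 0))
  expect_equal(nrow(sh$first), 6)
  expect_equal(nrow(sh$third), 6)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(sh$first),
                  key(cbind(c(1, 0, -1, -1, 0, 1) %% 10,
                            c(0, 1, 1, 0, -1, -1) %% 10)))
  # third shell holds (2,0) and (0,2) but not the sqrt(3) site (1,1)
  expect_true("2 0" %in% key(sh$third))
  expect_true("0 2" %in% key(sh$third))
  expect_false("1 1" %in% key(sh$third))
  # shells are disjoint and exclude the site itself
  expect_length(intersect(key(sh$first), key(sh$third)), 0)
  expect_false("0 0" %in% c(key(sh$first), key(sh$third)))
  expect_error(triangular_lattice(4), "minimum-image")
})

test_that("pair energies follow the coupling table", {
  J <- 2.7
  expect_equal(pair_energy(1, 1, "first", J), -1)
  expect_equal(pair_energy(2, 2, "first", J), -1)
  expect_equal(pair_energy(1, 2, "first", J), 1)
  expect_equal(pair_energy(1, 1, "third", J), J)
  expect_equal(pair_energy(1, 2, "third", J), -J)
  expect_equal(pair_energy(2, 1, "third", J), -J)
})

test_that("exact motif energies match the cluster energetics", {
  L <- 20
  # 4-particle rhombus: -5, J-independent
  expect_equal(total_energy_parts(motif_config(L, rhombus_sites())),
               c(e0 = -5L, e1 = 0L))
  # 7-particle filled hexagon: -12 + 3J
  expect_equal(total_energy_parts(motif_config(L, hexagon_sites())),
               c(e0 = -12L, e1 = 3L))
  # any pair beyond distance 2 does not interact
  far <- config_from_sites(L, c(0, 3), c(0, 0), c(1, 2))
  expect_equal(total_energy(far, 3), 0)
  # 28 particles as seven isolated rhombi -> -35
  offs <- expand.grid(i = c(0, 5, 10), j = c(0, 5, 10))[1:7, ]
  sites <- do.call(rbind, Map(function(i, j) rhombus_sites(i, j),
                              offs$i, offs$j))
  expect_equal(total_energy(motif_config(30, sites), 3), -35)
})

test_that("configurations at mutual distance >= 3 have zero energy", {
  set.seed(42)
  for (rep in 1:5) {
    # sparse sublattice placement guarantees separation >= 3
    pick <- sample(0:24, 6)
    cfg <- config_from_sites(30, (pick %% 5) * 5, (pick %/% 5) * 5,
                             sample(1:2, 6, replace = TRUE))
    expect_equal(total_energy(cfg, runif(1, 0.5, 5)), 0)
  }
})

test_that("grand-Hamiltonian density matches closed forms", {
  expect_equal(grand_hamiltonian_density(lattice_config(10), 3, 1, -2), 0)
  # fully occupied by species 1
  J <- 2.2; mu <- -1.3
  full <- lattice_config(10, rep(1L, 100))
  expect_equal(grand_hamiltonian_density(full, J, mu, 99),
               (-3 + 3 * J) - mu)
  # cc unit cell at J = 3, mu = 0
  cc <- generate_fixture("cc", 12)
  expect_equal(grand_hamiltonian_density(cc, 3, 0, 0), -10 / 3)
})

test_that("local fields sum the spin over the shells", {
  L <- 10
  expect_equal(local_field(lattice_config(L), c(3, 3)),
               c(Delta1 = 0L, Delta2 = 0L))
  one <- config_from_sites(L, 1, 0, 1)
  expect_equal(local_field(one, c(0, 0)), c(Delta1 = 1L, Delta2 = 0L))
  mixed <- config_from_sites(L, c(1, 0, 9, 9, 0, 2),
                             c(0, 1, 1, 0, 2, 0),
                             c(1, 1, 1, 2, 2, 1))
  # first shell of (0,0): three +1, one -1 (site (9,0)); (0,2),(2,0) are third
  expect_equal(local_field(mixed, c(0, 0)), c(Delta1 = 2L, Delta2 = 0L))
})

test_that("insertion energy change is exact and matches recomputation", {
  # one like neighbour at distance 1
  cfg <- config_from_sites(10, 0, 0, 1)
  expect_equal(insertion_energy_change(cfg, c(1, 0), 1, 3), -1)
  expect_equal(insertion_energy_change(cfg, c(1, 0), 2, 3), 1)
  # centre of a species-1 hexagonal ring, J = 3
  ring <- hexagon_sites()[-1, ]
  cfg <- motif_config(12, ring)
  expect_equal(insertion_energy_change(cfg, c(0, 0), 1, 3), -6)
  expect_error(insertion_energy_change(cfg, c(1, 0), 1, 3), "occupied")

  # property: equals from-scratch energy difference on random configurations
  set.seed(7)
  for (rep in 1:40) {
    J <- sample(c(1 / 3, 2, 3, 4.5), 1)
    cfg <- random_config(8, 20)
    empty <- which(cfg$S == 0L)
    site <- empty[sample.int(length(empty), 1)] - 1L
    sp <- sample(1:2, 1)
    de <- insertion_energy_change(cfg, c(site %% 8, site %/% 8), sp, J)
    cfg2 <- cfg
    cfg2$S[site + 1L] <- if (sp == 1) 1L else -1L
    expect_equal(de, total_energy(cfg2, J) - total_energy(cfg, J))
  }
})

test_that("energy is invariant under species swap and translation", {
  set.seed(11)
  for (rep in 1:10) {
    cfg <- random_config(9, 30)
    J <- runif(1, 0.5, 4)
    expect_identical(total_energy_parts(cfg),
                     total_energy_parts(species_swap(cfg)))
    expect_identical(total_energy_parts(cfg),
                     total_energy_parts(translate_config(cfg, sample(0:8, 1),
                                                         sample(0:8, 1))))
    # species swap exchanges the chemical-potential roles in h*
    mu1 <- runif(1, -5, 5); mu2 <- runif(1, -5, 5)
    expect_equal(grand_hamiltonian_density(cfg, J, mu1, mu2),
                 grand_hamiltonian_density(species_swap(cfg), J, mu2, mu1))
  }
})

test_that("configuration constructors enforce single occupancy", {
  expect_error(config_from_sites(10, c(0, 0), c(0, 0), c(1, 2)), "duplicate")
  expect_error(lattice_config(10, c(2L, rep(0L, 99))), "values")
})
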