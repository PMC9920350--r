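test_that("pair potentials evaluate the continuous model exactly", {
  # LJ terms cancel at r = 1, leaving the screened-electrostatic part
  expect_equal(pair_potential(1, 1, 1), 1.8 * exp(-0.5))
  # truncation: identically zero from the cutoff on
  expect_equal(pair_potential(c(6.75, 7, 20), 1, 1), c(0, 0, 0))
  expect_equal(pair_force(c(6.75, 7), 1, 2, q = 0.5), c(0, 0))
  # V22 = V11/q^2 at every distance
  r <- seq(0.8, 6.5, by = 0.3)
  expect_equal(pair_potential(r, 2, 2, q = 0.5),
               pair_potential(r, 1, 1, q = 0.5) * 4)
  # long-range attraction between unlike particles
  expect_lt(pair_potential(4, 1, 2, q = 1), 0)
  expect_error(pair_potential(-1, 1, 1), "positive")
})

test_that("wall potentials match the stated forms", {
  # attractive wall: minimum -epsilon at z = 2^(1/6)
  Lz <- 40
  expect_equal(wall_potential(2^(1 / 6), 1, "attract-both", Lz) -
                 2 / (Lz - 2^(1 / 6))^12, -1)
  zg <- seq(1, 1.3, by = 0.01)
  va <- wall_potential(zg, 1, "attract-both", Lz)
  expect_equal(zg[which.min(va)], 2^(1 / 6), tolerance = 0.01)
  # repulsive wall: 2 epsilon at unit distance
  expect_equal(wall_potential(1, 2, "repulsive", Lz) - 2 / (Lz - 1)^12, 2)
  # selective wall: species 2 sees only repulsion
  expect_gt(wall_potential(1.1, 2, "attract-species-1", Lz), 0)
  expect_lt(wall_potential(1.1, 1, "attract-species-1", Lz), 0)
  expect_error(wall_potential(-0.5, 1, "repulsive", Lz), "outside")
})

test_that("analytic forces agree with numerical derivatives to 1e-6", {
  set.seed(47)
  r <- runif(100, 0.7, 6.7)
  h <- 1e-5
  for (sp in list(c(1, 1), c(2, 2), c(1, 2))) {
    num <- (pair_potential(r + h, sp[1], sp[2], q = 0.5) -
            pair_potential(r - h, sp[1], sp[2], q = 0.5)) / (2 * h)
    ana <- -pair_force(r, sp[1], sp[2], q = 0.5)
    expect_lt(max(abs(num - ana) / pmax(abs(ana), 1e-8)), 1e-6)
  }
  z <- runif(100, 0.85, 3.5)
  num <- (wall_potential(z + h, 1, "attract-both", 40) -
          wall_potential(z - h, 1, "attract-both", 40)) / (2 * h)
  ana <- -wall_force(z, 1, "attract-both", 40)
  expect_lt(max(abs(num - ana) / pmax(abs(ana), 1e-8)), 1e-6)
})

test_that("NVE integration conserves energy and transverse momentum", {
  set.seed(3)
  sys <- md_system(50, 50, box = c(30, 30, 8), T_bar = 0.05)
  sys <- md_run(sys, 2000, T_target = 0.05, rescale_interval = 20,
                shifted = TRUE)
  nve <- md_run(sys, 10000, T_target = NA, shifted = TRUE,
                record_interval = 100)
  E <- nve$series$E_total
  # net drift is the integrator-quality measure; bounded symplectic
  # fluctuation around the mean is checked separately
  expect_lt(abs(E[length(E)] - E[1]) / abs(E[1]), 1e-4)
  expect_lt(max(abs(E - mean(E))) / abs(E[1]), 5e-4)
  expect_lt(max(abs(nve$series$Px), abs(nve$series$Py)), 1e-9)
})

test_that("velocity rescaling holds the kinetic temperature", {
  set.seed(3)
  sys <- md_system(50, 50, box = c(30, 30, 8), T_bar = 0.1)
  sys <- md_run(sys, 3000, T_target = 0.1, rescale_interval = 50)
  th <- md_run(sys, 1000, T_target = 0.1, rescale_interval = 50,
               record_interval = 10)
  expect_lt(abs(mean(th$series$T_kin) - 0.1) / 0.1, 0.01)
})

test_that("two distant resting particles only feel the walls", {
  pos <- rbind(c(5, 5, 2), c(20, 20, 2))
  sys <- md_system(1, 1, box = c(40, 40, 4), T_bar = 0,
                   positions = pos, velocities = matrix(0, 2, 3))
  out <- md_run(sys, 100, T_target = NA)
  expect_equal(out$positions[, 1:2], pos[, 1:2], tolerance = 1e-12)
})

test_that("energies are independent of the cell decomposition", {
  set.seed(53)
  sys <- md_system(40, 40, box = c(30, 30, 6), T_bar = 0.2)
  pe_ref <- md_potential_energy(sys)          # all-pairs reference
  run0 <- md_run(sys, 1, dt = 0, T_target = NA)  # cell-list evaluation
  expect_equal(run0$potential_energy, pe_ref, tolerance = 1e-10)
})

test_that("unstable configurations abort with a diagnostic", {
  pos <- rbind(c(5, 5, 2), c(5.3, 5, 2))
  sys <- md_system(1, 1, box = c(30, 30, 4), T_bar = 0,
                   positions = pos, velocities = matrix(0, 2, 3))
  expect_error(md_run(sys, 10, T_target = NA), "overlap")
  expect_error(md_system(1, 1, box = c(10, 10, 4), T_bar = 0.1) |>
                 md_run(10), "minimum image")
})

test_that("neutrality and desk budget are enforced for adsorption runs", {
  expect_error(run_adsorption_scaled(N2 = 301, q = 1 / 2), "integer")
  expect_error(run_adsorption_scaled(N2 = 2000, q = 1), "desk budget")
})

test_that("slit self-assembly aggregates at desk scale", {
  set.seed(11)
  sys <- md_system(50, 50, box = c(30, 30, 4), T_bar = 0.5)
  for (Ts in c(0.3, 0.25, 0.2, 0.16, 0.13))
    sys <- md_run(sys, 6000, T_target = Ts, rescale_interval = 50)
  sys <- md_run(sys, 70000, T_target = 0.12, rescale_interval = 50)
  expect_gte(md_largest_cluster_fraction(sys, 2.5), 0.5)
  # the aggregate stays inside the slab
  expect_true(all(sys$positions[, 3] > 0 & sys$positions[, 3] < 4))
})
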