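test_that("insertion/removal acceptance satisfies detailed balance", {
  for (J in c(1, 3)) for (T in c(0.2, 1, 5)) for (sp in 1:2)
    for (d1 in c(-6, -2, 0, 3, 6)) for (d2 in c(-6, 0, 4)) {
      mu1 <- -1.5; mu2 <- 2.25
      u <- (if (sp == 1) 1 else -1) * (d1 - J * d2)
      mu <- if (sp == 1) mu1 else mu2
      pi <- gcmc_acceptance(J, T, mu1, mu2, d1, d2, sp, "insertion")
      pr <- gcmc_acceptance(J, T, mu1, mu2, d1, d2, sp, "removal")
      # min(1,x)/min(1,1/x) = x for all x > 0
      expect_equal(pi / pr, exp((u + mu) / T), tolerance = 1e-12)
    }
})

test_that("acceptance matches the worked examples", {
  # isolated empty site, mu1 = 0: exp(0) capped at 1
  expect_equal(gcmc_acceptance(3, 1, 0, 0, 0, 0, 1, "insertion"), 1)
  # removal of an isolated particle at mu = -2, T* = 1: min(1, exp(2)) = 1
  expect_equal(gcmc_acceptance(3, 1, -2, 0, 0, 0, 1, "removal"), 1)
})

test_that("u_i is minus the insertion energy change", {
  # J = 3, fields (Delta1, Delta2) = (2, 1): u1 = 2 - 3 = -1, dE = +1
  cfg <- config_from_sites(12, c(1, 0, 2), c(0, 1, 0), c(1, 1, 1))
  f <- local_field(cfg, c(0, 0))
  expect_equal(unname(f), c(2, 1))
  de <- insertion_energy_change(cfg, c(0, 0), 1, 3)
  u1 <- f[["Delta1"]] - 3 * f[["Delta2"]]
  expect_equal(u1, -de)
})

test_that("species densities are symmetric at high temperature", {
  p <- gcmc_params(0, 0, J = 3, L = 24, T_schedule = c(5.0),
                   equil_steps = 200, prod_steps = 2000, seed = 42,
                   record_interval = 10, validate_interval = 1e4)
  r <- anneal_gcmc(p)
  prod <- r$series[r$series$step > 200, ]
  expect_lt(abs(mean(prod$N1) - mean(prod$N2)) / mean(prod$N1 + prod$N2), 0.05)
})

test_that("deep vacuum anneals to an essentially empty lattice", {
  p <- gcmc_params(-20, -20, J = 3, L = 24,
                   T_schedule = c(5, 1, 0.2),
                   equil_steps = 200, prod_steps = 500, seed = 1,
                   record_interval = 100, validate_interval = 1e4)
  r <- anneal_gcmc(p)
  expect_lt(sum(particle_counts(r$config)) / 24^2, 0.01)
})

test_that("incremental energy bookkeeping is validated against recomputation", {
  # validate_interval = 1e4 forces dozens of from-scratch integer checks;
  # the run aborts on any mismatch, so completing is the assertion
  p <- gcmc_params(-3.8, -3.8, J = 3, L = 20, T_schedule = c(5, 0.5),
                   equil_steps = 300, prod_steps = 300, seed = 3,
                   record_interval = 100, validate_interval = 1e4)
  r <- anneal_gcmc(p)
  expect_identical(unname(r$energy_parts),
                   unname(total_energy_parts(r$config)))
})

test_that("canonical moves conserve particle numbers exactly", {
  p <- canonical_params(10, 13, J = 3, L = 20, T_schedule = c(5, 1, 0.5),
                        equil_steps = 500, prod_steps = 500, seed = 5)
  r <- anneal_canonical(p)
  expect_identical(unname(particle_counts(r$config)), c(10L, 13L))
  expect_identical(unname(r$energy_parts),
                   unname(total_energy_parts(r$config)))
})

test_that("canonical annealing assembles a single porous raft", {
  p <- canonical_params(14, 14, J = 3, L = 30,
                        equil_steps = 5e3, prod_steps = 5e4, seed = 7)
  r <- anneal_canonical(p)
  rr <- raft_report(r$config)
  expect_equal(rr$n_rafts, 1)
  expect_gte(rr$largest_fraction, 0.9)
  expect_gt(rr$porosity[1], 0)
})

test_that("gcmc parameter validation rejects bad schedules", {
  expect_error(gcmc_params(0, 0, T_schedule = c(1, 2)), "decreasing")
  expect_error(canonical_params(300, 300, L = 20), "exceed")
})

test_that("annealed states classify as the ground-state phase across regions", {
  # reduced-scale scan over points well inside distinct regions
  pts <- list(v = c(-10, -10), c2 = c(-20, 0), ls = c(0, 0),
              cc = c(-3.8, -3.8), c12 = c(0, 10), b2 = c(-20, 10))
  hits <- 0
  for (nm in names(pts)) {
    p <- gcmc_params(pts[[nm]][1], pts[[nm]][2], J = 3, L = 36,
                     equil_steps = 5e3, prod_steps = 3e4, seed = 23,
                     record_interval = 1e4, snapshot_interval = 1e5)
    r <- anneal_gcmc(p)
    lab <- classify(r$config)$label
    ok <- lab %in% minimal_phase(3, pts[[nm]][1], pts[[nm]][2])
    hits <- hits + ok
  }
  expect_gte(hits, 5)
})
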