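test_that("order parameters of ideal fixtures match the cell geometry", {
  op <- order_parameters(generate_fixture("d1", 60))
  expect_equal(op$rho1, 1); expect_equal(op$rho2, 0)
  expect_equal(op$f_like_nn, 1); expect_equal(op$f_unlike_nn, 0)
  expect_equal(op$largest_mixed_fraction, 1)

  op <- order_parameters(generate_fixture("ls", 60))
  expect_equal(op$rho1, 1 / 2); expect_equal(op$rho2, 1 / 2)
  expect_gt(op$f_unlike_nn, 0)

  # cc: alternating rhombic clusters touch along the chains (6 unlike
  # contacts per 12-site cell); all like components are 4-clusters
  op <- order_parameters(generate_fixture("cc", 60))
  expect_equal(op$f_unlike_nn, 1 / 6)
  expect_equal(sort(unique(as.integer(names(op$cluster_sizes)))), 4L)

  # histogram of like-cluster sizes accounts for every particle
  cfg <- random_config(20, 60, seed = 31)
  op <- order_parameters(cfg)
  sizes <- as.integer(names(op$cluster_sizes))
  expect_equal(sum(sizes * as.integer(op$cluster_sizes)),
               sum(particle_counts(cfg)))
})

test_that("every catalog fixture classifies as itself with distance 0", {
  cat <- phase_catalog()
  for (p in names(cat)) {
    if (is.null(cat[[p]]$cell)) next
    L <- if (p %in% c("sa1", "sa2")) 63 else 60
    cl <- classify(generate_fixture(p, L))
    expect_equal(cl$label, p)
    expect_lt(cl$distance, 1e-12)
  }
})

test_that("classification is invariant under translation and rotation", {
  set.seed(37)
  for (p in c("cc", "ls", "c12", "b2", "zz")) {
    fx <- generate_fixture(p, 60)
    tr <- translate_config(fx, sample(0:59, 1), sample(0:59, 1))
    expect_equal(classify(tr)$label, p)
    expect_lt(classify(tr)$distance, 1e-12)
    expect_equal(classify(rotate_config(fx))$label, p)
  }
})

test_that("order parameters respect species swap composed with label swap", {
  cfg <- random_config(15, 80, seed = 41)
  a <- order_parameters(cfg)
  b <- order_parameters(species_swap(cfg))
  expect_equal(a$rho1, b$rho2)
  expect_equal(a$rho2, b$rho1)
  expect_equal(a$f_like_nn, b$f_like_nn)
  expect_equal(a$f_unlike_3rd, b$f_unlike_3rd)
  expect_equal(a$largest_mixed_fraction, b$largest_mixed_fraction)
})

test_that("configurations far from every phase report disordered/mixed", {
  # a hot random gas at half filling is no catalog phase
  cfg <- random_config(30, 450, seed = 43)
  expect_equal(classify(cfg)$label, "disordered/mixed")
})

test_that("raft_report counts distance-2 connected conglomerates", {
  expect_equal(raft_report(lattice_config(10))$n_rafts, 0)
  # two 4-clusters beyond interaction range
  sites <- rbind(rhombus_sites(0, 0), rhombus_sites(6, 0))
  rr <- raft_report(motif_config(15, sites))
  expect_equal(rr$n_rafts, 2)
  expect_equal(rr$sizes, c(4L, 4L))
  # the dimer-raft pattern joins into a single porous raft
  rr <- raft_report(generate_fixture("raft_dim", 12))
  expect_equal(rr$n_rafts, 1)
  expect_equal(rr$largest_fraction, 1)
  # unlike clusters at distance 2 (the cc chain motif) are one raft
  mixed <- config_from_sites(12, c(0, 1, 3, 4), c(0, 0, 0, 0),
                             c(1, 1, 2, 2))
  expect_equal(raft_report(mixed)$n_rafts, 1)
})

test_that("porosity measures empty sites inside the hull", {
  # a hexagonal ring (no centre) has exactly one interior vacancy
  ring <- hexagon_sites()[-1, ]
  rr <- raft_report(motif_config(12, ring))
  expect_equal(rr$n_rafts, 1)
  expect_equal(rr$porosity[1], 1 / 7)
  # a filled hexagon has none
  rr <- raft_report(motif_config(12, hexagon_sites()))
  expect_equal(rr$porosity[1], 0)
})
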