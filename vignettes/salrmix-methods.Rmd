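---
title: "Models and methods: pattern formation in two-component SALR monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pattern formation in two-component SALR monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salrmix)
```

## The physical problem

Charged inclusions in a near-critical membrane (or charged nanoparticles in
a near-critical solvent) experience two competing forces: a
solvent-fluctuation-induced (thermodynamic Casimir) attraction between
objects that prefer the same component, and a screened electrostatic
interaction.  For like-charged particles the net result is short-range
attraction with long-range repulsion (a SALR or "mermaid" potential), while
oppositely charged particles repel at short range and attract at long
range.  Instead of bulk demixing, such mixtures microphase-separate into
periodic patterns: clusters, stripes, bubbles, and mixed two-component
arrangements.  `salrmix` implements two complementary models of this
physics in two dimensions and the analysis needed to connect them.

## The lattice mixture

Particles of two species occupy cells of a triangular lattice (spin-1
encoding: `S = +1`, `-1`, `0` for species 1, species 2, empty).  In units
of the nearest-neighbour coupling `J1`, like pairs gain `-1` at distance
`1` and pay `+J` at distance `2`; unlike pairs do the opposite; the
intermediate `sqrt(3)` shell does not interact.  The single shape parameter
is `J = J2/J1`.  Everything in the ground-state engine is exact: energies
are tracked as integer pairs `(e0, e1)` with `E = e0 + e1*J`, and all
grand-potential algebra (phase energies, coexistence lines, triple points)
is done in integer/rational arithmetic, so equalities hold to machine
identity rather than to a tolerance.

At fixed chemical potentials the stable T = 0 pattern minimizes the
thermodynamic Hamiltonian density
`h* = (E - mu1*N1 - mu2*N2)/A`.  The catalog of candidate phases
(`phase_catalog()`) stores every phase as an explicit unit cell on a
sublattice in Hermite normal form; per-site grand potentials derived from
those cells reproduce the known closed forms, e.g.
`h*(cc) = -(1 + 3J + mu1 + mu2)/3` and
`h*(ls) = -(4 + 4J + 2(mu1 + mu2))/4`.

### How the non-printed cells were fixed

The one-component cells (`c`, `l`, `b`) and the two-component `cc`/`zz`
cells are not published as coordinates, so they were reconstructed by
exhaustive enumeration of periodic patterns (`enumerate_unit_cells()`):
every sublattice of the triangular lattice with up to 12 sites per cell and
every spin-1 occupancy of the cell.  The reconstruction is pinned by the
printed triple points, which over-determine the cell energies.  Notable
outcomes:

* `cc` is a chain pattern of alternating rhombic 4-clusters of the two
  species (the same 4-particle rhombi that build the `c1`/`c2`, `c12`/`c21`
  and bubble phases), with six unlike nearest-neighbour contacts per
  12-site cell.  Enumeration proves that no periodic pattern with the `cc`
  grand potential exists in which clusters of different species avoid
  first-shell contact: the degenerate partner `zz` (staircase zig-zag
  chains) is the only other geometry at those coefficients up to cell
  area 12.
* The dimer raft motif `raft_dim` (the pattern formed by fixed small
  particle numbers at `J = 3`) has an explicit 12-site cell and satisfies
  `h*(dim) = h*(cc)/2` identically.
* The triangle raft relation `h*(tri) = h*(cc)/3` admits **no** periodic
  realization: it forces density 1/9 per species with one like bond per two
  particles and three directed unlike third-neighbour contacts per
  particle, and exhaustive searches (all 18- and 27-site cells, all
  four-triangle 54-site cells, all three-block 81-site cells) find nothing.
  `raft_tri` is therefore carried as a derived catalog entry that
  implements the relation algebraically — the idealized limit in which
  triangle clusters would reach the same third-shell coordination as the
  chain phase — and `generate_fixture()` refuses it.  Tests of the raft
  relations validate the dimer relation geometrically and the triangle
  relation as the defining contract of the entry.

### A correction to the published ground state

The enumeration oracle is not only a consistency check; at `J = 3` it found
a pattern *below* the published catalog in a narrow off-diagonal band of
the chemical-potential plane: asymmetric diagonal stripes (7-site cell,
width-3 stripes of the majority species and width-2 stripes of the minority
species separated by single empty lanes), included as `sa1`/`sa2`.
Grand-canonical annealing confirms the phase independently: at
`(mu1, mu2) = (-1, -8.5)` the simulation converges to exactly
`h* = -3/7` with a 3:2 composition, far below the published catalog's
`-1/6`.  The band covers the published `c2-c12-cc` and `c2-cc-v` triple
points, which become crossings of metastable branches.  The published
chemical-potential scans never traverse this band, which explains how it
was missed.  `phase_catalog(extended = FALSE)` reproduces the published
diagram; the default includes the stripe phases.  The claim is established
against all unit cells of up to 12 sites and by simulation; still larger
cells are beyond the enumeration budget.

## Monte Carlo

Grand-canonical moves are single-site insertions and removals: a site is
picked uniformly; an empty site receives species 1 or 2 with probability
1/2 and acceptance `min(1, exp[(u_i + mu_i)/T*])`; an occupied site is
emptied with acceptance `min(1, exp[-(u_i + mu_i)/T*])`, with
`u_1 = -u_2 = Delta1 - J*Delta2` from the local fields.  The published
acceptance rule is quoted without the temperature factor; it is included
here (it is required for an annealing schedule to mean anything), and the
published `u1 = J1(Delta1 - 3*Delta2)` is read as the `J = 3` instance of
`Delta1 - J*Delta2`.  The pair (insertion, removal) satisfies detailed
balance exactly, which the tests verify on enumerated local states.  No
identity-exchange or cluster moves are used.

Annealing follows the protocol of the study: start from an empty lattice at
`T* = 5.0` and cool to `T* = 0.2`.  The intermediate temperatures are not
published; the default schedule `5.0, 2.0, 1.0, 0.5, 0.2` (roughly
geometric) is this package's choice.  One MC step is `L^2` attempted moves;
the package defaults are `1e5` equilibration and `1e6` production steps per
temperature on an `L = 60` lattice, and the test suite uses the reduced
`1e4`/`1e5` counts, which already reproduce every probed region of the
phase diagram.  Energies and local fields are maintained incrementally in
integer arithmetic and re-validated from scratch at a configurable
interval; any discrepancy aborts the run.

Canonical (fixed `N1`, `N2`) simulations use displacement moves of a random
particle to a random first-shell site with plain Metropolis acceptance on
the exact energy change.  Because raft coarsening proceeds through rare
detachment events, the canonical default schedule cools in nine stages
(`5.0 ... 0.2`).  Runs at `N1 = N2 = 14`, `J = 3` reproduce the single
"porous raft" with porosity well above zero.

## Pattern classification

The published phase assignments are visual; here they are operationalized
as a fingerprint of six intensive order parameters: the two species
densities and the like/unlike occupied-pair fractions of the first and
third shells (each a fraction of the `3 L^2` site pairs of the shell).  A
configuration is labelled by the nearest catalog fingerprint in Euclidean
distance, or `"disordered/mixed"` beyond a distance threshold of 0.15.
Every ideal fixture classifies as itself at distance zero, and the label is
invariant under translation, lattice rotation, and species swap composed
with label swap.  The closest catalog pair is `cc`/`zz` at distance 0.079 —
they are thermodynamically degenerate, so either label is accepted wherever
the pair is the prediction.  The next-closest pairs involve the asymmetric
stripe phases (`cc`-`sa1` at 0.176); all pairs not involving `sa1`/`sa2` or
the degenerate pair are at least 0.25 apart, a margin above 1.6x the
threshold for thermally roughened snapshots.  Raft structure is quantified on the graph joining
particles within distance 2 (the interaction range): connected components,
their sizes, and a porosity measure (empty-site fraction inside the convex
lattice hull of each component).

## The continuous model

The continuous-space binary mixture interacts through truncated
Lennard-Jones plus screened-electrostatic pair potentials,
`V11 = 6[r^-12 - r^-6 + 0.3 e^{-r/2}/r]`, `V22 = V11/q^2` and
`V12 = 6[r^-12 + r^-6 - 0.3 e^{-r/2}/r]/q`, cut off at `r = 6.75` particle
diameters.  The charge-asymmetry ratio `q` scales the second species'
self-interaction by `1/q^2` and the cross-interaction by `1/q`; the printed
grouping of the `q` factors is ambiguous and is resolved this way, which
also matches the remark that the second component crystallizes at a
`q^2`-lower temperature.  The potential is truncated without shift, as
published; because the resulting cutoff discontinuity (about `9e-3`
epsilon per crossing pair) is incompatible with strict energy conservation,
the energy-conservation oracle runs with the optional shifted variant
(`shifted = TRUE`), where velocity-Verlet integration at `dt = 0.004`
conserves energy to better than `1e-4` relative over `1e4` steps.

Particles live in a box periodic in x and y with confining walls:
repulsive `2/(z - zw)^12` walls for slit geometry (`Lz = 4`), or an
attractive `4[z^-12 - z^-6]` wall at `z = 0` (for one or both species) for
adsorption.  Temperature is imposed by velocity scaling every 50 steps
(uniform, or in three z-zones at temperatures 0.04/0.13/0.17 during the
initial stage of adsorption runs, with the zone heights scaled to the desk
box).  Timestep, particle mass (= 1) and rescale interval are not
published; the defaults here are stable for the `r^-12` core at the studied
temperatures.

Full-size slit runs (`N1 = N2 = 200`, `Lx = Ly = 150`) are available
through `run_slit()`, and a scaled-down adsorption mode
(`run_adsorption_scaled()`, at most 2000 particles) preserves the geometry
near the wall; the published 24,000- and 32,001-particle adsorption runs
are out of scope.  The automated tests exercise a smoke-scale slit
(`N1 = N2 = 50` in a `30 x 30 x 4` box, `1e5` steps, annealed to
`T = 0.12`): the mixture must aggregate into a conglomerate holding at
least half the particles.  The aggregation criterion joins particles within
`2.5` diameters because raft substructures of this model are like-species
stripes or clusters separated by gaps near the unlike-pair potential
minimum (`r = 1.94`); a tight contact cutoff (`1.35`, between the first and
second coordination shells) is used where single-cluster contact is meant.
The denser smoke box relative to the full slit (areal density 0.11 versus
0.018) compresses the aggregation kinetics into the desk-scale step budget;
it tests aggregation, not the full raft morphology of the production
geometry.

## What the synthetic fixtures do and do not show

Ideal fixtures are perfect periodic tilings; annealed configurations carry
thermal defects (domain walls, disclinations in lamellae, vapour), which is
why classification is threshold-based rather than exact.  Passing the
fixture and annealing tests shows that the implementation realizes the
model's own predictions; it says nothing about how faithfully the lattice
model represents any particular experimental membrane system.  Defect-free
lamellae, interfacial line tensions, finite-temperature phase boundaries
and finite-size scaling are out of scope.

## Numerical choices

* Ground-state algebra: exact integers/rationals; degeneracy tolerance
  `1e-9` only where floating-point `J` or `mu` enter.
* Monte Carlo acceptance factors are tabulated over the 169 possible local
  field pairs per temperature; the RNG is a xoshiro256++ stream seeded from
  R's RNG, so `set.seed()` (or the `seed` parameter) fully determines a
  run.
* Problem sizes used by the test suite: GCMC at `L = 60` with `1e4`/`1e5`
  steps per temperature (three seeds per region); canonical runs with 28
  particles at `L = 60` (unit tests use `L = 30`); MD with 100 particles
  for `1e4`-step conservation checks and `1e5`-step aggregation runs;
  enumeration to 12-site cells on a step-1 chemical-potential grid over
  `[-21, 21]^2`.
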