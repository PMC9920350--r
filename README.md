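# salrmix

Pattern formation in two-component monolayers of particles with competing
interactions.

Mixtures of oppositely charged particles in a near-critical solvent — for
instance charged protein inclusions in a biological membrane, or charged
nanoparticles adsorbed at an interface — interact through a
fluctuation-induced attraction plus screened electrostatics.  Like
particles then attract at short range and repel at long range (a SALR
potential) while unlike particles do the reverse, and instead of demixing
the monolayer self-assembles into periodic patterns.  `salrmix` is for
researchers studying this kind of microphase separation.  It implements:

* **an exactly solvable triangular-lattice mixture** — spin-1 occupancy
  field, couplings `-J1` / `+J2` (like pairs) and `+J1` / `-J2` (unlike
  pairs) on the first and third neighbour shells — with an explicit catalog
  of candidate ground-state phases, exact per-site grand potentials
  `h* = (E - mu1 N1 - mu2 N2)/A`, coexistence lines and triple points in
  the `(mu1*, mu2*)` plane, and a brute-force unit-cell enumeration oracle
  (every periodic pattern with up to 12 sites per cell);
* **grand-canonical and canonical Metropolis Monte Carlo** with simulated
  annealing (`T* = 5.0` down to `0.2`), acceptance
  `min(1, exp[±(u_i + mu_i*)/T*])` with `u_1 = -u_2 = Delta1 - J Delta2`;
* **continuous-space molecular dynamics** of the same physics: truncated
  `6[r^-12 - r^-6 + 0.3 e^{-r/2}/r]`-type pair potentials with charge
  asymmetry `q`, slit confinement or an adsorbing wall, velocity-Verlet
  integration with velocity-scaling temperature control;
* **pattern classification** of simulated configurations into the
  predicted phases via intensive order-parameter fingerprints, plus raft
  (conglomerate) structure analysis.

Along the way the enumeration oracle uncovered an asymmetric
diagonal-stripe phase (`sa1`/`sa2`, 7-site cell) that is missing from the
published ground-state diagram in a narrow off-diagonal band and is
confirmed independently by the package's own grand-canonical annealing; see
the methods vignette (`vignettes/salrmix-methods.Rmd`).

## Worked example

Exact ground-state structure at `J = 3`:

```r
library(salrmix)

phase_h("cc", 3, 0, 0)            # per-site grand potential of the cc phase
#> [1] -3.333333

coexistence_line("cc", "ls")
#> cc-ls coexistence: mu1* + mu2* = -4

subset(triple_points(3), phases %in% c("c2-cc-v", "c12-cc-ls"))
#>      phases   mu1   mu2 mu1_formula mu2_formula
#> 5   c2-cc-v -8.75 -1.25   1/4 - 3 J        -5/4
#> 6 c12-cc-ls -3.00 -1.00          -3          -1

minimal_phase(3, -3.8, -3.8)      # degenerate pair on the diagonal
#> [1] "cc" "zz"
```

The `cc` phase sits at `h* = -10/3` per site at the origin of the
chemical-potential plane; the `cc`-`ls` boundary is the J-independent line
`mu1* + mu2* = -4`; and the triple points come out as exact rational
functions of `J`.

Annealing an open system at `(mu1*, mu2*) = (-20, 0)` and classifying the
final low-temperature configuration:

```r
p <- gcmc_params(-20, 0, J = 3, L = 60, equil_steps = 1e4,
                 prod_steps = 1e5, seed = 1)
r <- anneal_gcmc(p)
classify(r$config)
#> Classified as: c2 (distance 0.035, confidence 0.77)
```

i.e. the simulation recovers the hexagonal crystal of species-2 rhombic
4-clusters predicted by the ground state in that region.  A fixed-N run
assembles the "porous raft":

```r
r <- anneal_canonical(canonical_params(14, 14, J = 3, L = 60, seed = 1))
raft_report(r$config)
#> Rafts: 1 | sizes: 28 | largest fraction: 1
```

A command-line interface wrapping these workflows is installed at
`inst/cli/salrmix` (subcommands `gs-diagram`, `gcmc`, `canonical`,
`md-slit`, `md-adsorb`, `classify`, `fixture`).

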