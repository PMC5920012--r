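# cntmd — coarse-grained molecular dynamics of protein–carbon-nanotube adsorption

Carbon nanotubes (CNTs) adsorb proteins, and simulating that process at
atomistic resolution is prohibitively slow for the microsecond timescales
involved. `cntmd` is an R package implementing the coarse-grained route:
the protein is reduced to two interaction sites per residue (a Cα trace
with attached side-chain spheres, plus derived peptide-group sites at the
virtual-bond midpoints) and the nanotube is an immovable infinite cylinder
of radius R₀ along z. A protein site at in-plane distance r from the tube
axis feels a surface-shifted Kihara (cylindrical Lennard-Jones) potential

    U_CNT(r) = 4ε [ (σ/(r−R₀))¹² − (σ/(r−R₀))⁶ ],

zero at r = R₀ + σ and minimal (−ε) at r = R₀ + 2^{1/6}σ, and the total
energy is

    U = U_protein + w_CNT · U_CNT + w_restraint · U_restraint,

with w_CNT = 1 by default, U_protein a documented surrogate coarse-grained
protein force field with analytic gradients, and U_restraint optional
flat-bottom Lorentzian restraints on Cα pairs (A = 24/x₀², σᵣ = (0.04 x₀)²,
weight 0.006).

On top of the energy model the package provides, for anyone studying
protein adsorption on nanomaterials with coarse-grained models:

* energy minimization (L-BFGS-B over the analytic gradients);
* NVE velocity-Verlet dynamics plus Berendsen (τ = 48.9 fs), Langevin
  (BAOAB, 0.01 × Stokes water friction) and Nosé–Hoover (Q = 5
  kcal·MTU²/mol) thermostats, with kinetic-temperature diagnostics;
* multiplexed replica-exchange MD on a configurable temperature ladder
  (the production ladder: 36 temperatures, 250–500 K, two replicas per
  temperature = 72 trajectories);
* binless WHAM reweighting with heat-capacity profiles
  Cv(T) = (⟨U²⟩ − ⟨U⟩²)/(R T²);
* ensemble analyses: per-residue tube-contact probabilities and contact
  fractions (8 Å from the tube *surface*), binding energies, Kabsch
  RMSD/RMSF, and Ward clustering with the ten-cluster reference-cutoff
  protocol;
* deterministic synthetic mini-protein fixtures, a YAML run configuration,
  PDB/XYZ trajectory output and a plain-text snapshot archive, so the whole
  pipeline runs and is tested without any external downloads.

The integrator and force kernels are compiled (Rcpp); million-step runs of
the 20-residue fixture take tens of seconds on one core.

## Worked example

```r
library(cntmd)

# A 20-residue mini-protein next to a tube of radius 6 A in a 220 A box
fx <- make_fixture("trpcage_like", placement = 10, radius = 6)
sys <- cg_system(fx$chain, fx$cylinder, fx$box)
min_res <- minimize_chain(sys)
min_res$energy
#> u_total = -29.669801 kcal/mol (protein -19.718954, tube -9.950848, restraint 0.000000)

# Short microcanonical run from the minimized structure
run <- run_md(min_res$system, steps = 20000, dt = 0.489, ensemble = "nve",
              T_set = 300, seed = 1, sample_every = 100)
run
#> md_run: nve, 20000 steps @ 0.489 fs (201 samples)
#>   <T> = 114.97 K, E_tot -3.4373 -> -3.4370 kcal/mol

# A toy replica-exchange run and its contact analysis at 300 K
lad <- temperature_ladder(c(300, 320, 340, 360), replicas_per_temperature = 2)
remd <- run_mremd(min_res$system, lad, n_cycles = 20, steps_per_cycle = 200,
                  dt = 4.89, seed = 7)
eq <- equilibrated_subset(remd$archive, discard = 0.5)
fit <- solve_wham(eq)
contact_profile(eq, weights = wham_weights(fit, 300))
#> contact_profile: 20 residues over 88 snapshots, average contact fraction 0.5476 (cutoff 8 A)
binding_energy(eq, weights = wham_weights(fit, 300))$binding_energy
#> [1] 3.175424
```

Reading the numbers: minimization relaxes the synthetic chain onto the
tube (the tube term drops to −9.95 kcal/mol — the chain adsorbs); the NVE
total energy is constant to ~3 × 10⁻⁴ kcal/mol over the 10 ps shown; and in
the WHAM-reweighted 300 K ensemble about 55% of residues sit within 8 Å of
the tube surface, with a mean binding energy of 3.18 kcal/mol (reported as
a positive magnitude for the attractive interaction).

A thin command-line front end wrapping the same functions lives at
`inst/cli/cntmd.R`:

```sh
Rscript inst/cli/cntmd.R fixture --kind helix --n 10 --seed 1 --out fxt
Rscript inst/cli/cntmd.R md --config fxt.yaml --ensemble nve --out run1
Rscript inst/cli/cntmd.R dump-config --out defaults.yaml
```

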