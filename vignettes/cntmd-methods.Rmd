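---
title: "Coarse-grained protein-nanotube simulations with cntmd: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained protein-nanotube simulations with cntmd: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntmd)
```

# The model

`cntmd` simulates a coarse-grained protein next to a carbon nanotube (CNT).
The protein is reduced to two interaction sites per residue: the C&alpha;
trace carries the backbone, a single sphere per residue represents the side
chain, and peptide-group sites are *derived* interaction points located
exactly half-way between consecutive C&alpha; pairs (they carry no mass and
no independent degrees of freedom). Glycine has no separate side-chain
sphere; its interaction center is the C&alpha; itself.

The nanotube is an immovable infinite cylinder of radius $R_0$ whose axis
runs along $z$ through the lateral center of a rectangular periodic box. A
protein site at in-plane distance $r$ from the axis interacts with the tube
surface through a surface-shifted Kihara (cylindrical Lennard-Jones)
potential

$$U_\mathrm{CNT}(r) = 4\varepsilon\left[\left(\frac{\sigma}{r-R_0}\right)^{12}
 - \left(\frac{\sigma}{r-R_0}\right)^{6}\right],$$

which is zero at $r = R_0 + \sigma$ and reaches $-\varepsilon$ at
$r = R_0 + 2^{1/6}\sigma$. The total energy is

$$U = U_\mathrm{protein} + w_\mathrm{CNT}\,U_\mathrm{CNT}
 + w_\mathrm{restraint}\,U_\mathrm{restraint},$$

with $w_\mathrm{CNT} = 1$ by default. The tube term sums the Kihara
potential over every side-chain sphere and every peptide-group midpoint,
each with its own $(\varepsilon, \sigma)$; forces on the massless peptide
sites are distributed half-and-half onto the flanking C&alpha; sites by the
chain rule.

Because the cylinder is infinite along $z$ and unique in the box (it is
deliberately *not* replicated in the lateral periodic images — a replicated
tube would silently change the physics), the site-axis distance uses the
minimum image in $x$ and $y$ only, while site-site terms use the minimum
image in all three dimensions.

## Tube interaction parameters

The carbon surface is treated as uniformly phenylalanine-like: one
$(\varepsilon, \sigma)$ pair for all side-chain types
($\varepsilon = 0.5$ kcal/mol, $\sigma = 4.0$ &#8491;) and one for the
peptide group ($0.3$ kcal/mol, $3.5$ &#8491;), shipped as an explicit,
fully overridable table (`default_kihara_table()`). Shipping one documented
default rather than pretending to know residue-resolved surface parameters
keeps the provenance of every number explicit; any study that has better
parameters overrides the table in the config.

## The surrogate intra-protein force field

The full physics-based residue-level potential of mean force that a
production coarse-grained force field provides (multibody terms,
temperature-dependent free-energy contributions, anisotropic side chains)
is out of scope here; `cntmd` ships a deliberately simple surrogate with
the same topology of terms:

* harmonic virtual bonds, $k_b (b - b_0)^2$ with $b_0 = 3.8$ &#8491; and
  $k_b = 50$ kcal/mol/&#8491;&sup2;;
* harmonic virtual-bond angles, $k_\theta(\theta - \theta_0)^2$ with
  $\theta_0 = 1.58$ rad (a helix-like angle) and $k_\theta = 10$;
* a cosine dihedral $k_\gamma\,[1 + \cos(n\gamma - \delta)]$ with
  $k_\gamma = 0.5$, $n = 1$, $\delta = -2.27$ rad (minimum near the helical
  virtual dihedral);
* harmonic side-chain attachment at the tabulated C&alpha;-SC distance
  (2.0 &#8491; for all non-glycine types — the source force field's
  side-chain geometry is not published, so one documented default is used);
* a truncated-and-shifted 12-6 Lennard-Jones term between all site pairs at
  least three residues apart ($\varepsilon = 0.2$ kcal/mol,
  $\sigma = 4$ &#8491;, cutoff $2.5\sigma$, shifted so the potential is
  continuous at the cutoff);
* optionally, native-contact (G&#333;) wells
  $\varepsilon_{ij}[(r_{ij}^0/r)^{12} - 2 (r_{ij}^0/r)^6]$ derived from a
  reference structure (`derive_go_contacts()`).

The force constants were chosen once so that the stiffest mode (the
virtual bond, period $\approx 150$ fs) is integrated comfortably at the
0.489 fs step, and are not tuned thereafter. All gradients are analytic and
are verified against central finite differences in the test suite at
relative tolerance $10^{-6}$.

## Flat-bottom Lorentzian restraints

Structure-based restraints on C&alpha; pairs use a flat-bottom
Lorentzian-like penalty: zero for $|x - x_0| < 0.1$ &#8491;, and otherwise
$A d^4 / (d^4 + \sigma_r)$ with $d$ the distance to the nearer flat-region
edge, $A = 24/x_0^2$, $\sigma_r = (0.04 x_0)^2$, entering the total with
weight $w_\mathrm{restraint} = 0.006$. The flat bottom is symmetric about
$x_0$ (the two outer branches force that reading), and the 0.1 half-width
is read in &#8491;, the unit of every other distance in the model. The penalty saturates at $A$ for large violations, so a single
broken contact cannot dominate the energy.

# Dynamics

Fixed-step velocity Verlet is the core integrator; the variable-time-step
scheme some production codes use is deliberately replaced by a fixed step,
which preserves every testable property (conservation, thermostat
statistics) with much simpler correctness arguments. Internally time is
handled in fs (1 MTU = 48.9 fs).

Thermostats:

* **Berendsen** — weak-coupling velocity rescale,
  $\lambda = \sqrt{1 + (dt/\tau)(T_\mathrm{set}/T - 1)}$, default
  $\tau = 48.9$ fs. Holds the mean temperature tightly but suppresses the
  canonical kinetic-temperature fluctuations; `temperature_distribution()`
  quantifies this as an empirical/canonical variance ratio well below 1.
* **Langevin** — BAOAB splitting with per-site Stokes friction
  $\gamma_i = 6\pi\eta r_i / m_i$ (water viscosity, site radius from a
  volumetric rule $r_i = 0.8\, m_i^{1/3}$ &#8491;), scaled by the
  conventional 0.01 water-friction factor.
* **Nos&eacute;-Hoover** — single chain with inertia $Q$
  (default 5 kcal MTU&sup2;/mol); the conserved extended Hamiltonian
  $E + Q\xi^2/2 + N_f k_B T \int \xi\,dt$ is tracked and reported.

Degrees of freedom: $N_f = 3N - 3$ for NVE, Berendsen and Nos&eacute;-Hoover
(center-of-mass momentum is removed at initialization and preserved);
$N_f = 3N$ for Langevin, whose noise breaks momentum conservation.
Velocities are initialized from the Maxwell-Boltzmann distribution at the
set temperature using the seeded generator; every stochastic run takes a
seed.

## Statistical design of the thermostat checks

The 0.5% bound on the Langevin mean temperature is a *statistics-limited*
check: with the 0.01 friction factor the kinetic energy decorrelates on a
$\sim 1/(2\gamma)$ timescale (measured integrated autocorrelation time of
the instantaneous temperature: about 700 fs on the 20-residue fixture), and
the canonical fluctuation of a single temperature sample is
$\sqrt{2/N_f}\,T \approx 13\%$. The accuracy runs therefore use
$1.2\times10^7$ steps of 2.445 fs per set point ($\approx 29$ ns),
averaging over the equilibrated half; the expected standard error of the
mean is then about 0.13% of the set point. The step is half the production
time step: on-step velocities of a velocity-Verlet-based scheme carry a
$-(\omega\,dt)^2/12$ kinetic-energy discretization bias per stiff mode,
which at the full 4.89 fs step amounts to a measurable $\sim 0.15\%$
underestimate from the bond and side-chain attachment modes and at
2.445 fs drops below 0.05%. The microcanonical check runs $2\times10^5$ steps
at 0.489 fs; Berendsen and Nos&eacute;-Hoover checks run $10^6$ steps at
0.489 fs. These problem sizes are the package's own statistical choices and
are stated here so they can be reproduced exactly.

# Replica exchange

`run_mremd()` implements multiplexed temperature replica exchange:
several replicas per temperature, Langevin segments between exchange
sweeps, and Metropolis acceptance
$\min\{1, \exp[(\beta_i - \beta_j)(U_i - U_j)]\}$ for adjacent-temperature
pairs. Sweeps alternate even/odd neighbor pairings (the standard scheme,
maximizing exchange throughput), and within a multiplexed temperature slot the partner is
drawn uniformly at random. Accepted swaps exchange temperature indices and
rescale velocities by $\sqrt{T_\mathrm{new}/T_\mathrm{old}}$, preserving
kinetic-energy continuity. Each replica owns an RNG stream derived from the
master seed and independent of the exchange stream, so disabling exchanges
reproduces independent trajectories bit for bit — a property the test suite
asserts.

The production temperature ladder (`mremd_ladder()`) spans 250-500 K in 36
temperatures (5 K spacing to 370 K, 10 K to 460 K, 20 K above), two
replicas per temperature, 72 trajectories. The exchange-attempt period and the equilibration discard fraction
(default 0.5) are configurable.

# WHAM and heat capacity

`solve_wham()` implements *binless* WHAM in the per-sample log-sum-exp
form: the dimensionless free-energy shifts $f_k$ of the simulated
temperatures are iterated to self-consistency entirely in log space
(overflow-safe), with $f_1 \equiv 0$ fixing the gauge. Binless WHAM avoids
histogram bin-width choices that the source protocol never states.
Non-overlapping adjacent energy distributions are detected and reported as
a bridging failure with the gap location rather than silently
mis-converging.

The implemented potential is temperature-independent, so the general
fluctuation expression for the heat capacity reduces exactly to

$$C_v(T) = \frac{\langle U^2\rangle_T - \langle U\rangle_T^2}{R\,T^2},$$

computed from WHAM-reweighted averages on a grid (default 1 K spacing
across the simulated range). This reduction is asserted in the tests by
computing both forms. The peak is the global grid maximum; local maxima
above 5% prominence are also reported since multimodal profiles are
physically meaningful. The validation suite checks the machinery against
closed forms (equipartition for harmonic samples; the exact two-level
partition function), *not* against any experimental transition
temperature: absolute peak temperatures of real proteins depend on a
calibrated production force field and are outside what the surrogate can
or should reproduce.

# Ensemble analyses

* **Contacts** — a residue is in contact when its C&alpha; lies within 8
  &#8491; of the tube *surface* ($r - R_0 < 8$), not the axis. The
  per-residue probability $p(i)$ is the fraction of snapshots with residue
  $i$ in contact, and the average contact fraction is the snapshot mean of
  (contacts/residues) — the reading under which both quantities are
  probabilities.
* **Binding energy** — ensemble mean of $w_\mathrm{CNT} U_\mathrm{CNT}$,
  reported as a magnitude (the conventional positive number for an
  attractive interaction) with the signed mean alongside.
* **RMSD/RMSF** — Kabsch superposition via SVD with the proper-rotation
  correction; RMSF superposes each snapshot onto the reference first (an
  `align = FALSE` escape hatch serves pre-aligned archives).
* **Clustering** — Ward minimum-variance linkage (`ward.D2`) on the
  pairwise C&alpha; RMSD matrix. The reference protocol clusters a
  tube-free ensemble into exactly ten clusters, records the tree-cut
  height, and reuses that height for every tube ensemble; both modes
  (`fixed_k`, `fixed_cutoff`) are provided and the recorded cutoff is
  chosen mid-interval so the two modes reproduce each other exactly.
  The dominant cluster is the most populated one; ties break toward lower
  mean RMSD to the reference. When WHAM weights are supplied, analyses are
  ensemble-weighted; otherwise they are plain averages over the
  equilibrated subset.

# The synthetic fixtures

`make_fixture()` builds deterministic mini-protein systems so that every
stage of the pipeline runs without downloaded structures:

* `helix` — an ideal C&alpha; helix (rise 1.5 &#8491;, 100&deg; per
  residue, radius chosen so consecutive distances are exactly 3.8 &#8491;);
* `extended` — a planar zigzag with constant virtual-bond angle;
* `trpcage_like` — a fixed 20-residue mini-protein with the Trp-cage
  sequence: residues 1-9 an ideal helix, residues 10-20 a near-extended
  tail grown from fixed internal coordinates.

The chain is laid out radially: the first residue's C&alpha; sits exactly
at the requested distance from the tube axis (default 10 &#8491; with
$R_0 = 6$ &#8491;, i.e. 4 &#8491; from the surface — mildly repulsive to
slightly attractive initially) and the rest of the chain extends away from
the tube, in a 220 &#8491; periodic box. All geometry is deterministic; the
seed only controls optional coordinate jitter (off by default).

What the fixtures emulate is the *protocol*: a small protein placed near a
tube, minimized, and propagated. What they do not emulate is real protein
energetics — there is no solvent, no electrostatics, no sequence-specific
side-chain packing, and the surrogate force field is far smoother than a
real free-energy surface. Passing tests therefore validate the mechanics
(energies, gradients, integrators, exchange bookkeeping, estimators) and
say nothing quantitative about adsorption of real proteins.

# Numerical choices and degenerate inputs

* Site coordinates are double precision &#8491; throughout; archives store
  full precision (`%.17g`), PDB output rounds to the format's 3 decimals.
* $r \le R_0$ (a site at or inside the tube surface) is a hard error in
  energy evaluation and aborts dynamics with the offending site and step;
  the divergent region is not extrapolated. The minimizer alone sees a
  linear continuation of the Kihara term below $0.35\sigma$ from the
  surface so that L-BFGS-B line searches remain finite while backtracking
  out; the returned configuration is re-checked against the true
  potential.
* Collinear C&alpha; triples make the dihedral undefined: flagged `NA` in
  internal coordinates, and the corresponding force term is skipped (the
  configuration has measure zero in dynamics).
* $\theta$ gradients are guarded by a $\sin\theta$ floor of $10^{-8}$.
* The nonbonded term is truncated *and shifted* at $2.5\sigma$, so the
  integrated potential is continuous; the residual force discontinuity at
  the cutoff is far below the thermal force scale and does not measurably
  affect the $2\times10^5$-step conservation check.
* A Verlet neighbor list (2 &#8491; skin, refreshed every 20 steps) serves
  the nonbonded loop; the skin comfortably bounds per-interval
  displacements at the largest supported step.
* Langevin noise comes from an internal xoshiro256++/Box-Muller generator
  seeded from R's RNG, so `set.seed()` fully determines trajectories while
  keeping million-step runs fast.
* Ties in the Ward tree cut: the recorded `fixed_k` cutoff is the midpoint
  of the height interval that yields exactly $k$ clusters.

# Known limitations

* The surrogate force field is not a calibrated protein model; folding
  thermodynamics, absolute heat-capacity peak temperatures and real
  contact maps are out of reach by design.
* Side chains are isotropic spheres; anisotropic (ellipsoidal) side-chain
  potentials, charged-residue electrostatics and functionalized tubes are
  not modeled.
* One chain, one tube, fixed box; no pressure coupling, constraints or
  multiple-time-step schemes.
* Exchange acceptance in `run_mremd()` assumes adjacent-temperature
  attempts only (non-adjacent attempts are rejected by construction of the
  sweep, not supported as input).
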