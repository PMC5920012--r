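# Time integration: NVE velocity Verlet plus Berendsen, Langevin (BAOAB) and
# single-chain Nose-Hoover thermostats, with kinetic-temperature diagnostics.

.THERMOSTATS <- c(nve = 0L, berendsen = 1L, langevin = 2L, nose_hoover = 3L)

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws site velocities from the Maxwell-Boltzmann distribution at `T` using
#' the current RNG state, optionally removing the center-of-mass momentum.
#'
#' @param mass per-site masses (amu).
#' @param T temperature (K).
#' @param remove_com remove the mass-weighted mean velocity.
#' @return n x 3 velocity matrix (A/fs).
#' @export
init_velocities <- function(mass, T, remove_com = TRUE) {
  n <- length(mass)
  sd <- sqrt(cnt_constants$R_KCAL * T * cnt_constants$ACC_CONV / mass)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  if (remove_com) {
    vcom <- colSums(v * mass) / sum(mass)
    v <- sweep(v, 2, vcom, `-`)
  }
  v
}

#' Kinetic temperature
#'
#' `T = 2 E_kin / (N_f R)` with `N_f = 3 n - n_removed_dof` degrees of
#' freedom. By convention the three center-of-mass translational degrees of
#' freedom are removed for NVE, Berendsen and Nose-Hoover runs (momentum is
#' conserved or preserved by rescaling) but not for Langevin runs, whose
#' noise breaks momentum conservation.
#'
#' @param velocities n x 3 matrix (A/fs).
#' @param mass per-site masses (amu).
#' @param n_removed_dof rigid-body degrees of freedom removed (default 3).
#' @return temperature (K).
#' @export
kinetic_temperature <- function(velocities, mass, n_removed_dof = 3) {
  v <- as.matrix(velocities)
  stopifnot(nrow(v) == length(mass), nrow(v) >= 1)
  ek <- 0.5 * sum(mass * rowSums(v^2)) / cnt_constants$ACC_CONV
  nf <- 3 * nrow(v) - n_removed_dof
  2 * ek / (nf * cnt_constants$R_KCAL)
}

#' Per-site Langevin friction from Stokes law
#'
#' Base water friction `6 pi eta r` per site (water viscosity 8.9e-4 Pa s)
#' divided by the site mass, times `friction_scale` (the conventional 0.01
#' water-friction factor), in 1/fs. The hydrodynamic site radius follows a
#' volumetric rule r = 0.8 m^(1/3) A (about 3.1 A for a backbone site,
#' 4.1 A for a tryptophan side chain) unless given explicitly.
#'
#' @param mass per-site masses (amu).
#' @param friction_scale multiplier on the base water friction.
#' @param radius hydrodynamic site radius (A); `NULL` for the volumetric
#'   rule.
#' @return friction coefficients gamma (1/fs), one per site.
#' @export
stokes_friction <- function(mass, friction_scale = 0.01, radius = NULL) {
  if (is.null(radius)) radius <- 0.8 * mass^(1 / 3)
  gamma_kg_s <- 6 * pi * 8.9e-4 * radius * 1e-10
  gamma_fs <- gamma_kg_s / (mass * 1.66053906660e-27) * 1e-15
  friction_scale * gamma_fs
}

#' Run molecular dynamics
#'
#' Fixed-step velocity-Verlet integration with the chosen ensemble:
#' `"nve"` (microcanonical), `"berendsen"` (weak-coupling velocity rescale
#' with time constant `tau`), `"langevin"` (BAOAB splitting with per-site
#' Stokes friction times `friction_scale`), or `"nose_hoover"` (single
#' extended variable with inertia `Q`; the conserved extended Hamiltonian is
#' reported in the `conserved` column).
#'
#' @param system a `cg_system`.
#' @param steps number of integration steps.
#' @param dt time step (fs).
#' @param ensemble one of `"nve"`, `"berendsen"`, `"langevin"`,
#'   `"nose_hoover"`.
#' @param T_set thermostat set temperature (K); also used for
#'   Maxwell-Boltzmann velocity initialization.
#' @param tau Berendsen coupling time (fs).
#' @param friction_scale Langevin multiplier on the base water friction.
#' @param Q Nose-Hoover thermostat inertia (kcal MTU^2/mol; 1 MTU = 48.9 fs).
#' @param seed integer seed for velocity initialization and Langevin noise;
#'   `NULL` leaves the RNG state untouched.
#' @param positions,velocities optional starting state (defaults: the
#'   system's chain coordinates and Maxwell-Boltzmann velocities at `T_set`).
#' @param sample_every energy/temperature sampling stride (steps).
#' @param traj_every trajectory frame stride (steps); 0 stores no frames.
#' @return object of class `md_run`: list with `samples` (data.frame: step,
#'   time_fs, u_protein, u_cnt, u_restraint, u_pot, e_kin, e_tot, T_inst,
#'   conserved), `positions`, `velocities`, `trajectory` (site x 3 x frame
#'   array or NULL), `n_dof`, and the run settings.
#' @export
run_md <- function(system, steps, dt = 0.489,
                   ensemble = c("nve", "berendsen", "langevin", "nose_hoover"),
                   T_set = 300, tau = 48.9, friction_scale = 0.01, Q = 5,
                   seed = NULL, positions = NULL, velocities = NULL,
                   sample_every = 10L, traj_every = 0L) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, steps >= 1, T_set > 0, tau > 0, Q > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positions)) positions <- system_positions(system)
  remove_com <- ensemble != "langevin"
  if (is.null(velocities))
    velocities <- init_velocities(system$mass, T_set, remove_com = remove_com)
  nf <- 3 * system$nsite - if (remove_com) 3 else 0
  gam <- stokes_friction(system$mass, friction_scale)
  Q_fs <- Q * cnt_constants$MTU_FS^2

  res <- cpp_run_md(positions, velocities, system$spec, dt, as.integer(steps),
                    .THERMOSTATS[[ensemble]], T_set, tau, gam, Q_fs, nf,
                    as.integer(sample_every), as.integer(traj_every), 0, 0)
  if (res$status != 0)
    stop("site crossed the tube surface at step ", res$bad_step,
         " (dynamic site ", res$bad_site,
         "): time step too large or bad starting configuration")
  samples <- as.data.frame(res$samples)
  structure(list(
    samples = samples, positions = res$positions,
    velocities = res$velocities,
    trajectory = if (!is.null(res$trajectory)) res$trajectory else NULL,
    xi = res$xi, eta = res$eta, n_dof = nf, ensemble = ensemble, dt = dt,
    steps = as.integer(steps), T_set = T_set, system = system
  ), class = "md_run")
}

#' @export
print.md_run <- function(x, ...) {
  s <- x$samples
  cat(sprintf("md_run: %s, %d steps @ %g fs (%d samples)\n", x$ensemble,
              x$steps, x$dt, nrow(s)))
  cat(sprintf("  <T> = %.2f K, E_tot %.4f -> %.4f kcal/mol\n",
              mean(s$T_inst), s$e_tot[1], s$e_tot[nrow(s)]))
  invisible(x)
}

#' Kinetic-temperature distribution diagnostics
#'
#' Compares an instantaneous-temperature series with the canonical
#' kinetic-temperature density for `n_dof` degrees of freedom (a gamma
#' density with shape `n_dof/2` and mean `T_set`, variance
#' `2 T_set^2 / n_dof`). The key diagnostic is the empirical-to-canonical
#' variance ratio: weak-coupling (Berendsen) runs give ratios well below 1,
#' canonical thermostats give ratios near 1.
#'
#' @param T_inst numeric vector of instantaneous temperatures (>= 1e4
#'   samples).
#' @param n_dof degrees of freedom behind the temperature estimator.
#' @param T_set set temperature (K); defaults to the series mean.
#' @param breaks histogram breaks (passed to [graphics::hist()] semantics via
#'   [base::cut()]-free binning).
#' @return list with `mean`, `variance`, `canonical_variance`,
#'   `variance_ratio`, `histogram` (data.frame: mid, density) and
#'   `theoretical` (data.frame: T, density).
#' @export
temperature_distribution <- function(T_inst, n_dof, T_set = mean(T_inst),
                                     breaks = 60) {
  if (length(T_inst) < 1e4)
    stop("need at least 1e4 temperature samples")
  shape <- n_dof / 2
  rate <- shape / T_set  # gamma with mean T_set
  h <- graphics::hist(T_inst, breaks = breaks, plot = FALSE)
  grid <- seq(min(T_inst), max(T_inst), length.out = 200)
  canon_var <- 2 * T_set^2 / n_dof
  list(mean = mean(T_inst), variance = stats::var(T_inst),
       canonical_variance = canon_var,
       variance_ratio = stats::var(T_inst) / canon_var,
       histogram = data.frame(mid = h$mids, density = h$density),
       theoretical = data.frame(T = grid,
                                density = stats::dgamma(grid, shape = shape,
                                                        rate = rate)))
}
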