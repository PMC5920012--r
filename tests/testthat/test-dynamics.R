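# Integrators and thermostats: free flight, reversibility, conservation
# order, kinetic temperature, Langevin stationary statistics, Nose-Hoover
# conserved quantity, temperature-distribution diagnostics.

test_that("free flight advances positions by v dt exactly", {
  sys <- gly2_system(kb = 0)
  v <- matrix(c(0.001, -0.002, 0.0005, 0.002, 0.001, -0.001), 2, 3)
  run <- run_md(sys, steps = 100, dt = 0.5, ensemble = "nve", T_set = 300,
                velocities = v, sample_every = 100)
  expect_equal(run$positions, system_positions(sys) + v * 100 * 0.5,
               tolerance = 1e-12)
  expect_equal(run$velocities, v, tolerance = 1e-14)
})

test_that("kinetic temperature follows equipartition", {
  m <- rep(50, 5)
  v <- matrix(0, 5, 3)
  expect_equal(kinetic_temperature(v, m), 0)
  set.seed(1)
  m <- rep(80, 10000)
  v <- init_velocities(m, 300, remove_com = FALSE)
  expect_equal(kinetic_temperature(v, m, n_removed_dof = 0), 300,
               tolerance = 0.01)
  expect_equal(kinetic_temperature(2 * v, m, n_removed_dof = 0),
               4 * kinetic_temperature(v, m, n_removed_dof = 0),
               tolerance = 1e-12)
})

test_that("velocity Verlet is time reversible", {
  sys <- fixture_system(minimized = TRUE)
  set.seed(3)
  v0 <- init_velocities(sys$mass, 300)
  p0 <- system_positions(sys)
  fwd <- run_md(sys, steps = 100, dt = 0.489, ensemble = "nve",
                positions = p0, velocities = v0, sample_every = 100)
  bwd <- run_md(sys, steps = 100, dt = 0.489, ensemble = "nve",
                positions = fwd$positions, velocities = -fwd$velocities,
                sample_every = 100)
  expect_lt(max(abs(bwd$positions - p0)), 1e-8)
})

test_that("NVE energy drift scales like dt^2", {
  sys <- fixture_system(minimized = TRUE)
  set.seed(5)
  v0 <- init_velocities(sys$mass, 300)
  spread <- function(dt, steps) {
    r <- run_md(sys, steps = steps, dt = dt, ensemble = "nve",
                positions = system_positions(sys), velocities = v0,
                sample_every = max(1, steps / 1000))
    diff(range(r$samples$e_tot))
  }
  s1 <- spread(0.978, 10000)
  s2 <- spread(0.489, 20000)
  # halving dt should cut the fluctuation amplitude by about 4 (Verlet order)
  expect_gt(s1 / s2, 2.5)
  expect_lt(s1 / s2, 6.5)
})

test_that("integration aborts with a diagnostic when a site would cross the tube", {
  sys <- gly2_system(cylinder = cnt_cylinder(6),
                     ca = rbind(c(110 + 8.5, 110, 0), c(110 + 8.5, 110, 3.8)))
  v <- matrix(0, 2, 3); v[, 1] <- -2  # one oversized step jumps the wall
  expect_error(run_md(sys, steps = 500, dt = 1.5, ensemble = "nve",
                      velocities = v, sample_every = 10),
               "crossed the tube surface")
})

test_that("Berendsen reduces to NVE when tau is huge and at the set point", {
  sys <- fixture_system(minimized = TRUE)
  set.seed(7)
  v0 <- init_velocities(sys$mass, 300)
  p0 <- system_positions(sys)
  nve <- run_md(sys, steps = 200, dt = 0.489, ensemble = "nve",
                positions = p0, velocities = v0, sample_every = 200)
  ber <- run_md(sys, steps = 200, dt = 0.489, ensemble = "berendsen",
                T_set = 300, tau = 1e12, positions = p0, velocities = v0,
                sample_every = 200)
  expect_equal(ber$positions, nve$positions, tolerance = 1e-9)
})

test_that("zero-friction Langevin is exactly velocity Verlet", {
  sys <- fixture_system(minimized = TRUE)
  set.seed(11)
  v0 <- init_velocities(sys$mass, 300, remove_com = FALSE)
  p0 <- system_positions(sys)
  nve <- run_md(sys, steps = 500, dt = 0.489, ensemble = "nve",
                positions = p0, velocities = v0, sample_every = 500)
  lan <- run_md(sys, steps = 500, dt = 0.489, ensemble = "langevin",
                T_set = 300, friction_scale = 0, seed = 1,
                positions = p0, velocities = v0, sample_every = 500)
  expect_equal(lan$positions, nve$positions, tolerance = 1e-10)
})

test_that("Langevin samples the canonical distribution of a harmonic bond", {
  # bond-only two-site chain: U = k (b - b0)^2, so the bond length is
  # Gaussian with variance kB T / (2 k) up to a tiny 3D Jacobian correction
  sys <- gly2_system(kb = 200)
  run <- run_md(sys, steps = 1e6, dt = 2, ensemble = "langevin",
                T_set = 300, friction_scale = 1, seed = 42,
                sample_every = 1, traj_every = 200)
  nf <- dim(run$trajectory)[3]
  b <- vapply(seq_len(nf), function(k)
    sqrt(sum((run$trajectory[2, , k] - run$trajectory[1, , k])^2)),
    numeric(1))
  b <- b[-seq_len(200)]  # discard equilibration
  kbt <- cnt_constants$R_KCAL * 300
  expect_equal(var(b), kbt / (2 * 200), tolerance = 0.03)
  ks <- stats::ks.test(b, "pnorm", mean = 3.8, sd = sqrt(kbt / (2 * 200)))
  expect_gt(ks$p.value, 0.01)
  # mean kinetic temperature at the set point
  eq <- run$samples[run$samples$step > 1e5, ]
  expect_lt(abs(mean(eq$T_inst) - 300) / 300, 0.005)
})

test_that("Nose-Hoover conserves its extended Hamiltonian and decouples at large Q", {
  sys <- fixture_system(minimized = TRUE)
  run <- run_md(sys, steps = 2e4, dt = 0.2445, ensemble = "nose_hoover",
                T_set = 300, Q = 5, seed = 13, sample_every = 10)
  drift <- abs(run$samples$conserved[nrow(run$samples)] -
               run$samples$conserved[1]) / 2   # per 1e4 steps
  expect_lt(drift, 1e-3)

  set.seed(17)
  v0 <- init_velocities(sys$mass, 300)
  p0 <- system_positions(sys)
  nve <- run_md(sys, steps = 200, dt = 0.489, ensemble = "nve",
                positions = p0, velocities = v0, sample_every = 200)
  nh <- run_md(sys, steps = 200, dt = 0.489, ensemble = "nose_hoover",
               T_set = 300, Q = 1e9, positions = p0, velocities = v0,
               sample_every = 200)
  expect_equal(nh$positions, nve$positions, tolerance = 1e-6)
})

test_that("temperature_distribution diagnoses canonical vs narrowed ensembles", {
  set.seed(23)
  nf <- 117
  # Maxwell-Boltzmann synthetic kinetic temperatures: gamma(shape nf/2)
  T_mb <- stats::rgamma(2e4, shape = nf / 2, rate = nf / 2 / 300)
  td <- temperature_distribution(T_mb, nf, 300)
  expect_equal(td$variance_ratio, 1, tolerance = 0.05)
  expect_equal(td$mean, 300, tolerance = 1)
  expect_error(temperature_distribution(T_mb[1:100], nf, 300), "1e4")
  # theoretical density integrates to ~1 over the sampled range
  dT <- diff(td$theoretical$T[1:2])
  expect_equal(sum(td$theoretical$density) * dT, 1, tolerance = 0.02)
})
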