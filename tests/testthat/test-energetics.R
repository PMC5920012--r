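# Kihara cylinder potential, restraints, surrogate force field, total-energy
# assembly, minimization.

test_that("Kihara potential has its analytic zero, minimum and tail", {
  expect_equal(u_kihara(6 + 4, 6, 0.5, 4), 0)
  expect_equal(u_kihara(6 + 2^(1 / 6) * 4, 6, 0.5, 4), -0.5)
  # direct evaluation: eps 1, sigma 4, R0 6, r 12 -> 4[(4/6)^12 - (4/6)^6]
  expect_equal(u_kihara(12, 6, 1, 4), 4 * ((4 / 6)^12 - (4 / 6)^6),
               tolerance = 1e-12)
  expect_equal(u_kihara(12, 6, 1, 4), -0.32034, tolerance = 1e-4)
  expect_error(u_kihara(5.9, 6, 1, 4), "r <= R0")
})

test_that("Kihara is monotone on either side of the minimum, sign flips at R0+sigma", {
  R0 <- 6; sig <- 4; eps <- 0.7
  rmin <- R0 + 2^(1 / 6) * sig
  left <- seq(R0 + 0.4 * sig, rmin, length.out = 200)
  right <- seq(rmin, R0 + 6 * sig, length.out = 200)
  ul <- u_kihara(left, R0, eps, sig)
  ur <- u_kihara(right, R0, eps, sig)
  expect_true(all(diff(ul) < 0))
  expect_true(all(diff(ur) > 0))
  expect_true(all(u_kihara(seq(R0 + 0.5, R0 + sig - 1e-6, length.out = 50),
                           R0, eps, sig) > 0))
  expect_true(all(u_kihara(seq(R0 + sig + 1e-6, R0 + 10 * sig,
                               length.out = 50), R0, eps, sig) < 0))
})

test_that("cylinder force is minus the gradient, radial, zero z component", {
  box <- periodic_box(220)
  cyl <- cnt_cylinder(6)
  # zero at the minimum
  p <- c(110 + 6 + 2^(1 / 6) * 4, 110, 13)
  expect_equal(f_kihara(p, cyl, box, "A"), c(0, 0, 0), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:100) {
    ang <- runif(1, 0, 2 * pi)
    r <- runif(1, 6 + 2.2, 6 + 14)
    p <- c(110 + r * cos(ang), 110 + r * sin(ang), runif(1, -20, 20))
    f <- f_kihara(p, cyl, box, "A")
    expect_identical(f[3], 0)
    h <- 1e-5
    for (k in 1:2) {
      pp <- p; pp[k] <- pp[k] + h
      pm <- p; pm[k] <- pm[k] - h
      uk <- function(q) u_kihara(axial_distance(q, cyl, box), 6, 0.5, 4)
      gfd <- (uk(pp) - uk(pm)) / (2 * h)
      expect_lt(abs(f[k] + gfd), 1e-6 * max(1e-4, abs(gfd)))
    }
  }
})

test_that("tube energy sums side-chain and peptide sites with their own parameters", {
  box <- periodic_box(220)
  cyl <- cnt_cylinder(6)
  # every site at its zero distance -> total 0: chain parallel to the axis
  ch <- build_chain(c("G", "G"), rbind(c(110 + 10, 110, 0), c(110 + 10, 110, 3.8)))
  # G sigma 4: move sites to r = R0 + sigma
  ch$ca[, 1] <- 110 + 6 + 4; ch$sc <- ch$ca
  u_sites <- u_kihara(axial_distance(ch$sc, cyl, box), 6, 0.5, 4)
  expect_equal(sum(u_sites), 0)
  # but the peptide site has sigma 3.5, so the total is the peptide term only
  expect_equal(u_cnt_total(ch, cyl, box), u_kihara(10, 6, 0.3, 3.5))

  # brute-force site-by-site sum on a 3-residue chain
  ch3 <- build_chain(c("A", "W", "F"),
                     rbind(c(120, 112, 0), c(123.5, 110, 1.5), c(126, 114, 3)))
  kih <- cyl$kihara
  manual <- 0
  for (i in 1:3) {
    k <- kih[kih$type == ch3$sequence[i], ]
    manual <- manual + u_kihara(axial_distance(ch3$sc[i, ], cyl, box),
                                6, k$epsilon, k$sigma)
  }
  pp <- peptide_positions(ch3)
  kp <- kih[kih$type == "p", ]
  for (i in 1:2)
    manual <- manual + u_kihara(axial_distance(pp[i, ], cyl, box),
                                6, kp$epsilon, kp$sigma)
  expect_equal(u_cnt_total(ch3, cyl, box), manual, tolerance = 1e-12)
  # and the compiled path agrees
  sys <- cg_system(ch3, cyl, box)
  expect_equal(total_energy(sys)$u_cnt_total, manual, tolerance = 1e-10)
})

test_that("flat-bottom restraint has its stated coefficients and shape", {
  rs <- restraint_set(1L, 2L, 5)
  expect_equal(rs$A, 24 / 25)
  expect_equal(rs$sigma_rest, 0.04)
  # flat bottom
  expect_equal(u_restraint(5, rs), 0)
  expect_equal(u_restraint(5.0999, rs), 0)
  expect_equal(u_restraint(4.9001, rs), 0)
  # worked value at x = 4: A d^4/(d^4 + sigma) with d = -0.9
  expect_equal(u_restraint(4, rs), 0.96 * 0.9^4 / (0.9^4 + 0.04),
               tolerance = 1e-12)
  expect_equal(u_restraint(4, rs), 0.904836, tolerance = 1e-5)
  # plateau -> A
  expect_equal(u_restraint(5 + 1e3, rs), rs$A, tolerance = 1e-8)
  # bounded in [0, A), even about the flat region, continuous at the edges
  xg <- seq(0.2, 30, by = 0.01)
  ug <- u_restraint(xg, restraint_set(rep(1L, length(xg)), rep(2L, length(xg)),
                                      rep(5, length(xg))), per_pair = TRUE)
  expect_true(all(ug >= 0 & ug < 24 / 25))
  dlt <- seq(0.1, 3, by = 0.01)
  u_hi <- u_restraint(5 + dlt, restraint_set(rep(1L, length(dlt)),
                                             rep(2L, length(dlt)),
                                             rep(5, length(dlt))),
                      per_pair = TRUE)
  u_lo <- u_restraint(5 - dlt, restraint_set(rep(1L, length(dlt)),
                                             rep(2L, length(dlt)),
                                             rep(5, length(dlt))),
                      per_pair = TRUE)
  expect_equal(u_hi, u_lo, tolerance = 1e-12)
  # value and first derivative vanish entering the flat region
  eps <- 1e-5
  expect_lt(u_restraint(5.1 + eps, rs), 1e-12)
  expect_lt((u_restraint(5.1 + 2 * eps, rs) - u_restraint(5.1 + eps, rs)) / eps,
            1e-8)
})

test_that("surrogate force-field gradient matches finite differences at random configs", {
  set.seed(52)
  fx <- make_fixture("trpcage_like")
  prm <- surrogate_ff_params(go = derive_go_contacts(fx$chain))
  sys <- cg_system(fx$chain, fx$cylinder, fx$box, params = prm,
                   restraints = derive_restraints(fx$chain))
  for (rep in 1:4) {
    pos <- system_positions(sys) + matrix(rnorm(sys$nsite * 3, sd = 0.3),
                                          sys$nsite, 3)
    r <- cntmd:::cpp_energy_forces(pos, sys$spec, FALSE)
    if (r$status != 0) next
    g <- -r$forces
    h <- 1e-5
    for (k in sample(length(pos), 25)) {
      pp <- pos; pp[k] <- pp[k] + h
      pm <- pos; pm[k] <- pm[k] - h
      gfd <- (cntmd:::cpp_energy_forces(pp, sys$spec, FALSE)$u_total -
              cntmd:::cpp_energy_forces(pm, sys$spec, FALSE)$u_total) / (2 * h)
      expect_lt(abs(g[k] - gfd), 1e-6 * max(1e-2, abs(gfd)))
    }
  }
})

test_that("surrogate energy is invariant under rigid motion and zero at ideal geometry", {
  set.seed(8)
  fx <- make_fixture("helix", 10)
  e0 <- u_protein(fx$chain)
  rot <- random_rotation()
  ch2 <- fx$chain
  ch2$ca <- sweep(fx$chain$ca %*% rot, 2, c(5, 6, 7), `+`)
  ch2$sc <- sweep(fx$chain$sc %*% rot, 2, c(5, 6, 7), `+`)
  e1 <- u_protein(ch2)
  expect_equal(e1$energy, e0$energy, tolerance = 1e-9)
  # a two-site chain at the equilibrium bond length has zero bonded energy
  ch <- build_chain(c("G", "G"), rbind(c(0, 0, 0), c(3.8, 0, 0)))
  e <- u_protein(ch, surrogate_ff_params(nb_epsilon = 0))
  expect_equal(e$energy, 0)
})

test_that("total energy assembles its breakdown exactly and scales with w_cnt", {
  fx <- make_fixture("trpcage_like")
  rs <- derive_restraints(fx$chain)
  mk <- function(w) {
    cyl <- cnt_cylinder(6, weight = w)
    ch2 <- fx$chain
    ch2$ca <- ch2$ca + 0.2  # off-native so restraints engage
    ch2$sc <- ch2$sc + 0.2
    total_energy(cg_system(ch2, cyl, fx$box, restraints = rs))
  }
  e1 <- mk(1); e2 <- mk(2); e0 <- mk(0)
  expect_equal(e1$u_total,
               e1$u_protein + 1 * e1$u_cnt_total + 0.006 * e1$u_restraint,
               tolerance = 1e-12)
  # doubling the weight doubles the tube contribution exactly
  expect_equal(e2$u_total - e2$u_protein - 0.006 * e2$u_restraint,
               2 * (e1$u_total - e1$u_protein - 0.006 * e1$u_restraint),
               tolerance = 1e-10)
  # weight 0: total independent of the cylinder
  no_cyl <- total_energy(cg_system({
    ch2 <- fx$chain; ch2$ca <- ch2$ca + 0.2; ch2$sc <- ch2$sc + 0.2; ch2
  }, NULL, fx$box, restraints = rs))
  expect_equal(e0$u_total, no_cyl$u_total, tolerance = 1e-10)
  # far from the tube the tail is negligible
  far <- fx$chain
  far$ca[, 1] <- far$ca[, 1] - 10 + 60
  far$sc[, 1] <- far$sc[, 1] - 10 + 60
  expect_lt(abs(total_energy(cg_system(far, fx$cylinder, fx$box))$u_cnt_total),
            1e-3)
})

test_that("minimization descends and finds the analytic tube minimum", {
  # chain parallel to the axis, bond unaffected: the radial coordinate sees
  # a pure Kihara well whose minimum is at r = R0 + 2^(1/6) sigma for every
  # interacting site when all (eps, sigma) match
  tab <- default_kihara_table()
  tab$epsilon[] <- 0.5; tab$sigma[] <- 4
  cyl <- cnt_cylinder(6, tab, 1)
  ca <- rbind(c(110 + 10.5, 110, 0), c(110 + 10.5, 110, 3.8))
  sys <- gly2_system(kb = 50, cylinder = cyl, ca = ca)
  mn <- minimize_chain(sys, tol = 1e-8)
  expect_lte(mn$energy$u_total, mn$initial_energy)
  r <- axial_distance(mn$chain$ca, cyl, periodic_box(220))
  expect_equal(r, rep(6 + 2^(1 / 6) * 4, 2), tolerance = 1e-4)

  # starting at a minimum returns unchanged
  mn2 <- minimize_chain(mn$system, tol = 1e-8)
  expect_equal(system_positions(mn2$system), system_positions(mn$system),
               tolerance = 1e-6)

  # full fixture: energy strictly decreases
  sys3 <- fixture_system()
  mn3 <- minimize_chain(sys3)
  expect_lt(mn3$energy$u_total, mn3$initial_energy)
})
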