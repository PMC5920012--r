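# Shared builders for small test systems and toy archives.

# bond-only two-glycine chain: one harmonic degree of freedom, no side-chain
# sites, optional cylinder
gly2_system <- function(kb = 50, cylinder = NULL, box = periodic_box(220),
                        ca = rbind(c(0, 0, 0), c(3.8, 0, 0))) {
  ch <- build_chain(c("G", "G"), ca)
  cg_system(ch, cylinder, box,
            surrogate_ff_params(kb = kb, ktheta = 0, kgamma = 0, ksc = 0,
                                nb_epsilon = 0))
}

# the standard 20-residue fixture system, optionally minimized
fixture_system <- function(minimized = FALSE, restraints = FALSE) {
  fx <- make_fixture("trpcage_like")
  rs <- if (restraints) derive_restraints(fx$chain) else NULL
  sys <- cg_system(fx$chain, fx$cylinder, fx$box, restraints = rs)
  if (minimized) sys <- minimize_chain(sys)$system
  sys
}

# archive with prescribed energies (no coordinates)
energy_archive <- function(u, temperature, w_cnt = 0) {
  n <- length(u)
  ensemble_archive(data.frame(
    replica = rep(1L, n), temp_index = match(temperature, sort(unique(temperature))),
    temperature = temperature, step = seq_len(n), u_protein = u,
    u_cnt = 0, u_restraint = 0, u_total = u),
    topology = list(sequence = c("A", "A"), w_cnt = w_cnt, w_restraint = 0))
}

# archive from a list of CA coordinate matrices (side-chain-free chains)
coord_archive <- function(frames, sequence = NULL, R0 = 6, box = 220,
                          u_cnt = NULL, w_cnt = 1) {
  n <- nrow(frames[[1]])
  if (is.null(sequence)) sequence <- rep("G", n)
  k <- length(frames)
  if (is.null(u_cnt)) u_cnt <- numeric(k)
  snaps <- data.frame(replica = 1L, temp_index = 1L, temperature = 300,
                      step = seq_len(k), u_protein = 0, u_cnt = u_cnt,
                      u_restraint = 0, u_total = w_cnt * u_cnt)
  coords <- array(unlist(frames), c(n, 3, k))
  ensemble_archive(snaps, coords,
                   topology = list(sequence = sequence, w_cnt = w_cnt,
                                   w_restraint = 0, R0 = R0,
                                   box = c(box, box, box)))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}
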