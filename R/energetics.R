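# Potential-energy terms and their assembly.
#
# The model energy is
#   U = U_protein + w_cnt * U_cnt + w_restraint * U_restraint
# where U_cnt sums a surface-shifted Kihara (cylindrical LJ) term over every
# side-chain and peptide-group site, U_restraint is a flat-bottom Lorentzian
# penalty on CA pair distances, and U_protein is the surrogate intra-protein
# coarse-grained force field (harmonic virtual bonds and angles, cosine
# dihedrals, harmonic side-chain attachment, truncated-shifted LJ, optional
# native-contact wells).

#' Surrogate intra-protein force-field parameters
#'
#' Parameters of the coarse-grained intra-protein potential that stands in
#' for a full physics-based residue-level force field. All force constants in
#' kcal/mol per squared unit; distances in A, angles in radians.
#'
#' @param kb,b0 virtual-bond constant and equilibrium CA-CA length.
#' @param ktheta,theta0 virtual-bond-angle constant and equilibrium angle.
#' @param kgamma,gamma_n,gamma_phase cosine dihedral: `kgamma * (1 +
#'   cos(gamma_n * g - gamma_phase))`.
#' @param ksc side-chain attachment constant (per-residue equilibrium
#'   distances come from [aa_parameters()]).
#' @param nb_epsilon,nb_sigma nonbonded LJ well depth and size, applied
#'   between all site pairs at least 3 residues apart in sequence.
#' @param nb_cut_factor cutoff in units of `nb_sigma`; the LJ term is
#'   truncated and shifted to zero there.
#' @param go optional data.frame of native contacts with columns `i`, `j`
#'   (residue indices), `r0` (A), `eps` (kcal/mol); each contributes
#'   `eps * ((r0/r)^12 - 2 (r0/r)^6)`.
#' @return object of class `ff_params`.
#' @export
surrogate_ff_params <- function(kb = 50, b0 = 3.8, ktheta = 10, theta0 = 1.58,
                                kgamma = 0.5, gamma_n = 1L,
                                gamma_phase = -2.27, ksc = 20,
                                nb_epsilon = 0.2, nb_sigma = 4.0,
                                nb_cut_factor = 2.5, go = NULL) {
  stopifnot(kb >= 0, ktheta >= 0, kgamma >= 0, ksc >= 0, nb_epsilon >= 0,
            nb_cut_factor > 1)
  structure(list(kb = kb, b0 = b0, ktheta = ktheta, theta0 = theta0,
                 kgamma = kgamma, gamma_n = as.integer(gamma_n),
                 gamma_phase = gamma_phase, ksc = ksc,
                 nb_epsilon = nb_epsilon, nb_sigma = nb_sigma,
                 nb_cut_factor = nb_cut_factor, go = go),
            class = "ff_params")
}

#' Flat-bottom Lorentzian restraint set
#'
#' Distance restraints on CA pairs: zero inside `|x - x0| < halfwidth`, and
#' `A d^4 / (d^4 + sigma_rest)` outside, with `d` measured from the nearer
#' flat-region edge, `A = 24 / x0^2` and `sigma_rest = (0.04 x0)^2`. The
#' restraint energy enters the total with weight `weight` (default 0.006).
#'
#' @param i,j residue indices of the restrained CA pairs.
#' @param x0 reference (native) distances (A), all > 0.
#' @param weight relative weight of the restraint term.
#' @param halfwidth flat-bottom half width (A).
#' @return object of class `restraint_set`.
#' @export
restraint_set <- function(i, j, x0, weight = 0.006, halfwidth = 0.1) {
  stopifnot(length(i) == length(j), length(i) == length(x0), all(x0 > 0),
            halfwidth >= 0)
  structure(list(i = as.integer(i), j = as.integer(j), x0 = as.numeric(x0),
                 A = 24 / x0^2, sigma_rest = (0.04 * x0)^2,
                 weight = weight, halfwidth = halfwidth),
            class = "restraint_set")
}

#' Kihara cylinder potential
#'
#' Surface-shifted Lennard-Jones interaction between a site at axial distance
#' `r` and an infinite cylinder of radius `R0`:
#' `4 eps * ((sigma/(r - R0))^12 - (sigma/(r - R0))^6)`. Zero at
#' r = R0 + sigma; minimum -eps at r = R0 + 2^(1/6) sigma.
#'
#' @param r axial distance(s) (A), strictly greater than `R0`.
#' @param R0 cylinder radius (A).
#' @param epsilon well depth (kcal/mol).
#' @param sigma zero-crossing distance (A).
#' @return energy (kcal/mol), vectorized over `r`.
#' @export
u_kihara <- function(r, R0, epsilon, sigma) {
  if (any(r <= R0))
    stop("u_kihara: site at or inside the tube surface (r <= R0)")
  s6 <- (sigma / (r - R0))^6
  4 * epsilon * (s6^2 - s6)
}

#' Force exerted by the cylinder on a site
#'
#' Minus the gradient of [u_kihara()] with respect to the site position; the
#' force is radial in the x-y plane (zero z component) and uses the
#' minimum-image in-plane distance to the axis.
#'
#' @param position 3-vector (A).
#' @param cylinder a `cnt_cylinder`.
#' @param box a `periodic_box`.
#' @param type site type (one-letter residue code or `"p"`); selects the
#'   (epsilon, sigma) row of the cylinder's Kihara table.
#' @return force 3-vector (kcal/mol/A).
#' @export
f_kihara <- function(position, cylinder, box, type = "A") {
  k <- cylinder$kihara[match(type, cylinder$kihara$type), ]
  if (any(is.na(k$epsilon))) stop("unknown site type: ", type)
  dx <- position[1] - box[["lx"]] / 2
  dy <- position[2] - box[["ly"]] / 2
  dx <- dx - box[["lx"]] * round(dx / box[["lx"]])
  dy <- dy - box[["ly"]] * round(dy / box[["ly"]])
  r <- sqrt(dx^2 + dy^2)
  if (r <= cylinder$radius)
    stop("f_kihara: site at or inside the tube surface")
  d <- r - cylinder$radius
  s6 <- (k$sigma / d)^6
  dudd <- (24 * k$epsilon / d) * (s6 - 2 * s6^2)
  c(-dudd * dx / r, -dudd * dy / r, 0)
}

#' Total tube-protein interaction energy
#'
#' Sums the Kihara term over every side-chain site (glycine's coincides with
#' its CA) and every derived peptide-group site, each with its type's
#' (epsilon, sigma). The returned value is unweighted; the cylinder weight is
#' applied in [total_energy()].
#'
#' @param chain a `chain_model`.
#' @param cylinder a `cnt_cylinder`.
#' @param box a `periodic_box`.
#' @return energy (kcal/mol).
#' @export
u_cnt_total <- function(chain, cylinder, box) {
  kih <- cylinder$kihara
  sc_par <- kih[match(chain$sequence, kih$type), ]
  r_sc <- axial_distance(chain$sc, cylinder, box)
  if (any(r_sc <= cylinder$radius))
    stop("side-chain site(s) at or inside the tube surface: residue ",
         paste(which(r_sc <= cylinder$radius), collapse = ", "))
  u <- sum(u_kihara(r_sc, cylinder$radius, sc_par$epsilon, sc_par$sigma))
  pp <- peptide_positions(chain)
  p_par <- kih[match("p", kih$type), ]
  r_p <- axial_distance(pp, cylinder, box)
  if (any(r_p <= cylinder$radius))
    stop("peptide-group site(s) at or inside the tube surface: bond ",
         paste(which(r_p <= cylinder$radius), collapse = ", "))
  u + sum(u_kihara(r_p, cylinder$radius, p_par$epsilon, p_par$sigma))
}

#' Flat-bottom Lorentzian restraint energy
#'
#' Evaluates the restraint penalty at the supplied pair distances. The value
#' is the unweighted sum over pairs (the restraint weight is applied in
#' [total_energy()]).
#'
#' @param x current pair distances (A), one per restraint pair.
#' @param restraints a `restraint_set`.
#' @param per_pair return the per-pair vector instead of the sum.
#' @return energy (kcal/mol).
#' @export
u_restraint <- function(x, restraints, per_pair = FALSE) {
  stopifnot(length(x) == length(restraints$x0))
  h <- restraints$halfwidth
  d <- ifelse(x <= restraints$x0 - h, x - restraints$x0 + h,
              ifelse(x >= restraints$x0 + h, x - restraints$x0 - h, 0))
  u <- restraints$A * d^4 / (d^4 + restraints$sigma_rest)
  if (per_pair) u else sum(u)
}

# ---------------------------------------------------------------------------
# System assembly: everything the C++ kernels need, precomputed once.

#' Assemble a simulation system
#'
#' Bundles a chain, an optional cylinder, the box, force-field parameters and
#' optional restraints into the flat arrays the compiled kernels consume.
#' The dynamic coordinates are the CA sites followed by the side-chain sites
#' of non-glycine residues; peptide groups are derived and massless.
#'
#' @param chain a `chain_model`.
#' @param cylinder a `cnt_cylinder` or `NULL` (no tube).
#' @param box a `periodic_box`.
#' @param params a `ff_params`.
#' @param restraints a `restraint_set` or `NULL`.
#' @return object of class `cg_system`.
#' @export
cg_system <- function(chain, cylinder = NULL, box = periodic_box(),
                      params = surrogate_ff_params(), restraints = NULL) {
  n <- length(chain$sequence)
  has_sc <- chain$sc_mass > 0
  sc_idx <- integer(n)          # 1-based dynamic index of each residue's SC
  sc_idx[!has_sc] <- which(!has_sc)
  sc_idx[has_sc] <- n + seq_len(sum(has_sc))
  nsite <- n + sum(has_sc)
  mass <- c(chain$ca_mass, chain$sc_mass[has_sc])
  site_res <- c(seq_len(n), which(has_sc))

  # nonbonded pairs: |residue separation| >= 3, skipping a site with itself
  pr <- which(outer(site_res, site_res, function(a, b) b - a) >= 3,
              arr.ind = TRUE)
  tab <- .aa_table[match(chain$sequence, .aa_table$code), ]

  if (!is.null(cylinder)) {
    kih <- cylinder$kihara
    scp <- kih[match(chain$sequence, kih$type), ]
    pp <- kih[match("p", kih$type), ]
    cnt <- list(use_cnt = TRUE, R0 = cylinder$radius, w_cnt = cylinder$weight,
                cntS_idx = sc_idx - 1L, cntS_eps = scp$epsilon,
                cntS_sig = scp$sigma,
                cntP_eps = rep(pp$epsilon, n - 1L),
                cntP_sig = rep(pp$sigma, n - 1L))
  } else {
    cnt <- list(use_cnt = FALSE, R0 = 1, w_cnt = 0,
                cntS_idx = integer(0), cntS_eps = numeric(0),
                cntS_sig = numeric(0), cntP_eps = numeric(0),
                cntP_sig = numeric(0))
  }

  if (!is.null(restraints)) {
    rs <- list(rs_i = restraints$i - 1L, rs_j = restraints$j - 1L,
               rs_x0 = restraints$x0, rs_A = restraints$A,
               rs_sig = restraints$sigma_rest,
               rs_half = restraints$halfwidth, w_rest = restraints$weight)
  } else {
    rs <- list(rs_i = integer(0), rs_j = integer(0), rs_x0 = numeric(0),
               rs_A = numeric(0), rs_sig = numeric(0), rs_half = 0.1,
               w_rest = 0)
  }

  go <- params$go
  go_l <- if (!is.null(go) && nrow(go))
    list(go_i = as.integer(go$i) - 1L, go_j = as.integer(go$j) - 1L,
         go_r0 = as.numeric(go$r0), go_eps = as.numeric(go$eps))
  else list(go_i = integer(0), go_j = integer(0), go_r0 = numeric(0),
            go_eps = numeric(0))

  spec <- c(list(
    n_res = n, nsite = nsite, sc_idx = sc_idx - 1L, mass = mass,
    box = as.numeric(box),
    kb = params$kb, b0 = params$b0, kth = params$ktheta, th0 = params$theta0,
    kgam = params$kgamma, gam_n = params$gamma_n,
    gam_phase = params$gamma_phase,
    ksc = rep(params$ksc, n), d0 = tab$sc_dist,
    nb_i = as.integer(pr[, 1]) - 1L, nb_j = as.integer(pr[, 2]) - 1L,
    nb_eps = rep(params$nb_epsilon, nrow(pr)),
    nb_sig = rep(params$nb_sigma, nrow(pr)),
    nb_cut_factor = params$nb_cut_factor), go_l, cnt, rs)

  structure(list(chain = chain, cylinder = cylinder, box = box,
                 params = params, restraints = restraints,
                 spec = spec, nsite = nsite, mass = mass,
                 sc_idx = sc_idx, has_sc = has_sc),
            class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d residues, %d dynamic sites, tube: %s, restraints: %d\n",
              x$spec$n_res, x$nsite,
              if (is.null(x$cylinder)) "none" else
                sprintf("R0 = %g A (w = %g)", x$cylinder$radius, x$cylinder$weight),
              length(x$spec$rs_i)))
  invisible(x)
}

#' Dynamic coordinate matrix of a system
#' @param system a `cg_system`.
#' @return nsite x 3 matrix (CA sites then non-glycine side chains).
#' @export
system_positions <- function(system) {
  rbind(system$chain$ca, system$chain$sc[system$has_sc, , drop = FALSE])
}

#' Rebuild a chain from a dynamic coordinate matrix
#' @param system a `cg_system`.
#' @param pos nsite x 3 matrix.
#' @return a `chain_model` with updated coordinates.
#' @export
system_chain <- function(system, pos) {
  n <- system$spec$n_res
  ch <- system$chain
  ch$ca <- pos[seq_len(n), , drop = FALSE]
  sc <- pos[system$sc_idx, , drop = FALSE]
  ch$sc <- sc
  ch
}

#' Intra-protein surrogate energy and gradient
#'
#' Evaluates the surrogate coarse-grained protein potential (no tube, no
#' restraints) with its analytic gradient.
#'
#' @param chain a `chain_model`.
#' @param params a `ff_params`.
#' @param box a `periodic_box`.
#' @return list with `energy` (kcal/mol), `gradient` (nsite x 3,
#'   d U / d position) and the per-term breakdown.
#' @export
u_protein <- function(chain, params = surrogate_ff_params(),
                      box = periodic_box()) {
  sys <- cg_system(chain, cylinder = NULL, box = box, params = params)
  r <- cpp_energy_forces(system_positions(sys), sys$spec, FALSE)
  list(energy = r$u_protein, gradient = -r$forces,
       terms = r[c("u_bond", "u_angle", "u_dihedral", "u_sc_attach",
                   "u_nonbonded", "u_go")])
}

#' Total energy breakdown
#'
#' Assembles `u_total = u_protein + w_cnt * u_cnt_total + w_restraint *
#' u_restraint` (the weights live on the cylinder and the restraint set).
#'
#' @param system a `cg_system`, or a `chain_model` when the remaining pieces
#'   are given explicitly.
#' @param cylinder,restraints,params,box used when `system` is a
#'   `chain_model`.
#' @return object of class `energy_breakdown`: list with `u_protein`,
#'   `u_cnt_total`, `u_restraint`, `u_total`, per-term components and
#'   `forces` (of the weighted total).
#' @export
total_energy <- function(system, cylinder = NULL, restraints = NULL,
                         params = surrogate_ff_params(),
                         box = periodic_box()) {
  if (inherits(system, "chain_model"))
    system <- cg_system(system, cylinder = cylinder, box = box,
                        params = params, restraints = restraints)
  r <- cpp_energy_forces(system_positions(system), system$spec, FALSE)
  if (r$status != 0)
    stop("site at or inside the tube surface (dynamic site ", r$bad_site, ")")
  structure(r[c("u_protein", "u_cnt_total", "u_restraint", "u_total",
                "u_bond", "u_angle", "u_dihedral", "u_sc_attach",
                "u_nonbonded", "u_go", "forces")],
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("u_total = %.6f kcal/mol (protein %.6f, tube %.6f, restraint %.6f)\n",
              x$u_total, x$u_protein, x$u_cnt_total, x$u_restraint))
  invisible(x)
}

#' Energy minimization
#'
#' L-BFGS-B minimization of the total energy over the dynamic coordinates
#' using the analytic gradients. Inside an inner guard region near the tube
#' surface the Kihara term is continued linearly so the objective stays
#' finite while the minimizer backtracks out; the returned configuration is
#' re-checked against the true (hard-wall) potential.
#'
#' @param system a `cg_system`.
#' @param max_steps iteration cap.
#' @param tol convergence tolerance on the projected gradient (kcal/mol/A).
#' @return list with `system` (relaxed), `chain`, `energy`
#'   (an `energy_breakdown`), `initial_energy`, `converged`, `warning_flag`
#'   and the optimizer `message`.
#' @export
minimize_chain <- function(system, max_steps = 2000, tol = 1e-6) {
  p0 <- system_positions(system)
  dm <- dim(p0)
  e0 <- cpp_energy_forces(p0, system$spec, TRUE)
  fn <- function(x) {
    cpp_energy_forces(matrix(x, dm[1], dm[2]), system$spec, TRUE)$u_total
  }
  gr <- function(x) {
    -as.vector(cpp_energy_forces(matrix(x, dm[1], dm[2]), system$spec, TRUE)$forces)
  }
  opt <- stats::optim(as.vector(p0), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_steps, factr = 10,
                                     pgtol = tol))
  warn <- opt$convergence != 0 && opt$convergence != 1
  if (opt$value > e0$u_total + 1e-9) {  # keep the better of start/end
    opt$par <- as.vector(p0)
    warn <- TRUE
  }
  pos <- matrix(opt$par, dm[1], dm[2])
  chain <- system_chain(system, pos)
  system$chain <- chain
  list(system = system, chain = chain,
       energy = total_energy(system),
       initial_energy = e0$u_total,
       converged = opt$convergence == 0,
       warning_flag = warn, message = opt$message)
}
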