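# Synthetic mini-protein fixtures: deterministic chains placed next to the
# tube, used by every test and by the acceptance protocol in place of
# downloaded structures.

.helix_ca <- function(n) {
  # ideal CA helix: rise 1.5 A, 100 deg/residue, radius chosen so consecutive
  # CA-CA distances are exactly 3.8 A
  rise <- 1.5; twist <- 100 * pi / 180
  rad <- sqrt(3.8^2 - rise^2) / (2 * sin(twist / 2))
  i <- seq_len(n) - 1
  cbind(rad * cos(i * twist), rad * sin(i * twist), rise * i)
}

.zigzag_ca <- function(n, theta = 2.2) {
  # planar zigzag with 3.8 A bonds and constant virtual-bond angle theta
  a <- (pi - theta) / 2
  d1 <- c(sin(a), 0, cos(a)); d2 <- c(-sin(a), 0, cos(a))
  ca <- matrix(0, n, 3)
  for (i in seq_len(n - 1))
    ca[i + 1, ] <- ca[i, ] + 3.8 * (if (i %% 2) d1 else d2)
  ca
}

# next CA position from bond length r, angle theta and dihedral phi
# (natural extension reference frame)
.nerf <- function(a, b, c, r, theta, phi) {
  m1 <- .unit(c - b)
  n1 <- .unit(.cross(b - a, m1))
  m2 <- .cross(n1, m1)
  c + r * (-cos(theta) * m1 + sin(theta) * (cos(phi) * m2 + sin(phi) * n1))
}

.trpcage_ca <- function() {
  # 20 residues: N-terminal helix (1-9) + near-extended coil tail grown with
  # fixed internal coordinates (theta 2.1 rad, alternating near-trans
  # dihedrals so the tail keeps extending away from the helix)
  ca <- matrix(0, 20, 3)
  ca[1:9, ] <- .helix_ca(9)
  for (i in 10:20)
    ca[i, ] <- .nerf(ca[i - 3, ], ca[i - 2, ], ca[i - 1, ], 3.8, 2.1,
                     if (i %% 2) 2.9 else -2.9)
  ca
}

.rot_z_to_x <- function(p) cbind(p[, 3], p[, 2], -p[, 1])

#' Synthetic chain + tube fixtures
#'
#' Deterministic synthetic systems: an ideal CA helix (`"helix"`), a planar
#' zigzag (`"extended"`), or a 20-residue mini-protein with the Trp-cage
#' sequence and a helix + coil geometry (`"trpcage_like"`). The chain is laid
#' out radially: the first residue's CA sits exactly `placement` A from the
#' tube axis and the chain extends away from the tube.
#'
#' @param kind fixture kind.
#' @param n_residues chain length (>= 2; fixed at 20 for
#'   `"trpcage_like"`).
#' @param placement axial distance of the first CA from the tube axis (A);
#'   must exceed the tube radius.
#' @param radius tube radius R0 (A).
#' @param box_edge periodic box edge (A).
#' @param seed RNG seed (used for the optional coordinate `jitter`).
#' @param jitter Gaussian coordinate noise amplitude (A), default 0
#'   (fully deterministic).
#' @return object of class `cnt_fixture`: list with `chain` (a
#'   `chain_model`), `cylinder` (a `cnt_cylinder`), `box` (a `periodic_box`).
#' @export
make_fixture <- function(kind = c("helix", "extended", "trpcage_like"),
                         n_residues = 20, placement = 10, radius = 6,
                         box_edge = 220, seed = 1, jitter = 0) {
  kind <- match.arg(kind)
  stopifnot(n_residues >= 2)
  if (placement <= radius)
    stop("placement (", placement, " A) must put the chain outside the tube (R0 = ",
         radius, " A)")
  set.seed(seed)
  if (kind == "trpcage_like") {
    if (n_residues != 20)
      stop("trpcage_like fixture is a fixed 20-residue mini-protein")
    seqs <- strsplit("NLYIQWLKDGGPSSGRPPPS", "")[[1]]
    ca <- .trpcage_ca()
  } else if (kind == "helix") {
    seqs <- rep(c("A", "L", "E", "K", "F"), length.out = n_residues)
    ca <- .helix_ca(n_residues)
  } else {
    seqs <- rep(c("S", "G", "V", "T"), length.out = n_residues)
    ca <- .zigzag_ca(n_residues)
  }
  ca <- .rot_z_to_x(ca)   # chain now extends along +x
  if (jitter > 0) ca <- ca + matrix(stats::rnorm(length(ca), sd = jitter),
                                    nrow(ca), 3)
  box <- periodic_box(box_edge)
  cyl <- cnt_cylinder(radius = radius)
  # translate: first CA exactly at `placement` from the axis, chain radial
  target <- c(box[["lx"]] / 2 + placement, box[["ly"]] / 2, box[["lz"]] / 2)
  ca <- sweep(ca, 2, target - ca[1, ], `+`)
  chain <- build_chain(seqs, ca)
  structure(list(chain = chain, cylinder = cyl, box = box, kind = kind,
                 placement = placement, seed = seed),
            class = "cnt_fixture")
}

#' @export
print.cnt_fixture <- function(x, ...) {
  cat(sprintf("cnt_fixture '%s': %d residues, R0 = %g A, box %g A, first CA at %g A\n",
              x$kind, length(x$chain$sequence), x$cylinder$radius,
              x$box[["lx"]], x$placement))
  invisible(x)
}

#' Native-contact (Go) list from a reference structure
#'
#' CA pairs at least `min_sep` residues apart whose reference distance is
#' below `cutoff` become attractive wells at the native distance.
#'
#' @param chain a `chain_model` (its `reference` coordinates are used).
#' @param cutoff contact distance cutoff (A).
#' @param min_sep minimum sequence separation.
#' @param eps well depth (kcal/mol).
#' @return data.frame with columns `i`, `j`, `r0`, `eps` suitable for
#'   [surrogate_ff_params()]'s `go` argument.
#' @export
derive_go_contacts <- function(chain, cutoff = 8, min_sep = 3, eps = 0.5) {
  ref <- chain$reference
  n <- nrow(ref)
  out <- list()
  for (i in seq_len(n - min_sep)) for (j in seq(i + min_sep, n)) {
    r0 <- sqrt(sum((ref[i, ] - ref[j, ])^2))
    if (r0 < cutoff) out[[length(out) + 1L]] <- c(i, j, r0)
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                      eps = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), r0 = m[, 3],
             eps = eps)
}

#' Flat-bottom restraints from a reference structure
#'
#' Builds a [restraint_set()] on the native CA-CA contact distances of the
#' reference coordinates.
#'
#' @inheritParams derive_go_contacts
#' @param weight restraint weight (default 0.006).
#' @param halfwidth flat-bottom half width (A).
#' @return a `restraint_set`.
#' @export
derive_restraints <- function(chain, cutoff = 8, min_sep = 3,
                              weight = 0.006, halfwidth = 0.1) {
  g <- derive_go_contacts(chain, cutoff = cutoff, min_sep = min_sep)
  restraint_set(g$i, g$j, g$r0, weight = weight, halfwidth = halfwidth)
}
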