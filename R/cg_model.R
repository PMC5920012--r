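# Coarse-grained chain representation: two interaction sites per residue
# (alpha-carbon + side-chain sphere), peptide-group sites derived as
# virtual-bond midpoints, an immovable infinite cylinder for the nanotube,
# and rectangular periodic boundaries.

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) return(c(NA_real_, NA_real_, NA_real_))
  v / n
}

# Deterministic unit vector perpendicular to u
.perp <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(a - sum(a * u) * u)
}

# Outward side-chain placement direction for residue i: the negative bisector
# of the local CA frame; terminal residues borrow the adjacent internal frame.
.sc_direction <- function(ca, i) {
  n <- nrow(ca)
  if (n < 3L) return(.perp(.unit(ca[2L, ] - ca[1L, ])))
  j <- min(max(i, 2L), n - 1L)
  u <- .unit(ca[j - 1L, ] - ca[j, ])
  w <- .unit(ca[j + 1L, ] - ca[j, ])
  b <- u + w
  if (any(is.na(b)) || sqrt(sum(b * b)) < 1e-8) .perp(u) else -.unit(b)
}

#' Build a coarse-grained chain model
#'
#' Constructs the two-site-per-residue representation: the supplied
#' alpha-carbon trace plus one side-chain sphere per residue, placed at a
#' residue-type-specific distance from the CA along the outward (negative
#' bisector) direction of the local CA frame. Glycine's side-chain site
#' coincides with its CA. Peptide-group sites are never stored; they are
#' derived as exact midpoints of consecutive CA pairs (see
#' [peptide_positions()]).
#'
#' @param sequence character vector of one-letter residue codes (length >= 2).
#' @param ca_positions numeric n x 3 matrix of CA coordinates (A).
#' @param sc_positions optional n x 3 matrix of explicit side-chain
#'   coordinates; when `NULL` they are placed by the bisector rule.
#' @param reference optional n x 3 matrix of reference CA coordinates used for
#'   restraints and RMSD (defaults to `ca_positions`).
#' @return An object of class `chain_model`: a list with elements `sequence`,
#'   `ca` (n x 3), `sc` (n x 3), `ca_mass`, `sc_mass` (amu) and `reference`.
#' @examples
#' ch <- build_chain(c("A", "A"), rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' peptide_positions(ch)   # one site at the bond midpoint
#' @export
build_chain <- function(sequence, ca_positions, sc_positions = NULL,
                        reference = NULL) {
  sequence <- .check_sequence(sequence)
  ca <- as.matrix(ca_positions)
  if (length(sequence) < 2L) stop("a chain needs at least 2 residues")
  if (!is.numeric(ca) || ncol(ca) != 3L || nrow(ca) != length(sequence))
    stop("ca_positions must be an n x 3 numeric matrix matching the sequence")
  if (!all(is.finite(ca))) stop("CA coordinates must be finite")
  bl <- sqrt(rowSums((ca[-1L, , drop = FALSE] - ca[-nrow(ca), , drop = FALSE])^2))
  if (any(bl <= 0)) stop("consecutive CA positions must be distinct")

  tab <- .aa_table[match(sequence, .aa_table$code), ]
  if (is.null(sc_positions)) {
    sc <- ca
    for (i in seq_along(sequence)) {
      d <- tab$sc_dist[i]
      if (d > 0) sc[i, ] <- ca[i, ] + d * .sc_direction(ca, i)
    }
  } else {
    sc <- as.matrix(sc_positions)
    if (!identical(dim(sc), dim(ca))) stop("sc_positions must match ca_positions")
    sc[sequence == "G", ] <- ca[sequence == "G", ]
  }
  if (is.null(reference)) reference <- ca
  structure(list(
    sequence = sequence, ca = unname(ca), sc = unname(sc),
    ca_mass = tab$ca_mass, sc_mass = tab$sc_mass,
    reference = unname(as.matrix(reference))
  ), class = "chain_model")
}

#' @export
print.chain_model <- function(x, ...) {
  cat(sprintf("chain_model: %d residues (%s)\n", length(x$sequence),
              paste(x$sequence, collapse = "")))
  cat(sprintf("  %d dynamic sites (%d CA + %d side chains), %d peptide groups\n",
              length(x$sequence) + sum(x$sequence != "G"),
              length(x$sequence), sum(x$sequence != "G"),
              length(x$sequence) - 1L))
  invisible(x)
}

#' Derived peptide-group site positions
#'
#' Peptide groups sit exactly half-way between consecutive CA sites; they are
#' derived interaction points (massless), never stored independently.
#'
#' @param chain a `chain_model`.
#' @return (n-1) x 3 matrix of midpoints (A).
#' @export
peptide_positions <- function(chain) {
  ca <- chain$ca
  (ca[-1L, , drop = FALSE] + ca[-nrow(ca), , drop = FALSE]) / 2
}

#' Internal coordinates of a CA trace
#'
#' Virtual-bond angles `theta` (one per CA triple, in (0, pi]), virtual-bond
#' dihedrals `gamma` (one per CA quadruple, IUPAC sign convention, in
#' (-pi, pi]; `NA` where a collinear triple leaves the dihedral undefined),
#' and polar angles `alpha`/`beta` locating each side-chain site in its local
#' CA frame (`NA` for glycine, whose side-chain vector is zero).
#'
#' @param chain a `chain_model`.
#' @return list with numeric vectors `theta` (n-2), `gamma` (n-3), `alpha`
#'   (n), `beta` (n).
#' @export
internal_coordinates <- function(chain) {
  ca <- chain$ca
  n <- nrow(ca)
  if (n < 3L) stop("need >= 3 residues for virtual-bond angles")
  theta <- vapply(seq_len(n - 2L), function(i) {
    u <- .unit(ca[i, ] - ca[i + 1L, ]); w <- .unit(ca[i + 2L, ] - ca[i + 1L, ])
    acos(max(-1, min(1, sum(u * w))))
  }, numeric(1))
  gamma <- if (n >= 4L) vapply(seq_len(n - 3L), function(i) {
    b1 <- ca[i + 1L, ] - ca[i, ]
    b2 <- ca[i + 2L, ] - ca[i + 1L, ]
    b3 <- ca[i + 3L, ] - ca[i + 2L, ]
    n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
    if (sqrt(sum(n1 * n1)) < 1e-10 || sqrt(sum(n2 * n2)) < 1e-10)
      return(NA_real_)  # collinear triple: dihedral undefined
    atan2(sum(.cross(n1, n2) * .unit(b2)), sum(n1 * n2))
  }, numeric(1)) else numeric(0)
  alpha <- beta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- chain$sc[i, ] - chain$ca[i, ]
    if (sqrt(sum(v * v)) < 1e-10) next
    j <- min(max(i, 2L), n - 1L)
    u <- .unit(ca[j - 1L, ] - ca[j, ]); w <- .unit(ca[j + 1L, ] - ca[j, ])
    eb <- .unit(u + w); et <- .unit(w - u)
    if (any(is.na(eb))) next
    en <- .cross(eb, et)
    vh <- .unit(v)
    alpha[i] <- acos(max(-1, min(1, sum(vh * en))))
    beta[i] <- atan2(sum(v * et), sum(v * eb))
  }
  list(theta = theta, gamma = gamma, alpha = alpha, beta = beta)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Carbon-nanotube cylinder
#'
#' The nanotube is an immovable infinite cylinder of radius `radius` whose
#' axis runs along z through the lateral box center. Each site type (the 20
#' side-chain types plus the peptide group, `"p"`) interacts with the tube
#' surface through a Kihara potential with its own well depth and zero-
#' crossing distance; the defaults model the carbon surface as
#' phenylalanine-like, uniformly for all side chains.
#'
#' @param radius tube radius R0 (A), > 0.
#' @param kihara data.frame with columns `type`, `epsilon` (kcal/mol), `sigma`
#'   (A); defaults to [default_kihara_table()].
#' @param weight dimensionless weight of the tube-protein energy (default 1).
#' @return object of class `cnt_cylinder`.
#' @export
cnt_cylinder <- function(radius = 6, kihara = default_kihara_table(),
                         weight = 1) {
  stopifnot(is.numeric(radius), length(radius) == 1L, radius > 0)
  kihara <- as.data.frame(kihara)
  need <- c(.aa_table$code, "p")
  if (!all(need %in% kihara$type))
    stop("kihara table must cover all residue types and the peptide group 'p'")
  if (any(kihara$epsilon <= 0) || any(kihara$sigma <= 0))
    stop("kihara epsilon and sigma must be positive")
  structure(list(radius = radius, kihara = kihara, weight = weight),
            class = "cnt_cylinder")
}

#' @export
print.cnt_cylinder <- function(x, ...) {
  cat(sprintf("cnt_cylinder: R0 = %g A, weight = %g, %d site types\n",
              x$radius, x$weight, nrow(x$kihara)))
  invisible(x)
}

#' Default tube-site Kihara parameter table
#'
#' One (epsilon, sigma) pair per side-chain type plus the peptide group.
#' The shipped defaults (side chains: epsilon 0.5 kcal/mol, sigma 4.0 A;
#' peptide group: 0.3 kcal/mol, 3.5 A) treat every side chain as
#' phenylalanine-like against the carbon surface and are fully overridable
#' via the config.
#'
#' @return data.frame with columns `type`, `epsilon`, `sigma`.
#' @export
default_kihara_table <- function() {
  data.frame(
    type = c(.aa_table$code, "p"),
    epsilon = c(rep(0.5, nrow(.aa_table)), 0.3),
    sigma = c(rep(4.0, nrow(.aa_table)), 3.5),
    stringsAsFactors = FALSE
  )
}

#' Rectangular periodic box
#'
#' @param lx,ly,lz box edge lengths (A), all > 0. The tube axis pierces the
#'   box at (lx/2, ly/2) parallel to z.
#' @return object of class `periodic_box` (numeric length-3 vector).
#' @export
periodic_box <- function(lx = 220, ly = lx, lz = lx) {
  stopifnot(lx > 0, ly > 0, lz > 0)
  structure(c(lx = lx, ly = ly, lz = lz), class = "periodic_box")
}

#' Minimum-image distance from sites to the tube axis
#'
#' The in-plane (x, y) minimum-image distance from each position to the
#' cylinder axis at (lx/2, ly/2); z never enters (the cylinder is infinite),
#' and the cylinder itself is not replicated in the lateral images.
#'
#' @param positions 3-vector or n x 3 matrix (A).
#' @param cylinder a `cnt_cylinder` (unused beyond its axis convention; kept
#'   for interface symmetry).
#' @param box a `periodic_box`.
#' @return numeric vector of axial distances r (A).
#' @export
axial_distance <- function(positions, cylinder, box) {
  p <- if (is.null(dim(positions))) matrix(positions, ncol = 3) else as.matrix(positions)
  dx <- p[, 1] - box[["lx"]] / 2
  dy <- p[, 2] - box[["ly"]] / 2
  dx <- dx - box[["lx"]] * round(dx / box[["lx"]])
  dy <- dy - box[["ly"]] * round(dy / box[["ly"]])
  sqrt(dx * dx + dy * dy)
}

#' Wrap a molecule into the primary box as a whole
#'
#' Translates all positions by an integer multiple of the box edges so the
#' geometric center lands inside `[0, L)` in each dimension. Because the whole
#' molecule shifts together, bonded sites are never split across images and
#' pairwise geometry is unchanged.
#'
#' @param positions n x 3 matrix (A).
#' @param box a `periodic_box`.
#' @return shifted n x 3 matrix.
#' @export
wrap_chain <- function(positions, box) {
  p <- as.matrix(positions)
  ctr <- colMeans(p)
  L <- as.numeric(box)
  shift <- -L * floor(ctr / L)
  sweep(p, 2, shift, `+`)
}
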