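# Ensemble analyses: Kabsch RMSD/RMSF, tube contact profiles, binding
# energies, Ward clustering of conformations.

#' Optimal-superposition RMSD
#'
#' Root-mean-square deviation between two coordinate sets after optimal
#' rigid-body superposition (Kabsch algorithm via SVD, proper rotation
#' enforced).
#'
#' @param coords_a,coords_b n x 3 matrices, n >= 3.
#' @return RMSD (A).
#' @export
rmsd <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  stopifnot(identical(dim(a), dim(b)), nrow(a) >= 3, ncol(a) == 3)
  bf <- superpose(a, b)
  sqrt(mean(rowSums((bf - b)^2)))
}

#' Superpose one coordinate set onto another
#'
#' Applies the optimal (Kabsch) rotation + translation of `mobile` onto
#' `target` and returns the transformed copy.
#'
#' @param mobile,target n x 3 matrices.
#' @return transformed `mobile`.
#' @export
superpose <- function(mobile, target) {
  a <- as.matrix(mobile); b <- as.matrix(target)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))        # t(a0) %*% b0
  d <- sign(det(s$u %*% t(s$v)))
  Dm <- diag(c(1, 1, d))
  rot <- s$u %*% Dm %*% t(s$v)       # a0 %*% rot approximates b0
  sweep(a0 %*% rot, 2, cb, `+`)
}

.archive_ca <- function(archive, subset = NULL) {
  if (is.null(archive$coords))
    stop("archive stores no coordinates")
  n <- length(archive$topology$sequence)
  ix <- if (is.null(subset)) seq_len(dim(archive$coords)[3]) else subset
  list(ca = archive$coords[seq_len(n), , ix, drop = FALSE], ix = ix, n = n)
}

#' Tube contact profile of an ensemble
#'
#' A residue is in contact in a snapshot when its CA lies within `cutoff` of
#' the tube *surface* (axial distance minus R0). Returns the per-residue
#' contact probability (fraction of snapshots in contact, optionally
#' ensemble-weighted) and the average contact fraction (snapshot average of
#' contacts / residues).
#'
#' @param archive an `ensemble_archive` with coordinates.
#' @param cylinder a `cnt_cylinder`; defaults to the archive topology's
#'   radius.
#' @param box a `periodic_box`; defaults to the archive topology's box.
#' @param cutoff contact cutoff from the tube surface (A), default 8.
#' @param weights optional per-snapshot weights (e.g. [wham_weights()]);
#'   default uniform.
#' @param subset optional snapshot indices.
#' @return object of class `contact_profile`: list with
#'   `per_residue_probability`, `average_contact_fraction`, `cutoff`.
#' @export
contact_profile <- function(archive, cylinder = NULL, box = NULL, cutoff = 8,
                            weights = NULL, subset = NULL) {
  x <- .archive_ca(archive, subset)
  if (!length(x$ix)) stop("empty snapshot subset")
  R0 <- if (!is.null(cylinder)) cylinder$radius else archive$topology$R0
  bx <- if (!is.null(box)) box else periodic_box(archive$topology$box[1],
                                                 archive$topology$box[2],
                                                 archive$topology$box[3])
  if (is.null(weights)) weights <- rep(1 / length(x$ix), length(x$ix))
  if (!is.null(subset)) weights <- weights / sum(weights)
  stopifnot(length(weights) == length(x$ix))
  contact <- matrix(FALSE, x$n, length(x$ix))
  for (k in seq_along(x$ix)) {
    r <- axial_distance(x$ca[, , k], NULL, bx)
    contact[, k] <- (r - R0) < cutoff
  }
  p <- as.vector(contact %*% weights)
  frac <- sum(colMeans(contact) * weights)
  structure(list(per_residue_probability = p,
                 average_contact_fraction = frac, cutoff = cutoff,
                 n_snapshots = length(x$ix)),
            class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile: %d residues over %d snapshots, average contact fraction %.4f (cutoff %g A)\n",
              length(x$per_residue_probability), x$n_snapshots,
              x$average_contact_fraction, x$cutoff))
  invisible(x)
}

#' Ensemble-averaged tube binding energy
#'
#' The (optionally weighted) mean of the weighted tube interaction energy
#' `w_cnt * u_cnt` over the snapshots; reported as a magnitude (the
#' conventional positive binding energy of an attractive interaction) with
#' the signed mean alongside.
#'
#' @param archive an `ensemble_archive`.
#' @param weights optional per-snapshot weights; default uniform.
#' @param subset optional snapshot indices.
#' @return list with `binding_energy` (magnitude, kcal/mol), `signed_mean`.
#' @export
binding_energy <- function(archive, weights = NULL, subset = NULL) {
  s <- archive$snapshots
  ix <- if (is.null(subset)) seq_len(nrow(s)) else subset
  if (!length(ix)) stop("empty snapshot subset")
  w_cnt <- if (is.null(archive$topology$w_cnt)) 1 else archive$topology$w_cnt
  if (is.null(weights)) weights <- rep(1 / length(ix), length(ix))
  weights <- weights / sum(weights)
  m <- sum(weights * w_cnt * s$u_cnt[ix])
  list(binding_energy = abs(m), signed_mean = m)
}

#' Pairwise RMSD matrix of archived snapshots
#'
#' @param archive an `ensemble_archive` with coordinates.
#' @param subset optional snapshot indices.
#' @return symmetric matrix of CA RMSD values (A).
#' @export
rmsd_matrix <- function(archive, subset = NULL) {
  x <- .archive_ca(archive, subset)
  k <- length(x$ix)
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    m[i, j] <- m[j, i] <- rmsd(x$ca[, , i], x$ca[, , j])
  }
  m
}

#' Ward clustering of conformations
#'
#' Agglomerative Ward minimum-variance clustering on the pairwise CA RMSD
#' matrix. In `fixed_k` mode the tree is cut into exactly `k` clusters and
#' the corresponding RMSD cutoff is recorded; in `fixed_cutoff` mode a
#' previously recorded cutoff is applied (the cross-simulation reference
#' protocol: derive the cutoff from a tube-free reference ensemble at
#' `k = 10`, then reuse it for every tube ensemble).
#'
#' @param archive an `ensemble_archive` with coordinates (or a precomputed
#'   distance matrix).
#' @param mode `"fixed_k"` or `"fixed_cutoff"`.
#' @param k cluster count for `fixed_k` (default 10).
#' @param cutoff tree height for `fixed_cutoff`.
#' @param subset optional snapshot indices.
#' @return object of class `cluster_result`: list with `labels`,
#'   `linkage_cutoff`, `cluster_populations`, `medoids` (snapshot index per
#'   cluster), `hclust`.
#' @export
ward_cluster <- function(archive, mode = c("fixed_k", "fixed_cutoff"),
                         k = 10, cutoff = NULL, subset = NULL) {
  mode <- match.arg(mode)
  dm <- if (is.matrix(archive)) archive else rmsd_matrix(archive, subset)
  ns <- nrow(dm)
  if (ns < 2) stop("need at least 2 snapshots to cluster")
  hc <- stats::hclust(stats::as.dist(dm), method = "ward.D2")
  if (mode == "fixed_k") {
    if (k > ns) stop("k (", k, ") exceeds the number of snapshots (", ns, ")")
    labels <- stats::cutree(hc, k = k)
    h <- c(0, sort(hc$height))
    # any height in [h[ns-k+1], h[ns-k+2]) yields exactly k clusters
    linkage_cutoff <- if (k == 1) max(hc$height) else
      (h[ns - k + 1] + h[ns - k + 2]) / 2
  } else {
    if (is.null(cutoff)) stop("fixed_cutoff mode needs a cutoff")
    labels <- stats::cutree(hc, h = cutoff)
    linkage_cutoff <- cutoff
  }
  pops <- as.vector(table(labels)) / ns
  medoids <- vapply(sort(unique(labels)), function(cl) {
    ix <- which(labels == cl)
    if (length(ix) == 1) return(ix)
    ix[which.min(rowSums(dm[ix, ix, drop = FALSE]))]
  }, numeric(1))
  structure(list(labels = labels, linkage_cutoff = linkage_cutoff,
                 cluster_populations = pops, medoids = as.integer(medoids),
                 hclust = hc),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d snapshots (cutoff %.4g), populations %s\n",
              length(x$cluster_populations), length(x$labels),
              x$linkage_cutoff,
              paste(sprintf("%.2f", x$cluster_populations), collapse = " ")))
  invisible(x)
}

#' Per-residue root-mean-square fluctuation
#'
#' Each snapshot's CA trace is superposed onto the reference (same Kabsch
#' algorithm as [rmsd()]); the RMSF of residue i is the root-mean-square
#' displacement of its CA from the reference across the subset.
#'
#' @param archive an `ensemble_archive` with coordinates.
#' @param reference n x 3 reference CA coordinates (e.g. the native
#'   structure or a cluster medoid).
#' @param subset optional snapshot indices.
#' @param align superpose each snapshot onto the reference first (default);
#'   set `FALSE` when the frames are already aligned.
#' @return numeric vector of per-residue RMSF values (A).
#' @export
rmsf <- function(archive, reference, subset = NULL, align = TRUE) {
  x <- .archive_ca(archive, subset)
  if (!length(x$ix)) stop("empty snapshot subset")
  ref <- as.matrix(reference)
  stopifnot(nrow(ref) == x$n)
  acc <- matrix(0, x$n, 1)
  for (kk in seq_along(x$ix)) {
    fit <- if (align) superpose(x$ca[, , kk], ref) else x$ca[, , kk]
    acc <- acc + rowSums((fit - ref)^2)
  }
  sqrt(as.vector(acc) / length(x$ix))
}
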