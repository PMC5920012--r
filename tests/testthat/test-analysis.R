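# Ensemble analyses against brute-force oracles: Kabsch RMSD, contact
# profiles, binding energies, Ward linkage, RMSF.

test_that("rmsd removes rigid motion and is symmetric", {
  set.seed(1)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0)
  b <- sweep(a %*% random_rotation(), 2, c(4, -2, 9), `+`)
  expect_lt(rmsd(a, b), 1e-10)
  for (k in 1:50) {
    x <- matrix(rnorm(24), 8, 3)
    y <- matrix(rnorm(24), 8, 3)
    expect_equal(rmsd(x, y), rmsd(y, x), tolerance = 1e-10)
    expect_equal(rmsd(x, x), 0)
  }
})

test_that("rmsd agrees with an independent rotation-search oracle and bio3d", {
  set.seed(7)
  a <- matrix(rnorm(12, sd = 2), 4, 3)
  b <- matrix(rnorm(12, sd = 2), 4, 3)
  ours <- rmsd(a, b)

  # oracle: random search over rotations + Nelder-Mead refinement on Euler
  # angles, fully independent of the SVD path
  rot_euler <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  obj <- function(ang) sqrt(mean(rowSums((a0 %*% rot_euler(ang) - b0)^2)))
  best <- Inf; best_ang <- c(0, 0, 0)
  for (k in 1:20000) {
    ang <- runif(3, -pi, pi)
    v <- obj(ang)
    if (v < best) { best <- v; best_ang <- ang }
  }
  ref <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))$value
  expect_lt(abs(ours - ref), 1e-3)

  # independent library cross-check
  bfit <- suppressWarnings(bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a))))
  brmsd <- sqrt(mean(colSums(matrix((bfit - as.vector(t(b)))^2, 3))))
  expect_equal(ours, brmsd, tolerance = 1e-6)
})

test_that("contact profile matches a naive per-frame recount", {
  set.seed(11)
  n <- 10; k <- 25; R0 <- 6; box <- 220
  frames <- lapply(1:k, function(i) {
    r <- runif(n, R0 + 0.5, R0 + 20)
    ang <- runif(n, 0, 2 * pi)
    cbind(box / 2 + r * cos(ang), box / 2 + r * sin(ang), runif(n, 0, 50))
  })
  arch <- coord_archive(frames, R0 = R0, box = box)
  cp <- contact_profile(arch, cutoff = 8)
  # brute force
  p_ref <- numeric(n); frac_ref <- 0
  for (f in frames) {
    r <- sqrt((f[, 1] - box / 2)^2 + (f[, 2] - box / 2)^2)
    inc <- (r - R0) < 8
    p_ref <- p_ref + inc
    frac_ref <- frac_ref + mean(inc)
  }
  expect_equal(cp$per_residue_probability, p_ref / k)
  expect_equal(cp$average_contact_fraction, frac_ref / k)
  expect_true(all(cp$per_residue_probability >= 0 &
                  cp$per_residue_probability <= 1))

  # single-frame example: 3 of 10 residues within the cutoff
  f1 <- frames[[1]]
  r <- sqrt((f1[, 1] - box / 2)^2 + (f1[, 2] - box / 2)^2)
  near <- order(r)[1:3]
  f1[near, 1] <- box / 2 + R0 + 2; f1[near, 2] <- box / 2
  f1[-near, 1] <- box / 2 + R0 + 50; f1[-near, 2] <- box / 2
  cp1 <- contact_profile(coord_archive(list(f1), R0 = R0, box = box))
  expect_equal(cp1$average_contact_fraction, 0.3)
  expect_equal(sort(which(cp1$per_residue_probability == 1)), sort(near))
  expect_equal(sum(cp1$per_residue_probability), 3)

  # all far -> zero
  far <- lapply(frames, function(f) { f[, 1] <- box / 2 + 60; f[, 2] <- box / 2; f })
  cp0 <- contact_profile(coord_archive(far, R0 = R0, box = box))
  expect_equal(cp0$average_contact_fraction, 0)
  expect_equal(cp0$per_residue_probability, rep(0, n))
})

test_that("binding energy is the weighted mean magnitude of the tube term", {
  u_cnt <- c(-3, -5, -1, 0.5)
  frames <- replicate(4, matrix(rnorm(9) + 110, 3, 3), simplify = FALSE)
  arch <- coord_archive(frames, u_cnt = u_cnt, w_cnt = 1)
  be <- binding_energy(arch)
  expect_equal(be$binding_energy, abs(mean(u_cnt)))
  expect_equal(be$signed_mean, mean(u_cnt))
  # single snapshot
  be1 <- binding_energy(arch, subset = 2)
  expect_equal(be1$binding_energy, 5)
  # explicit weights
  w <- c(0.4, 0.3, 0.2, 0.1)
  be_w <- binding_energy(arch, weights = w)
  expect_equal(be_w$signed_mean, sum(w * u_cnt))
  # tube weight folds in
  arch2 <- coord_archive(frames, u_cnt = u_cnt, w_cnt = 2)
  expect_equal(binding_energy(arch2)$signed_mean, 2 * mean(u_cnt))
})

test_that("ward clustering separates rigid groups and matches a brute-force linkage", {
  set.seed(17)
  base1 <- matrix(rnorm(15), 5, 3)
  base2 <- matrix(rnorm(15, sd = 3), 5, 3)   # a genuinely different shape
  frames <- c(
    lapply(1:5, function(i) sweep(base1 %*% random_rotation(), 2, rnorm(3), `+`)),
    lapply(1:5, function(i) sweep(base2 %*% random_rotation(), 2, rnorm(3), `+`))
  )
  # rigid copies: zero within-group RMSD, large between-group RMSD
  dm <- matrix(0, 10, 10)
  for (i in 1:9) for (j in (i + 1):10)
    dm[i, j] <- dm[j, i] <- rmsd(frames[[i]], frames[[j]])
  cl <- ward_cluster(dm, "fixed_k", k = 2)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  expect_false(cl$labels[1] == cl$labels[6])
  expect_equal(sum(cl$cluster_populations), 1)

  # brute-force Ward (Lance-Williams) merge sequence on a random 6x6 matrix
  d0 <- matrix(0, 6, 6)
  for (i in 1:5) for (j in (i + 1):6) d0[i, j] <- d0[j, i] <- runif(1, 1, 10)
  hc <- stats::hclust(stats::as.dist(d0), method = "ward.D2")
  # oracle: explicit agglomeration minimizing the Ward.D2 criterion
  active <- rep(TRUE, 6); dm2 <- d0^2; sizes <- rep(1, 6)
  merges <- list()
  while (length(merges) < 5) {
    ids <- which(active)
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(ids)) for (jj in seq_len(ii - 1)) {
      i <- ids[ii]; j <- ids[jj]
      if (dm2[i, j] < bestd) { bestd <- dm2[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- sort(c(i, j))
    new <- length(sizes) + 1L
    dm2 <- rbind(cbind(dm2, 0), 0)
    sizes <- c(sizes, sizes[i] + sizes[j])
    for (k in ids) {
      if (k == i || k == j) next
      dm2[new, k] <- dm2[k, new] <-
        ((sizes[i] + sizes[k]) * dm2[i, k] + (sizes[j] + sizes[k]) * dm2[j, k] -
         sizes[k] * dm2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    active[c(i, j)] <- FALSE
    active <- c(active, TRUE)
  }
  # map hclust's merge matrix to the same (cluster id) encoding
  to_id <- function(x) ifelse(x < 0, -x, x + 6)
  hc_merges <- lapply(seq_len(nrow(hc$merge)), function(r)
    sort(to_id(hc$merge[r, ])))
  expect_equal(hc_merges, merges)

  # fixed_k then fixed_cutoff at the recorded cutoff reproduces the labels
  cl10 <- ward_cluster(dm, "fixed_k", k = 4)
  cl_cut <- ward_cluster(dm, "fixed_cutoff", cutoff = cl10$linkage_cutoff)
  expect_equal(unname(cl_cut$labels), unname(cl10$labels))

  # a cutoff below every pairwise distance yields all singletons
  cl_s <- ward_cluster(dm, "fixed_cutoff", cutoff = min(dm[dm > 0]) / 2)
  expect_equal(length(unique(cl_s$labels)), 10L)
  expect_error(ward_cluster(dm, "fixed_k", k = 11), "exceeds")
})

test_that("rmsf reproduces a constructed half-displaced residue", {
  set.seed(23)
  ref <- matrix(rnorm(30, sd = 4), 10, 3)
  # displace residue 4 by 1 A along x in half of 20 pre-aligned snapshots:
  # its RMSF is sqrt(10 * 1^2 / 20) = sqrt(0.5) exactly
  frames <- lapply(1:20, function(k) {
    f <- ref
    if (k <= 10) f[4, 1] <- f[4, 1] + 1
    f
  })
  arch <- coord_archive(frames, box = 220)
  rf <- rmsf(arch, ref, align = FALSE)
  expect_equal(rf[4], sqrt(0.5), tolerance = 1e-12)
  expect_equal(rf[-4], rep(0, 9))
  # with superposition on, the aligned result matches the direct formula
  rf_al <- rmsf(arch, ref)
  acc <- matrix(0, 10, 1)
  for (f in frames) {
    fit <- superpose(f, ref)
    acc <- acc + rowSums((fit - ref)^2)
  }
  expect_equal(rf_al, sqrt(as.vector(acc) / 20), tolerance = 1e-12)

  # identical copies -> all zeros; rigid motions per frame leave RMSF alone
  same <- coord_archive(lapply(1:5, function(i) ref), box = 220)
  expect_equal(rmsf(same, ref), rep(0, 10), tolerance = 1e-10)
  moved <- coord_archive(lapply(1:5, function(i)
    sweep(ref %*% random_rotation(), 2, rnorm(3, sd = 5), `+`)), box = 220)
  expect_equal(rmsf(moved, ref), rep(0, 10), tolerance = 1e-8)
})
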