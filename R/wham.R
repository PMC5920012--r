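# Binless WHAM (per-sample log-sum-exp form) over a multi-temperature
# archive, heat-capacity profiles and reweighted observables.
#
# Because the implemented potential is temperature-independent, the
# fluctuation form of the heat capacity reduces exactly to
#   Cv(T) = (<U^2>_T - <U>_T^2) / (R T^2),
# computed from WHAM-reweighted averages.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Solve the WHAM self-consistency equations
#'
#' Binless (per-sample) WHAM on the potential energies of a multi-temperature
#' archive: iterates the dimensionless free-energy shifts `f_k` of the
#' simulated temperatures to self-consistency (all accumulation in log
#' space). `f_1` is pinned to 0.
#'
#' @param archive an `ensemble_archive`, or a data.frame with columns
#'   `u_total` and `temperature`.
#' @param tol convergence tolerance on `max |delta f_k|`.
#' @param max_iter iteration cap.
#' @return object of class `wham_fit`: list with `f` (free-energy shifts),
#'   `temperatures`, `beta`, `n_k`, `u` (snapshot energies), `iterations`,
#'   `residual`.
#' @export
solve_wham <- function(archive, tol = 1e-10, max_iter = 10000) {
  s <- if (inherits(archive, "ensemble_archive")) archive$snapshots else archive
  u <- s$u_total
  temps <- sort(unique(s$temperature))
  K <- length(temps)
  beta <- 1 / (cnt_constants$R_KCAL * temps)
  n_k <- vapply(temps, function(t) sum(s$temperature == t), numeric(1))

  if (K >= 2) {
    # adjacent simulated temperatures must sample overlapping energy ranges
    rng <- vapply(temps, function(t) range(u[s$temperature == t]), numeric(2))
    for (k in seq_len(K - 1)) {
      if (rng[1, k + 1] > rng[2, k] || rng[1, k] > rng[2, k + 1])
        stop(sprintf(paste0("energy histograms at %g K and %g K do not ",
                            "overlap (gap %g..%g kcal/mol); WHAM cannot ",
                            "bridge them"), temps[k], temps[k + 1],
                     min(rng[2, k], rng[2, k + 1]),
                     max(rng[1, k], rng[1, k + 1])))
    }
  }

  f <- numeric(K)
  bu <- outer(u, beta)              # n x K matrix beta_k * u_n
  logN <- log(n_k)
  iter <- 0L; resid <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    # log denominator per sample: logsumexp_k(log N_k + f_k - beta_k u_n)
    a <- sweep(-bu, 2, logN + f, `+`)
    amax <- apply(a, 1, max)
    logden <- amax + log(rowSums(exp(a - amax)))
    fnew <- -vapply(seq_len(K), function(k)
      .logsumexp(-bu[, k] - logden), numeric(1))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %g)",
                 max_iter, resid))
  structure(list(f = f, temperatures = temps, beta = beta, n_k = n_k,
                 u = u, iterations = iter, residual = resid),
            class = "wham_fit")
}

#' @export
print.wham_fit <- function(x, ...) {
  cat(sprintf("wham_fit: %d temperatures (%g-%g K), %d samples, %d iterations (residual %g)\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), length(x$u), x$iterations, x$residual))
  invisible(x)
}

#' Per-snapshot WHAM weights at a target temperature
#'
#' Normalized weights (sum 1) of every archived snapshot in the canonical
#' ensemble at temperature `T`.
#'
#' @param fit a `wham_fit`.
#' @param T target temperature (K).
#' @return numeric weight vector, one entry per snapshot.
#' @export
wham_weights <- function(fit, T) {
  beta_t <- 1 / (cnt_constants$R_KCAL * T)
  a <- sweep(-outer(fit$u, fit$beta), 2, log(fit$n_k) + fit$f, `+`)
  amax <- apply(a, 1, max)
  logden <- amax + log(rowSums(exp(a - amax)))
  lw <- -beta_t * fit$u - logden
  w <- exp(lw - .logsumexp(lw))
  w / sum(w)
}

#' Reweighted ensemble average
#'
#' Weight-averaged expectation of a per-snapshot observable at an arbitrary
#' target temperature.
#'
#' @param fit a `wham_fit`.
#' @param observable numeric vector, one value per snapshot.
#' @param T target temperature (K).
#' @return the expectation value.
#' @export
reweighted_observable <- function(fit, observable, T) {
  stopifnot(length(observable) == length(fit$u))
  sum(wham_weights(fit, T) * observable)
}

#' Heat-capacity profile
#'
#' `Cv(T) = (<U^2>_T - <U>_T^2) / (R T^2)` on a temperature grid, from
#' WHAM-reweighted averages. The peak is the global grid maximum; all local
#' maxima with at least 5 percent prominence (relative to the profile range)
#' are reported for multimodal profiles.
#'
#' @param fit a `wham_fit`.
#' @param T_grid temperature grid (K); default 1 K spacing across the
#'   simulated range.
#' @return object of class `heat_capacity_profile`: list with `profile`
#'   (data.frame: T, cv, u_mean), `peak_temperature`, `peaks` (local maxima
#'   passing the prominence filter), `f`.
#' @export
heat_capacity <- function(fit, T_grid = NULL) {
  if (is.null(T_grid))
    T_grid <- seq(min(fit$temperatures), max(fit$temperatures), by = 1)
  if (!length(T_grid)) stop("empty temperature grid")
  R <- cnt_constants$R_KCAL
  cv <- numeric(length(T_grid)); um <- numeric(length(T_grid))
  for (i in seq_along(T_grid)) {
    w <- wham_weights(fit, T_grid[i])
    m1 <- sum(w * fit$u)
    v <- sum(w * (fit$u - m1)^2)
    um[i] <- m1
    cv[i] <- v / (R * T_grid[i]^2)
  }
  ipk <- which.max(cv)
  loc <- which(diff(sign(diff(cv))) == -2) + 1L
  prom <- diff(range(cv)) * 0.05
  loc <- loc[cv[loc] >= min(cv) + prom]
  structure(list(profile = data.frame(T = T_grid, cv = cv, u_mean = um),
                 peak_temperature = T_grid[ipk],
                 peaks = T_grid[union(loc, ipk)], f = fit$f),
            class = "heat_capacity_profile")
}

#' @export
print.heat_capacity_profile <- function(x, ...) {
  cat(sprintf("heat_capacity_profile: %d grid points, peak at %g K (Cv = %.4g kcal/mol/K)\n",
              nrow(x$profile), x$peak_temperature, max(x$profile$cv)))
  invisible(x)
}
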