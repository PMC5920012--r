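# Multiplexed replica-exchange molecular dynamics: temperature ladder,
# Metropolis exchanges between neighboring temperatures (even/odd alternating
# sweeps), several replicas per temperature.

#' Temperature ladder
#'
#' @param temperatures strictly increasing temperatures (K).
#' @param replicas_per_temperature trajectories per temperature (multiplexed
#'   replica exchange uses more than one).
#' @return object of class `temperature_ladder`.
#' @export
temperature_ladder <- function(temperatures, replicas_per_temperature = 2L) {
  temperatures <- as.numeric(temperatures)
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  structure(list(temperatures = temperatures,
                 replicas_per_temperature = as.integer(replicas_per_temperature)),
            class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("temperature_ladder: %d temperatures (%g-%g K), %d replica(s)/T = %d trajectories\n",
              length(x$temperatures), min(x$temperatures),
              max(x$temperatures), x$replicas_per_temperature,
              length(x$temperatures) * x$replicas_per_temperature))
  invisible(x)
}

#' Default multiplexed replica-exchange ladder
#'
#' The standard 36-temperature production ladder: 250-370 K every 5 K,
#' 370-460 K every 10 K, 460-500 K every 20 K; with the default two replicas
#' per temperature this yields 72 trajectories.
#'
#' @param replicas_per_temperature trajectories per temperature (default 2).
#' @return a `temperature_ladder` with 36 temperatures from 250 to 500 K.
#' @export
mremd_ladder <- function(replicas_per_temperature = 2L) {
  temperature_ladder(c(seq(250, 370, by = 5), seq(380, 460, by = 10),
                       c(480, 500)),
                     replicas_per_temperature)
}

#' Metropolis exchange attempt between two replicas
#'
#' Accepts the temperature swap with probability
#' `min(1, exp((beta_i - beta_j) (U_i - U_j)))` where `beta = 1/(R T)`.
#' Consumes one uniform deviate from the current RNG stream.
#'
#' @param replica_i,replica_j lists with elements `U` (potential energy,
#'   kcal/mol) and `T` (current temperature, K).
#' @return list with `accepted` (logical), `prob`, and `delta` (the log
#'   acceptance argument).
#' @export
attempt_exchange <- function(replica_i, replica_j) {
  R <- cnt_constants$R_KCAL
  bi <- 1 / (R * replica_i$T); bj <- 1 / (R * replica_j$T)
  delta <- (bi - bj) * (replica_i$U - replica_j$U)
  prob <- min(1, exp(delta))
  list(accepted = stats::runif(1) < prob, prob = prob, delta = delta)
}

# per-replica and exchange seeds derived reproducibly from the master seed
.mremd_seeds <- function(seed, n_replicas) {
  set.seed(seed)
  list(replica = sample.int(.Machine$integer.max %/% 2, n_replicas),
       exchange = sample.int(.Machine$integer.max %/% 2, 1))
}

#' Run multiplexed replica-exchange molecular dynamics
#'
#' Alternates Langevin MD cycles (each replica at its current temperature)
#' with sweeps of Metropolis exchanges between adjacent temperatures. Sweeps
#' alternate even/odd neighbor pairings; within a multiplexed temperature
#' slot the exchange partner is drawn uniformly at random. On acceptance the
#' two replicas swap temperature indices and velocities are rescaled by
#' `sqrt(T_new/T_old)`. One snapshot per replica per cycle (plus the initial
#' state) is appended to the archive.
#'
#' Each replica owns an RNG stream derived from `seed`, independent of the
#' exchange stream, so a run with `exchange = FALSE` reproduces independent
#' Langevin trajectories bit for bit.
#'
#' @param system a `cg_system`.
#' @param ladder a `temperature_ladder`.
#' @param n_cycles number of MD/exchange cycles.
#' @param steps_per_cycle MD steps between exchange sweeps.
#' @param dt time step (fs).
#' @param friction_scale Langevin friction multiplier.
#' @param seed master seed (required: the run is stochastic).
#' @param exchange set `FALSE` to disable exchanges (independent
#'   trajectories).
#' @param store_coords keep snapshot coordinates in the archive.
#' @return list with `archive` (an `ensemble_archive`), `exchange_log`
#'   (data.frame: cycle, temp_i, temp_j, replica_a, replica_b, delta,
#'   accepted), and `acceptance_by_pair` (data.frame per adjacent
#'   temperature pair).
#' @export
run_mremd <- function(system, ladder, n_cycles, steps_per_cycle = 1000,
                      dt = 4.89, friction_scale = 0.01, seed,
                      exchange = TRUE, store_coords = TRUE) {
  stopifnot(inherits(ladder, "temperature_ladder"), n_cycles >= 0)
  temps <- ladder$temperatures
  m <- ladder$replicas_per_temperature
  n_rep <- length(temps) * m
  seeds <- .mremd_seeds(seed, n_rep)

  # replica r starts at temperature slot ceiling(r/m)
  temp_index <- rep(seq_along(temps), each = m)
  pos <- replicate(n_rep, system_positions(system), simplify = FALSE)
  vel <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    set.seed(seeds$replica[r])
    vel[[r]] <- init_velocities(system$mass, temps[temp_index[r]],
                                remove_com = FALSE)
  }

  snaps <- list(); coords <- list(); xlog <- list()
  take_snapshot <- function(cycle) {
    for (r in seq_len(n_rep)) {
      e <- total_energy(.with_positions(system, pos[[r]]))
      snaps[[length(snaps) + 1L]] <<- data.frame(
        replica = r, temp_index = temp_index[r],
        temperature = temps[temp_index[r]],
        step = cycle * steps_per_cycle,
        u_protein = e$u_protein, u_cnt = e$u_cnt_total,
        u_restraint = e$u_restraint, u_total = e$u_total)
      if (store_coords) coords[[length(coords) + 1L]] <<- pos[[r]]
    }
  }
  take_snapshot(0L)

  for (cycle in seq_len(n_cycles)) {
    for (r in seq_len(n_rep)) {
      set.seed(seeds$replica[r] + cycle)
      run <- run_md(system, steps = steps_per_cycle, dt = dt,
                    ensemble = "langevin", T_set = temps[temp_index[r]],
                    friction_scale = friction_scale, seed = NULL,
                    positions = pos[[r]], velocities = vel[[r]],
                    sample_every = steps_per_cycle)
      pos[[r]] <- run$positions
      vel[[r]] <- run$velocities
    }
    if (exchange && length(temps) > 1) {
      set.seed(seeds$exchange + cycle)
      u_pot <- vapply(seq_len(n_rep), function(r)
        total_energy(.with_positions(system, pos[[r]]))$u_total, numeric(1))
      first <- if (cycle %% 2) 1L else 2L
      pair_starts <- if (first <= length(temps) - 1L)
        seq(first, length(temps) - 1L, by = 2L) else integer(0)
      for (t in pair_starts) {
        lo <- sample(which(temp_index == t))
        hi <- sample(which(temp_index == t + 1L))
        for (k in seq_len(min(length(lo), length(hi)))) {
          a <- lo[k]; b <- hi[k]
          att <- attempt_exchange(list(U = u_pot[a], T = temps[t]),
                                  list(U = u_pot[b], T = temps[t + 1L]))
          xlog[[length(xlog) + 1L]] <- data.frame(
            cycle = cycle, temp_i = t, temp_j = t + 1L, replica_a = a,
            replica_b = b, delta = att$delta, accepted = att$accepted)
          if (att$accepted) {
            temp_index[a] <- t + 1L; temp_index[b] <- t
            vel[[a]] <- vel[[a]] * sqrt(temps[t + 1L] / temps[t])
            vel[[b]] <- vel[[b]] * sqrt(temps[t] / temps[t + 1L])
          }
        }
      }
    }
    take_snapshot(cycle)
  }

  snap_df <- do.call(rbind, snaps)
  coord_arr <- if (store_coords)
    array(unlist(coords), c(system$nsite, 3, length(coords)))
  else NULL
  xdf <- if (length(xlog)) do.call(rbind, xlog) else
    data.frame(cycle = integer(0), temp_i = integer(0), temp_j = integer(0),
               replica_a = integer(0), replica_b = integer(0),
               delta = numeric(0), accepted = logical(0))
  acc <- if (nrow(xdf))
    do.call(rbind, lapply(split(xdf, xdf$temp_i), function(d) data.frame(
      temp_i = d$temp_i[1], temp_j = d$temp_j[1], attempts = nrow(d),
      accepted = sum(d$accepted), rate = mean(d$accepted))))
  else data.frame(temp_i = integer(0), temp_j = integer(0),
                  attempts = integer(0), accepted = integer(0),
                  rate = numeric(0))
  topo <- list(sequence = system$chain$sequence,
               w_cnt = if (is.null(system$cylinder)) 0 else system$cylinder$weight,
               w_restraint = if (is.null(system$restraints)) 0.006 else
                 system$restraints$weight,
               R0 = if (is.null(system$cylinder)) NA else system$cylinder$radius,
               box = as.numeric(system$box))
  arch <- ensemble_archive(snap_df, coord_arr, topo,
                           list(seed = seed, n_cycles = n_cycles,
                                steps_per_cycle = steps_per_cycle, dt = dt))
  list(archive = arch, exchange_log = xdf, acceptance_by_pair = acc,
       final_temp_index = temp_index)
}

.with_positions <- function(system, pos) {
  system$chain <- system_chain(system, pos)
  system
}
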