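#' Exponentially spaced temperature ladder
#'
#' T_i = T_min * (T_max/T_min)^(i/(n-1)), i = 0..n-1: consecutive ratios are
#' constant and the endpoints are exact. The reference protocol spans
#' 100-700 K.
#'
#' @param n number of replicas (>= 2).
#' @param T_min,T_max ladder endpoints, K.
#' @return numeric vector of temperatures, class `temperature_ladder`.
#' @export
make_ladder <- function(n, T_min = 100, T_max = 700) {
  if (n < 2L) stop("need at least 2 replicas")
  if (!(T_min > 0 && T_max > T_min)) stop("invalid temperature bounds")
  structure(T_min * (T_max / T_min)^((seq_len(n) - 1) / (n - 1)),
            class = "temperature_ladder")
}

#' Metropolis replica-exchange acceptance
#'
#' Accepts a swap between replicas at temperatures T_i and T_j with potential
#' energies U_i and U_j with probability
#' min(1, exp((1/kT_i - 1/kT_j) (U_i - U_j))).
#'
#' @param U_i,U_j potential energies, kJ/mol.
#' @param T_i,T_j temperatures, K.
#' @return list(`accepted`, `probability`).
#' @export
attempt_exchange <- function(U_i, U_j, T_i, T_j) {
  delta <- (1 / (KB * T_i) - 1 / (KB * T_j)) * (U_i - U_j)
  p <- min(1, exp(delta))
  list(accepted = runif(1) < p, probability = p)
}

#' Run replica-exchange CG-MD
#'
#' Sequential REMD driver: each temperature slot runs Langevin segments of
#' `exchange_interval` steps; at each attempt, neighbor pairs are tried in
#' alternating even/odd sweeps with the Metropolis criterion, and accepted
#' swaps exchange configurations between temperature slots with velocities
#' rescaled by sqrt(T_new/T_old). Snapshot energies are recorded per
#' temperature every `record_interval` steps (via the per-segment stride).
#' Occupancy bookkeeping (which replica is at which temperature) is exact:
#' the replica-to-temperature assignment is a permutation at all times.
#'
#' @inheritParams run_cg_md
#' @param ladder a [make_ladder()] temperature ladder.
#' @param exchange_interval steps between exchange attempts.
#' @param n_steps total steps per replica.
#' @param positions starting coordinates, either one `n x 3` matrix used for
#'   all replicas or a list, one per temperature slot.
#' @param seed master seed; per-replica segment streams are derived from it
#'   (sequential execution makes the run deterministic).
#' @return a `replica_ensemble`: `ladder`, `energies` (list per temperature
#'   of potential-energy series), `frames` (list per temperature of final
#'   segment frames), `exchanges` (data.frame: step, slot_i, slot_j,
#'   probability, accepted), `occupancy` (matrix: attempts+1 rows, replica id
#'   per temperature slot), `final` (per-slot state).
#' @export
run_remd <- function(topology, tables, bonded, config, ladder,
                     exchange_interval, n_steps, positions, seed = 1L) {
  n_rep <- length(ladder)
  if (is.matrix(positions) || is.data.frame(positions)) {
    positions <- replicate(n_rep, as.matrix(positions), simplify = FALSE)
  }
  stopifnot(length(positions) == n_rep)
  set.seed(seed)
  states <- vector("list", n_rep)
  for (k in seq_len(n_rep)) {
    states[[k]] <- list(
      pos = positions[[k]],
      vel = maxwell_velocities(topology$sites$mass, ladder[k]),
      U = NA_real_)
  }
  replica_at <- seq_len(n_rep)  # replica id occupying each temperature slot
  n_attempts <- if (exchange_interval > n_steps) 0L
                else n_steps %/% exchange_interval
  n_segments <- max(1L, n_attempts)
  seg_steps <- if (n_attempts > 0L) exchange_interval else n_steps
  if (seg_steps %% config$stride != 0L) {
    stop("exchange_interval must be a multiple of the recording stride ",
         "so exchange energies are current")
  }
  energies <- rep(list(numeric()), n_rep)
  frames <- rep(list(list()), n_rep)
  exchanges <- list()
  occupancy <- matrix(NA_integer_, n_attempts + 1L, n_rep)
  occupancy[1L, ] <- replica_at
  for (seg in seq_len(n_segments)) {
    for (k in seq_len(n_rep)) {
      cfg <- config
      cfg$temperature <- ladder[k]
      traj <- run_cg_md(topology, tables, bonded, cfg, seg_steps,
                        states[[k]]$pos, velocities = states[[k]]$vel,
                        set_seed = FALSE)
      states[[k]]$pos <- traj$final_pos
      states[[k]]$vel <- traj$final_vel
      states[[k]]$U <- traj$energies$potential[nrow(traj$energies)]
      energies[[k]] <- c(energies[[k]], traj$energies$potential[-1])
      frames[[k]][[length(frames[[k]]) + 1L]] <- traj$final_pos
    }
    if (seg <= n_attempts) {
      start <- if (seg %% 2L == 1L) 1L else 2L
      pairs <- if (start > n_rep - 1L) integer() else
        seq(start, n_rep - 1L, by = 2L)
      for (i in pairs) {
        j <- i + 1L
        ex <- attempt_exchange(states[[i]]$U, states[[j]]$U,
                               ladder[i], ladder[j])
        exchanges[[length(exchanges) + 1L]] <- data.frame(
          step = seg * seg_steps, slot_i = i, slot_j = j,
          probability = ex$probability, accepted = ex$accepted)
        if (ex$accepted) {
          tmp <- states[[i]]; states[[i]] <- states[[j]]; states[[j]] <- tmp
          states[[i]]$vel <- states[[i]]$vel * sqrt(ladder[i] / ladder[j])
          states[[j]]$vel <- states[[j]]$vel * sqrt(ladder[j] / ladder[i])
          replica_at[c(i, j)] <- replica_at[c(j, i)]
        }
      }
      occupancy[seg + 1L, ] <- replica_at
    }
  }
  exchanges <- if (length(exchanges)) do.call(rbind, exchanges) else
    data.frame(step = integer(), slot_i = integer(), slot_j = integer(),
               probability = numeric(), accepted = logical())
  structure(list(ladder = ladder, energies = energies, frames = frames,
                 exchanges = exchanges, occupancy = occupancy,
                 final = states), class = "replica_ensemble")
}

#' Exchange acceptance report
#'
#' Per-neighbor-pair acceptance rates with an out-of-band flag. Pairs with no
#' attempts are reported as `NA` (undefined), not 0. The reference protocol
#' sizes the ladder so rates stay within 20-40%.
#'
#' @param ensemble a `replica_ensemble`.
#' @param band acceptable acceptance-rate band.
#' @return data.frame: `slot_i`, `slot_j`, `attempts`, `accepted`, `rate`,
#'   `in_band`.
#' @export
acceptance_report <- function(ensemble, band = c(0.2, 0.4)) {
  n_rep <- length(ensemble$ladder)
  ex <- ensemble$exchanges
  out <- lapply(seq_len(n_rep - 1L), function(i) {
    rows <- ex[ex$slot_i == i & ex$slot_j == i + 1L, , drop = FALSE]
    n <- nrow(rows)
    acc <- sum(rows$accepted)
    rate <- if (n > 0L) acc / n else NA_real_
    data.frame(slot_i = i, slot_j = i + 1L, attempts = n, accepted = acc,
               rate = rate,
               in_band = if (n > 0L) rate >= band[1] & rate <= band[2]
                         else NA)
  })
  do.call(rbind, out)
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat("Replica ensemble:", length(x$ladder), "replicas,",
      sprintf("%.0f-%.0f K,", min(x$ladder), max(x$ladder)),
      nrow(x$exchanges), "exchange attempts\n")
  invisible(x)
}
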