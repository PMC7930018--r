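#' Langevin integration parameters
#'
#' Parameter bundle for the BAOAB Langevin integrator.
#'
#' @param n_steps number of integration steps.
#' @param timestep timestep in ps (default 0.01).
#' @param friction friction coefficient in 1/ps; 0 gives the deterministic
#'   (velocity-Verlet) limit.
#' @param temperature thermostat temperature in K; may be a vector of length
#'   `n_steps` for annealing schedules.
#' @param save_interval store a snapshot every this many steps.
#' @param rng_seed integer seed; identical seeds give identical trajectories.
#' @return a list of class `langevin_params`.
#' @export
langevin_params <- function(n_steps, timestep = 0.01, friction = 2,
                            temperature = 300, save_interval = 10,
                            rng_seed = 1) {
  stopifnot(timestep > 0, n_steps >= 1, save_interval >= 1, friction >= 0)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 save_interval = as.integer(save_interval),
                 rng_seed = rng_seed),
            class = "langevin_params")
}

coord_cols <- function(n) {
  paste0(rep(c("x", "y", "z"), n), rep(seq_len(n), each = 3))
}

#' Run a Langevin trajectory
#'
#' Integrates the system with the BAOAB scheme, optionally under a
#' multicanonical bias (the force is scaled by \eqn{1 + dB/dE} evaluated at
#' the instantaneous potential energy).  Snapshots are recorded every
#' `save_interval` steps; the recorded `energy` column is the potential
#' energy including restraint terms, i.e. the argument of the bias.
#'
#' @param system a `toy_system`.
#' @param params a [langevin_params()] bundle.
#' @param restraints list of [restraints].
#' @param bias optional `mcmd_bias`; `NULL` runs plain canonical dynamics.
#' @param init optional starting coordinates (defaults to the preset's
#'   reference configuration); `init_vel` optional starting velocities.
#' @param observer optional list(`idx`, `origin`, `axis`, `every`) recording
#'   the centre-of-mass projection \eqn{\lambda} of the `idx` selection every
#'   `every` steps (used by the umbrella-sampling driver).
#' @param traj trajectory id stored in the output.
#' @return an ensemble tibble with one row per snapshot: `traj`, `step`,
#'   `time_ps`, `energy`, `restraint_energy`, `bias_energy`,
#'   `kinetic_energy`, coordinate columns `x1,y1,z1,...`, and `biased`
#'   (logical multicanonical flag).  The final phase-space state, and any
#'   observer series, are attached as attributes `final_state` and
#'   `lambda_series`.
#' @export
run_langevin <- function(system, params, restraints = list(), bias = NULL,
                         init = NULL, init_vel = NULL, observer = NULL,
                         traj = 1L) {
  stopifnot(inherits(params, "langevin_params"))
  init <- as_coord_matrix(if (is.null(init)) system$mobile0 else init,
                          nrow(system$mobile0))
  bias_cpp <- if (is.null(bias)) NULL else bias_for_cpp(bias)
  res <- run_dynamics_cpp(
    system, as_restraint_list(restraints), bias_cpp, init, init_vel,
    params$n_steps, params$timestep, params$friction,
    as.numeric(params$temperature), params$save_interval,
    as.numeric(params$rng_seed),
    if (is.null(observer)) list() else observer
  )
  xs <- res$coords
  colnames(xs) <- coord_cols(nrow(init))
  out <- tibble(
    traj = as.integer(traj), step = res$step,
    time_ps = res$step * params$timestep,
    energy = res$energy, restraint_energy = res$restraint_energy,
    bias_energy = res$bias_energy, kinetic_energy = res$kinetic_energy,
    biased = !is.null(bias)
  )
  out <- dplyr::bind_cols(out, as_tibble(xs))
  attr(out, "final_state") <- list(coords = res$final_coords, vel = res$final_vel)
  attr(out, "lambda_series") <- res$lambda_series
  attr(out, "seed") <- params$rng_seed
  out
}

#' Coordinates of one ensemble snapshot
#'
#' @param ensemble an ensemble tibble from [run_langevin()] or [run_mcmd()].
#' @param i row index of the snapshot.
#' @param n_beads number of mobile beads.
#' @return n x 3 coordinate matrix.
#' @export
snapshot_coords <- function(ensemble, i, n_beads) {
  matrix(unlist(ensemble[i, coord_cols(n_beads)], use.names = FALSE),
         ncol = 3, byrow = TRUE)
}

coords_block <- function(ensemble, n_beads) {
  as.matrix(ensemble[, coord_cols(n_beads)])
}

# per-snapshot centre of mass of a bead selection (mass-weighted)
ensemble_com <- function(ensemble, system, idx) {
  w <- system$mass[idx] / sum(system$mass[idx])
  xs <- coords_block(ensemble, nrow(system$mobile0))
  com <- matrix(0, nrow(ensemble), 3)
  for (q in seq_along(idx)) {
    i <- idx[q]
    com <- com + w[q] * xs[, 3 * (i - 1) + 1:3, drop = FALSE]
  }
  com
}

#' Simulation bookkeeping
#'
#' Snapshot and aggregate-time arithmetic for a parallel multicanonical
#' protocol: `n_traj` trajectories, a `prerun_ns` bias-refinement stage and a
#' `production_ns` sampling stage per trajectory, saved every `save_ps`.
#'
#' @param n_traj number of parallel trajectories.
#' @param prerun_ns,production_ns per-trajectory simulation lengths in ns.
#' @param save_ps production snapshot interval in ps.
#' @return one-row tibble with `prerun_total_us`, `production_total_us` and
#'   `n_snapshots`.
#' @examples
#' sampling_budget(32, 750, 1000, 5) # 24 us pre-run, 6.4e6 snapshots
#' @export
sampling_budget <- function(n_traj, prerun_ns, production_ns, save_ps) {
  tibble(
    n_traj = n_traj,
    prerun_total_us = n_traj * prerun_ns / 1000,
    production_total_us = n_traj * production_ns / 1000,
    n_snapshots = n_traj * floor(production_ns * 1000 / save_ps)
  )
}
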