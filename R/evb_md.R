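#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian velocities at the requested temperature; component standard
#' deviation `sqrt(kB T f / m)` in A/fs with the kcal/mol unit conversion
#' factor `f`. Uses R's RNG so `set.seed()` makes trajectories reproducible.
#'
#' @param mass atomic masses (amu)
#' @param temp_K temperature (K)
#' @return n x 3 velocity matrix (A/fs)
#' @export
maxwell_velocities <- function(mass, temp_K) {
  n <- length(mass)
  sds <- sqrt(.R_GAS * temp_K * .MD_ACC / mass)
  matrix(rnorm(3 * n, 0, rep(sds, 3)), n, 3)
}

#' Run one EVB mapping frame
#'
#' Leapfrog dynamics on the mapping potential
#' `Em = (1 - lambda) e1 + lambda (e2 + alpha)` with an optional Berendsen
#' thermostat and SHAKE constraints on the water geometry (the transferring
#' hydrogen is never constrained). Samples of the diabatic energies are
#' recorded at a fixed stride; the energy gap `X = e1 - e2p` is the reaction
#' coordinate used downstream.
#'
#' @param system an [evb_system()]
#' @param lambda mapping parameter in `[0, 1]`
#' @param n_steps number of MD steps
#' @param dt time step (fs)
#' @param temp_K thermostat target temperature (K)
#' @param tau_fs Berendsen coupling time (fs)
#' @param thermostat logical; `FALSE` gives NVE dynamics (conservation checks)
#' @param stride sampling stride (steps)
#' @param burn_frac fraction of initial samples discarded as equilibration
#' @param coords,vel starting coordinates/velocities; default system
#'   coordinates and fresh Maxwell-Boltzmann velocities
#' @param record_traj keep coordinates at every sample
#' @return object of class `mapping_frame`: `lambda`, `samples` (data.frame
#'   `e1`, `e2p`, `em`, `eg`, `gap`, `ke`, `weight`), final `coords`/`vel`,
#'   `ndof`, and (optionally) `traj`
#' @export
run_mapping_frame <- function(system, lambda, n_steps, dt = 1, temp_K = 300,
                              tau_fs = 100, thermostat = TRUE, stride = 10,
                              burn_frac = 0.2, coords = NULL, vel = NULL,
                              record_traj = FALSE) {
  stopifnot(lambda >= 0, lambda <= 1, n_steps >= stride)
  x0 <- if (is.null(coords)) system$xyz else as.matrix(coords)
  v0 <- if (is.null(vel)) maxwell_velocities(system$mass, temp_K) else as.matrix(vel)
  out <- .evb_md_cpp(.pack_system(system), x0, v0, lambda,
                     as.integer(n_steps), dt, temp_K, tau_fs,
                     isTRUE(thermostat), as.integer(stride),
                     1e-8, 500L, isTRUE(record_traj))
  alpha <- system$coupling$alpha %||% 0
  h12 <- coupling_h12(system$coupling, out$coords)
  sm <- out$samples
  keep <- seq_len(nrow(sm)) > floor(burn_frac * nrow(sm))
  e1 <- sm[keep, 1]; e2p <- sm[keep, 2] + alpha; ke <- sm[keep, 3]
  frame <- mapping_frame(lambda, e1, e2p, h12,
                         ke = ke, weight = rep(1, length(e1)))
  frame$coords <- out$coords
  frame$vel <- out$vel
  frame$ndof <- out$ndof
  frame$all_samples <- sm  # pre-burn, for conservation diagnostics
  if (record_traj) frame$traj <- out$traj[keep]
  frame
}

#' Construct a mapping frame from energy samples
#'
#' Builds the per-frame record used by [fep_free_energy()] and
#' [umbrella_profile()]: the mapping energy `em = (1-lambda) e1 + lambda e2p`
#' (verified against the stored samples to 1e-8), the EVB ground-state energy
#' and the gap coordinate. `weight` allows exhaustively enumerated (grid)
#' samples with Boltzmann weights in place of MD sampling.
#'
#' @param lambda mapping parameter
#' @param e1,e2p diabatic energy samples (e2p includes the gas shift)
#' @param h12 off-diagonal coupling used for the ground state
#' @param ke optional kinetic-energy samples
#' @param weight optional sample weights (default 1)
#' @param em optional externally computed mapping energies (consistency-checked)
#' @return object of class `mapping_frame`
#' @export
mapping_frame <- function(lambda, e1, e2p, h12, ke = NULL, weight = NULL,
                          em = NULL) {
  stopifnot(lambda >= 0, lambda <= 1, length(e1) == length(e2p))
  em_calc <- (1 - lambda) * e1 + lambda * e2p
  if (!is.null(em) && max(abs(em - em_calc)) > 1e-8)
    stop("mapping energies inconsistent with (1-lambda) e1 + lambda e2p")
  gs <- ground_state(e1, e2p, h12)
  samples <- data.frame(e1 = e1, e2p = e2p, em = em_calc, eg = gs$eg,
                        gap = e1 - e2p,
                        ke = if (is.null(ke)) NA_real_ else ke,
                        weight = if (is.null(weight)) 1 else weight)
  structure(list(lambda = lambda, h12 = h12, samples = samples),
            class = "mapping_frame")
}

#' Linearly spaced mapping-parameter schedule
#'
#' @param n number of frames (default 51)
#' @return strictly increasing lambda values from 0 to 1
#' @export
lambda_schedule <- function(n = 51) {
  stopifnot(n >= 2)
  seq(0, 1, length.out = n)
}

#' Run a full EVB-FEP/US mapping series
#'
#' Runs [run_mapping_frame()] over a lambda schedule, chaining the final
#' coordinates and velocities of each frame into the next so the system is
#' dragged adiabatically from the reactant (`lambda = 0`) to the product
#' (`lambda = 1`) bonding pattern.
#'
#' @inheritParams run_mapping_frame
#' @param lambdas mapping schedule, e.g. [lambda_schedule()]
#' @param equil_steps extra equilibration steps at `lambda = 0` before the
#'   first frame (not recorded)
#' @param verbose print progress
#' @return list of `mapping_frame` objects (class `evb_fep_run`)
#' @export
run_evb_fep <- function(system, lambdas = lambda_schedule(51), n_steps = 2000,
                        dt = 1, temp_K = 300, tau_fs = 100, stride = 10,
                        burn_frac = 0.2, equil_steps = 2000, verbose = FALSE) {
  stopifnot(all(diff(lambdas) > 0))
  coords <- system$xyz
  vel <- maxwell_velocities(system$mass, temp_K)
  if (equil_steps > 0) {
    eq <- run_mapping_frame(system, lambdas[1], equil_steps, dt, temp_K,
                            tau_fs, TRUE, stride, 0, coords, vel)
    coords <- eq$coords; vel <- eq$vel
  }
  frames <- vector("list", length(lambdas))
  for (m in seq_along(lambdas)) {
    fr <- run_mapping_frame(system, lambdas[m], n_steps, dt, temp_K, tau_fs,
                            TRUE, stride, burn_frac, coords, vel)
    coords <- fr$coords; vel <- fr$vel
    frames[[m]] <- fr
    if (verbose) message(sprintf("frame %d/%d lambda=%.3f", m, length(lambdas),
                                 lambdas[m]))
  }
  class(frames) <- "evb_fep_run"
  frames
}

#' Minimize an EVB system
#'
#' Steepest-descent minimization on the mapping potential (default pure
#' state 1) with backtracking step control.
#'
#' @param system an [evb_system()]
#' @param lambda mapping parameter of the surface to minimize on
#' @param n_steps maximum minimization steps
#' @param step0 initial displacement (Angstrom)
#' @return the system with updated coordinates; attribute `"energy"` holds
#'   the final mapping energy
#' @export
minimize_system <- function(system, lambda = 0, n_steps = 500, step0 = 0.02) {
  out <- .evb_min_cpp(.pack_system(system), system$xyz, lambda,
                      as.integer(n_steps), step0)
  system$xyz <- out$coords
  attr(system, "energy") <- out$energy
  system
}

#' Default staged heating / restraint-release schedule
#'
#' Mirrors a droplet equilibration protocol: short minimization, dynamics
#' started at 1 K under a strong solute restraint, staged heating to 300 K
#' while the restraint is tapered to 0.5 kcal/mol/A^2.
#'
#' @param n_steps_per_stage MD steps per heating stage
#' @param dt time step (fs)
#' @return data.frame with columns `n_steps`, `temp_K`, `restraint_k`, `dt`
#' @export
default_equilibration_schedule <- function(n_steps_per_stage = 500, dt = 1) {
  data.frame(
    n_steps = n_steps_per_stage,
    temp_K = c(1, 50, 100, 200, 300, 300),
    restraint_k = c(200, 100, 50, 10, 2, 0.5),
    dt = c(dt / 2, dt / 2, dt, dt, dt, dt))
}

#' Staged equilibration of an EVB system
#'
#' Runs the declarative `schedule` (one row per stage: steps, target
#' temperature, solute position-restraint force constant, time step) on the
#' `lambda = 0` surface, recording the solute RMSD from the starting
#' coordinates after every stage. A zero-row schedule returns the system
#' unchanged.
#'
#' @param system an [evb_system()]
#' @param schedule data.frame as from [default_equilibration_schedule()]
#' @param minimize_steps initial minimization steps (0 to skip)
#' @param tau_fs thermostat coupling time (fs)
#' @return list: `system` (equilibrated coordinates), `vel`, `rmsd_trace`
#'   (per stage, Angstrom), `final_temp_K`
#' @export
equilibration_protocol <- function(system, schedule = default_equilibration_schedule(),
                                   minimize_steps = 200, tau_fs = 50) {
  x_start <- system$xyz
  if (nrow(schedule) == 0 && minimize_steps == 0) {
    return(list(system = system, vel = NULL, rmsd_trace = numeric(0),
                final_temp_K = NA_real_))
  }
  if (minimize_steps > 0) system <- minimize_system(system, 0, minimize_steps)
  vel <- NULL
  rmsd_trace <- numeric(0)
  final_T <- NA_real_
  sol <- system$solute
  base_posres <- system$posres
  for (s in seq_len(nrow(schedule))) {
    st <- schedule[s, ]
    sys_s <- system
    if (st$restraint_k > 0) {
      pr <- cbind(sol, st$restraint_k, x_start[sol, , drop = FALSE])
      sys_s$posres <- .as_mat(rbind(base_posres, pr), 5)
    }
    if (is.null(vel)) vel <- maxwell_velocities(system$mass, max(st$temp_K, 1))
    fr <- run_mapping_frame(sys_s, 0, st$n_steps, st$dt, st$temp_K, tau_fs,
                            TRUE, max(1L, st$n_steps %/% 50), 0,
                            system$xyz, vel)
    system$xyz <- fr$coords
    vel <- fr$vel
    d <- system$xyz[sol, , drop = FALSE] - x_start[sol, , drop = FALSE]
    rmsd_trace <- c(rmsd_trace, sqrt(mean(rowSums(d^2))))
    ke_mean <- mean(fr$samples$ke)
    final_T <- 2 * ke_mean / (fr$ndof * .R_GAS)
  }
  list(system = system, vel = vel, rmsd_trace = rmsd_trace,
       final_temp_K = final_T)
}
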