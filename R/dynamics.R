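# Molecular dynamics: velocity Verlet with thermostats, barostat, SHAKE.

#' Integrator configuration
#'
#' Defaults follow the simulation protocol used for the force-field
#' validation runs: 0.5 fs timestep, Nose-Hoover thermostat with 100 fs
#' coupling, Nose-Hoover-style barostat with 2000 fs coupling at 1 atm.
#'
#' @param dt timestep, fs.
#' @param thermostat one of `"none"`, `"berendsen"`, `"langevin"`,
#'   `"nosehoover"`.
#' @param tau_t thermostat coupling constant, fs.
#' @param temperature target temperature, K.
#' @param barostat logical; couple an isotropic barostat.
#' @param tau_p barostat coupling constant, fs.
#' @param pressure target pressure, bar.
#' @param seed integer seed for the (Langevin) noise stream.
#' @param save_every store a frame every this many steps.
#' @param shake_tol relative SHAKE convergence tolerance.
#' @param com_every re-zero centre-of-mass motion every this many steps under
#'   Langevin dynamics (the noise does not conserve momentum); 0 disables.
#' @return list of class `bilff_integrator`.
#' @export
integrator <- function(dt = 0.5, thermostat = c("nosehoover", "none",
                                                "berendsen", "langevin"),
                       tau_t = 100, temperature = 350, barostat = FALSE,
                       tau_p = 2000, pressure = 1.01325, seed = 1,
                       save_every = 50, shake_tol = 1e-8, com_every = 100) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, tau_t >= dt)
  structure(list(dt = dt, thermostat = thermostat, tau_t = tau_t,
                 temperature = temperature, barostat = barostat, tau_p = tau_p,
                 pressure = pressure, seed = seed, save_every = save_every,
                 shake_tol = shake_tol, com_every = com_every),
            class = "bilff_integrator")
}

.th_code <- function(x) match(x, c("none", "berendsen", "langevin",
                                   "nosehoover")) - 1L

.run_md <- function(sys, opts, cfg, steps, vel) {
  tu <- bilff_constants$time_unit_fs
  ccfg <- list(
    dt = cfg$dt / tu, nsteps = as.integer(steps),
    thermostat = .th_code(cfg$thermostat), tau_t = cfg$tau_t / tu,
    temperature = cfg$temperature, barostat = isTRUE(cfg$barostat),
    tau_p = cfg$tau_p / tu, pressure = cfg$pressure * bilff_constants$bar,
    save_every = as.integer(cfg$save_every), seed = cfg$seed,
    shake_tol = cfg$shake_tol, com_every = as.integer(cfg$com_every),
    nlist_skin = 1.0, nlist_every = 10L)
  r <- cpp_md_run(.engine_args(sys), sys$pos, vel, sys$box, unclass(opts), ccfg)
  nf <- r$nframes
  structure(list(
    topology = sys,
    frames = r$frames[seq_len(nf), , drop = FALSE],
    time = r$time[seq_len(nf)] * tu,                  # fs
    box = r$box[seq_len(nf)],                         # Angstrom
    temperature = r$temperature[seq_len(nf)],
    pressure = r$pressure[seq_len(nf)] / bilff_constants$bar,  # bar
    epot = r$epot[seq_len(nf)], ekin = r$ekin[seq_len(nf)],
    virial = r$virial[seq_len(nf)], cons_virial = r$cons_virial[seq_len(nf)],
    final = list(pos = r$final_pos, vel = r$final_vel, box = r$final_box)
  ), class = "bilff_trajectory")
}

#' Run NVT (or NVE) molecular dynamics
#'
#' Velocity-Verlet integration at constant volume. With
#' `thermostat = "none"` this is an NVE run (energy-conserving, used for
#' integrator validation).
#'
#' @param sys a `bilff_system` with positions.
#' @param opts [nb_options()].
#' @param cfg [integrator()] configuration (its `barostat` flag is ignored).
#' @param steps number of timesteps.
#' @param vel initial velocities (internal units); default
#'   [init_velocities()] at the target temperature with the config seed.
#' @return `bilff_trajectory`.
#' @export
integrate_nvt <- function(sys, opts = nb_options(), cfg = integrator(),
                          steps = 1000, vel = NULL) {
  stopifnot(!is.null(sys$pos))
  .check_cutoff_box(sys, opts)
  cfg$barostat <- FALSE
  if (is.null(vel)) vel <- init_velocities(sys, cfg$temperature, cfg$seed)
  if (steps == 0) {
    return(structure(list(topology = sys,
                          frames = matrix(t(sys$pos), nrow = 1),
                          time = 0, box = sys$box, temperature = NA_real_,
                          pressure = NA_real_, epot = NA_real_, ekin = NA_real_,
                          final = list(pos = sys$pos, vel = vel, box = sys$box)),
                     class = "bilff_trajectory"))
  }
  .run_md(sys, opts, cfg, steps, vel)
}

#' Run NpT molecular dynamics
#'
#' As [integrate_nvt()] but with the isotropic barostat coupled; the cubic
#' box fluctuates and the mean density over the sampled frames is reported
#' in the result (`attr(x, "mean_density")`, g/cm^3). Requires a pairwise
#' electrostatics method (cutoff or DSF).
#'
#' @inheritParams integrate_nvt
#' @export
integrate_npt <- function(sys, opts = nb_options(), cfg = integrator(),
                          steps = 1000, vel = NULL) {
  stopifnot(!is.null(sys$pos))
  .check_cutoff_box(sys, opts)
  cfg$barostat <- TRUE
  if (is.null(vel)) vel <- init_velocities(sys, cfg$temperature, cfg$seed)
  traj <- .run_md(sys, opts, cfg, steps, vel)
  m <- sum(sys$atoms$mass)
  dens <- (m / bilff_constants$avogadro) / ((traj$box * 1e-8)^3)
  attr(traj, "mean_density") <- mean(dens[-seq_len(ceiling(length(dens) / 2))])
  attr(traj, "density_series") <- dens
  traj
}

#' Apply SHAKE to a configuration
#'
#' Iteratively restores all holonomic distance constraints of the system
#' (rigid water geometry) and re-places virtual sites.
#'
#' @param sys a `bilff_system` carrying constraints.
#' @param pos N x 3 positions, Angstrom (default: the system's own).
#' @param tol relative convergence tolerance on the squared distances.
#' @param maxit iteration cap; non-convergence (e.g. infeasible constraints)
#'   is an error reporting the worst violation.
#' @return constrained position matrix.
#' @export
shake_constrain <- function(sys, pos = sys$pos, tol = 1e-10, maxit = 500) {
  cpp_apply_shake(.engine_args(sys), pos, tol, as.integer(maxit))
}

#' @export
print.bilff_trajectory <- function(x, ...) {
  cat(sprintf("bilff trajectory: %d frames, %d atoms, %.1f ps, box %.2f A\n",
              length(x$time), nrow(x$topology$atoms),
              diff(range(x$time)) / 1000, utils::tail(x$box, 1)))
  invisible(x)
}

#' Extract one frame of a trajectory
#'
#' @param traj a `bilff_trajectory`.
#' @param i frame index.
#' @return N x 3 position matrix (Angstrom).
#' @export
frame_pos <- function(traj, i) {
  matrix(traj$frames[i, ], ncol = 3, byrow = TRUE)
}

#' Number of frames
#' @param traj a `bilff_trajectory`.
#' @export
n_frames <- function(traj) length(traj$time)

#' Run the full equilibration + production protocol
#'
#' Stages (all durations and couplings configurable, defaults as in the
#' validation protocol): (1) pack and briefly minimize; (2) 500 K NVT
#' scramble with a Berendsen thermostat (1 fs coupling); (3) NpT at the
#' target temperature with Nose-Hoover thermostat (100 fs) and barostat
#' (2000 fs); (4) short Langevin damping stage; (5) NVT production with the
#' Nose-Hoover thermostat at 0.5 fs timestep.
#'
#' @param comp a [composition()].
#' @param ff force field resolving all species.
#' @param seed master seed; packing, velocities and thermostat noise all
#'   derive from it, so identical seeds give identical trajectories.
#' @param temperature production temperature, K.
#' @param opts [nb_options()]; DSF electrostatics by default.
#' @param dt timestep, fs.
#' @param t_scramble,t_npt,t_damp,t_prod stage durations in ps.
#' @param save_every production frame stride, steps.
#' @param npt logical; include the NpT stage.
#' @return `bilff_trajectory` of the production stage; `attr(,"stages")`
#'   holds the stage log (data frame of stage, ensemble, thermostat, K, ps),
#'   `attr(,"equil_density")` the mean NpT density.
#' @export
run_protocol <- function(comp, ff, seed = 1, temperature = 350,
                         opts = nb_options(), dt = 0.5,
                         t_scramble = 2, t_npt = 5, t_damp = 1, t_prod = 10,
                         save_every = 50, npt = TRUE) {
  steps_of <- function(ps) as.integer(round(ps * 1000 / dt))
  stages <- list()
  log_stage <- function(name, ensemble, thermo, temp, ps)
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name, ensemble = ensemble, thermostat = thermo,
      temperature = temp, duration_ps = ps)

  sys <- build_system(comp, ff)
  sys <- pack_system(sys, ff, seed = seed)
  log_stage("pack", "-", "-", NA, NA)

  # 500 K scramble, Berendsen 1 fs
  cfg <- integrator(dt = dt, thermostat = "berendsen", tau_t = 1,
                    temperature = 500, seed = seed + 1,
                    save_every = max(1, steps_of(t_scramble)))
  tr <- integrate_nvt(sys, opts, cfg, steps_of(t_scramble))
  sys$pos <- tr$final$pos
  log_stage("scramble", "NVT", "berendsen", 500, t_scramble)

  vel <- tr$final$vel
  dens <- NA_real_
  if (npt && t_npt > 0) {
    cfg <- integrator(dt = dt, thermostat = "nosehoover", tau_t = 100,
                      temperature = temperature, barostat = TRUE,
                      tau_p = 2000, seed = seed + 2,
                      save_every = max(1, steps_of(t_npt) %/% 200))
    tr <- integrate_npt(sys, opts, cfg, steps_of(t_npt),
                        vel = init_velocities(sys, temperature, seed + 2))
    sys$pos <- tr$final$pos
    sys$box <- tr$final$box
    vel <- tr$final$vel
    dens <- attr(tr, "mean_density")
    log_stage("equilibrate", "NpT", "nosehoover", temperature, t_npt)
  }
  if (t_damp > 0) {
    cfg <- integrator(dt = dt, thermostat = "langevin", tau_t = 100,
                      temperature = temperature, seed = seed + 3,
                      save_every = max(1, steps_of(t_damp)))
    tr <- integrate_nvt(sys, opts, cfg, steps_of(t_damp), vel = vel)
    sys$pos <- tr$final$pos
    vel <- tr$final$vel
    log_stage("damp", "NVT", "langevin", temperature, t_damp)
  }
  cfg <- integrator(dt = dt, thermostat = "nosehoover", tau_t = 100,
                    temperature = temperature, seed = seed + 4,
                    save_every = save_every)
  traj <- integrate_nvt(sys, opts, cfg, steps_of(t_prod), vel = vel)
  log_stage("production", "NVT", "nosehoover", temperature, t_prod)
  attr(traj, "stages") <- do.call(rbind, stages)
  attr(traj, "equil_density") <- dens
  traj
}
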