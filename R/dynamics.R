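# Time integration: Langevin thermostat, zero-tension XY barostat,
# rigid-body particle motion, stochastic ligand-receptor bond kinetics,
# and the wrapping-run orchestration.

#' Integrator configuration
#'
#' Defaults follow the published protocol: timestep 0.01 tau, Langevin
#' thermostat at temperature 1 epsilon/kB with damping constant 1/tau,
#' and a zero-tension barostat in the XY plane with pressure-damping
#' constant 1 tau. The barostat here is a weak-coupling (Berendsen
#' style) area rescale driving the instantaneous lateral tension to
#' `target_tension` on the timescale `barostat_damp * area_modulus`;
#' `area_modulus` (epsilon/sigma^2) is an order-of-magnitude estimate
#' of the membrane area compressibility used only to set the coupling
#' strength, not the fixed point.
#'
#' Bond checks run every `bond_check_interval` steps (0.1 tau at the
#' default timestep); per-step checks at 50% formation probability make
#' formation effectively instantaneous, so the cadence is exposed and
#' recorded in run metadata.
#'
#' @param dt Timestep, tau.
#' @param temperature Target temperature, epsilon/kB.
#' @param gamma Langevin damping constant, 1/tau.
#' @param barostat Logical; rescale the box toward zero tension.
#' @param barostat_damp Barostat coupling time, tau.
#' @param area_modulus Area-compressibility scale for the coupling,
#'   epsilon/sigma^2.
#' @param target_tension Target lateral tension, epsilon/sigma^2.
#' @param steps Number of steps to run.
#' @param seed Integer RNG seed.
#' @param bond_check_interval Steps between bond kinetics updates.
#' @param thermostat Logical; disable for deterministic NVE-like tests.
#' @param rigid_mobile Logical; if FALSE the particle is frozen in
#'   place (sensitivity checks).
#' @param f_ext Constant external force applied to the rigid particle
#'   (3-vector, epsilon/sigma); zero by default.
#' @param debug Logical; assert valence injectivity at every bond
#'   update.
#' @return An `integrator_config` list.
#' @export
integrator_config <- function(dt = 0.01, temperature = 1, gamma = 1,
                              barostat = TRUE, barostat_damp = 1,
                              area_modulus = 20, target_tension = 0,
                              steps = 1000L, seed = 1L,
                              bond_check_interval = 10L,
                              thermostat = TRUE, rigid_mobile = TRUE,
                              f_ext = c(0, 0, 0), debug = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (barostat_damp <= 0) stop("barostat_damp must be positive")
  structure(list(dt = dt, temperature = temperature, gamma = gamma,
                 barostat = barostat, barostat_damp = barostat_damp,
                 area_modulus = area_modulus,
                 target_tension = target_tension,
                 steps = as.integer(steps), seed = as.integer(seed),
                 bond_check_interval = as.integer(bond_check_interval),
                 thermostat = thermostat, rigid_mobile = rigid_mobile,
                 f_ext = f_ext, debug = debug),
            class = "integrator_config")
}

#' Ligand-receptor bond kinetics parameters
#'
#' Reversible Morse bonds: an unbound ligand and unbound receptor
#' within `r_form` = 1.3 sigma form a bond with probability `p_form` =
#' 0.5 at each check; a bond breaks with certainty once its length
#' exceeds `r_break` = 4 sigma. A valence constraint keeps the bond map
#' one-to-one in both directions.
#'
#' @param r_form Capture radius, sigma.
#' @param p_form Formation probability per check.
#' @param r_break Break distance, sigma (> r_form).
#' @return A `bond_kinetics` list.
#' @export
bond_kinetics <- function(r_form = 1.3, p_form = 0.5, r_break = 4) {
  if (r_form >= r_break) stop("r_form must be < r_break")
  if (p_form < 0 || p_form > 1) stop("p_form must be in [0, 1]")
  structure(list(r_form = r_form, p_form = p_form, r_break = r_break),
            class = "bond_kinetics")
}

ff_pack <- function(ff) {
  code <- matrix(match(ff$pair_type, c("none", "wca", "cos")) - 1L, 5, 5)
  list(pair_type_code = code, pair_b = unname(ff$pair_b),
       pair_wc = unname(ff$pair_wc),
       K1 = ff$K1, fene_rmax = ff$fene_rmax, K2 = ff$K2,
       theta0 = ff$theta0,
       morse_eps = ff$morse$eps_LR, morse_r0 = ff$morse$r0,
       morse_alpha = ff$morse$alpha, morse_rcut = ff$morse$rcut)
}

state_lr_vec <- function(state) {
  n <- nrow(state$positions)
  lr <- state$lr_bonds
  if (length(lr) != n) lr <- integer(n)
  lr
}

#' Advance a system in time
#'
#' Runs `cfg$steps` velocity-Verlet Langevin steps with the optional
#' zero-tension barostat, rigid particle motion, and (if `kinetics` is
#' supplied) stochastic ligand-receptor bond updates. Periodic in XY,
#' open in Z; no interaction crosses the Z boundary.
#'
#' @param state A `system_state`.
#' @param ff A [forcefield()].
#' @param cfg An [integrator_config()].
#' @param kinetics A [bond_kinetics()] or NULL to freeze the bond map.
#' @param obs_stride Record observables every this many steps (0 =
#'   never).
#' @param frame_stride Record full-position frames every this many
#'   steps (0 = never).
#' @return List with `state` (advanced), `obs` (data.frame: time,
#'   temperature, area, tension, wrap_fraction, bond_count,
#'   potential_energy), `frames` (list of time/x/xu/box/lr_bonds) and
#'   engine counters (`n_rebuilds`, `morse_evals`).
#' @export
simulate_dynamics <- function(state, ff = forcefield(),
                              cfg = integrator_config(),
                              kinetics = bond_kinetics(),
                              obs_stride = 100L, frame_stride = 0L) {
  n <- nrow(state$positions)
  if (is.null(state$xu) || nrow(state$xu) != n) state$xu <- state$positions
  params <- list(
    dt = cfg$dt, temperature = cfg$temperature, gamma = cfg$gamma,
    barostat_damp = cfg$barostat_damp, area_modulus = cfg$area_modulus,
    target_tension = cfg$target_tension, thermostat = cfg$thermostat,
    barostat = cfg$barostat, rigid_mobile = cfg$rigid_mobile,
    debug = cfg$debug,
    bond_check_interval = cfg$bond_check_interval,
    r_form = if (is.null(kinetics)) 1.3 else kinetics$r_form,
    p_form = if (is.null(kinetics)) 0.5 else kinetics$p_form,
    r_break = if (is.null(kinetics)) 4 else kinetics$r_break,
    kinetics = !is.null(kinetics),
    f_ext = as.numeric(cfg$f_ext),
    nsteps = cfg$steps, obs_stride = as.integer(obs_stride),
    frame_stride = as.integer(frame_stride),
    seed = as.double(cfg$seed), skin = 0.9)
  res <- run_md_cpp(state$positions, state$velocities, state$xu,
                    state$kinds, state$fene_bonds, state$angles,
                    state_lr_vec(state), state$particle_idx,
                    state$box[1:2], ff_pack(ff), params)
  out <- state
  out$positions <- res$x
  out$velocities <- res$v
  out$xu <- res$xu
  out$box[1:2] <- res$box
  out$lr_bonds <- res$lr_bonds
  out$time <- state$time + cfg$steps * cfg$dt
  obs <- res$obs
  obs$time <- obs$time + state$time
  frames <- res$frames
  for (k in seq_along(frames)) frames[[k]]$time <- frames[[k]]$time + state$time
  list(state = out, obs = obs, frames = frames,
       n_rebuilds = res$n_rebuilds, morse_evals = res$morse_evals,
       t_build = res$t_build, t_force = res$t_force,
       n_pairs_w = res$n_pairs_w, n_pairs_c = res$n_pairs_c)
}

#' Single Langevin step
#'
#' Convenience wrapper: one velocity-Verlet Langevin update of all
#' non-rigid beads (no bond kinetics).
#'
#' @inheritParams simulate_dynamics
#' @return The advanced `system_state`.
#' @export
langevin_step <- function(state, ff = forcefield(), cfg = integrator_config()) {
  cfg$steps <- 1L
  simulate_dynamics(state, ff, cfg, kinetics = NULL, obs_stride = 0L)$state
}

#' One stochastic ligand-receptor bond update
#'
#' Applies the break rule (length > `r_break` removes the bond) and the
#' formation rule (each unbound ligand-unbound receptor pair within
#' `r_form` binds with probability `p_form`, in randomized order, so
#' the one-to-one valence constraint is never violated) to a static
#' configuration.
#'
#' @param state A `system_state`.
#' @param kinetics A [bond_kinetics()].
#' @param seed Integer seed for this update.
#' @param ff A [forcefield()] (pair table used for the candidate
#'   search).
#' @return The `system_state` with an updated bond map.
#' @export
update_lr_bonds <- function(state, kinetics = bond_kinetics(), seed = 1,
                            ff = forcefield()) {
  res <- update_lr_bonds_cpp(state$positions, state$kinds,
                             state_lr_vec(state), state$box[1:2],
                             ff_pack(ff), kinetics$r_form, kinetics$p_form,
                             kinetics$r_break, as.double(seed))
  state$lr_bonds <- res$lr_bonds
  state
}

#' Total potential energy of a configuration (engine path)
#'
#' Nonbonded (neighbor-list), FENE, angle and bonded-Morse energy via
#' the same kernels the integrator uses.
#'
#' @param state A `system_state`.
#' @param ff A [forcefield()].
#' @param nonbonded_only If TRUE, only the pair-table part.
#' @return Energy in epsilon.
#' @export
system_energy <- function(state, ff = forcefield(), nonbonded_only = FALSE) {
  if (nonbonded_only) {
    nb_energy_cpp(state$positions, state$kinds, state$box[1:2], ff_pack(ff))
  } else {
    energy_cpp(state$positions, state$kinds, state$fene_bonds, state$angles,
               state_lr_vec(state), state$box[1:2], ff_pack(ff))
  }
}

#' Conservative forces on every bead (engine path)
#'
#' @param state A `system_state`.
#' @param ff A [forcefield()].
#' @return N x 3 matrix of forces (epsilon/sigma), with the total
#'   potential energy attached as attribute `potential_energy`.
#' @export
system_forces <- function(state, ff = forcefield()) {
  forces_cpp(state$positions, state$kinds, state$fene_bonds, state$angles,
             state_lr_vec(state), state$box[1:2], ff_pack(ff))
}

#' Equilibrate a bilayer under the thermostat and barostat
#'
#' @param state A `system_state`.
#' @param tau Duration, tau.
#' @param ff,cfg Force field and integrator configuration (steps and
#'   kinetics are overridden; bond kinetics are off during membrane
#'   equilibration).
#' @param obs_stride,frame_stride Recording strides (steps).
#' @return As [simulate_dynamics()].
#' @export
equilibrate_bilayer <- function(state, tau = 1000, ff = forcefield(),
                                cfg = integrator_config(),
                                obs_stride = 100L, frame_stride = 0L) {
  cfg$steps <- as.integer(round(tau / cfg$dt))
  simulate_dynamics(state, ff, cfg, kinetics = NULL,
                    obs_stride = obs_stride, frame_stride = frame_stride)
}

derive_seed <- function(master_seed, stream) {
  # deterministic, keeps results in 32-bit integer range
  (as.double(master_seed) * 1103515245 + 12345 * stream) %% 2147483647
}

#' Run one or more wrapping replicas
#'
#' Orchestrates the full pipeline: build the bilayer, assign receptors,
#' equilibrate, insert the particle, then simulate with bond kinetics,
#' emitting a wrapping trace per replica. Replica seeds derive
#' deterministically from `master_seed`.
#'
#' @param particle A `surface_beads` with ligands placed.
#' @param membrane List with `n_lipids_x`, `n_lipids_y`,
#'   `area_per_lipid`, `receptor_fraction`, `equilibration_tau`.
#' @param horizon_tau Production length per replica, tau.
#' @param replicas Number of replicas.
#' @param master_seed Master seed.
#' @param ff,cfg,kinetics Model parameters.
#' @param obs_stride,frame_stride Recording strides (steps).
#' @param standoff Initial particle-membrane gap, sigma.
#' @param checkpoint_dir Optional directory for final-state
#'   checkpoints.
#' @return List of `wrapping_trace` objects (one per replica).
#' @export
run_wrapping <- function(particle,
                         membrane = list(n_lipids_x = 28, n_lipids_y = 28,
                                         area_per_lipid = 1.1345,
                                         receptor_fraction = 0.5,
                                         equilibration_tau = 100),
                         horizon_tau = 2000, replicas = 1,
                         master_seed = 1, ff = forcefield(),
                         cfg = integrator_config(),
                         kinetics = bond_kinetics(),
                         obs_stride = 100L, frame_stride = 0L,
                         standoff = 1, checkpoint_dir = NULL) {
  traces <- vector("list", replicas)
  for (rep_i in seq_len(replicas)) {
    seed_i <- derive_seed(master_seed, rep_i)
    bil <- build_bilayer(membrane$n_lipids_x, membrane$n_lipids_y,
                         membrane$area_per_lipid)
    bil <- assign_receptors(bil, membrane$receptor_fraction, seed_i)
    cfg_eq <- cfg
    cfg_eq$seed <- as.integer(seed_i %% 2147483647)
    eq <- equilibrate_bilayer(bil, membrane$equilibration_tau, ff, cfg_eq,
                              obs_stride = obs_stride)
    sys <- assemble_system(eq$state, particle, standoff = standoff)
    cfg_run <- cfg
    cfg_run$seed <- as.integer(derive_seed(seed_i, 7) %% 2147483647)
    cfg_run$steps <- as.integer(round(horizon_tau / cfg$dt))
    run <- simulate_dynamics(sys, ff, cfg_run, kinetics,
                             obs_stride = obs_stride,
                             frame_stride = frame_stride)
    tr <- structure(list(
      times = run$obs$time,
      wrap_fraction = run$obs$wrap_fraction,
      bond_count = run$obs$bond_count,
      obs = run$obs,
      frames = run$frames,
      head_idx = sys$head_idx,
      replica_id = rep_i,
      seed = seed_i,
      final_state = run$state,
      meta = list(bond_check_interval = cfg$bond_check_interval,
                  dt = cfg$dt, horizon_tau = horizon_tau,
                  morse_evals = run$morse_evals)),
      class = "wrapping_trace")
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      write_checkpoint(run$state,
                       file.path(checkpoint_dir,
                                 sprintf("replica-%02d.chk", rep_i)))
    }
    traces[[rep_i]] <- tr
  }
  traces
}

#' @export
print.wrapping_trace <- function(x, ...) {
  cat(sprintf("<wrapping_trace> replica %d: %d samples over %.4g tau, final wrap fraction %.3f (%d bonds)\n",
              x$replica_id, length(x$times),
              if (length(x$times)) max(x$times) else 0,
              if (length(x$wrap_fraction)) utils::tail(x$wrap_fraction, 1) else NA,
              if (length(x$bond_count)) utils::tail(x$bond_count, 1) else NA))
  invisible(x)
}

#' Write a trajectory in LAMMPS dump dialect
#'
#' Text frames (`id type x y z`, plus image-flag-free unwrapped
#' coordinates `xu yu zu`) and a per-frame ligand-receptor bond table
#' appended as comment lines.
#'
#' @param frames Frame list from [simulate_dynamics()].
#' @param kinds Integer bead kinds.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dump <- function(frames, kinds, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$x)
    writeLines(c("ITEM: TIMESTEP", sprintf("%.6f", fr$time),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp ff",
                 sprintf("0 %.10g", fr$box[1]),
                 sprintf("0 %.10g", fr$box[2]),
                 sprintf("%.10g %.10g", min(fr$x[, 3]) - 1, max(fr$x[, 3]) + 1),
                 "ITEM: ATOMS id type x y z xu yu zu"), con)
    writeLines(sprintf("%d %d %.6g %.6g %.6g %.6g %.6g %.6g",
                       seq_len(n), kinds, fr$x[, 1], fr$x[, 2], fr$x[, 3],
                       fr$xu[, 1], fr$xu[, 2], fr$xu[, 3]), con)
    bonded <- which(fr$lr_bonds > 0 & kinds == 5L)
    writeLines(paste("# lr_bonds:",
                     paste(bonded, fr$lr_bonds[bonded], collapse = " ")), con)
  }
  invisible(path)
}
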