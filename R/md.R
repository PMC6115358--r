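#' Integrator specification
#'
#' Velocity-Verlet dynamics with rigid-group constraints (SHAKE/RATTLE).
#' `NVT` couples a Nose-Hoover (default) or Langevin thermostat; `NsigmaT`
#' additionally relaxes each box length independently toward the external
#' stress through an anisotropic weak-coupling barostat. Stress sign
#' convention: tension positive, so `sigma_ext = 0` targets zero pressure.
#'
#' @param dt Time step, ps (default 0.001 = 1 fs).
#' @param T_target Thermostat temperature, K.
#' @param thermostat_tau Thermostat relaxation time, ps (default 0.5 = 500 fs).
#' @param barostat_tau Barostat relaxation time, ps.
#' @param sigma_ext External stress per axis, Pa (tension positive).
#' @param ensemble One of `"NVE"`, `"NVT"`, `"NsigmaT"`.
#' @param thermostat `"nose-hoover"`, `"langevin"` or `"none"`.
#' @param langevin_gamma Langevin friction, 1/ps.
#' @param kappa Barostat coupling (effective compressibility), (kJ/mol/nm^3)^-1.
#' @return Object of class `IntegratorSpec`.
#' @export
integrator_spec <- function(dt = 0.001, T_target = 300, thermostat_tau = 0.5,
                            barostat_tau = 2.0, sigma_ext = c(0, 0, 0),
                            ensemble = c("NVT", "NVE", "NsigmaT"),
                            thermostat = c("nose-hoover", "langevin", "none"),
                            langevin_gamma = 5, kappa = 7.5e-4) {
  ensemble <- match.arg(ensemble)
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, thermostat_tau > 0, barostat_tau > 0)
  if (length(sigma_ext) == 1) sigma_ext <- rep(sigma_ext, 3)
  structure(list(dt = dt, T_target = T_target, thermostat_tau = thermostat_tau,
                 barostat_tau = barostat_tau, sigma_ext = sigma_ext,
                 ensemble = ensemble, thermostat = thermostat,
                 langevin_gamma = langevin_gamma, kappa = kappa),
            class = "IntegratorSpec")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param state A `SystemState`.
#' @param T Temperature, K.
#' @param seed Optional integer seed (uses and restores the global stream).
#' @return The state with fresh velocities (frozen-host sites get zero;
#'   net momentum of mobile sites removed).
#' @export
maxwell_velocities <- function(state, T, seed = NULL) {
  with_seed(seed, {
    n <- nrow(state$sites)
    v <- matrix(rnorm(3 * n), n, 3) * sqrt(.kB * T / state$sites$mass)
    if (isTRUE(state$frozen_host)) v[state$sites$role == "host", ] <- 0
    mob <- if (isTRUE(state$frozen_host)) state$sites$role != "host" else rep(TRUE, n)
    if (any(mob)) {
      m <- state$sites$mass[mob]
      v[mob, ] <- sweep(v[mob, , drop = FALSE], 2, colSums(v[mob, , drop = FALSE] * m) / sum(m))
    }
    state$velocities <- v
    state
  })
}

#' Run molecular dynamics
#'
#' @param state A `SystemState`.
#' @param spec An [integrator_spec()].
#' @param n_steps Number of steps.
#' @param cutoff,alpha Nonbonded model parameters (nm, 1/nm).
#' @param thermo_stride Steps between thermodynamic trace rows (0 = start only).
#' @param traj_stride Steps between stored frames (0 = none).
#' @param nlist_every Neighbour-list rebuild interval (steps).
#' @param skin Neighbour-list skin, nm.
#' @param com_every Centre-of-mass motion removal interval (steps).
#' @param seed Optional seed for the Langevin noise stream.
#' @return Updated `SystemState` with attributes `traces` (data frame: step,
#'   time, T, V, per-axis pressure in kJ/mol/nm^3, energies) and `frames`
#'   (list of `step`/`pos`/`box` snapshots).
#' @export
step_md <- function(state, spec, n_steps, cutoff = 0.9, alpha = 2.0,
                    thermo_stride = 10, traj_stride = 0, nlist_every = 10,
                    skin = 0.15, com_every = 100, seed = NULL) {
  packed <- pack_system(state, cutoff, alpha)
  thermo_code <- if (spec$ensemble == "NVE") 0L
    else switch(spec$thermostat, "nose-hoover" = 1L, "langevin" = 2L, "none" = 0L)
  barostat <- spec$ensemble == "NsigmaT"
  P_target <- -spec$sigma_ext / .Pa_per_internal
  out <- with_seed(seed,
    cpp_run_md(packed, state$velocities, spec$dt, as.integer(n_steps),
               thermo_code, spec$T_target, spec$thermostat_tau,
               spec$langevin_gamma, barostat, P_target, spec$barostat_tau,
               spec$kappa, as.integer(nlist_every), skin,
               as.integer(thermo_stride), as.integer(traj_stride),
               as.integer(com_every)))
  state$sites[, c("x", "y", "z")] <- out$pos
  state$velocities <- out$vel
  state$box <- simulation_box(out$box, state$box$periodic)
  tr <- as.data.frame(out$traces)
  names(tr) <- c("step", "time", "T", "V", "Pxx", "Pyy", "Pzz",
                 "elj", "ecoul", "ebonded", "ekin")
  attr(state, "traces") <- tr
  attr(state, "frames") <- out$frames
  state
}

#' Instantaneous virial stress
#'
#' Per-axis virial stress including the kinetic term; tension positive.
#' Constraint-force contributions are not included here -- for constrained
#' (rigid-water) dynamics read the stress from the integrator traces, which
#' carry the full constraint virial.
#'
#' @param state A `SystemState`.
#' @param cutoff,alpha Nonbonded model parameters.
#' @return Stress 3-vector in Pa (tension positive).
#' @export
measure_stress <- function(state, cutoff = 0.9, alpha = 2.0) {
  s <- cpp_measure_stress(pack_system(state, cutoff, alpha), state$velocities)
  s * .Pa_per_internal
}

#' Mass density of a system
#' @param state A `SystemState`.
#' @return Density in g/cm^3.
#' @export
mass_density <- function(state) {
  sum(state$sites$mass) / 602.21408 / box_volume(state$box)
}

# traces helper: mean pressure -> stress in GPa (tension positive)
traces_sigma_gpa <- function(traces) {
  p <- rowMeans(traces[, c("Pxx", "Pyy", "Pzz"), drop = FALSE])
  -p * .Pa_per_internal / 1e9
}
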