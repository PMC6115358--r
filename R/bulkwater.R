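#' Simulate bulk liquid water
#'
#' Equilibrates and samples a box of rigid SPC/E waters at the requested
#' density and temperature: a short Langevin start-up (relaxes the initial
#' lattice), Nose-Hoover NVT equilibration, then NVT production with frames
#' stored for analysis.
#'
#' @param n Number of molecules. The default 216 is the smallest cube number
#'   whose ambient-density box satisfies the minimum-image requirement
#'   `L/2 >= cutoff` at the default 0.9 nm cutoff.
#' @param T Temperature, K.
#' @param density Density, g/cm^3 (default 0.997, ambient liquid water).
#' @param equil_ps,prod_ps Equilibration and production lengths, ps.
#' @param dt Time step, ps (2 fs is safe for the rigid constraint dynamics).
#' @param frame_ps Interval between stored production frames, ps.
#' @param cutoff,alpha Nonbonded model parameters.
#' @param seed Seed for initial placement, velocities and the thermostat.
#' @return List (class `BulkWaterRun`): final `state`, production `frames`,
#'   production `traces`, and the run parameters.
#' @export
simulate_bulk_water <- function(n = 216, T = 300, density = 0.997,
                                equil_ps = 20, prod_ps = 50, dt = 0.002,
                                frame_ps = 0.5, cutoff = 0.9, alpha = 2.0,
                                seed = 1) {
  with_seed(seed, {
    st <- make_fixture("bulk_water", n = n, density = density)
    st <- maxwell_velocities(st, T)
    # stiff-contact-safe start from the lattice
    lang <- integrator_spec(dt = dt / 2, T_target = T, ensemble = "NVT",
                            thermostat = "langevin", langevin_gamma = 10)
    st <- step_md(st, lang, 1000L, cutoff, alpha, thermo_stride = 0)
    nh <- integrator_spec(dt = dt, T_target = T, ensemble = "NVT")
    st <- step_md(st, nh, as.integer(equil_ps / dt), cutoff, alpha,
                  thermo_stride = 100)
    st <- step_md(st, nh, as.integer(prod_ps / dt), cutoff, alpha,
                  thermo_stride = 100, traj_stride = as.integer(frame_ps / dt))
    structure(list(state = st, frames = attr(st, "frames"),
                   traces = attr(st, "traces"),
                   n = n, T = T, density = density, dt = dt,
                   prod_ps = prod_ps, cutoff = cutoff, alpha = alpha,
                   seed = seed),
              class = "BulkWaterRun")
  })
}

# view a raw step/pos/box frame as a SystemState sharing the run's topology
frame_state <- function(run, frame) {
  st <- run$state
  st$sites[, c("x", "y", "z")] <- frame$pos
  st$box <- simulation_box(frame$box, st$box$periodic)
  st
}

#' Hydrogen bonds per molecule in a bulk-water run
#'
#' Counts geometric hydrogen bonds on each stored production frame and
#' reports the per-molecule participation count (each bond links two
#' molecules, so per molecule this is twice the bond count over N).
#'
#' @param run A [simulate_bulk_water()] result.
#' @param crit An [hb_criterion()].
#' @param max_frames Cap on analysed frames (evenly subsampled).
#' @return List with `hb_per_molecule`, per-frame values, and the s.e.m.
#' @export
bulk_hb_count <- function(run, crit = hb_criterion(), max_frames = Inf) {
  frames <- .subsample(run$frames, max_frames)
  per_frame <- vapply(frames, function(fr) {
    st <- frame_state(run, fr)
    2 * nrow(detect_hbonds(st, crit)) / run$n
  }, numeric(1))
  list(hb_per_molecule = mean(per_frame), per_frame = per_frame,
       se = sd(per_frame) / sqrt(length(per_frame)))
}

#' Cohesive energy per molecule of a bulk-water run
#'
#' Minus the mean intermolecular potential energy per molecule over
#' production. For effective pair models parameterized with a
#' self-polarization term (SPC/E), that term (read from the forcefield file)
#' is subtracted by default so the value sits on the experimental
#' cohesive-energy scale; set `polarization_correction = FALSE` for the raw
#' configurational energy.
#'
#' @param run A [simulate_bulk_water()] result.
#' @param polarization_correction Apply the SPC/E self-energy correction.
#' @return List with `cohesive_kJ_mol`, the raw `u_config_kJ_mol`, and the
#'   correction used.
#' @export
bulk_cohesive_energy <- function(run, polarization_correction = TRUE) {
  tr <- run$traces
  upot <- mean(tr$elj + tr$ecoul)
  corr <- if (polarization_correction)
    read_forcefield(sorpflex_file("spce.ff"))$extra$polarization_correction
  else 0
  list(cohesive_kJ_mol = -upot / run$n - corr,
       u_config_kJ_mol = upot / run$n, correction_kJ_mol = corr)
}

#' Water-water hydrogen-bond energy by pair isolation
#'
#' For each detected water-water bond, the two molecules are isolated and
#' their intermolecular LJ + bare Coulomb energy evaluated; the binding
#' magnitudes are averaged over bonds and frames (kcal/mol).
#'
#' @param run A [simulate_bulk_water()] result.
#' @param crit An [hb_criterion()].
#' @param max_frames Cap on analysed frames.
#' @param max_bonds_per_frame Random subsample of bonds per frame (keeps the
#'   cost bounded; `Inf` = all).
#' @return List with `e_hb_kcal_mol`, per-frame means, and the s.e.m.
#' @export
bulk_hb_energy <- function(run, crit = hb_criterion(), max_frames = Inf,
                           max_bonds_per_frame = 200) {
  frames <- .subsample(run$frames, max_frames)
  per_frame <- vapply(frames, function(fr) {
    st <- frame_state(run, fr)
    rec <- detect_hbonds(st, crit)
    if (!nrow(rec)) return(NA_real_)
    if (nrow(rec) > max_bonds_per_frame)
      rec <- rec[sample.int(nrow(rec), max_bonds_per_frame), , drop = FALSE]
    mean(hb_energies(st, rec, "WW"))
  }, numeric(1))
  per_frame <- per_frame[is.finite(per_frame)]
  list(e_hb_kcal_mol = mean(per_frame), per_frame = per_frame,
       se = sd(per_frame) / sqrt(length(per_frame)))
}

.subsample <- function(frames, max_frames) {
  if (length(frames) > max_frames)
    frames[round(seq(1, length(frames), length.out = max_frames))]
  else frames
}
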