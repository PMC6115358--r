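#' Stochastic inscribed-sphere pore size distribution
#'
#' For random test points in the void space, the diameter of the largest
#' sphere that contains the point while overlapping no site (sites treated as
#' hard spheres of the probe van der Waals radius) is recorded; the histogram
#' of those diameters is the geometric pore size distribution. Sphere radii
#' are capped at half the smallest box length so every reported pore fits in
#' the periodic cell.
#'
#' @param frame A `SystemState`.
#' @param probe Probe van der Waals radius, nm (default 0.1).
#' @param n_samples Number of void test points.
#' @param n_centers Number of candidate sphere centers.
#' @param bin_width Histogram bin width, nm.
#' @param seed Optional seed.
#' @return Object of class `PSDHistogram`: raw `diameters`, histogram
#'   `breaks`/`mids`/`density` (integrating to 1 when any void exists),
#'   `probe_vdw_radius`, `n_sample_points`, and `empty` flag for a fully
#'   dense frame.
#' @export
compute_psd <- function(frame, probe = 0.1, n_samples = 2000,
                        n_centers = 5000, bin_width = 0.05, seed = NULL) {
  s <- frame$sites
  pos <- unname(as.matrix(s[, c("x", "y", "z")]))
  L <- frame$box$lengths
  for (a in 1:3) pos[, a] <- pos[, a] %% L[a]
  d <- with_seed(seed,
    cpp_psd_sample(pos, L, frame$box$periodic, probe,
                   as.integer(n_centers), as.integer(n_samples)))
  empty <- length(d) == 0
  if (empty) {
    return(structure(list(diameters = numeric(0), breaks = numeric(0),
                          mids = numeric(0), density = numeric(0),
                          probe_vdw_radius = probe, n_sample_points = 0L,
                          empty = TRUE), class = "PSDHistogram"))
  }
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  h <- hist(d, breaks = breaks, plot = FALSE)
  structure(list(diameters = d, breaks = breaks, mids = h$mids,
                 density = h$density, probe_vdw_radius = probe,
                 n_sample_points = length(d), empty = FALSE),
            class = "PSDHistogram")
}

#' Modal pore diameter of a PSD
#' @param psd A `PSDHistogram`.
#' @return Bin-center diameter of the highest-density bin, nm.
#' @export
psd_mode <- function(psd) {
  if (psd$empty) return(NA_real_)
  psd$mids[which.max(psd$density)]
}

#' Volume strain relative to a reference volume
#'
#' `eps_V = V / V0 - 1`, the swelling of the hydrated sample relative to the
#' dry reference; negative values are contraction.
#'
#' @param V Current volume, nm^3.
#' @param V0 Reference (dry) volume, nm^3 (> 0).
#' @return Dimensionless volume strain.
#' @export
#' @examples
#' volume_strain(1.36, 1)   # 0.36
volume_strain <- function(V, V0) {
  if (any(V0 <= 0)) stop("volume_strain: V0 must be positive")
  V / V0 - 1
}

# rescale box lengths by per-axis factors; free sites scale affinely, rigid
# groups move by their center of mass so constrained geometry is untouched
scale_box <- function(state, factors) {
  if (length(factors) == 1) factors <- rep(factors, 3)
  s <- state$sites
  pos <- unname(as.matrix(s[, c("x", "y", "z")]))
  newpos <- sweep(pos, 2, factors, `*`)
  for (g in state$topology$rigid_groups) {
    m <- s$mass[g]
    com <- colSums(pos[g, , drop = FALSE] * m) / sum(m)
    shift <- com * (factors - 1)
    newpos[g, ] <- sweep(pos[g, , drop = FALSE], 2, shift, `+`)
  }
  state$sites[, c("x", "y", "z")] <- newpos
  state$box <- simulation_box(state$box$lengths * factors, state$box$periodic)
  state
}

#' Volumetric tensile test under molecular dynamics
#'
#' The box is dilated isotropically so the volume strain follows a linear
#' ramp from 0 to `eps_max` over the stated duration while NVT dynamics runs
#' at constant moisture content (no particle exchange); the virial tension is
#' recorded continuously. The slope at small strain is the undrained bulk
#' modulus.
#'
#' @param state An equilibrated `SystemState`.
#' @param eps_max Final volume strain (default 0.1).
#' @param duration_ns Ramp duration, ns.
#' @param T Temperature, K.
#' @param dt Time step, ps.
#' @param n_chunks Number of ramp increments (stress is averaged per chunk).
#' @param thermostat `"nose-hoover"` or `"langevin"` (the latter damps the
#'   ringing a discrete ramp excites in stiff, nearly harmonic systems).
#' @param cutoff,alpha Nonbonded model parameters.
#' @param seed Optional seed.
#' @return Object of class `StressStrainCurve`: data frame with `eps_V` and
#'   `sigma` (GPa, tension positive), plus `strain_rate` (1/ns) and
#'   `duration` attributes. A truncated curve carries `attr(, "truncated")`.
#' @export
tensile_test <- function(state, eps_max = 0.1, duration_ns = 4, T = 300,
                         dt = 0.001, n_chunks = 100,
                         thermostat = c("nose-hoover", "langevin"),
                         cutoff = 0.9, alpha = 2.0, seed = NULL) {
  thermostat <- match.arg(thermostat)
  steps_total <- max(n_chunks, round(duration_ns * 1000 / dt))
  steps_chunk <- max(1L, as.integer(steps_total / n_chunks))
  spec <- integrator_spec(dt = dt, T_target = T, ensemble = "NVT",
                          thermostat = thermostat, langevin_gamma = 20)
  state <- maxwell_velocities(state, T, seed)
  eps_grid <- seq(0, eps_max, length.out = n_chunks + 1)
  out <- data.frame(eps_V = numeric(0), sigma = numeric(0))
  truncated <- FALSE
  V_now <- box_volume(state$box)
  V0 <- V_now
  for (ck in seq_len(n_chunks)) {
    target_V <- V0 * (1 + eps_grid[ck + 1])
    f <- (target_V / box_volume(state$box))^(1 / 3)
    state <- scale_box(state, f)
    res <- try(step_md(state, spec, steps_chunk, cutoff, alpha,
                       thermo_stride = max(1L, steps_chunk %/% 10L)),
               silent = TRUE)
    if (inherits(res, "try-error")) { truncated <- TRUE; break }
    state <- res
    tr <- attr(state, "traces")
    out <- rbind(out, data.frame(eps_V = volume_strain(box_volume(state$box), V0),
                                 sigma = mean(traces_sigma_gpa(tr[-1, , drop = FALSE]))))
  }
  curve <- structure(out, class = c("StressStrainCurve", "data.frame"))
  attr(curve, "strain_rate") <- eps_max / duration_ns
  attr(curve, "duration") <- duration_ns
  attr(curve, "truncated") <- truncated
  attr(curve, "final_state") <- state
  curve
}

#' Undrained bulk modulus from a stress-strain curve
#'
#' Least-squares slope of tension versus volume strain over the linear
#' (small-strain) window; loading at fixed moisture content makes this the
#' undrained modulus.
#'
#' @param curve A `StressStrainCurve` (or data frame with `eps_V`, `sigma`).
#' @param linear_window Strain window `c(lo, hi)` used for the fit
#'   (default `c(0, 0.02)`).
#' @return List with `K` (GPa), standard error `se`, and `n` points used.
#' @export
bulk_modulus <- function(curve, linear_window = c(0, 0.02)) {
  sel <- curve$eps_V >= linear_window[1] & curve$eps_V <= linear_window[2]
  if (sum(sel) < 5) stop("bulk_modulus: fewer than 5 samples in the linear window")
  fit <- lm(sigma ~ eps_V, data = curve[sel, , drop = FALSE])
  sm <- suppressWarnings(summary(fit))
  list(K = unname(coef(fit)[2]), se = unname(sm$coefficients[2, 2]),
       n = sum(sel))
}
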