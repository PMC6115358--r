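#' Vapor reservoir specification
#'
#' Fixes the chemical potential of the water reservoir through the relative
#' humidity: the vapor is treated as an ideal gas, so
#' `mu - mu0 = kB T ln(RH)` and the absolute activity used in insertion
#' weights is `z = P / (kB T)` with `P = RH * P0`.
#'
#' @param T Temperature, K.
#' @param RH Relative humidity in `[0, 1]`. `RH = 0` is the dry limit: no
#'   insertions, `mu_offset = -Inf`.
#' @param P0 Saturation vapor pressure of the water model, Pa (1017 Pa for
#'   SPC/E at 300 K).
#' @return Object of class `ReservoirSpec` with `mu_offset` (kJ/mol),
#'   `activity` (nm^-3) and `thermal_wavelength`-free convention noted.
#' @export
#' @examples
#' reservoir_spec(300, 0.5)$mu_offset   # kB*300*log(0.5)
reservoir_spec <- function(T, RH, P0 = 1017) {
  stopifnot(T > 0, RH >= 0, RH <= 1, P0 > 0)
  mu <- if (RH > 0) .kB * T * log(RH) else -Inf
  P_int <- RH * P0 / .Pa_per_internal          # kJ/mol/nm^3
  structure(list(T = T, RH = RH, P0 = P0, mu_offset = mu,
                 activity = P_int / (.kB * T)), class = "ReservoirSpec")
}

#' Relative humidity to chemical potential offset
#'
#' @param RH Relative humidity, `0 < RH <= 1`.
#' @param T Temperature, K.
#' @param P0 Model saturation pressure, Pa.
#' @return List with `mu_offset` (kJ/mol, `kB T ln RH`) and `activity`
#'   (`P/(kB T)`, nm^-3).
#' @export
#' @examples
#' rh_to_mu(0.5, 300)$mu_offset    # -1.7289 kJ/mol
rh_to_mu <- function(RH, T, P0 = 1017) {
  stopifnot(RH > 0, RH <= 1)
  r <- reservoir_spec(T, RH, P0)
  list(mu_offset = r$mu_offset, activity = r$activity)
}

# shared helper: run the compiled GCMC kernel and rebuild the SystemState
run_gcmc_cpp <- function(state, reservoir, n_moves, move_mix, dmax, amax,
                         cutoff, alpha, trace_stride = 0, seed = NULL) {
  s <- state$sites
  water_idx <- which(s$role == "water")
  host_idx <- which(s$role == "host")
  if (length(water_idx) && length(host_idx) && max(host_idx) > min(water_idx))
    stop("water sites must follow all host sites")
  water_start <- if (length(host_idx)) max(host_idx) + 1L else 1L
  tpl <- water_template()
  packed <- pack_system(state, cutoff, alpha)
  probs <- move_mix[c("insert", "delete", "translate", "rotate")]
  probs[is.na(probs)] <- 0
  out <- with_seed(seed,
    cpp_run_gcmc(packed, water_start, tpl$rel, tpl$charge, tpl$sigma,
                 tpl$epsilon, tpl$mass, reservoir$T, reservoir$activity,
                 as.integer(n_moves), as.numeric(probs), dmax, amax,
                 as.integer(trace_stride)))
  # rebuild: host block unchanged, water block replaced
  host_sites <- s[s$role == "host", , drop = FALSE]
  nh <- nrow(host_sites)
  nw <- out$n_water
  topo <- state$topology
  topo$rigid_groups <- Filter(function(g) all(g <= nh), topo$rigid_groups)
  newstate <- system_state(state$box, host_sites, topo,
                           state$velocities[seq_len(nh), , drop = FALSE],
                           state$frozen_host)
  if (nw > 0) {
    wpos <- out$water_pos
    wsites <- do.call(rbind, lapply(seq_len(nw), function(w) {
      m <- make_water(c(0, 0, 0))$sites
      m[, c("x", "y", "z")] <- wpos[(w - 1) * 3 + 1:3, , drop = FALSE]
      m$molecule_id <- max(c(0L, host_sites$molecule_id)) + w
      m
    }))
    groups <- newstate$topology$rigid_groups
    for (w in seq_len(nw)) groups[[length(groups) + 1]] <- nh + (w - 1) * 3 + 1:3
    topo2 <- newstate$topology
    topo2$rigid_groups <- groups
    newstate <- system_state(newstate$box, rbind(host_sites, wsites), topo2,
                             rbind(newstate$velocities, matrix(0, 3 * nw, 3)),
                             state$frozen_host)
  }
  stats <- structure(list(attempted = out$attempted, accepted = out$accepted,
                          ratio = ifelse(out$attempted > 0,
                                         out$accepted / out$attempted, NA_real_)),
                     class = "MoveStats")
  list(state = newstate, stats = stats, nw_trace = out$nw_trace)
}

#' Attempt a single grand canonical move
#'
#' Metropolis acceptance with the standard grand canonical weights: insertion
#' `min(1, zV/(N+1) exp(-beta dU))`, deletion `min(1, N/(zV) exp(-beta dU))`,
#' displacement/rotation `min(1, exp(-beta dU))`. A deletion attempted on a
#' dry system is rejected and flagged, not an error.
#'
#' @param state A `SystemState`.
#' @param kind One of `"insert"`, `"delete"`, `"translate"`, `"rotate"`.
#' @param reservoir A [reservoir_spec()].
#' @param dmax Maximum translation half-width, nm.
#' @param amax Maximum rotation half-angle, rad.
#' @param cutoff,alpha Nonbonded model parameters.
#' @param seed Optional seed.
#' @return List with updated `state`, logical `accepted`, logical `empty`
#'   (deletion on a dry system) and `stats`.
#' @export
attempt_move <- function(state, kind = c("insert", "delete", "translate", "rotate"),
                         reservoir, dmax = 0.15, amax = pi / 4,
                         cutoff = 0.9, alpha = 2.0, seed = NULL) {
  kind <- match.arg(kind)
  empty <- (kind %in% c("delete", "translate", "rotate")) && n_water(state) == 0
  mix <- c(insert = 0, delete = 0, translate = 0, rotate = 0)
  mix[kind] <- 1
  res <- run_gcmc_cpp(state, reservoir, 1L, mix, dmax, amax, cutoff, alpha,
                      seed = seed)
  list(state = res$state, accepted = sum(res$stats$accepted) > 0,
       empty = empty, stats = res$stats)
}

#' Run a block of grand canonical Monte Carlo moves
#'
#' Host sites are never touched by GCMC; only rigid waters are inserted,
#' deleted, displaced or rotated against the ideal-vapor reservoir.
#'
#' @param state A `SystemState`.
#' @param reservoir A [reservoir_spec()].
#' @param n_moves Number of attempted moves.
#' @param move_mix Named probabilities over
#'   `insert/delete/translate/rotate`; must sum to 1.
#' @param dmax,amax Maximum displacement (nm) and rotation (rad).
#' @param cutoff,alpha Nonbonded model parameters.
#' @param trace_stride Record `N_w` every this many attempts (0 = off).
#' @param seed Optional seed.
#' @return List with updated `state`, `stats` (`MoveStats`) and `nw_trace`.
#' @export
run_gcmc_block <- function(state, reservoir, n_moves,
                           move_mix = c(insert = 0.25, delete = 0.25,
                                        translate = 0.25, rotate = 0.25),
                           dmax = 0.15, amax = pi / 4, cutoff = 0.9,
                           alpha = 2.0, trace_stride = 0, seed = NULL) {
  stopifnot(abs(sum(move_mix) - 1) < 1e-9)
  if (reservoir$RH == 0) {
    # dry limit: no insertions; deletions always accepted in the z -> 0 limit
    move_mix <- c(insert = 0, delete = move_mix["delete"] + move_mix["insert"],
                  translate = move_mix["translate"], rotate = move_mix["rotate"])
    names(move_mix) <- c("insert", "delete", "translate", "rotate")
    move_mix <- move_mix / sum(move_mix)
    reservoir <- reservoir_spec(reservoir$T, .Machine$double.xmin, reservoir$P0)
  }
  run_gcmc_cpp(state, reservoir, n_moves, move_mix, dmax, amax, cutoff, alpha,
               trace_stride, seed)
}
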