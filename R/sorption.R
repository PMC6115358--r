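#' Schedule for hybrid GCMC/MD sorption runs
#'
#' Each block is a sweep of grand canonical attempts followed (for a
#' deformable or flexible host) by constant-stress or constant-volume MD.
#' The run is declared converged when two consecutive `window`-block means of
#' both moisture content and volume agree within `tol` (relative), after
#' which `prod_blocks` production blocks are accumulated.
#'
#' @param gcmc_moves GCMC attempts per block.
#' @param md_steps MD steps per block (0 disables MD: pure GCMC).
#' @param dt MD time step, ps.
#' @param T Temperature, K.
#' @param sigma_ext External stress, Pa (tension positive).
#' @param max_blocks Convergence budget.
#' @param window Blocks per convergence window.
#' @param tol Relative tolerance on consecutive window means.
#' @param prod_blocks Production blocks after convergence.
#' @param move_mix GCMC move probabilities.
#' @param dmax,amax GCMC displacement (nm) and rotation (rad) amplitudes.
#' @param cutoff,alpha Nonbonded model parameters.
#' @param constant_volume Hold the box fixed (controls); otherwise NsigmaT.
#' @param sample_hb Collect hydrogen-bond summaries during production.
#' @param hb_crit Criterion for [detect_hbonds()].
#' @return Object of class `SorptionSchedule`.
#' @export
sorption_schedule <- function(gcmc_moves = 2000, md_steps = 1000, dt = 0.001,
                              T = 300, sigma_ext = 0, max_blocks = 60,
                              window = 10, tol = 0.02, prod_blocks = 10,
                              move_mix = c(insert = 0.25, delete = 0.25,
                                           translate = 0.25, rotate = 0.25),
                              dmax = 0.15, amax = pi / 4, cutoff = 0.9,
                              alpha = 2.0, constant_volume = FALSE,
                              sample_hb = TRUE, hb_crit = hb_criterion()) {
  stopifnot(gcmc_moves >= 0, md_steps >= 0, max_blocks >= 2 * window)
  structure(list(gcmc_moves = gcmc_moves, md_steps = md_steps, dt = dt, T = T,
                 sigma_ext = sigma_ext, max_blocks = max_blocks,
                 window = window, tol = tol, prod_blocks = prod_blocks,
                 move_mix = move_mix, dmax = dmax, amax = amax,
                 cutoff = cutoff, alpha = alpha,
                 constant_volume = constant_volume, sample_hb = sample_hb,
                 hb_crit = hb_crit), class = "SorptionSchedule")
}

M_WATER <- 18.0154   # g/mol

# one GCMC + MD block; returns updated state
.hybrid_block <- function(state, reservoir, sch) {
  res <- run_gcmc_block(state, reservoir, sch$gcmc_moves, sch$move_mix,
                        sch$dmax, sch$amax, sch$cutoff, sch$alpha)
  state <- res$state
  if (sch$md_steps > 0) {
    # fresh thermal velocities for (possibly new) waters; host keeps its own
    nh <- sum(state$sites$role == "host")
    nw3 <- nrow(state$sites) - nh
    if (nw3 > 0) {
      vw <- matrix(rnorm(3 * nw3), nw3, 3) *
        sqrt(.kB * sch$T / state$sites$mass[(nh + 1):(nh + nw3)])
      state$velocities[(nh + 1):(nh + nw3), ] <- vw
    }
    # brief damped settling pass: freshly inserted waters can sit in strained
    # contacts that the constraint solver cannot take at full step
    n_settle <- min(50L, max(10L, sch$md_steps %/% 10L))
    settle <- integrator_spec(dt = sch$dt / 4, T_target = sch$T,
                              ensemble = "NVT", thermostat = "langevin",
                              langevin_gamma = 30)
    state <- step_md(state, settle, n_settle, sch$cutoff, sch$alpha,
                     thermo_stride = 0)
    spec <- integrator_spec(dt = sch$dt, T_target = sch$T,
                            sigma_ext = sch$sigma_ext,
                            ensemble = if (sch$constant_volume) "NVT" else "NsigmaT")
    st2 <- try(step_md(state, spec, sch$md_steps, sch$cutoff, sch$alpha,
                       thermo_stride = 0), silent = TRUE)
    if (inherits(st2, "try-error")) {
      # one retry at half step after extra damping
      state <- step_md(state, settle, 4L * n_settle, sch$cutoff, sch$alpha,
                       thermo_stride = 0)
      spec$dt <- sch$dt / 2
      st2 <- step_md(state, spec, sch$md_steps, sch$cutoff, sch$alpha,
                     thermo_stride = 0)
    }
    state <- st2
  }
  list(state = state, stats = res$stats)
}

#' Equilibrate and measure one point of the sorption isotherm
#'
#' Alternates GCMC water exchange with NsigmaT (or NVT) molecular dynamics at
#' fixed (mu, sigma, T) until moisture content and volume are stationary,
#' then averages over production blocks. Non-convergence within the block
#' budget yields a flagged (kept) point.
#'
#' @param state A `SystemState`.
#' @param reservoir A [reservoir_spec()].
#' @param schedule A [sorption_schedule()].
#' @param V0 Dry reference volume for the strain, nm^3 (defaults to the
#'   current volume).
#' @param seed Optional seed.
#' @return List with the final `state` and `point` (class `SorptionPoint`):
#'   RH, moisture content `m`, `eps_V`, mean `N_w`, `V`, `hb` summary,
#'   `n_blocks_to_converge`, `converged`.
#' @export
run_hybrid_point <- function(state, reservoir, schedule = sorption_schedule(),
                             V0 = NULL, seed = NULL) {
  with_seed(seed, {
    sch <- schedule
    if (is.null(V0)) V0 <- box_volume(state$box)
    dm <- dry_mass(state)
    m_tr <- numeric(0); v_tr <- numeric(0)
    converged <- FALSE; nconv <- sch$max_blocks
    for (b in seq_len(sch$max_blocks)) {
      state <- .hybrid_block(state, reservoir, sch)$state
      m_tr <- c(m_tr, if (dm > 0) n_water(state) * M_WATER / dm else 0)
      v_tr <- c(v_tr, box_volume(state$box))
      if (b >= 2 * sch$window) {
        w2 <- (b - sch$window + 1):b
        w1 <- w2 - sch$window
        rel <- function(x) abs(mean(x[w2]) - mean(x[w1])) /
          max(mean(x[c(w1, w2)]), 1e-3)
        if (rel(m_tr) < sch$tol && rel(v_tr) < sch$tol) {
          converged <- TRUE; nconv <- b; break
        }
      }
    }
    nw_acc <- numeric(0); v_acc <- numeric(0); hb_acc <- list()
    for (b in seq_len(sch$prod_blocks)) {
      state <- .hybrid_block(state, reservoir, sch)$state
      nw_acc <- c(nw_acc, n_water(state))
      v_acc <- c(v_acc, box_volume(state$box))
      if (sch$sample_hb)
        hb_acc[[length(hb_acc) + 1]] <-
          summarize_hbonds(detect_hbonds(state, sch$hb_crit), state)
    }
    hb <- if (length(hb_acc)) {
      num <- names(hb_acc[[1]])[vapply(hb_acc[[1]], is.numeric, logical(1))]
      av <- lapply(num, function(f)
        mean(vapply(hb_acc, function(h) h[[f]], numeric(1)), na.rm = TRUE))
      structure(setNames(av, num), class = "HBSummary")
    } else NULL
    mean_nw <- mean(nw_acc)
    point <- structure(list(
      RH = reservoir$RH,
      m = if (dm > 0) mean_nw * M_WATER / dm else 0,
      eps_V = volume_strain(mean(v_acc), V0),
      N_w = mean_nw, V = mean(v_acc), V0 = V0,
      sd_m = if (dm > 0) sd(nw_acc) * M_WATER / dm else 0,
      sd_V = sd(v_acc),
      hb = hb, K = NA_real_,
      n_blocks_to_converge = nconv, converged = converged),
      class = "SorptionPoint")
    list(state = state, point = point)
  })
}

#' Run a sorption isotherm branch over an RH grid
#'
#' Each point inherits the previous point's configuration -- the history
#' dependence is the mechanism under study. Adsorption must scan RH upward
#' from a relaxed dry host; desorption scans downward from a swollen state.
#'
#' @param initial_state Starting `SystemState`.
#' @param RH_grid Relative humidities, strictly monotone in the direction.
#' @param direction `"adsorption"` or `"desorption"`.
#' @param schedule A [sorption_schedule()].
#' @param V0 Dry reference volume (defaults to the initial state's volume --
#'   pass the dry volume explicitly for desorption).
#' @param P0 Model saturation pressure, Pa.
#' @param seed Optional seed (stored as `realization_seed`).
#' @param keep_states Retain the configuration at each grid point (for
#'   per-point post-analysis such as mechanical testing).
#' @return Object of class `IsothermBranch`: `direction`, list of `points`,
#'   `final_state`, `realization_seed`, and (optionally) `states`. Use
#'   [branch_table()] for a data frame view.
#' @export
run_isotherm <- function(initial_state, RH_grid,
                         direction = c("adsorption", "desorption"),
                         schedule = sorption_schedule(), V0 = NULL,
                         P0 = 1017, seed = NULL, keep_states = FALSE) {
  direction <- match.arg(direction)
  d <- diff(RH_grid)
  if (direction == "adsorption" && length(d) && any(d <= 0))
    stop("adsorption grid must be strictly increasing")
  if (direction == "desorption" && length(d) && any(d >= 0))
    stop("desorption grid must be strictly decreasing")
  if (is.null(V0)) V0 <- box_volume(initial_state$box)
  state <- initial_state
  points <- vector("list", length(RH_grid))
  states <- if (keep_states) vector("list", length(RH_grid)) else NULL
  with_seed(seed, {
    for (i in seq_along(RH_grid)) {
      res <- run_hybrid_point(state, reservoir_spec(schedule$T, RH_grid[i], P0),
                              schedule, V0 = V0)
      state <- res$state
      points[[i]] <- res$point
      if (keep_states) states[[i]] <- state
    }
  })
  structure(list(direction = direction, points = points, final_state = state,
                 realization_seed = seed, states = states),
            class = "IsothermBranch")
}

#' Tabulate an isotherm branch
#' @param branch An `IsothermBranch`.
#' @return Data frame with RH, m, eps_V, N_w, HB columns, K and flags.
#' @export
branch_table <- function(branch) {
  do.call(rbind, lapply(branch$points, function(p) {
    data.frame(RH = p$RH, m = p$m, eps_V = p$eps_V, N_w = p$N_w, V = p$V,
               hb_ww = if (!is.null(p$hb)) p$hb$hb_ww_per_water else NA,
               hb_cw = if (!is.null(p$hb)) p$hb$hb_cw_per_water else NA,
               hb_cc = if (!is.null(p$hb)) p$hb$hb_cc_per_unit else NA,
               n_ww_raw = if (!is.null(p$hb)) p$hb$n_ww_raw else NA,
               K = p$K, converged = p$converged,
               n_blocks = p$n_blocks_to_converge)
  }))
}

#' Constant-volume adsorption/desorption control cycles
#'
#' Water sorption cycles in a host held at fixed volume, either with chain
#' relaxation (`flexible = TRUE`: NVT MD between GCMC blocks) or with the
#' host frozen (pure GCMC). These controls are hysteresis-free; comparing
#' them with the deformable run isolates the role of swelling.
#'
#' @param state Host state whose volume (and, if frozen, configuration) is
#'   held; use the dry and the swollen states for the two control families.
#' @param flexible Allow host relaxation at constant volume.
#' @param RH_grid Humidity grid (given increasing; the down sweep reverses it).
#' @param schedule A [sorption_schedule()] (its `constant_volume` flag is
#'   forced on; `md_steps` forced to 0 when frozen).
#' @param P0 Saturation pressure, Pa.
#' @param seed Optional seed.
#' @return List with `up` and `down` `IsothermBranch`es.
#' @export
run_fixed_volume_control <- function(state, flexible, RH_grid,
                                     schedule = sorption_schedule(),
                                     P0 = 1017, seed = NULL) {
  sch <- schedule
  sch$constant_volume <- TRUE
  state$frozen_host <- !flexible
  if (!flexible) sch$md_steps <- 0L
  RH_up <- sort(RH_grid)
  RH_dn <- rev(RH_up)
  up <- run_isotherm(state, RH_up, "adsorption", sch,
                     V0 = box_volume(state$box), P0 = P0, seed = seed)
  dn <- run_isotherm(up$final_state, RH_dn, "desorption", sch,
                     V0 = box_volume(state$box), P0 = P0,
                     seed = if (is.null(seed)) NULL else seed + 1L)
  list(up = up, down = dn)
}
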