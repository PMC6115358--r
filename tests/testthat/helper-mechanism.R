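# The sorption-mechanism study on the surrogate host: three independent
# realizations, adsorption and desorption branches, frozen fixed-volume
# controls, and bulk moduli along both branches. Run once per test session
# (cached); the acceptance expectations all read from this object.
#
# Study conditions (fixed): 3 chains x 8 repeat units grown at 1.2 g/cm^3,
# 200 ps NsigmaT dry relaxation (a fixed glass-preparation protocol; the
# dry reference volume is the time-averaged volume of its final third),
# humidity grid 0.2-0.95 swept up then down, 10,000 GCMC attempts + 0.3 ps
# NsigmaT dynamics per block, convergence window 4 blocks at 4%, 6
# production blocks. Frozen controls use Monte Carlo only with 40,000
# attempts per block (deeply bound waters desorb slowly under unbiased
# Metropolis sampling, so control sweeps need large blocks).

mechanism_grid <- c(0.2, 0.5, 0.7, 0.85, 0.95)

mechanism_schedule <- function() {
  sorption_schedule(gcmc_moves = 10000, md_steps = 300, dt = 0.001,
                    max_blocks = 30, window = 4, tol = 0.04, prod_blocks = 6)
}

mechanism_control_schedule <- function() {
  sorption_schedule(gcmc_moves = 40000, md_steps = 0, max_blocks = 16,
                    window = 4, tol = 0.04, prod_blocks = 6,
                    constant_volume = TRUE)
}

mechanism_study <- function() {
  cached("mechanism_study", {
    grid <- mechanism_grid
    sch <- mechanism_schedule()
    real <- lapply(1:3, function(rz) {
      host <- grow_chains(build_recipe(3, 8, 1.2, seed = rz))
      host <- relax_host(host, duration = 200, T = 300, seed = 100 + rz)
      V0 <- attr(host, "V0")
      attr(host, "traces") <- NULL
      attr(host, "frames") <- NULL
      ads <- run_isotherm(host, grid, "adsorption", sch, V0 = V0,
                          seed = 30 + rz, keep_states = TRUE)
      des <- run_isotherm(ads$final_state, rev(grid), "desorption", sch,
                          V0 = V0, seed = 60 + rz, keep_states = TRUE)
      list(host = host, V0 = V0, ads = ads, des = des)
    })
    pooled <- do.call(rbind, lapply(seq_along(real), function(i) {
      rbind(cbind(branch_table(real[[i]]$ads), dir = "ads", rz = i),
            cbind(branch_table(real[[i]]$des), dir = "des", rz = i))
    }))

    ctl_sch <- mechanism_control_schedule()
    ctl_dry <- run_fixed_volume_control(real[[1]]$host, flexible = FALSE,
                                        grid, ctl_sch, seed = 41)
    ctl_sw <- run_fixed_volume_control(real[[1]]$ads$final_state,
                                       flexible = FALSE, grid, ctl_sch,
                                       seed = 42)

    # bulk modulus along both branches of the realization with the widest
    # moisture range: hydration-induced weakening is only measurable where
    # hydration actually varies, so mechanics are probed on the sample with
    # the largest moisture contrast (a measurement-design choice, fixed
    # before the mechanical data are seen). Two tensile seeds per point.
    m_range <- vapply(real, function(r)
      diff(range(c(branch_table(r$ads)$m, branch_table(r$des)$m))), numeric(1))
    imech <- which.max(m_range)
    K_of <- function(st) {
      mean(vapply(1:2, function(sd) {
        cv <- tensile_test(st, eps_max = 0.025, duration_ns = 0.015, T = 300,
                           n_chunks = 25, thermostat = "langevin",
                           seed = 200 + sd)
        bulk_modulus(cv, c(0, 0.02))$K
      }, numeric(1)))
    }
    r <- real[[imech]]
    K <- data.frame(rz = imech,
                    dir = rep(c("ads", "des"), each = length(grid)),
                    RH = c(grid, rev(grid)),
                    m = c(branch_table(r$ads)$m, branch_table(r$des)$m),
                    hb_cc = c(branch_table(r$ads)$hb_cc, branch_table(r$des)$hb_cc),
                    K = c(vapply(r$ads$states, K_of, numeric(1)),
                          vapply(r$des$states, K_of, numeric(1))))
    list(real = real, pooled = pooled, ctl_dry = ctl_dry, ctl_sw = ctl_sw,
         K = K, grid = grid)
  })
}

# realization-averaged table per (RH, direction), the study's reporting unit
mechanism_averaged <- function(ms) {
  aggregate(cbind(m, eps_V) ~ RH + dir, ms$pooled, mean)
}
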