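# a fast schedule for contract-level checks
fast_schedule <- function(...) {
  sorption_schedule(gcmc_moves = 1500, md_steps = 0, max_blocks = 8,
                    window = 2, tol = 0.1, prod_blocks = 3, sample_hb = FALSE,
                    ...)
}

test_that("moisture content identity and the dry limit hold exactly", {
  st <- make_fixture("slit_pore", gap = 1.2)
  res <- run_hybrid_point(st, reservoir_spec(300, 0.7), fast_schedule(), seed = 1)
  p <- res$point
  expect_equal(p$m, p$N_w * 18.0154 / dry_mass(st), tolerance = 1e-9)
  expect_gte(p$m, 0)
  expect_gt(p$eps_V, -1)

  dry <- run_hybrid_point(st, reservoir_spec(300, 0), fast_schedule(), seed = 2)
  expect_equal(dry$point$m, 0)
  expect_equal(dry$point$eps_V, 0, tolerance = 1e-9)
})

test_that("isotherm grids are validated and single-point branches work", {
  st <- make_fixture("slit_pore", gap = 1.2)
  expect_error(run_isotherm(st, c(0.5, 0.3), "adsorption", fast_schedule()),
               "increasing")
  expect_error(run_isotherm(st, c(0.3, 0.5), "desorption", fast_schedule()),
               "decreasing")
  br <- run_isotherm(st, 0.6, "adsorption", fast_schedule(), seed = 3)
  expect_equal(length(br$points), 1)
  expect_equal(branch_table(br)$RH, 0.6)
})

test_that("a frozen host at constant volume makes the hybrid method pure GCMC", {
  # distributional equivalence: the hybrid driver with md_steps = 0 must agree
  # with a long plain GCMC chain on the same slit pore
  st <- make_fixture("slit_pore", gap = 1.2)
  res <- reservoir_spec(300, 0.9)
  sch <- sorption_schedule(gcmc_moves = 3000, md_steps = 0, max_blocks = 10,
                           window = 2, tol = 0.05, prod_blocks = 8,
                           sample_hb = FALSE, constant_volume = TRUE)
  hp <- with_seed(11, run_hybrid_point(st, res, sch))
  pure <- with_seed(12, {
    s <- st
    burn <- run_gcmc_block(s, res, 15000)
    ns <- integer(0)
    s <- burn$state
    for (b in 1:8) {
      out <- run_gcmc_block(s, res, 3000)
      s <- out$state
      ns <- c(ns, n_water(s))
    }
    ns
  })
  se <- sqrt(var(pure) / length(pure) + (hp$point$sd_m * dry_mass(st) / 18.0154)^2 / 8)
  expect_lt(abs(hp$point$N_w - mean(pure)), 3 * max(se, 1))
})

test_that("constant-volume controls keep the box fixed and produce both sweeps", {
  st <- make_fixture("slit_pore", gap = 1.2)
  V <- box_volume(st$box)
  ctl <- run_fixed_volume_control(st, flexible = FALSE, c(0.3, 0.8),
                                  fast_schedule(), seed = 4)
  expect_equal(ctl$up$direction, "adsorption")
  expect_equal(ctl$down$direction, "desorption")
  for (p in c(ctl$up$points, ctl$down$points)) {
    expect_equal(p$V, V, tolerance = 1e-12)
    expect_equal(p$eps_V, 0, tolerance = 1e-12)
  }
})

test_that("two seeds give statistically compatible uptake", {
  st <- make_fixture("slit_pore", gap = 1.2)
  res <- reservoir_spec(300, 0.8)
  sch <- sorption_schedule(gcmc_moves = 4000, md_steps = 0, max_blocks = 8,
                           window = 2, tol = 0.05, prod_blocks = 6,
                           sample_hb = FALSE, constant_volume = TRUE)
  p1 <- run_hybrid_point(st, res, sch, seed = 21)$point
  p2 <- run_hybrid_point(st, res, sch, seed = 22)$point
  pooled <- sqrt(p1$sd_m^2 / 6 + p2$sd_m^2 / 6)
  expect_lt(abs(p1$m - p2$m), 3 * max(pooled, 18.0154 / dry_mass(st)))
})
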