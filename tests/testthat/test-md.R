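test_that("NVE dynamics conserves energy for an LJ dimer", {
  s <- data.frame(x = c(1, 1.38), y = 1, z = 1, label = "X", charge = 0,
                  sigma = 0.3, epsilon = 1.0, mass = 20,
                  molecule_id = 1:2, role = "host", hb_role = "",
                  stringsAsFactors = FALSE)
  st <- system_state(simulation_box(rep(4, 3)), s)
  st <- maxwell_velocities(st, 50, seed = 1)
  r <- step_md(st, integrator_spec(dt = 0.001, ensemble = "NVE"), 10000,
               cutoff = 1.5, thermo_stride = 100)
  tr <- attr(r, "traces")
  etot <- tr$ekin + tr$elj + tr$ecoul + tr$ebonded
  scale <- max(abs(etot[1]), max(tr$ekin))
  expect_lt(max(abs(etot - etot[1])) / scale, 1e-4)
})

test_that("the thermostat maintains the target temperature", {
  # unconstrained ideal gas (no interactions)
  st <- make_fixture("harmonic_solid", nx = 4, a = 0.4, k = 0)
  st$sites$molecule_id <- seq_len(nrow(st$sites))
  st$topology <- topology()
  st <- maxwell_velocities(st, 300, seed = 2)
  r <- step_md(st, integrator_spec(dt = 0.002, ensemble = "NVT"), 10000,
               thermo_stride = 20)
  tr <- attr(r, "traces")
  Ts <- tr$T[-(1:100)]
  se <- sd(Ts) / sqrt(length(Ts) / 20)   # crude decorrelation allowance
  expect_lt(abs(mean(Ts) - 300), 3 * max(se, 2))
})

test_that("a frozen host never moves and momentum stays removed", {
  st <- make_fixture("slit_pore", gap = 1.0, lateral = 1.2)
  st <- add_waters(st, matrix(c(0.5, 0.5, 0.65), 1, 3))
  st <- maxwell_velocities(st, 300, seed = 3)
  host_pos <- as.matrix(st$sites[st$sites$role == "host", c("x", "y", "z")])
  r <- step_md(st, integrator_spec(dt = 0.001, ensemble = "NVT"), 500)
  expect_identical(as.matrix(r$sites[r$sites$role == "host", c("x", "y", "z")]),
                   host_pos)

  # momentum conservation without frozen sites
  st2 <- make_fixture("bulk_water", n = 27, seed = 4)
  st2 <- maxwell_velocities(st2, 300, seed = 5)
  r2 <- step_md(st2, integrator_spec(dt = 0.002, ensemble = "NVT"), 300,
                cutoff = 0.45, com_every = 10)
  p <- colSums(r2$velocities * r2$sites$mass)
  expect_lt(max(abs(p)), 1e-8)
})

test_that("virial stress matches closed forms", {
  # zero-velocity harmonic solid at its lattice geometry: stress is zero
  hs <- make_fixture("harmonic_solid", nx = 3, a = 0.4, k = 500)
  expect_lt(max(abs(measure_stress(hs))), 1e-9 * 1.66e6)

  # uniformly stretched lattice: sigma = 2 k eps / (a (1+eps)^2), tension +
  eps <- 0.01
  hs2 <- sorpflex:::scale_box(hs, 1 + eps)
  analytic <- 2 * 500 * eps / (0.4 * (1 + eps)^2) * sorpflex_constants()$Pa_per_internal
  expect_equal(mean(measure_stress(hs2)), analytic, tolerance = 1e-9)

  # moving ideal gas: per-axis stress = -(sum m v_a^2)/V exactly (no forces)
  ig <- make_fixture("harmonic_solid", nx = 4, a = 0.4, k = 0)
  ig$topology <- topology()
  ig$sites$molecule_id <- seq_len(nrow(ig$sites))
  ig <- maxwell_velocities(ig, 300, seed = 6)
  V <- box_volume(ig$box)
  expected <- -colSums(ig$velocities^2 * ig$sites$mass) / V *
    sorpflex_constants()$Pa_per_internal
  expect_equal(measure_stress(ig), expected, tolerance = 1e-9)
})

test_that("rigid water geometry is preserved through dynamics", {
  st <- make_fixture("bulk_water", n = 27, seed = 8)
  st <- maxwell_velocities(st, 300, seed = 9)
  r <- step_md(st, integrator_spec(dt = 0.002, ensemble = "NVT"), 500,
               cutoff = 0.45)
  pos <- as.matrix(r$sites[, c("x", "y", "z")])
  for (g in r$topology$rigid_groups[1:5]) {
    doh1 <- sqrt(sum((pos[g[2], ] - pos[g[1], ])^2))
    doh2 <- sqrt(sum((pos[g[3], ] - pos[g[1], ])^2))
    expect_equal(doh1, 0.1, tolerance = 1e-8)
    expect_equal(doh2, 0.1, tolerance = 1e-8)
  }
})
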