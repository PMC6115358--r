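test_that("inscribed-sphere PSD recovers slit and empty-cell geometry", {
  sp <- make_fixture("slit_pore", gap = 1.2)
  psd <- compute_psd(sp, probe = 0.1, n_samples = 2500, n_centers = 8000, seed = 1)
  # geometric pore diameter = gap - 2 * probe = 1.0 nm, within one bin
  expect_lt(abs(psd_mode(psd) - 1.0), 0.075)
  # density integrates to one
  expect_equal(sum(psd$density * diff(psd$breaks)), 1, tolerance = 1e-6)

  empty <- system_state(simulation_box(rep(3, 3)))
  psd_e <- compute_psd(empty, probe = 0.1, n_samples = 400, n_centers = 1500, seed = 1)
  expect_lt(abs(psd_mode(psd_e) - 3.0), 0.075)
})

test_that("PSD is reproducible across seeds and invariant under translation", {
  sp <- make_fixture("slit_pore", gap = 1.0)
  p1 <- compute_psd(sp, n_samples = 2000, n_centers = 6000, seed = 11)
  p2 <- compute_psd(sp, n_samples = 2000, n_centers = 6000, seed = 12)
  expect_lt(abs(mean(p1$diameters) - mean(p2$diameters)),
            3 * sqrt(var(p1$diameters) / 2000 + var(p2$diameters) / 2000) + 0.01)
  sp_t <- sp
  sp_t$sites[, c("x", "y", "z")] <- sp_t$sites[, c("x", "y", "z")] +
    matrix(c(0.37, -0.61, 0.52), nrow(sp$sites), 3, byrow = TRUE)
  p3 <- compute_psd(sp_t, n_samples = 2000, n_centers = 6000, seed = 11)
  expect_lt(abs(mean(p1$diameters) - mean(p3$diameters)),
            3 * sqrt(var(p1$diameters) / 2000 + var(p3$diameters) / 2000) + 0.01)
})

test_that("volume strain is the exact ratio minus one", {
  expect_equal(volume_strain(2.5, 2.5), 0)
  expect_equal(volume_strain(1.36, 1.0), 0.36)
  expect_equal(volume_strain(0.9, 1.0), -0.1)
  expect_error(volume_strain(1, 0), "positive")
})

test_that("bulk modulus extraction is exact on synthetic curves", {
  eps <- seq(0, 0.05, length.out = 60)
  lin <- structure(data.frame(eps_V = eps, sigma = 2.0 * eps),
                   class = c("StressStrainCurve", "data.frame"))
  expect_equal(bulk_modulus(lin, c(0, 0.05))$K, 2.0, tolerance = 1e-9)

  # quadratic curve: a least-squares line over a window [0, w] of
  # sigma = K eps + c eps^2 has slope K + c w exactly (dense sampling), so
  # the fitted slope converges to K as the window shrinks
  quad <- data.frame(eps_V = eps, sigma = 2 * eps + 50 * eps^2)
  expect_equal(bulk_modulus(quad, c(0, 0.01))$K, 2.0 + 50 * 0.01, tolerance = 0.02)
  eps_f <- seq(0, 0.002, length.out = 40)
  quad_f <- data.frame(eps_V = eps_f, sigma = 2 * eps_f + 50 * eps_f^2)
  expect_equal(bulk_modulus(quad_f, c(0, 0.002))$K, 2.0, tolerance = 0.06)

  with_seed(5, {
    noisy <- data.frame(eps_V = eps, sigma = 3.5 * eps + rnorm(60, sd = 0.01))
    fit <- bulk_modulus(noisy, c(0, 0.05))
    expect_lt(abs(fit$K - 3.5), 3 * fit$se)
  })
  expect_error(bulk_modulus(lin, c(0, 0.001)), "fewer than 5")
})

test_that("the volumetric tensile test recovers the lattice bulk modulus", {
  k <- 1000; a <- 0.4
  hs <- make_fixture("harmonic_solid", nx = 4, a = a, k = k)
  K_analytic <- 2 * k / (3 * a) * sorpflex_constants()$Pa_per_internal / 1e9
  cv <- tensile_test(hs, eps_max = 0.03, duration_ns = 0.06, T = 1,
                     n_chunks = 60, thermostat = "langevin", seed = 2)
  K <- bulk_modulus(cv, c(0, 0.02))$K
  expect_lt(abs(K - K_analytic) / K_analytic, 0.10)

  # halving the strain rate leaves the slope essentially unchanged
  cv2 <- tensile_test(hs, eps_max = 0.03, duration_ns = 0.12, T = 1,
                      n_chunks = 60, thermostat = "langevin", seed = 3)
  K2 <- bulk_modulus(cv2, c(0, 0.02))$K
  expect_lt(abs(K2 - K) / K_analytic, 0.10)
})

test_that("an ideal gas under dilation follows -N kB T / V", {
  ig <- make_fixture("harmonic_solid", nx = 4, a = 0.4, k = 0)
  ig$topology <- topology()
  ig$sites$molecule_id <- seq_len(nrow(ig$sites))
  cv <- tensile_test(ig, eps_max = 0.2, duration_ns = 0.02, T = 300,
                     n_chunks = 20, thermostat = "langevin", seed = 4)
  V0 <- 1.6^3
  n <- nrow(ig$sites)
  expected <- -n * sorpflex_constants()$kB * 300 / (V0 * (1 + cv$eps_V)) *
    sorpflex_constants()$Pa_per_internal / 1e9
  # each chunk average within a few s.e. of the closed form; test the mean ratio
  expect_equal(mean(cv$sigma / expected), 1, tolerance = 0.1)
})
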