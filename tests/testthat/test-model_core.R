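test_that("minimum image wraps displacements into the primary cell", {
  b <- simulation_box(c(1, 1, 1))
  expect_equal(minimum_image(c(0, 0, 0), c(0.9, 0, 0), b), c(-0.1, 0, 0))
  expect_equal(minimum_image(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5), b), c(0, 0, 0))
  # tie at exactly L/2 resolves toward +L/2
  expect_equal(minimum_image(c(0, 0, 0), c(0.5, 0, 0), b), c(0.5, 0, 0))
  # non-periodic axes untouched
  bnp <- simulation_box(c(1, 1, 1), periodic = c(FALSE, TRUE, TRUE))
  expect_equal(minimum_image(c(0, 0, 0), c(0.9, 0.9, 0), bnp)[1], 0.9)
  expect_error(minimum_image(c(NA, 0, 0), c(0, 0, 0), b), "finite")
})

test_that("pair energy reproduces the LJ minimum, Coulomb reference and cutoff", {
  b <- simulation_box(rep(10, 3), periodic = rep(FALSE, 3))
  lj1 <- list(x = 0, y = 0, z = 0, charge = 0, sigma = 0.3, epsilon = 0.5)
  lj2 <- list(x = 2^(1/6) * 0.3, y = 0, z = 0, charge = 0, sigma = 0.3, epsilon = 0.5)
  expect_equal(pair_energy(lj1, lj2, b, cutoff = 2), -0.5, tolerance = 1e-12)
  # +e/-e at 1 nm, bare Coulomb: the Coulomb constant in kJ/mol nm e^-2
  qp <- list(x = 0, y = 0, z = 0, charge = 1, sigma = 0, epsilon = 0)
  qm <- list(x = 1, y = 0, z = 0, charge = -1, sigma = 0, epsilon = 0)
  expect_equal(pair_energy(qp, qm, b, cutoff = 5, coulomb = "bare"),
               -138.935458, tolerance = 1e-6)
  # beyond cutoff: exactly zero
  far <- list(x = 3, y = 0, z = 0, charge = -1, sigma = 0.3, epsilon = 0.5)
  expect_identical(pair_energy(lj1, far, b, cutoff = 1), 0)
  # overlapping interacting sites are an error
  expect_error(pair_energy(lj1, modifyList(lj2, list(x = 1e-9)), b), "overlap")
})

test_that("total energy satisfies its contract on simple systems", {
  empty <- system_state(simulation_box(rep(3, 3)))
  e0 <- total_energy(empty)
  expect_identical(unlist(e0[c("lj", "coulomb", "bonded", "total")]),
                   c(lj = 0, coulomb = 0, bonded = 0, total = 0))

  # two neutral LJ sites at the minimum
  s <- data.frame(x = c(1, 1 + 2^(1/6) * 0.3), y = 1, z = 1, label = "X",
                  charge = 0, sigma = 0.3, epsilon = 0.5, mass = 10,
                  molecule_id = 1:2, role = "host", hb_role = "",
                  stringsAsFactors = FALSE)
  st <- system_state(simulation_box(rep(5, 3)), s)
  expect_equal(total_energy(st, cutoff = 2)$total, -0.5, tolerance = 1e-12)

  # one harmonic bond stretched by delta: E = k delta^2 (and excluded nonbonded)
  delta <- 0.07
  s2 <- s
  s2$molecule_id <- c(1L, 1L)
  s2$x[2] <- s2$x[1] + 0.4 + delta
  topo <- topology(bonds = data.frame(i = 1L, j = 2L, k = 250, r0 = 0.4))
  st2 <- system_state(simulation_box(rep(5, 3)), s2, topo)
  e2 <- total_energy(st2, cutoff = 2)
  expect_equal(e2$bonded, 250 * delta^2, tolerance = 1e-12)
  expect_equal(e2$lj, 0)
  # breakdown invariant
  expect_equal(e2$total, e2$lj + e2$coulomb + e2$bonded, tolerance = 1e-9)
})

test_that("energy is invariant under translation and site permutation", {
  st <- random_site_system(50, seed = 3)
  e0 <- total_energy(st)$total
  st_t <- st
  st_t$sites[, c("x", "y", "z")] <- st_t$sites[, c("x", "y", "z")] +
    matrix(c(0.71, -1.3, 2.2), nrow(st$sites), 3, byrow = TRUE)
  expect_equal(total_energy(st_t)$total, e0, tolerance = 1e-9)
  perm <- with_seed(4, sample(nrow(st$sites)))
  st_p <- st
  st_p$sites <- st$sites[perm, ]
  st_p$sites$molecule_id <- st$sites$molecule_id[perm]
  expect_equal(total_energy(st_p)$total, e0, tolerance = 1e-9)
})

test_that("nonbonded energy matches a brute-force double-loop oracle", {
  for (seed in 1:3) {
    st <- random_site_system(60, seed = seed)
    expect_equal(total_energy(st)$total, oracle_nonbonded(st), tolerance = 1e-9)
  }
  # and with topology exclusions in play (bonded chain + rigid triplet)
  st <- random_site_system(30, seed = 9)
  st$sites$molecule_id <- rep(1:10, each = 3)
  topo <- topology(bonds = data.frame(i = seq(1, 28, 3), j = seq(2, 29, 3),
                                      k = 0, r0 = 0.3),
                   rigid_groups = list(4:6))
  st$topology <- topo
  e <- sorpflex:::cpp_total_energy(sorpflex:::pack_system(st, 0.9, 2.0))
  expect_equal(e$lj + e$coulomb, oracle_nonbonded(st), tolerance = 1e-9)
})

test_that("forces are the negative energy gradient and obey Newton's third law", {
  st <- random_site_system(20, seed = 5)
  f <- compute_forces(st)
  expect_lt(max(abs(colSums(f$forces))), 1e-8)   # action = reaction
  h <- 1e-6
  with_seed(11, {
    for (trial in 1:6) {
      i <- sample(nrow(st$sites), 1)
      ax <- sample(3, 1)
      stp <- st; stm <- st
      col <- c("x", "y", "z")[ax]
      stp$sites[i, col] <- stp$sites[i, col] + h
      stm$sites[i, col] <- stm$sites[i, col] - h
      fd <- -(total_energy(stp)$total - total_energy(stm)$total) / (2 * h)
      expect_equal(f$forces[i, ax], fd, tolerance = 1e-4)
    }
  })
})

test_that("make_water builds the published rigid geometry from the parameter file", {
  ff <- read_forcefield(sorpflex_file("spce.ff"))
  w <- make_water(c(0, 0, 0), c(1, 0, 0, 0), ff)
  expect_equal(as.numeric(w$sites[1, c("x", "y", "z")]), c(0, 0, 0))
  d1 <- sqrt(sum((w$sites[2, c("x","y","z")] - w$sites[1, c("x","y","z")])^2))
  d2 <- sqrt(sum((w$sites[3, c("x","y","z")] - w$sites[1, c("x","y","z")])^2))
  expect_equal(d1, ff$extra$r_OH, tolerance = 1e-12)
  expect_equal(abs(d1 - d2), 0, tolerance = 1e-12)
  v1 <- as.numeric(w$sites[2, c("x","y","z")]); v2 <- as.numeric(w$sites[3, c("x","y","z")])
  ang <- acos(sum(v1 * v2) / (d1 * d2)) * 180 / pi
  expect_equal(ang, ff$extra$angle_HOH, tolerance = 1e-9)
  expect_equal(sum(w$sites$charge), 0)

  # dipole rotates exactly with the quaternion
  th <- 0.7
  q <- c(cos(th / 2), sin(th / 2) * c(1, 0, 0))
  w2 <- make_water(c(0, 0, 0), q, ff)
  dip <- function(ws) {
    p <- as.matrix(ws$sites[, c("x", "y", "z")])
    colSums(p * ws$sites$charge)
  }
  R <- sorpflex:::quat_to_matrix(q)
  expect_equal(unname(dip(w2)), as.numeric(R %*% dip(w)), tolerance = 1e-12)
})

test_that("system invariants are enforced", {
  expect_error(simulation_box(c(1, -1, 1)))
  expect_error(topology(bonds = data.frame(i = 1L, j = 1L, k = 1, r0 = 0.1)),
               "identical")
  expect_error(topology(rigid_groups = list(1:3, 3:5)), "disjoint")
  st <- make_fixture("bulk_water", n = 8, seed = 1)
  expect_equal(dry_mass(st), 0)
  expect_equal(n_water(st), 8)
})
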