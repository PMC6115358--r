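test_that("recipes are validated and the box matches the target density", {
  expect_error(build_recipe(0, 10))
  expect_error(build_recipe(2, 1))
  expect_error(build_recipe(2, 5, target_density = -1))
  rec <- build_recipe(2, 4, target_density = 1.2, seed = 3)
  st <- grow_chains(rec)
  total_mass <- sum(st$sites$mass)
  expect_equal(box_volume(st$box), total_mass / (602.21408 * 1.2),
               tolerance = 1e-6)
  expect_equal(mass_density(st), 1.2, tolerance = 1e-6)
})

test_that("the smallest chain is a single connected bonded molecule", {
  st <- grow_chains(build_recipe(1, 2, target_density = 0.8, seed = 1))
  expect_equal(length(unique(st$sites$molecule_id)), 1)
  expect_equal(nrow(st$sites), 6)      # 2 units x 3 beads
  # bonded graph spans both units (single component)
  b <- st$topology$bonds
  adj <- lapply(seq_len(nrow(st$sites)), function(i)
    c(b$j[b$i == i], b$i[b$j == i]))
  seen <- 1L; frontier <- 1L
  while (length(frontier)) {
    nxt <- setdiff(unlist(adj[frontier]), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_setequal(seen, seq_len(nrow(st$sites)))
  # no hard-core overlaps
  pos <- as.matrix(st$sites[, c("x", "y", "z")])
  L <- st$box$lengths
  dmin <- Inf
  for (i in 1:(nrow(pos) - 1)) {
    d <- sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ])
    for (a in 1:3) d[, a] <- d[, a] - L[a] * round(d[, a] / L[a])
    dmin <- min(dmin, sqrt(min(rowSums(d^2))))
  }
  expect_gte(dmin, 0.08)
})

test_that("chain growth is deterministic and respects the hard core over seeds", {
  rec <- build_recipe(2, 5, seed = 7)
  expect_identical(grow_chains(rec)$sites, grow_chains(rec)$sites)
  for (seed in 1:12) {
    st <- grow_chains(build_recipe(2, 4, seed = seed))
    pos <- as.matrix(st$sites[, c("x", "y", "z")])
    L <- st$box$lengths
    # exclude directly bonded pairs from the check
    b <- st$topology$bonds
    bonded <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    for (i in 1:(nrow(pos) - 1)) {
      d <- sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ])
      for (a in 1:3) d[, a] <- d[, a] - L[a] * round(d[, a] / L[a])
      dd <- sqrt(rowSums(d^2))
      js <- (i + 1):nrow(pos)
      keep <- !(paste(i, js) %in% bonded)
      if (any(keep)) expect_gte(min(dd[keep]), 0.08)
    }
  }
})

test_that("host relaxation finds the bonded minimum for a cold dimer", {
  s <- data.frame(x = c(1, 1.52), y = 1, z = 1, label = "X", charge = 0,
                  sigma = 0, epsilon = 0, mass = 30, molecule_id = c(1L, 1L),
                  role = "host", hb_role = "", stringsAsFactors = FALSE)
  topo <- topology(bonds = data.frame(i = 1L, j = 2L, k = 2000, r0 = 0.4))
  st <- system_state(simulation_box(rep(4, 3)), s, topo)
  out <- relax_host(st, duration = 6, T = 0.01, dt = 0.0005, seed = 2)
  r <- sqrt(sum((out$sites[2, c("x","y","z")] - out$sites[1, c("x","y","z")])^2))
  expect_lt(abs(r - 0.4), 1e-3)
})

test_that("relaxation reproducibility: two seeds give comparable densities", {
  st <- grow_chains(build_recipe(2, 5, seed = 2))
  d <- vapply(c(11, 12), function(sd) {
    attr(relax_host(st, duration = 25, T = 300, seed = sd), "density")
  }, numeric(1))
  expect_lt(abs(d[1] - d[2]) / mean(d), 0.10)
})

test_that("fixtures meet their geometric contracts", {
  bw <- make_fixture("bulk_water", n = 125, seed = 1)
  expect_equal(nrow(bw$sites), 375)
  expect_equal(sum(bw$sites$charge), 0, tolerance = 1e-12)
  expect_equal(mass_density(bw), 0.997, tolerance = 1e-9)

  sp <- make_fixture("slit_pore", gap = 1.2)
  z <- sp$sites$z
  expect_equal(min(abs(outer(z[z == min(z)], z[z == max(z)], "-"))), 1.2,
               tolerance = 1e-9)

  hs <- make_fixture("harmonic_solid", nx = 3, a = 0.4, k = 900)
  expect_equal(total_energy(hs)$bonded, 0, tolerance = 1e-9)

  expect_error(make_fixture("noble_gas"))
})
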