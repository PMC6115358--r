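# a minimal system with one host hydroxyl donor and one water acceptor at
# controllable geometry
hb_pair_system <- function(acceptor_pos, box_L = 5) {
  sites <- data.frame(
    x = c(0, 0.10), y = c(0, 0), z = c(0, 0),
    label = c("OH", "HO"),
    charge = c(-0.85, 0.5), sigma = c(0.312, 0.08),
    epsilon = c(0.71, 0.19), mass = c(16, 1),
    molecule_id = c(1L, 1L), role = "host",
    hb_role = c("donor_O,acceptor", "donor_H"),
    stringsAsFactors = FALSE)
  topo <- topology(bonds = data.frame(i = 1L, j = 2L, k = 40000, r0 = 0.0945))
  st <- system_state(simulation_box(rep(box_L, 3), periodic = rep(FALSE, 3)),
                     sites, topo)
  # acceptor: a full rigid water, dipole pointing away along +x, acting as
  # acceptor only (donor roles stripped so the probe geometry is unambiguous)
  st <- add_waters(st, matrix(acceptor_pos, 1, 3),
                   matrix(c(cos(pi / 4), 0, sin(pi / 4), 0), 1, 4))
  st$sites$hb_role[st$sites$label == "HW"] <- ""
  st$sites$hb_role[st$sites$label == "OW"] <- "acceptor"
  st
}

test_that("geometric detection applies the distance and angular cuts", {
  crit_oh <- hb_criterion(distance_convention = "O_to_H", angle_at = "H")
  # collinear O-H...acceptor at O...H = 0.18 nm: one bond
  st <- hb_pair_system(c(0.28, 0, 0))
  rec <- detect_hbonds(st, crit_oh)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$hb_class, "CW")
  # distance cut: acceptor at 0.5 nm
  expect_equal(nrow(detect_hbonds(hb_pair_system(c(0.5, 0, 0)), crit_oh)), 0)
  # angle cut: donor angle 45 degrees at compliant distance
  th <- 45 * pi / 180
  st3 <- hb_pair_system(c(0.10 + 0.2 * cos(th), 0.2 * sin(th), 0))
  expect_equal(nrow(detect_hbonds(st3, crit_oh)), 0)
  # default O-O convention finds the collinear pair as well
  expect_equal(nrow(detect_hbonds(st, hb_criterion())), 1)
})

test_that("detection agrees exactly with the all-pairs oracle, both conventions", {
  run <- mini_water_run()
  st <- run$state
  for (conv in c("O_to_O", "O_to_H")) for (at in c("donor_O", "H")) {
    crit <- hb_criterion(distance_convention = conv, angle_at = at)
    rec <- detect_hbonds(st, crit)
    got <- as.matrix(rec[order(rec$donor_H, rec$acceptor), 1:3])
    dimnames(got) <- NULL
    want <- oracle_hbonds(st, distance_convention = conv, angle_at = at)
    dimnames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("summaries follow the per-water / per-unit normalizations", {
  # two isolated waters forming one mutual bond
  st <- make_fixture("two_molecule", r_oo = 0.28)
  rec <- detect_hbonds(st, hb_criterion())
  expect_equal(nrow(rec), 1)
  sm <- summarize_hbonds(rec, st)
  expect_equal(sm$hb_ww_per_water, 0.5)
  expect_equal(sm$n_ww_raw, 1)
  expect_equal(sm$hb_total_per_water, sm$hb_ww_per_water + sm$hb_cw_per_water,
               tolerance = 1e-9)

  # one water bonded only to a host hydroxyl
  st2 <- hb_pair_system(c(0.29, 0, 0))
  rec2 <- detect_hbonds(st2, hb_criterion())
  expect_gte(nrow(rec2), 1)
  sm2 <- summarize_hbonds(rec2, st2, n_repeat_units = 1)
  expect_equal(sm2$fraction_water_bound_to_host, 1.0)
  expect_equal(sm2$hb_ww_per_water, 0)

  # dry frame: per-water fields undefined, host-host still reported
  dry <- st2
  dry$topology$rigid_groups <- list()
  dry$sites <- dry$sites[dry$sites$role == "host", ]
  dry$velocities <- dry$velocities[1:2, ]
  rec3 <- detect_hbonds(dry, hb_criterion())
  sm3 <- summarize_hbonds(rec3, dry, n_repeat_units = 1)
  expect_true(is.nan(sm3$hb_ww_per_water))
  expect_false(is.nan(sm3$hb_cc_per_unit))
})

test_that("pair-isolation energies behave physically", {
  # effectively infinite separation: zero
  far <- make_fixture("two_molecule", r_oo = 4.5)
  rec <- data.frame(donor_O = 1L, donor_H = 2L, acceptor = 4L, hb_class = "WW")
  expect_lt(abs(hb_energy(far, rec)), 0.05)

  # optimal water dimer: an independent grid search over the O-O distance of
  # the aligned dimer gives the binding magnitude band of the rigid 3-site
  # model
  grid <- seq(0.25, 0.34, by = 0.002)
  e <- vapply(grid, function(r) {
    st <- make_fixture("two_molecule", r_oo = r)
    hb_energy(st, rec)
  }, numeric(1))
  best <- max(e)
  expect_gt(best, 5.8)   # kcal/mol; aligned-geometry optimum of SPC/E-type models
  expect_lt(best, 7.2)

  # record referencing a single molecule errors
  st <- make_fixture("two_molecule")
  bad <- data.frame(donor_O = 1L, donor_H = 2L, acceptor = 3L, hb_class = "WW")
  expect_error(hb_energy(st, bad), "single molecule")
})

test_that("density maps are normalized per frame and localize single bonds", {
  st <- make_fixture("two_molecule", r_oo = 0.28)
  st$box <- simulation_box(rep(5, 3))    # periodic for wrapping
  mp <- hb_density_map(list(st, st), hb_class = "WW", plane = "xy", grid_n = 10)
  expect_equal(sum(mp$density > 0), 1)
  expect_equal(mp$total_mass, 1)     # one bond per frame
  expect_error(hb_density_map(list()), "empty")
})

test_that("RDF is flat for an ideal gas and shows the HB peak in water", {
  # ideal gas of O sites
  with_seed(3, {
    n <- 400
    sites <- data.frame(x = runif(n, 0, 4), y = runif(n, 0, 4), z = runif(n, 0, 4),
                        label = "OW", charge = 0, sigma = 0, epsilon = 0, mass = 16,
                        molecule_id = seq_len(n), role = "water", hb_role = "",
                        stringsAsFactors = FALSE)
    st <- system_state(simulation_box(rep(4, 3)), sites)
    rdf <- compute_rdf(list(st), st, c("OW", "OW"), rmax = 1.5, nbins = 30)
    sel <- rdf$r > 0.3
    expect_lt(max(abs(rdf$g[sel] - 1)), 0.35)  # ~3 s.e. at these counts
    expect_error(compute_rdf(list(st), st, c("OW", "OW"), rmax = 1, nbins = 0))
  })

  run <- mini_water_run()
  rdf <- compute_rdf(run$frames, run$state, c("OW", "HW"), rmax = 0.6, nbins = 120)
  first_peak <- rdf$r[which.max(rdf$g * (rdf$r < 0.25))]
  expect_gte(first_peak, 0.17)
  expect_lte(first_peak, 0.21)

  # coordination integral over the first O-H peak tracks the geometric bond
  # count: H neighbours of an oxygen inside the first shell are the bonds
  # that molecule accepts, i.e. the per-water bond count n_ww / N_w (half
  # the per-molecule participation count)
  sel <- rdf$r > 0.2 & rdf$r < 0.32
  valley <- rdf$r[sel][which.min(rdf$g[sel])]
  coord <- coordination_number(rdf, 0.12, valley)
  bonds_per_water <- bulk_hb_count(run)$hb_per_molecule / 2
  expect_lt(abs(coord - bonds_per_water) / bonds_per_water, 0.20)
})

test_that("water-water bond count scaling is recovered from synthetic data", {
  m <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  fit2 <- nww_scaling(list(m = m, n_ww = 7 * m^2))
  expect_equal(fit2$exponent, 2, tolerance = 1e-9)
  fit1 <- nww_scaling(list(m = m, n_ww = 3 * m))
  expect_equal(fit1$exponent, 1, tolerance = 1e-9)
  expect_error(nww_scaling(list(m = m[1:3], n_ww = m[1:3])), "at least 4")
})

test_that("capillary shift follows 4 lambda Tc / D", {
  expect_equal(capillary_shift(4 * 0.28, 0.28, 647), 647)
  expect_equal(capillary_shift(2, 0.28, 647), 2 * capillary_shift(4, 0.28, 647))
  expect_equal(capillary_shift(0.28, 0.28, 600), 4 * 600)
  expect_error(capillary_shift(-1))
  # sub-nm pores at room temperature fill reversibly
  expect_true(all(reversible_filling(c(0.2, 0.3, 0.4), T_op = 300)))
})
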