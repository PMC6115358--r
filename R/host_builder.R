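#' Recipe for growing an amorphous polymer host
#'
#' @param n_chains Number of chains (>= 1).
#' @param units_per_chain Repeat units per chain (>= 2). Each unit carries a
#'   backbone bead, a hydroxyl oxygen (donor/acceptor) and a hydroxyl
#'   hydrogen, standing in for a glucopyranose ring.
#' @param target_density Packing density, g/cm^3 (default 1.2).
#' @param seed Integer seed; same seed gives bit-identical coordinates.
#' @param box_shape `"cubic"` or `"orthorhombic"` (2:1:1).
#' @return Object of class `BuildRecipe`.
#' @export
build_recipe <- function(n_chains = 3, units_per_chain = 10,
                         target_density = 1.2, seed = 1,
                         box_shape = c("cubic", "orthorhombic")) {
  box_shape <- match.arg(box_shape)
  stopifnot(n_chains >= 1, units_per_chain >= 2, target_density > 0)
  structure(list(n_chains = as.integer(n_chains),
                 units_per_chain = as.integer(units_per_chain),
                 target_density = target_density, seed = as.integer(seed),
                 box_shape = box_shape), class = "BuildRecipe")
}


.rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Grow self-avoiding bead-spring chains into a periodic box
#'
#' Chains are grown unit by unit as self-avoiding random walks at the recipe's
#' target density; each repeat unit carries one hydroxyl donor pair (O-H) and
#' one acceptor site. The box volume satisfies
#' `V = total mass / target_density` exactly.
#'
#' @param recipe A [build_recipe()].
#' @param ff Parsed host forcefield (default the shipped
#'   `surrogate_host.ff`).
#' @param max_restarts Chain-level restart budget before a packing error.
#' @return An unrelaxed `SystemState` (one molecule per chain).
#' @export
grow_chains <- function(recipe, ff = read_forcefield(sorpflex_file("surrogate_host.ff")),
                        max_restarts = 200) {
  at <- ff$atoms
  prm <- function(lbl) at[at$label == lbl, ]
  cb <- prm("CB"); oh <- prm("OH"); ho <- prm("HO")
  unit_mass <- cb$mass + oh$mass + ho$mass
  total_mass <- recipe$n_chains * recipe$units_per_chain * unit_mass
  V <- total_mass / (602.21408 * recipe$target_density)
  L <- if (recipe$box_shape == "cubic") rep(V^(1/3), 3)
       else V^(1/3) * c(2, 1, 1) / prod(c(2, 1, 1))^(1/3)
  box <- simulation_box(L)

  bnd <- function(li, lj) {
    b <- ff$bonds
    r <- b[(b$label_i == li & b$label_j == lj) | (b$label_i == lj & b$label_j == li), ]
    r[1, ]
  }
  r_cc <- bnd("CB", "CB")$r0; r_co <- bnd("CB", "OH")$r0; r_oh <- bnd("OH", "HO")$r0
  hard <- function(l1, l2) {
    if (l1 == "CB" && l2 == "CB") 0.30
    else if (l1 == "HO" || l2 == "HO") 0.10
    else 0.18
  }

  with_seed(recipe$seed, {
    coords <- matrix(numeric(0), 0, 3)
    labels <- character(0); molids <- integer(0)
    restarts <- 0
    for (ch in seq_len(recipe$n_chains)) {
      repeat {
        ch_coords <- matrix(numeric(0), 0, 3); ch_labels <- character(0)
        pos <- runif(3) * box$lengths
        dir <- .rand_unit()
        ok_chain <- TRUE
        for (u in seq_len(recipe$units_per_chain)) {
          placed <- FALSE
          for (try in 1:40) {
            cand <- if (u == 1) pos else ch_coords[nrow(ch_coords) - 2, ] + dir * r_cc
            if (u > 1 && try > 1) {
              dir <- .norm3(dir + 0.8 * .rand_unit())
              cand <- ch_coords[nrow(ch_coords) - 2, ] + dir * r_cc
            }
            allc <- rbind(coords, ch_coords)
            alll <- c(labels, ch_labels)
            if (!.site_fits(cand, "CB", allc, alll, box, hard)) next
            # hydroxyl decoration
            u_perp <- .norm3(pracma_cross(dir, .rand_unit()))
            o_ok <- FALSE
            for (t2 in 1:20) {
              o_pos <- cand + u_perp * r_co
              h_pos <- o_pos + .norm3(u_perp + 0.5 * .rand_unit()) * r_oh
              if (.site_fits(o_pos, "OH", allc, alll, box, hard) &&
                  .site_fits(h_pos, "HO", allc, alll, box, hard)) { o_ok <- TRUE; break }
              u_perp <- .norm3(pracma_cross(dir, .rand_unit()))
            }
            if (!o_ok) next
            ch_coords <- rbind(ch_coords, cand, o_pos, h_pos)
            ch_labels <- c(ch_labels, "CB", "OH", "HO")
            if (u > 1) dir <- .norm3(dir + 0.35 * .rand_unit())
            placed <- TRUE
            break
          }
          if (!placed) { ok_chain <- FALSE; break }
        }
        if (ok_chain) {
          coords <- rbind(coords, ch_coords)
          labels <- c(labels, ch_labels)
          molids <- c(molids, rep(ch, length(ch_labels)))
          break
        }
        restarts <- restarts + 1
        if (restarts > max_restarts) {
          achieved <- sum(at$mass[match(labels, at$label)]) / (602.21408 * box_volume(box))
          stop(sprintf("grow_chains: packing failed after %d restarts (achieved density %.3f g/cm^3 of target %.3f)",
                       restarts, achieved, recipe$target_density))
        }
      }
    }
    prm_of <- at[match(labels, at$label), ]
    sites <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        label = labels, charge = prm_of$charge, sigma = prm_of$sigma,
                        epsilon = prm_of$epsilon, mass = prm_of$mass,
                        molecule_id = molids, role = "host",
                        hb_role = ifelse(prm_of$hb_role == "none", "", prm_of$hb_role),
                        stringsAsFactors = FALSE)
    n_units <- recipe$units_per_chain
    bonds <- list(); angles <- list()
    for (ch in seq_len(recipe$n_chains)) {
      base <- (ch - 1) * 3 * n_units
      for (u in seq_len(n_units)) {
        i_cb <- base + (u - 1) * 3 + 1
        bonds[[length(bonds) + 1]] <- c(i_cb, i_cb + 1, bnd("CB", "OH")$k, r_co)
        bonds[[length(bonds) + 1]] <- c(i_cb + 1, i_cb + 2, bnd("OH", "HO")$k, r_oh)
        angles[[length(angles) + 1]] <- c(i_cb, i_cb + 1, i_cb + 2,
                                          .angle_par(ff, "CB", "OH", "HO"))
        if (u < n_units) {
          bonds[[length(bonds) + 1]] <- c(i_cb, i_cb + 3, bnd("CB", "CB")$k, r_cc)
          angles[[length(angles) + 1]] <- c(i_cb + 3, i_cb, i_cb + 1,
                                            .angle_par(ff, "CB", "CB", "OH"))
        }
        if (u < n_units - 1) {
          angles[[length(angles) + 1]] <- c(i_cb, i_cb + 3, i_cb + 6,
                                            .angle_par(ff, "CB", "CB", "CB"))
        }
      }
    }
    bm <- do.call(rbind, bonds); am <- do.call(rbind, angles)
    topo <- topology(
      bonds = data.frame(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
                         k = bm[, 3], r0 = bm[, 4]),
      angles = data.frame(i = as.integer(am[, 1]), j = as.integer(am[, 2]),
                          k = as.integer(am[, 3]), ktheta = am[, 4], theta0 = am[, 5]))
    system_state(box, sites, topo)
  })
}

.norm3 <- function(v) v / sqrt(sum(v^2))
pracma_cross <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3],
                                 a[1]*b[2] - a[2]*b[1])
.site_fits <- function(p, lbl, coords, labels, box, hard) {
  if (nrow(coords) == 0) return(TRUE)
  d <- sweep(coords, 2, p)
  L <- box$lengths
  for (a in 1:3) d[, a] <- d[, a] - L[a] * round(d[, a] / L[a])
  dd <- sqrt(rowSums(d^2))
  lim <- vapply(labels, function(l2) hard(lbl, l2), numeric(1))
  all(dd >= lim)
}
.angle_par <- function(ff, l1, l2, l3) {
  a <- ff$angles
  r <- a[(a$label_i == l1 & a$label_j == l2 & a$label_k == l3) |
         (a$label_i == l3 & a$label_j == l2 & a$label_k == l1), ]
  c(r$ktheta[1], r$theta0[1])
}

#' Relax a host with constant-temperature, constant-stress dynamics
#'
#' A short Langevin startup (stiff-contact safe) followed by Nose-Hoover
#' NsigmaT dynamics at the requested stress; returns the relaxed state with
#' density and energy traces attached.
#'
#' @param state A `SystemState` (e.g. from [grow_chains()]).
#' @param duration Total duration, ps.
#' @param T Temperature, K.
#' @param sigma_ext External stress, Pa (tension positive; scalar or 3-vector).
#' @param dt Time step, ps.
#' @param seed Optional seed.
#' @param cutoff,alpha Nonbonded model parameters.
#' @return Relaxed `SystemState`; `attr(, "traces")` holds the NsigmaT trace
#'   and `attr(, "density")` the final density in g/cm^3.
#' @export
relax_host <- function(state, duration = 100, T = 300, sigma_ext = 0,
                       dt = 0.001, seed = NULL, cutoff = 0.9, alpha = 2.0) {
  n_start <- max(50L, as.integer(0.1 * duration / dt))
  n_main <- max(0L, as.integer(duration / dt) - n_start)
  state <- maxwell_velocities(state, T, seed)
  sp_start <- integrator_spec(dt = dt / 2, T_target = T, ensemble = "NVT",
                              thermostat = "langevin", langevin_gamma = 20)
  state <- step_md(state, sp_start, n_start, cutoff, alpha, seed = seed)
  sp <- integrator_spec(dt = dt, T_target = T, sigma_ext = sigma_ext,
                        ensemble = "NsigmaT")
  state <- step_md(state, sp, n_main, cutoff, alpha, thermo_stride = 50)
  attr(state, "density") <- mass_density(state)
  # time-averaged equilibrium volume over the last third of the NsigmaT run:
  # the proper dry reference for volume strains (an instantaneous final V
  # carries the full barostat fluctuation)
  tr <- attr(state, "traces")
  attr(state, "V0") <- mean(tail(tr$V, max(1, nrow(tr) %/% 3)))
  state
}

#' Construct validation fixtures
#'
#' * `bulk_water`: `n` rigid SPC/E waters on a perturbed lattice at the given
#'    density (default 0.997 g/cm^3).
#' * `slit_pore`: two square-lattice LJ walls normal to z with the given
#'    center-to-center gap (walls frozen by default).
#' * `harmonic_solid`: `nx^3` simple-cubic lattice with nearest-neighbour
#'    springs (`E = k (r-a)^2`, equilibrium at the lattice geometry).
#' * `two_molecule`: a water dimer with the donor O-H bond pointing at the
#'    acceptor oxygen at distance `r_oo` (non-periodic).
#'
#' @param kind Fixture name.
#' @param n Number of water molecules (`bulk_water`).
#' @param density Water density, g/cm^3 (`bulk_water`).
#' @param gap Wall gap, nm (`slit_pore`).
#' @param lateral Lateral wall extent, nm (`slit_pore`).
#' @param wall_spacing Wall lattice spacing, nm (`slit_pore`).
#' @param nx Lattice cells per edge (`harmonic_solid`).
#' @param a Lattice constant, nm (`harmonic_solid`).
#' @param k Spring constant, kJ/mol/nm^2 (`harmonic_solid`).
#' @param r_oo O-O separation, nm (`two_molecule`).
#' @param seed Optional seed (water orientations).
#' @return A `SystemState`.
#' @export
make_fixture <- function(kind = c("bulk_water", "slit_pore", "harmonic_solid",
                                  "two_molecule"),
                         n = 125, density = 0.997, gap = 1.2, lateral = 2.0,
                         wall_spacing = 0.15, nx = 4, a = 0.4, k = 1000,
                         r_oo = 0.28, seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    bulk_water = with_seed(seed, {
      m_w <- 18.0154
      V <- n * m_w / (602.21408 * density)
      L <- V^(1/3)
      box <- simulation_box(rep(L, 3))
      ncell <- ceiling(n^(1/3))
      sp <- L / ncell
      pts <- expand.grid(x = 0:(ncell-1), y = 0:(ncell-1), z = 0:(ncell-1))
      pts <- as.matrix(pts)[seq_len(n), , drop = FALSE] * sp + sp / 2
      st <- system_state(box)
      add_waters(st, pts, orientations = matrix(rnorm(4 * n), n, 4))
    }),
    slit_pore = {
      nxy <- max(2L, round(lateral / wall_spacing))
      lat <- nxy * wall_spacing
      g <- expand.grid(x = (0:(nxy-1)) * wall_spacing, y = (0:(nxy-1)) * wall_spacing)
      wall1 <- cbind(g$x, g$y, 0.15)
      wall2 <- cbind(g$x, g$y, 0.15 + gap)
      pos <- rbind(wall1, wall2)
      box <- simulation_box(c(lat, lat, gap + 0.3))
      sites <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          label = "WL", charge = 0, sigma = 0.3, epsilon = 0.5,
                          mass = 100, molecule_id = 1L, role = "host",
                          hb_role = "", stringsAsFactors = FALSE)
      system_state(box, sites, frozen_host = TRUE)
    },
    harmonic_solid = {
      L <- nx * a
      g <- expand.grid(x = 0:(nx-1), y = 0:(nx-1), z = 0:(nx-1))
      pos <- as.matrix(g) * a
      nsite <- nrow(pos)
      idx <- function(i, j, l) ((i %% nx) * nx + (j %% nx)) * nx + (l %% nx) + 1
      bonds <- list()
      for (i in 0:(nx-1)) for (j in 0:(nx-1)) for (l in 0:(nx-1)) {
        s <- idx(i, j, l)
        bonds[[length(bonds) + 1]] <- c(s, idx(i + 1, j, l), k, a)
        bonds[[length(bonds) + 1]] <- c(s, idx(i, j + 1, l), k, a)
        bonds[[length(bonds) + 1]] <- c(s, idx(i, j, l + 1), k, a)
      }
      bm <- do.call(rbind, bonds)
      bm <- bm[bm[, 1] != bm[, 2], , drop = FALSE]
      sites <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          label = "HS", charge = 0, sigma = 0, epsilon = 0,
                          mass = 50, molecule_id = seq_len(nsite), role = "host",
                          hb_role = "", stringsAsFactors = FALSE)
      topo <- topology(bonds = data.frame(i = as.integer(bm[, 1]),
                                          j = as.integer(bm[, 2]),
                                          k = bm[, 3], r0 = bm[, 4]))
      system_state(simulation_box(rep(L, 3)), sites, topo)
    },
    two_molecule = {
      box <- simulation_box(rep(5, 3), periodic = c(FALSE, FALSE, FALSE))
      ff <- read_forcefield(sorpflex_file("spce.ff"))
      half <- ff$extra$angle_HOH * pi / 180 / 2
      phi <- pi / 2 - half       # rotate dipole so one O-H bond points along +x
      st <- system_state(box)
      st <- add_waters(st, matrix(c(0, 0, 0), 1, 3),
                       matrix(c(cos(phi / 2), 0, sin(phi / 2), 0), 1, 4), ff)
      # acceptor dipole along +x (hydrogens pointing away from the donor)
      st <- add_waters(st, matrix(c(r_oo, 0, 0), 1, 3),
                       matrix(c(cos(pi / 4), 0, sin(pi / 4), 0), 1, 4), ff)
      st
    })
}
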