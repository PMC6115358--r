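#' Geometric hydrogen-bond criterion
#'
#' A donor O-H and acceptor O form a hydrogen bond when a distance and an
#' angular cut are both met. The distance is measured H...acceptor
#' (`"O_to_H"`) or donor-O...acceptor (`"O_to_O"`); the angular cut bounds
#' the deviation from donor-H...acceptor linearity measured at the hydrogen
#' (`angle_at = "H"`), or the H-donorO-acceptor angle at the donor oxygen
#' (`angle_at = "donor_O"`). The default pairs the O...O distance convention
#' with the donor-oxygen angle, the combination standard in the liquid-water
#' literature; both conventions are first-class and recorded in outputs.
#'
#' @param d_max Distance cutoff, nm (default 0.35).
#' @param angle_max Angular cutoff, degrees (default 30, must be in (0, 90)).
#' @param distance_convention `"O_to_O"` or `"O_to_H"`.
#' @param angle_at `"donor_O"` or `"H"`.
#' @return Object of class `HBCriterion`.
#' @export
hb_criterion <- function(d_max = 0.35, angle_max = 30,
                         distance_convention = c("O_to_O", "O_to_H"),
                         angle_at = c("donor_O", "H")) {
  distance_convention <- match.arg(distance_convention)
  angle_at <- match.arg(angle_at)
  stopifnot(d_max > 0, angle_max > 0, angle_max < 90)
  structure(list(d_max = d_max, angle_max = angle_max,
                 distance_convention = distance_convention, angle_at = angle_at),
            class = "HBCriterion")
}

# donor/acceptor bookkeeping from site annotations
hb_sites <- function(state) {
  s <- state$sites
  donH <- which(grepl("donor_H", s$hb_role))
  acc <- which(grepl("acceptor", s$hb_role))
  donO_all <- which(grepl("donor_O", s$hb_role))
  # map each donor H to its oxygen: bonded partner if a bond exists, else the
  # nearest donor O in the same molecule (rigid waters have no bond rows)
  bond_o <- integer(0)
  b <- state$topology$bonds
  donO <- integer(length(donH))
  for (t in seq_along(donH)) {
    h <- donH[t]
    o <- integer(0)
    if (nrow(b)) {
      o <- c(b$j[b$i == h], b$i[b$j == h])
      o <- o[o %in% donO_all]
    }
    if (!length(o)) {
      cand <- donO_all[s$molecule_id[donO_all] == s$molecule_id[h]]
      if (!length(cand)) stop("donor H site ", h, " has no donor O")
      if (length(cand) > 1) {
        d2 <- (s$x[cand] - s$x[h])^2 + (s$y[cand] - s$y[h])^2 + (s$z[cand] - s$z[h])^2
        cand <- cand[which.min(d2)]
      }
      o <- cand
    }
    donO[t] <- o[1]
  }
  list(donor_H = donH, donor_O = donO, acceptors = acc)
}

#' Detect hydrogen bonds in a configuration
#'
#' One record per (donor H, acceptor) pair meeting the criterion, with the
#' bond classified by the roles of the two molecules: water-water (`WW`),
#' host-water in either direction (`CW`), host-host (`CC`). Intramolecular
#' pairs are never counted. A frame without donors yields zero records.
#'
#' @param frame A `SystemState`.
#' @param crit An [hb_criterion()].
#' @return Data frame (class `HBRecords`) with columns `donor_O`, `donor_H`,
#'   `acceptor`, `hb_class`.
#' @export
detect_hbonds <- function(frame, crit = hb_criterion()) {
  hs <- hb_sites(frame)
  empty <- data.frame(donor_O = integer(0), donor_H = integer(0),
                      acceptor = integer(0), hb_class = character(0),
                      stringsAsFactors = FALSE)
  if (!length(hs$donor_H) || !length(hs$acceptors))
    return(structure(empty, class = c("HBRecords", "data.frame"), criterion = crit))
  pos <- unname(as.matrix(frame$sites[, c("x", "y", "z")]))
  rec <- cpp_detect_hb(pos, frame$box$lengths, frame$box$periodic,
                       as.integer(hs$donor_H), as.integer(hs$donor_O),
                       as.integer(hs$acceptors),
                       as.integer(frame$sites$molecule_id),
                       crit$d_max, crit$angle_max,
                       ifelse(crit$distance_convention == "O_to_H", 0L, 1L),
                       ifelse(crit$angle_at == "H", 0L, 1L))
  if (!nrow(rec))
    return(structure(empty, class = c("HBRecords", "data.frame"), criterion = crit))
  role <- frame$sites$role
  cls <- ifelse(role[rec[, 1]] == "water" & role[rec[, 3]] == "water", "WW",
         ifelse(role[rec[, 1]] == "host" & role[rec[, 3]] == "host", "CC", "CW"))
  out <- data.frame(donor_O = rec[, 1], donor_H = rec[, 2], acceptor = rec[, 3],
                    hb_class = cls, stringsAsFactors = FALSE)
  structure(out, class = c("HBRecords", "data.frame"), criterion = crit)
}

#' Summarize hydrogen-bond records
#'
#' Water-water and host-water counts are normalized by the number of water
#' molecules, host-host counts by the number of host repeat units;
#' `n_ww_raw` is the unnormalized water-water bond count and
#' `fraction_water_bound_to_host` the fraction of waters with at least one
#' bond (donated or accepted) to the host. For a dry frame the per-water
#' fields are `NaN` (undefined) while the host-host count is still reported.
#'
#' @param records An `HBRecords` data frame from [detect_hbonds()].
#' @param frame The `SystemState` the records came from.
#' @param n_repeat_units Number of host repeat units; defaults to the number
#'   of host acceptor sites (one hydroxyl per repeat unit in the surrogate
#'   host).
#' @return Object of class `HBSummary`.
#' @export
summarize_hbonds <- function(records, frame, n_repeat_units = NULL) {
  nw <- n_water(frame)
  s <- frame$sites
  if (is.null(n_repeat_units))
    n_repeat_units <- sum(s$role == "host" & grepl("acceptor", s$hb_role))
  n_ww <- sum(records$hb_class == "WW")
  n_cw <- sum(records$hb_class == "CW")
  n_cc <- sum(records$hb_class == "CC")
  if (nw > 0) {
    ww <- n_ww / nw; cw <- n_cw / nw
    cw_waters <- unique(c(
      s$molecule_id[records$donor_O[records$hb_class == "CW"]],
      s$molecule_id[records$acceptor[records$hb_class == "CW"]]))
    cw_waters <- cw_waters[cw_waters %in% unique(s$molecule_id[s$role == "water"])]
    frac <- length(cw_waters) / nw
  } else {
    ww <- NaN; cw <- NaN; frac <- NaN
  }
  structure(list(hb_ww_per_water = ww, hb_cw_per_water = cw,
                 hb_cc_per_unit = if (n_repeat_units > 0) n_cc / n_repeat_units else NaN,
                 hb_total_per_water = ww + cw,
                 n_ww_raw = n_ww, n_cw_raw = n_cw, n_cc_raw = n_cc,
                 fraction_water_bound_to_host = frac,
                 n_water = nw, n_repeat_units = n_repeat_units),
            class = "HBSummary")
}

#' Pair-isolation energy of one hydrogen bond
#'
#' The two bonded molecules are isolated (all other molecules removed) and
#' their total intermolecular energy -- full Lennard-Jones plus bare
#' (undamped, uncut) Coulomb -- is evaluated at minimum image. Returned as a
#' positive binding magnitude in kcal/mol.
#'
#' @param frame A `SystemState`.
#' @param record One row of an `HBRecords` data frame.
#' @return Binding magnitude, kcal/mol (negative if the pair is repulsive).
#' @export
hb_energy <- function(frame, record) {
  s <- frame$sites
  molA <- s$molecule_id[record$donor_O]
  molB <- s$molecule_id[record$acceptor]
  if (molA == molB) stop("hb_energy: record references a single molecule")
  idxA <- which(s$molecule_id == molA)
  idxB <- which(s$molecule_id == molB)
  pos <- unname(as.matrix(s[, c("x", "y", "z")]))
  e <- cpp_pair_isolation_energy(pos, frame$box$lengths, frame$box$periodic,
                                 s$charge, s$sigma, s$epsilon,
                                 as.integer(idxA), as.integer(idxB))
  -e$total / .kcal
}

# vectorized pair-isolation energies for all records of one class
hb_energies <- function(frame, records, hb_class = NULL) {
  if (!is.null(hb_class)) records <- records[records$hb_class == hb_class, , drop = FALSE]
  if (!nrow(records)) return(numeric(0))
  vapply(seq_len(nrow(records)), function(r) hb_energy(frame, records[r, ]),
         numeric(1))
}

#' Radial distribution function over a trajectory
#'
#' Shell-normalized pair histogram between two site selections (by label),
#' with same-molecule pairs excluded by default.
#'
#' @param frames List of frames (`step`/`pos`/`box` as returned in the
#'   `frames` attribute of [step_md()]), or a list of `SystemState`s.
#' @param state Reference `SystemState` supplying site labels/topology.
#' @param pair Character 2-vector of site labels, e.g. `c("OW", "HW")`.
#' @param rmax Histogram range, nm.
#' @param nbins Number of bins.
#' @param intermolecular Exclude same-molecule pairs.
#' @return Object of class `RadialDistribution` with `r` (bin centers),
#'   `g`, `rho` (number density of the second selection, nm^-3).
#' @export
compute_rdf <- function(frames, state, pair = c("OW", "OW"), rmax = 1.0,
                        nbins = 200, intermolecular = TRUE) {
  stopifnot(nbins > 0, rmax > 0)
  sel1 <- which(state$sites$label == pair[1])
  sel2 <- which(state$sites$label == pair[2])
  if (!length(sel1) || !length(sel2)) stop("compute_rdf: empty selection")
  counts <- numeric(nbins)
  vsum <- 0
  nf <- 0
  for (fr in frames) {
    pos <- if (inherits(fr, "SystemState")) unname(as.matrix(fr$sites[, c("x","y","z")])) else fr$pos
    bx <- if (inherits(fr, "SystemState")) fr$box$lengths else fr$box
    counts <- counts + cpp_pair_histogram(pos, bx, state$box$periodic,
                                          as.integer(sel1), as.integer(sel2),
                                          as.integer(state$sites$molecule_id),
                                          intermolecular, rmax, as.integer(nbins))
    vsum <- vsum + prod(bx)
    nf <- nf + 1
  }
  V <- vsum / nf
  rho2 <- length(sel2) / V
  edges <- seq(0, rmax, length.out = nbins + 1)
  vshell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (nf * length(sel1) * rho2 * vshell)
  structure(list(r = (edges[-1] + edges[-(nbins + 1)]) / 2, g = g,
                 pair = pair, rho = rho2, nframes = nf), class = "RadialDistribution")
}

#' Coordination number from a radial distribution function
#'
#' Integrates `4 pi r^2 rho g(r)` over `[rmin, rmax]` (bin-wise, using exact
#' shell volumes).
#'
#' @param rdf A `RadialDistribution`.
#' @param rmin,rmax Integration bounds, nm.
#' @return Mean number of selection-2 neighbours per selection-1 site.
#' @export
coordination_number <- function(rdf, rmin, rmax) {
  nb <- length(rdf$r)
  w <- diff(c(0, rdf$r))[1] * 2  # uniform bins: width
  edges <- seq(rdf$r[1] - w / 2, by = w, length.out = nb + 1)
  vshell <- 4 / 3 * pi * diff(edges^3)
  inb <- rdf$r >= rmin & rdf$r <= rmax
  sum(rdf$rho * rdf$g[inb] * vshell[inb])
}

#' Spatial density map of hydrogen bonds
#'
#' Midpoints of the donor-O...acceptor segments of one bond class, binned on
#' a projection plane and normalized per frame, so the total map mass equals
#' the mean bond count per frame.
#'
#' @param frames List of `SystemState` frames (or `step/pos/box` frames plus
#'   `state`).
#' @param state Reference `SystemState` (roles/topology) when raw frames are
#'   given.
#' @param hb_class `"WW"`, `"CW"` or `"CC"`.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param grid_n Bins per axis.
#' @param crit An [hb_criterion()].
#' @return List with `density` matrix (grid_n x grid_n), bin edges and the
#'   per-frame mean bond count `total_mass`.
#' @export
hb_density_map <- function(frames, state = NULL, hb_class = "WW", plane = "xy",
                           grid_n = 20, crit = hb_criterion()) {
  if (!length(frames)) stop("hb_density_map: empty trajectory")
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3),
               stop("unknown plane"))
  first <- frames[[1]]
  ref <- if (inherits(first, "SystemState")) first else state
  L <- ref$box$lengths
  xe <- seq(0, L[ax[1]], length.out = grid_n + 1)
  ye <- seq(0, L[ax[2]], length.out = grid_n + 1)
  dens <- matrix(0, grid_n, grid_n)
  nf <- 0
  for (fr in frames) {
    st <- if (inherits(fr, "SystemState")) fr else {
      s2 <- state; s2$sites[, c("x", "y", "z")] <- fr$pos
      s2$box <- simulation_box(fr$box, state$box$periodic); s2
    }
    rec <- detect_hbonds(st, crit)
    rec <- rec[rec$hb_class == hb_class, , drop = FALSE]
    nf <- nf + 1
    if (!nrow(rec)) next
    pos <- unname(as.matrix(st$sites[, c("x", "y", "z")]))
    for (r in seq_len(nrow(rec))) {
      o <- pos[rec$donor_O[r], ]; a <- pos[rec$acceptor[r], ]
      mid <- o + 0.5 * minimum_image(o, a, st$box)
      mid <- mid %% st$box$lengths
      i <- min(grid_n, 1 + floor(mid[ax[1]] / L[ax[1]] * grid_n))
      j <- min(grid_n, 1 + floor(mid[ax[2]] / L[ax[2]] * grid_n))
      dens[i, j] <- dens[i, j] + 1
    }
  }
  list(density = dens / nf, x_edges = xe, y_edges = ye, plane = plane,
       hb_class = hb_class, total_mass = sum(dens) / nf)
}

#' Scaling exponent of the raw water-water bond count with moisture content
#'
#' Log-log least-squares fit of `n_ww` against `m`; in swelling sorbents the
#' raw water-water bond count grows roughly quadratically in moisture content
#' (bond density ~ m per water, times ~m waters).
#'
#' @param points Data frame (or list) with components `m` and `n_ww` (> 0).
#' @return List with `exponent`, `se`, `intercept`.
#' @export
nww_scaling <- function(points) {
  m <- points$m; n <- points$n_ww
  keep <- is.finite(m) & is.finite(n) & m > 0 & n > 0
  m <- m[keep]; n <- n[keep]
  if (length(m) < 4) stop("nww_scaling: need at least 4 points with m > 0")
  fit <- lm(log(n) ~ log(m))
  sm <- suppressWarnings(summary(fit))   # exact power laws fit perfectly
  list(exponent = unname(coef(fit)[2]),
       se = unname(sm$coefficients[2, 2]),
       intercept = unname(coef(fit)[1]))
}

#' Capillary critical-point shift for a pore of size D
#'
#' In a pore of diameter `D` the capillary critical temperature `T_cc` is
#' depressed from the bulk `T_c` by approximately `4 lambda T_c / D`, with
#' `lambda` the size of the confined molecule (0.28 nm for water). Pores with
#' `T_cc` at or below the operating temperature fill reversibly.
#'
#' @param D Pore diameter, nm (> 0; vectorized).
#' @param lambda Confined-molecule size, nm.
#' @param Tc Bulk critical temperature, K.
#' @return Shift `T_c - T_cc` in K.
#' @export
#' @examples
#' capillary_shift(1.12, 0.28, 647)   # equals Tc
capillary_shift <- function(D, lambda = 0.28, Tc = 647) {
  stopifnot(all(D > 0), lambda > 0, Tc > 0)
  4 * lambda * Tc / D
}

#' Which pore sizes fill reversibly at an operating temperature?
#' @inheritParams capillary_shift
#' @param T_op Operating temperature, K.
#' @return Logical vector: `TRUE` where `T_cc <= T_op` (reversible filling).
#' @export
reversible_filling <- function(D, T_op = 300, lambda = 0.28, Tc = 647) {
  (Tc - capillary_shift(D, lambda, Tc)) <= T_op
}
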