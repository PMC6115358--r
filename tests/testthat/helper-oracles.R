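# Independent reference implementations used as oracles. These deliberately
# share no code with the package kernels: plain R, written from the model
# definitions.

KB <- 0.0083144621
KC <- 138.935458

erfc_r <- function(x) 2 * pnorm(-x * sqrt(2))

oracle_min_image <- function(d, L, periodic) {
  for (a in 1:3) {
    if (periodic[a]) {
      d[a] <- d[a] - L[a] * floor(d[a] / L[a] + 0.5)
      if (d[a] == -0.5 * L[a]) d[a] <- d[a] + L[a]
    }
  }
  d
}

# LJ (LB mixing) + damped shifted-force Coulomb for one site pair
oracle_pair <- function(ri, rj, qi, qj, si, sj, ei, ej, L, periodic,
                        cutoff, alpha) {
  d <- oracle_min_image(rj - ri, L, periodic)
  r <- sqrt(sum(d^2))
  if (r > cutoff) return(0)
  e <- 0
  eps <- sqrt(ei * ej)
  if (eps > 0) {
    sg <- (si + sj) / 2
    e <- e + 4 * eps * ((sg / r)^12 - (sg / r)^6)
  }
  if (qi * qj != 0) {
    esh <- erfc_r(alpha * cutoff) / cutoff
    fsh <- esh / cutoff + 2 * alpha / sqrt(pi) * exp(-alpha^2 * cutoff^2) / cutoff
    e <- e + KC * qi * qj * (erfc_r(alpha * r) / r - esh + fsh * (r - cutoff))
  }
  e
}

# double-loop nonbonded energy with 1-2/1-3/rigid-group exclusions
oracle_nonbonded <- function(state, cutoff = 0.9, alpha = 2.0) {
  s <- state$sites
  n <- nrow(s)
  topo <- state$topology
  excl <- matrix(FALSE, n, n)
  mark <- function(i, j) excl[cbind(c(i, j), c(j, i))] <<- TRUE
  b <- topo$bonds
  if (nrow(b)) mark(b$i, b$j)
  a <- topo$angles
  if (nrow(a)) { mark(a$i, a$j); mark(a$j, a$k); mark(a$i, a$k) }
  for (g in topo$rigid_groups)
    for (i in g) for (j in g) if (i != j) excl[i, j] <- TRUE
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (s$molecule_id[i] == s$molecule_id[j] && excl[i, j]) next
    e <- e + oracle_pair(as.numeric(s[i, c("x","y","z")]), as.numeric(s[j, c("x","y","z")]),
                         s$charge[i], s$charge[j], s$sigma[i], s$sigma[j],
                         s$epsilon[i], s$epsilon[j],
                         state$box$lengths, state$box$periodic, cutoff, alpha)
  }
  e
}

# all-pairs geometric hydrogen-bond detector
oracle_hbonds <- function(state, d_max = 0.35, angle_max = 30,
                          distance_convention = "O_to_O", angle_at = "donor_O") {
  s <- state$sites
  donH <- which(grepl("donor_H", s$hb_role))
  acc <- which(grepl("acceptor", s$hb_role))
  donO_all <- which(grepl("donor_O", s$hb_role))
  pos <- as.matrix(s[, c("x", "y", "z")])
  res <- NULL
  for (h in donH) {
    cand <- donO_all[s$molecule_id[donO_all] == s$molecule_id[h]]
    if (length(cand) > 1) {
      d2 <- rowSums(sweep(pos[cand, , drop = FALSE], 2, pos[h, ])^2)
      cand <- cand[which.min(d2)]
    }
    o <- cand
    for (ac in acc) {
      if (s$molecule_id[ac] == s$molecule_id[h]) next
      ref <- if (distance_convention == "O_to_H") h else o
      dv <- oracle_min_image(pos[ac, ] - pos[ref, ], state$box$lengths,
                             state$box$periodic)
      if (sqrt(sum(dv^2)) >= d_max) next
      if (angle_at == "H") {
        u <- oracle_min_image(pos[o, ] - pos[h, ], state$box$lengths, state$box$periodic)
        w <- oracle_min_image(pos[ac, ] - pos[h, ], state$box$lengths, state$box$periodic)
        dev <- 180 - acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
      } else {
        u <- oracle_min_image(pos[h, ] - pos[o, ], state$box$lengths, state$box$periodic)
        w <- oracle_min_image(pos[ac, ] - pos[o, ], state$box$lengths, state$box$periodic)
        dev <- acos(sum(u * w) / sqrt(sum(u^2) * sum(w^2))) * 180 / pi
      }
      if (dev >= angle_max) next
      res <- rbind(res, c(o, h, ac))
    }
  }
  if (is.null(res)) matrix(integer(0), 0, 3) else res[order(res[, 2], res[, 3]), , drop = FALSE]
}
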