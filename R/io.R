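#' Write a system to an XYZ or extended-XYZ file
#'
#' Extended-XYZ carries the box (`Lattice=...`), periodicity, charges and
#' roles; plain XYZ only species and coordinates (in nm). Coordinates are
#' printed to 1e-9 nm so a round trip preserves them to print precision.
#'
#' @param state A `SystemState`.
#' @param path Output path.
#' @param format `"extended-xyz"` or `"xyz"`.
#' @param comment Comment line (plain XYZ only).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(state, path, format = c("extended-xyz", "xyz"),
                      comment = "sorpflex configuration") {
  format <- match.arg(format)
  s <- state$sites
  n <- nrow(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  if (format == "extended-xyz") {
    L <- state$box$lengths
    lat <- sprintf('Lattice="%.9f 0 0 0 %.9f 0 0 0 %.9f"', L[1], L[2], L[3])
    pbc <- sprintf('pbc="%s"', paste(ifelse(state$box$periodic, "T", "F"), collapse = " "))
    props <- 'Properties=species:S:1:pos:R:3:charge:R:1:molecule_id:I:1:role:S:1'
    writeLines(paste(lat, props, pbc), con)
  } else {
    writeLines(comment, con)
  }
  if (n > 0) {
    if (format == "extended-xyz") {
      writeLines(sprintf("%s %.9f %.9f %.9f %.9f %d %s",
                         s$label, s$x, s$y, s$z, s$charge, s$molecule_id, s$role), con)
    } else {
      writeLines(sprintf("%s %.9f %.9f %.9f", s$label, s$x, s$y, s$z), con)
    }
  }
  invisible(path)
}

#' Write the bonded topology companion file (JSON)
#'
#' @param state A `SystemState`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(state, path) {
  topo <- state$topology
  payload <- list(bonds = topo$bonds, angles = topo$angles,
                  dihedrals = topo$dihedrals,
                  rigid_groups = lapply(topo$rigid_groups, as.integer),
                  site_params = state$sites[, c("label", "charge", "sigma",
                                                "epsilon", "mass", "hb_role")],
                  frozen_host = state$frozen_host)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an XYZ / extended-XYZ file
#'
#' For extended-XYZ the box, charges and roles come from the header/columns;
#' LJ parameters and masses are filled from `forcefield` by label when given,
#' or from `topology_path` (a [write_topology()] companion) when present.
#'
#' @param path Input path.
#' @param forcefield Optional parsed forcefield for site parameters.
#' @param topology_path Optional companion topology JSON.
#' @param box Fallback `SimulationBox` for plain XYZ.
#' @return A `SystemState`.
#' @export
read_xyz <- function(path, forcefield = NULL, topology_path = NULL, box = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("malformed XYZ (line 1): file too short")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ (line 1): expected an atom count")
  if (length(lines) < 2 + n) stop(sprintf("malformed XYZ (line %d): truncated", length(lines)))
  header <- lines[2]
  ext <- grepl("Lattice=", header)
  if (ext) {
    lat <- regmatches(header, regexpr('Lattice="[^"]*"', header))
    latv <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "[[:space:]]+")[[1]])
    L <- latv[c(1, 5, 9)]
    per <- c(TRUE, TRUE, TRUE)
    if (grepl('pbc="', header)) {
      pb <- gsub('.*pbc="([^"]*)".*', "\\1", header)
      per <- strsplit(pb, "[[:space:]]+")[[1]] == "T"
    }
    bx <- simulation_box(L, per)
  } else {
    bx <- if (is.null(box)) simulation_box(c(10, 10, 10)) else box
  }
  rows <- strsplit(trimws(lines[2 + seq_len(n)]), "[[:space:]]+")
  bad <- which(vapply(rows, length, integer(1)) < 4)
  if (length(bad)) stop(sprintf("malformed XYZ (line %d): expected >= 4 fields", 2 + bad[1]))
  ncol1 <- if (n > 0) length(rows[[1]]) else 0L
  lab <- vapply(rows, `[`, character(1), 1)
  xyz <- if (n > 0) t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
         else matrix(numeric(0), 0, 3)
  charge <- if (ext && ncol1 >= 5)
    vapply(rows, function(r) as.numeric(r[5]), numeric(1)) else rep(0, n)
  molid <- if (ext && ncol1 >= 6)
    vapply(rows, function(r) as.integer(r[6]), integer(1)) else rep(1L, n)
  role <- if (ext && ncol1 >= 7)
    vapply(rows, `[`, character(1), 7) else rep("host", n)
  sites <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], label = lab,
                      charge = charge, sigma = rep(0, n), epsilon = rep(0, n),
                      mass = rep(1, n), molecule_id = molid, role = role,
                      hb_role = rep("", n), stringsAsFactors = FALSE)
  topo <- topology()
  frozen <- FALSE
  if (!is.null(topology_path) && file.exists(topology_path)) {
    tp <- jsonlite::read_json(topology_path, simplifyVector = TRUE)
    pr <- as.data.frame(tp$site_params)
    if (n > 0 && nrow(pr) == n) {
      sites$charge <- pr$charge; sites$sigma <- pr$sigma
      sites$epsilon <- pr$epsilon; sites$mass <- pr$mass
      sites$hb_role <- ifelse(is.na(pr$hb_role), "", pr$hb_role)
    }
    mk <- function(df, cols) if (is.null(df) || !length(df)) NULL else as.data.frame(df)
    rg <- tp$rigid_groups
    rg <- if (is.matrix(rg)) lapply(seq_len(nrow(rg)), function(i) as.integer(rg[i, ]))
          else lapply(rg, as.integer)
    topo <- topology(bonds = mk(tp$bonds), angles = mk(tp$angles),
                     dihedrals = mk(tp$dihedrals), rigid_groups = rg)
    frozen <- isTRUE(tp$frozen_host)
  } else if (!is.null(forcefield)) {
    at <- forcefield$atoms
    hit <- match(lab, at$label)
    if (anyNA(hit)) stop("unknown species in ", path, ": ",
                         paste(unique(lab[is.na(hit)]), collapse = ", "))
    sites$charge <- at$charge[hit]; sites$sigma <- at$sigma[hit]
    sites$epsilon <- at$epsilon[hit]; sites$mass <- at$mass[hit]
    sites$hb_role <- ifelse(at$hb_role[hit] %in% c("none", NA), "", at$hb_role[hit])
  }
  system_state(bx, sites, topo, frozen_host = frozen)
}

#' Write / read a system as prefix.exyz + prefix.topology.json
#' @param state A `SystemState`.
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_system <- function(state, prefix) {
  write_xyz(state, paste0(prefix, ".exyz"), "extended-xyz")
  write_topology(state, paste0(prefix, ".topology.json"))
  invisible(prefix)
}

#' @rdname write_system
#' @export
read_system <- function(prefix) {
  read_xyz(paste0(prefix, ".exyz"),
           topology_path = paste0(prefix, ".topology.json"))
}

#' Export a system as a LAMMPS-style data file
#'
#' `atom_style full` layout (id mol type q x y z) with Masses, Bonds and
#' Angles sections; lengths are written in nm (unit system declared in the
#' header comment).
#'
#' @param state A `SystemState`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(state, path) {
  s <- state$sites
  types <- unique(s$label)
  tid <- match(s$label, types)
  b <- state$topology$bonds
  a <- state$topology$angles
  btypes <- if (nrow(b)) unique(paste(b$k, b$r0)) else character(0)
  atypes <- if (nrow(a)) unique(paste(a$ktheta, a$theta0)) else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("sorpflex LAMMPS data file (lengths nm, energies kJ/mol)")
  w("")
  w("%d atoms", nrow(s))
  w("%d bonds", nrow(b))
  w("%d angles", nrow(a))
  w("%d atom types", length(types))
  w("%d bond types", length(btypes))
  w("%d angle types", length(atypes))
  w("")
  L <- state$box$lengths
  w("0.0 %.9f xlo xhi", L[1]); w("0.0 %.9f ylo yhi", L[2]); w("0.0 %.9f zlo zhi", L[3])
  w("")
  w("Masses")
  w("")
  for (t in seq_along(types)) w("%d %.6f  # %s", t, s$mass[match(types[t], s$label)], types[t])
  w("")
  w("Atoms  # full")
  w("")
  for (i in seq_len(nrow(s)))
    w("%d %d %d %.6f %.9f %.9f %.9f", i, s$molecule_id[i], tid[i], s$charge[i],
      s$x[i], s$y[i], s$z[i])
  if (nrow(b)) {
    w(""); w("Bonds"); w("")
    bt <- match(paste(b$k, b$r0), btypes)
    for (r in seq_len(nrow(b))) w("%d %d %d %d", r, bt[r], b$i[r], b$j[r])
  }
  if (nrow(a)) {
    w(""); w("Angles"); w("")
    at2 <- match(paste(a$ktheta, a$theta0), atypes)
    for (r in seq_len(nrow(a))) w("%d %d %d %d %d", r, at2[r], a$i[r], a$j[r], a$k[r])
  }
  invisible(path)
}

#' Read a LAMMPS-style data file written by [write_lammps_data()]
#'
#' Restores coordinates, charges, molecule ids and bond/angle connectivity
#' (force-field parameters are not encoded in LAMMPS data files; supply a
#' `forcefield` to restore LJ parameters by species label).
#'
#' @param path Input path.
#' @param forcefield Optional parsed forcefield.
#' @return A `SystemState`.
#' @export
read_lammps_data <- function(path, forcefield = NULL) {
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  counts <- function(word) {
    ln <- grep(paste0("^[0-9]+ ", word, "$"), stripped, value = TRUE)
    if (!length(ln)) 0L else as.integer(strsplit(ln[1], " ")[[1]][1])
  }
  na <- counts("atoms"); nb <- counts("bonds"); nang <- counts("angles")
  getL <- function(tag) {
    ln <- grep(paste0(tag, "$"), stripped, value = TRUE)[1]
    v <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]][1:2])
    v[2] - v[1]
  }
  L <- c(getL("xlo xhi"), getL("ylo yhi"), getL("zlo zhi"))
  section <- function(name, ncols, nrows) {
    i0 <- grep(paste0("^", name, "$"), stripped)[1]
    if (is.na(i0) || nrows == 0) return(NULL)
    block <- stripped[(i0 + 1):length(stripped)]
    block <- block[nzchar(block)][seq_len(nrows)]
    do.call(rbind, lapply(strsplit(block, "[[:space:]]+"), function(t) as.numeric(t[seq_len(ncols)])))
  }
  # masses by type (comment carries the label)
  i0 <- grep("^Masses$", stripped)[1]
  mass_lines <- lines[(i0 + 1):length(lines)]
  mass_lines <- mass_lines[nzchar(trimws(mass_lines))]
  ntypes <- counts("atom types")
  mass_lines <- mass_lines[seq_len(ntypes)]
  tl <- lapply(strsplit(trimws(mass_lines), "[[:space:]]+"), identity)
  type_mass <- vapply(tl, function(t) as.numeric(t[2]), numeric(1))
  type_label <- vapply(tl, function(t) if (length(t) >= 4) t[4] else t[1], character(1))
  at <- section("Atoms", 7, na)
  ord <- order(at[, 1])
  at <- at[ord, , drop = FALSE]
  lab <- type_label[at[, 3]]
  sites <- data.frame(x = at[, 5], y = at[, 6], z = at[, 7], label = lab,
                      charge = at[, 4], sigma = 0, epsilon = 0,
                      mass = type_mass[at[, 3]],
                      molecule_id = as.integer(at[, 2]), role = "host",
                      hb_role = "", stringsAsFactors = FALSE)
  if (!is.null(forcefield)) {
    hit <- match(lab, forcefield$atoms$label)
    ok <- !is.na(hit)
    sites$sigma[ok] <- forcefield$atoms$sigma[hit[ok]]
    sites$epsilon[ok] <- forcefield$atoms$epsilon[hit[ok]]
    sites$hb_role[ok] <- ifelse(forcefield$atoms$hb_role[hit[ok]] == "none", "",
                                forcefield$atoms$hb_role[hit[ok]])
  }
  bsec <- section("Bonds", 4, nb)
  asec <- section("Angles", 5, nang)
  topo <- topology(
    bonds = if (!is.null(bsec)) data.frame(i = as.integer(bsec[, 3]),
                                           j = as.integer(bsec[, 4]),
                                           k = 0, r0 = 0) else NULL,
    angles = if (!is.null(asec)) data.frame(i = as.integer(asec[, 3]),
                                            j = as.integer(asec[, 4]),
                                            k = as.integer(asec[, 5]),
                                            ktheta = 0, theta0 = 0) else NULL)
  system_state(simulation_box(L), sites, topo)
}

#' Read a TOML-style run configuration
#'
#' A deliberately small dialect: `[section]` headers, `key = value` pairs,
#' quoted strings, numbers, `true`/`false`, and flat arrays `[a, b, c]`.
#'
#' @param path Config file path.
#' @return Nested named list (one element per section; top-level keys under
#'   `$global`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- "global"
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[", v)) {
      items <- strsplit(gsub("^\\[|\\]$", "", v), ",")[[1]]
      return(unlist(lapply(items, parse_val)))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) { section <- gsub("\\[|\\]", "", ln); next }
    kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    out[[section]][[trimws(kv[1])]] <- parse_val(kv[2])
  }
  out
}

#' Write a reproducibility manifest next to run outputs
#'
#' Records the package version, seeds, config and forcefield checksums and
#' the electrostatics/forcefield choices, so every output can be traced to
#' its inputs.
#'
#' @param path Manifest path (JSON).
#' @param config_path Optional config file to checksum.
#' @param seeds Named list/vector of seeds.
#' @param extra Extra metadata fields.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config_path = NULL, seeds = list(), extra = list()) {
  m <- c(list(
    package = "sorpflex",
    version = as.character(utils::packageVersion("sorpflex")),
    electrostatics = "damped-shifted-force (alpha 2 nm^-1)",
    config_md5 = if (!is.null(config_path)) unname(tools::md5sum(config_path)) else NA,
    forcefield_md5 = list(
      spce = unname(tools::md5sum(sorpflex_file("spce.ff"))),
      surrogate_host = unname(tools::md5sum(sorpflex_file("surrogate_host.ff")))),
    seeds = seeds), extra)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
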