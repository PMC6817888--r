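species_to_type <- function(species) match(species, SPECIES_LEVELS)
type_to_species <- function(type) SPECIES_LEVELS[type]

#' Write / read a LAMMPS-style dump frame
#'
#' The interchange trajectory format: `ITEM: TIMESTEP / NUMBER OF ATOMS /
#' BOX BOUNDS pp pp pp / ATOMS id type x y z vx vy vz`, with species encoded
#' as integers (H = 1, T = 2, W = 3) and coordinates printed with 17
#' significant digits so that `read_dump(write_dump(x))` round-trips
#' bit-exactly.
#'
#' @param system A `dpd_system`.
#' @param path Output file path (or a connection for `read_dump`).
#' @param append Append the frame to an existing dump file.
#' @return `write_dump`: the path, invisibly. `read_dump`: a `dpd_system`
#'   (bonded topology is not part of the dump; the returned system carries
#'   none).
#' @examples
#' f <- tempfile(fileext = ".dump")
#' write_dump(water_box(3, seed = 1), f)
#' read_dump(f)
#' @export
write_dump <- function(system, path, append = FALSE) {
  b <- system$beads
  lines <- c(
    "ITEM: TIMESTEP",
    format(system$step),
    "ITEM: NUMBER OF ATOMS",
    format(nrow(b)),
    "ITEM: BOX BOUNDS pp pp pp",
    sprintf("%.17g %.17g", 0, system$box[1]),
    sprintf("%.17g %.17g", 0, system$box[2]),
    sprintf("%.17g %.17g", 0, system$box[3]),
    "ITEM: ATOMS id type x y z vx vy vz"
  )
  if (nrow(b) > 0) {
    lines <- c(lines, sprintf(
      "%d %d %.17g %.17g %.17g %.17g %.17g %.17g",
      b$id, species_to_type(b$species), b$x, b$y, b$z, b$vx, b$vy, b$vz))
  }
  if (append) {
    cat(lines, file = path, sep = "\n", append = TRUE)
    cat("\n", file = path, append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_dump
#' @export
read_dump <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  expect_item <- function(idx, what) {
    if (idx > length(lines) || !startsWith(lines[idx], paste0("ITEM: ", what))) {
      abort(sprintf("malformed dump: expected 'ITEM: %s' at line %d", what, idx))
    }
  }
  expect_item(1, "TIMESTEP")
  step <- as.integer(lines[2])
  expect_item(3, "NUMBER OF ATOMS")
  n <- as.integer(lines[4])
  expect_item(5, "BOX BOUNDS")
  bounds <- do.call(rbind, lapply(lines[6:8], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (any(is.na(bounds))) abort("malformed dump: unreadable box bounds at line 6-8")
  box <- bounds[, 2] - bounds[, 1]
  expect_item(9, "ATOMS")
  cols <- strsplit(sub("ITEM: ATOMS ", "", lines[9]), "\\s+")[[1]]
  need <- c("id", "type", "x", "y", "z", "vx", "vy", "vz")
  if (!identical(cols, need)) {
    abort(sprintf("malformed dump: unexpected ATOMS columns at line 9"))
  }
  if (n > 0) {
    body <- lines[10:(9 + n)]
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                nrow = n, byrow = TRUE)
    if (ncol(m) != 8 || any(is.na(m))) {
      abort("malformed dump: unreadable atom record after line 9")
    }
    m <- m[order(m[, 1]), , drop = FALSE]
    beads <- tibble(
      id = as.integer(m[, 1]), species = type_to_species(as.integer(m[, 2])),
      chain = NA_integer_,
      x = m[, 3], y = m[, 4], z = m[, 5],
      vx = m[, 6], vy = m[, 7], vz = m[, 8]
    )
  } else {
    beads <- make_beads(character(), integer(), matrix(0, 0, 3))
  }
  validate_dpd_system(new_dpd_system(beads, box, step = step,
                                     time = NA_real_))
}

#' Write an extended-XYZ frame
#'
#' One-frame extended-XYZ with a `Lattice=...` and
#' `Properties=species:S:1:pos:R:3:vel:R:3` comment line, for visualizers.
#'
#' @param system A `dpd_system`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xyz <- function(system, path) {
  b <- system$beads
  L <- system$box
  header <- sprintf(
    'Lattice="%g 0 0 0 %g 0 0 0 %g" Properties=species:S:1:pos:R:3:vel:R:3 Time=%g',
    L[1], L[2], L[3], system$time)
  lines <- c(format(nrow(b)), header)
  if (nrow(b) > 0) {
    lines <- c(lines, sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g",
                              b$species, b$x, b$y, b$z, b$vx, b$vy, b$vz))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export topology as a LAMMPS data file
#'
#' Writes atoms (molecular style: id, molecule, type, x, y, z), bonds and
#' angles with species encoded H = 1, T = 2, W = 3. Bond and angle types are
#' numbered by distinct parameter combinations, listed in header comments.
#'
#' @param system A `dpd_system`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_lammps_data <- function(system, path) {
  b <- system$beads
  bonds <- system$bonds
  angles <- system$angles
  bond_types <- unique(bonds[, c("k_bond", "r_bond")])
  angle_types <- unique(angles[, c("k_angle", "theta0")])
  bt <- if (nrow(bonds)) {
    match(paste(bonds$k_bond, bonds$r_bond),
          paste(bond_types$k_bond, bond_types$r_bond))
  } else integer()
  at <- if (nrow(angles)) {
    match(paste(angles$k_angle, angles$theta0),
          paste(angle_types$k_angle, angle_types$theta0))
  } else integer()
  lines <- c(
    sprintf("LAMMPS data file via dpdshear %s",
            as.character(utils::packageVersion("dpdshear"))),
    "",
    sprintf("%d atoms", nrow(b)),
    sprintf("%d bonds", nrow(bonds)),
    sprintf("%d angles", nrow(angles)),
    "",
    "3 atom types",
    sprintf("%d bond types", nrow(bond_types)),
    sprintf("%d angle types", nrow(angle_types)),
    "",
    sprintf("0 %.17g xlo xhi", system$box[1]),
    sprintf("0 %.17g ylo yhi", system$box[2]),
    sprintf("0 %.17g zlo zhi", system$box[3]),
    "",
    "Masses",
    "",
    "1 1.0", "2 1.0", "3 1.0",
    "",
    "Atoms # molecular",
    ""
  )
  mol <- ifelse(is.na(b$chain), 0L, b$chain)
  lines <- c(lines, sprintf("%d %d %d %.17g %.17g %.17g",
                            b$id, mol, species_to_type(b$species),
                            b$x, b$y, b$z))
  if (nrow(bonds) > 0) {
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nrow(bonds)), bt,
                       bonds$i, bonds$j))
  }
  if (nrow(angles) > 0) {
    lines <- c(lines, "", "Angles", "",
               sprintf("%d %d %d %d %d", seq_len(nrow(angles)), at,
                       angles$i, angles$j, angles$k))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write observable series as TSV
#'
#' Tab-separated observable time series with a comment header carrying the
#' package version and the run seed, so outputs are self-describing.
#'
#' @param trajectory A `dpd_trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_observables <- function(trajectory, path) {
  hdr <- sprintf("# dpdshear %s seed=%s dt=%g",
                 as.character(utils::packageVersion("dpdshear")),
                 format(trajectory$params$seed), trajectory$params$dt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(trajectory$observables, con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    rho = 3, L = 30, phi = 0.35, n_head = 3, n_tail = 4,
    dt = 0.01, lambda = 0.65, steps = 200000, seed = 1,
    sigma = 3, kBT = 1, a_like = 50, a_unlike = 200,
    k_bond = 100, r_bond = 0.7, k_angle = 6,
    W = 0, n_slabs = 20, sample_every = 100, frame_every = 0
  )
}

#' Load a flat key=value run configuration
#'
#' Parses `key = value` lines (blank lines and `#` comments ignored) on top
#' of the standard parameter set: bead density 3, box edge 30, time step
#' 0.01 tau, sigma = 3 (so friction 4.5 at kBT = 1), bond constants
#' k = 100 and r0 = 0.7 r_c, bending constant 6, repulsion 50/200, shear off
#' (`W = 0`). Unknown keys, unparsable values and out-of-range `phi` are
#' rejected with a message naming the key.
#'
#' @param path Path to a config file, or `NULL` for pure defaults.
#' @return A named list of class `dpd_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) abort(sprintf("config line not key=value: '%s'", ln))
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) abort(sprintf("unknown config key: '%s'", key))
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) abort(sprintf("config key '%s' has non-numeric value '%s'",
                                    key, val))
      cfg[[key]] <- num
    }
  }
  if (cfg$phi < 0 || cfg$phi > 1) abort("config key 'phi' out of range [0, 1]")
  if (cfg$dt <= 0) abort("config key 'dt' must be positive")
  if (cfg$steps < 0) abort("config key 'steps' must be non-negative")
  structure(cfg, class = "dpd_config")
}
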