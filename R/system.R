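#' @title Particle system container
#' @description Internal constructor for the `dpd_system` class: a beads
#'   tibble plus global bonded topology and box metadata.
#' @param beads Tibble with columns `id`, `species`, `chain`, `x`, `y`, `z`,
#'   `vx`, `vy`, `vz`.
#' @param box Numeric length-3 box edges (r_c units).
#' @param bonds,angles Global bonded-topology tibbles (bead indices refer to
#'   rows of `beads`).
#' @param step,time Step counter and elapsed time.
#' @keywords internal
new_dpd_system <- function(beads, box,
                           bonds = tibble(i = integer(), j = integer(),
                                          k_bond = double(), r_bond = double()),
                           angles = tibble(i = integer(), j = integer(),
                                           k = integer(), k_angle = double(),
                                           theta0 = double()),
                           step = 0L, time = 0) {
  structure(
    list(beads = beads, box = as.numeric(box), bonds = bonds, angles = angles,
         step = as.integer(step), time = time),
    class = "dpd_system"
  )
}

#' Validate a particle system
#'
#' Checks the structural invariants of a `dpd_system`: consistent column
#' lengths, finite coordinates and velocities, positions wrapped into
#' `[0, L)` per axis, and bonded-topology indices within range.
#'
#' @param system A `dpd_system`.
#' @return The system, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_dpd_system <- function(system) {
  b <- system$beads
  need <- c("id", "species", "chain", "x", "y", "z", "vx", "vy", "vz")
  if (!all(need %in% names(b))) {
    abort(paste("beads tibble lacks columns:",
                paste(setdiff(need, names(b)), collapse = ", ")))
  }
  if (length(system$box) != 3 || any(!is.finite(system$box)) ||
      any(system$box <= 0)) {
    abort("box must be three positive finite edge lengths")
  }
  num <- as.matrix(b[, c("x", "y", "z", "vx", "vy", "vz")])
  if (any(!is.finite(num))) abort("non-finite coordinate or velocity")
  for (ax in 1:3) {
    v <- num[, ax]
    if (nrow(b) > 0 && (min(v) < 0 || max(v) >= system$box[ax])) {
      abort(sprintf("positions on axis %d not wrapped to [0, L)", ax))
    }
  }
  if (!all(b$species %in% SPECIES_LEVELS)) abort("unknown bead species")
  idx <- c(system$bonds$i, system$bonds$j,
           system$angles$i, system$angles$j, system$angles$k)
  if (length(idx) && (min(idx) < 1 || max(idx) > nrow(b))) {
    abort("bonded topology refers to beads outside the system")
  }
  invisible(system)
}

#' @export
print.dpd_system <- function(x, ...) {
  comp <- table(factor(x$beads$species, levels = SPECIES_LEVELS))
  cat(sprintf(
    "<dpd_system> %d beads (H %d, T %d, W %d), box %.4g x %.4g x %.4g, step %d\n",
    nrow(x$beads), comp[["H"]], comp[["T"]], comp[["W"]],
    x$box[1], x$box[2], x$box[3], x$step))
  cat(sprintf("  %d chains, %d bonds, %d angles, time %.4g tau\n",
              n_chains(x), nrow(x$bonds), nrow(x$angles), x$time))
  invisible(x)
}

#' Number of lipid chains in a system
#' @param system A `dpd_system`.
#' @return Integer chain count.
#' @export
n_chains <- function(system) {
  ch <- system$beads$chain
  if (all(is.na(ch))) 0L else length(unique(ch[!is.na(ch)]))
}

#' Bead table of a system
#'
#' @param system A `dpd_system`.
#' @return The beads tibble (`id`, `species`, `chain`, positions,
#'   velocities).
#' @export
as_bead_tibble <- function(system) system$beads

# replicate one lipid's bonded topology across n_chains chains whose beads
# occupy the first n_chains * n_beads rows in chain-major order
replicate_topology <- function(lipid, n_chains) {
  nb <- lipid$n_beads
  if (n_chains == 0) {
    return(list(
      bonds = tibble(i = integer(), j = integer(),
                     k_bond = double(), r_bond = double()),
      angles = tibble(i = integer(), j = integer(), k = integer(),
                      k_angle = double(), theta0 = double())))
  }
  off <- rep((seq_len(n_chains) - 1L) * nb, each = nrow(lipid$bonds))
  bonds <- tibble(
    i = rep(lipid$bonds$i, n_chains) + off,
    j = rep(lipid$bonds$j, n_chains) + off,
    k_bond = rep(lipid$bonds$k_bond, n_chains),
    r_bond = rep(lipid$bonds$r_bond, n_chains)
  )
  offa <- rep((seq_len(n_chains) - 1L) * nb, each = nrow(lipid$angles))
  angles <- tibble(
    i = rep(lipid$angles$i, n_chains) + offa,
    j = rep(lipid$angles$j, n_chains) + offa,
    k = rep(lipid$angles$k, n_chains) + offa,
    k_angle = rep(lipid$angles$k_angle, n_chains),
    theta0 = rep(lipid$angles$theta0, n_chains)
  )
  list(bonds = bonds, angles = angles)
}

make_beads <- function(species, chain, pos, vel = NULL) {
  n <- length(species)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  tibble(
    id = seq_len(n), species = species, chain = chain,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3]
  )
}

wrap_positions <- function(pos, box) {
  for (ax in 1:3) pos[, ax] <- pos[, ax] - box[ax] * floor(pos[, ax] / box[ax])
  pos
}

# fold coordinates into [0, L) by reflection at the walls
reflect_into <- function(v, L) {
  q <- v %% (2 * L)
  ifelse(q > L, 2 * L - q, q)
}

random_unit_rows <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Random solvated lipid solution
#'
#' Generates a periodic cubic box at bead density `density` containing
#' lipid chains at fraction `phi` (see [compose_system()]) and water for the
#' remainder. Chains are laid down as random walks with step `r_bond`,
#' reflected at the box walls and then wrapped; water beads are uniform.
#' Soft DPD cores make overlap removal unnecessary. Velocities are zero;
#' call [init_velocities()] before running.
#'
#' @param phi Lipid bead fraction in `[0, 1]`.
#' @param box_edge Cubic box edge (r_c units).
#' @param density Bead density (default 3).
#' @param lipid A `lipid_topology` from [build_lipid()].
#' @param seed Optional integer seed for reproducible placement.
#' @return A `dpd_system`.
#' @examples
#' sys <- random_solution(0.35, box_edge = 6, seed = 1)
#' @export
random_solution <- function(phi, box_edge, density = 3,
                            lipid = build_lipid(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  comp <- compose_system(phi, box_edge, density,
                         n_head = lipid$n_head, n_tail = lipid$n_tail)
  L <- rep(box_edge, 3)
  nb <- lipid$n_beads
  nc <- comp$n_chains
  r0 <- lipid$bonds$r_bond[1] %||% 0.7

  if (nc > 0) {
    pos <- array(0, dim = c(nc, nb, 3))
    pos[, 1, ] <- matrix(runif(nc * 3), nc, 3) * box_edge
    for (b in seq_len(nrow(lipid$bonds))) {
      i <- lipid$bonds$i[b]; j <- lipid$bonds$j[b]
      step <- random_unit_rows(nc) * lipid$bonds$r_bond[b]
      p <- pos[, i, , drop = FALSE][, 1, ] + step
      if (nc == 1) p <- matrix(p, 1, 3)
      for (ax in 1:3) p[, ax] <- reflect_into(p[, ax], box_edge)
      pos[, j, ] <- p
    }
    lipid_pos <- matrix(aperm(pos, c(2, 1, 3)), nc * nb, 3)
  } else {
    lipid_pos <- matrix(0, 0, 3)
  }
  water_pos <- matrix(runif(comp$n_water * 3), comp$n_water, 3) * box_edge
  pos_all <- wrap_positions(rbind(lipid_pos, water_pos), L)
  species <- c(rep(lipid$species, nc), rep("W", comp$n_water))
  chain <- c(rep(seq_len(nc), each = nb), rep(NA_integer_, comp$n_water))
  topo <- replicate_topology(lipid, nc)
  sys <- new_dpd_system(make_beads(species, chain, pos_all), L,
                        topo$bonds, topo$angles)
  attr(sys, "composition") <- comp
  attr(sys, "lipid") <- lipid
  validate_dpd_system(sys)
}

#' Water-only box
#'
#' A pure-solvent periodic box at the given density: `round(density *
#' box_edge^3)` water beads placed uniformly. Used for thermostat and
#' shear-viscosity characterization.
#'
#' @param box_edge Cubic box edge (r_c units).
#' @param density Bead density (default 3).
#' @param seed Optional integer seed.
#' @return A `dpd_system` with no bonded topology.
#' @examples
#' water_box(5, seed = 1)
#' @export
water_box <- function(box_edge, density = 3, seed = NULL) {
  if (box_edge <= 0 || density <= 0) {
    abort("`box_edge` and `density` must be positive")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(density * box_edge^3)
  pos <- matrix(runif(n * 3), n, 3) * box_edge
  sys <- new_dpd_system(
    make_beads(rep("W", n), rep(NA_integer_, n), pos), rep(box_edge, 3))
  validate_dpd_system(sys)
}

#' Idealized porous-cylinder initial state
#'
#' Builds a pre-assembled lipid cylinder along the z axis whose cross-section
#' contains `n_pores` water-filled channels arranged on a regular polygon
#' (triangle, square, pentagon or hexagon). Tail beads fill the annular
#' matrix between the outer surface and the pores; head beads coat the
#' lipid--water interfaces; water fills the pores and the exterior. This is an
#' idealization for scaled-down shear experiments, not a bead-for-bead
#' reproduction of a self-assembled state.
#'
#' @param phi Lipid bead fraction; sets the outer radius via the bead budget.
#' @param box_edge Cubic box edge (r_c units).
#' @param n_pores Number of inner water channels, one of 3, 4, 5, 6.
#' @param pore_radius Radius of each inner channel (r_c units).
#' @param ring_radius Distance of pore centres from the cylinder axis;
#'   default keeps neighbouring pores separated by at least one bilayer.
#' @param density Bead density (default 3).
#' @param lipid A `lipid_topology`.
#' @param seed Optional integer seed.
#' @return A `dpd_system`.
#' @examples
#' sys <- porous_cylinder_system(0.35, box_edge = 12, n_pores = 3, seed = 1)
#' @export
porous_cylinder_system <- function(phi, box_edge, n_pores = 3,
                                   pore_radius = box_edge / 9,
                                   ring_radius = NULL,
                                   density = 3, lipid = build_lipid(),
                                   seed = NULL) {
  if (!n_pores %in% 3:6) abort("`n_pores` must be 3, 4, 5 or 6")
  if (!is.null(seed)) set.seed(seed)
  comp <- compose_system(phi, box_edge, density,
                         n_head = lipid$n_head, n_tail = lipid$n_tail)
  L <- box_edge
  nc <- comp$n_chains
  nb <- lipid$n_beads
  n_lip <- nc * nb
  r_p <- pore_radius
  # annulus area holds all lipid beads at the global density
  R_out <- sqrt(n_lip / (density * pi * L) + n_pores * r_p^2)
  spacing_needed <- 2 * r_p + 1    # neighbouring pores separated by a bilayer
  if (is.null(ring_radius)) {
    ring_radius <- max(spacing_needed / (2 * sin(pi / n_pores)), r_p + 0.7)
  }
  if (ring_radius + r_p + 0.7 > R_out) {
    abort("pores do not fit inside the outer cylinder; reduce `pore_radius` or raise `phi`")
  }
  if (R_out > L / 2 - 0.5) {
    abort("outer cylinder does not fit in the box; raise `box_edge` or reduce `phi`")
  }
  c0 <- c(L / 2, L / 2)
  pore_ang <- 2 * pi * (seq_len(n_pores) - 1) / n_pores
  pore_xy <- cbind(c0[1] + ring_radius * cos(pore_ang),
                   c0[2] + ring_radius * sin(pore_ang))

  r_bond <- lipid$bonds$r_bond[1] %||% 0.7
  # pick an interface per chain, area-weighted
  areas <- c(outer = 2 * pi * R_out * L, rep(2 * pi * r_p * L, n_pores))
  iface <- sample.int(n_pores + 1, nc, replace = TRUE, prob = areas) - 1L

  pos <- matrix(0, n_lip, 3)
  in_pore <- function(xy) {
    d2 <- (outer(xy[, 1], pore_xy[, 1], "-"))^2 +
          (outer(xy[, 2], pore_xy[, 2], "-"))^2
    apply(d2 < (r_p + 0.25)^2, 1, any)
  }
  for (ci in seq_len(nc)) {
    th <- runif(1, 0, 2 * pi)
    zz <- runif(1, 0, L)
    if (iface[ci] == 0L) {
      centre <- c0; rad <- R_out; inward <- -1
    } else {
      centre <- pore_xy[iface[ci], ]; rad <- r_p; inward <- +1
    }
    anchor <- c(centre + rad * c(cos(th), sin(th)), zz)
    nrm <- inward * c(cos(th), sin(th), 0)    # points into the tail matrix
    chain_pos <- matrix(0, nb, 3)
    # head beads lie along the surface (tangent = z), so every H bead sits on
    # a lipid-water interface by construction
    for (h in seq_len(lipid$n_head)) {
      chain_pos[h, ] <- anchor + c(0, 0, (h - 1) * r_bond)
    }
    junction <- chain_pos[lipid$n_head, ]
    for (tail in 1:2) {
      prev <- junction
      for (tb in seq_len(lipid$n_tail)) {
        idx <- lipid$n_head + (tail - 1L) * lipid$n_tail + tb
        for (try in 1:8) {
          dirv <- 0.75 * nrm + 0.55 * rnorm(3)
          dirv <- dirv / sqrt(sum(dirv^2))
          cand <- prev + r_bond * dirv
          cxy <- matrix(cand[1:2], 1, 2)
          rr <- sqrt(sum((cand[1:2] - c0)^2))
          ok <- rr < R_out - 0.15 && !in_pore(cxy)
          if (ok || try == 8) break
        }
        if (!ok) {  # project back to mid-matrix radius
          dirr <- (cand[1:2] - c0) / max(rr, 1e-9)
          cand[1:2] <- c0 + dirr * (ring_radius + r_p + 0.5)
        }
        chain_pos[idx, ] <- cand
        prev <- cand
      }
    }
    pos[(ci - 1L) * nb + seq_len(nb), ] <- chain_pos
  }

  # water: fill pores and exterior proportionally to their volumes
  v_pore <- n_pores * pi * r_p^2 * L
  v_ext <- L^3 - pi * R_out^2 * L
  n_w <- comp$n_water
  n_w_pore <- round(n_w * v_pore / (v_pore + v_ext))
  n_w_ext <- n_w - n_w_pore
  wp <- matrix(0, n_w_pore, 3)
  if (n_w_pore > 0) {
    which_pore <- sample.int(n_pores, n_w_pore, replace = TRUE)
    rr <- r_p * sqrt(runif(n_w_pore))
    aa <- runif(n_w_pore, 0, 2 * pi)
    wp[, 1] <- pore_xy[which_pore, 1] + rr * cos(aa)
    wp[, 2] <- pore_xy[which_pore, 2] + rr * sin(aa)
    wp[, 3] <- runif(n_w_pore, 0, L)
  }
  we <- matrix(0, 0, 3)
  if (n_w_ext > 0) {
    got <- 0
    parts <- list()
    while (got < n_w_ext) {
      m <- max(1000, 2 * (n_w_ext - got))
      cand <- matrix(runif(3 * m), m, 3) * L
      keep <- sqrt((cand[, 1] - c0[1])^2 + (cand[, 2] - c0[2])^2) > R_out
      cand <- cand[keep, , drop = FALSE]
      parts[[length(parts) + 1]] <- cand
      got <- got + nrow(cand)
    }
    we <- do.call(rbind, parts)[seq_len(n_w_ext), , drop = FALSE]
  }

  pos_all <- wrap_positions(rbind(pos, wp, we), rep(L, 3))
  species <- c(rep(lipid$species, nc), rep("W", n_w))
  chain <- c(rep(seq_len(nc), each = nb), rep(NA_integer_, n_w))
  topo <- replicate_topology(lipid, nc)
  sys <- new_dpd_system(make_beads(species, chain, pos_all), rep(L, 3),
                        topo$bonds, topo$angles)
  attr(sys, "composition") <- comp
  attr(sys, "lipid") <- lipid
  attr(sys, "pore_centres") <- pore_xy
  attr(sys, "outer_radius") <- R_out
  attr(sys, "pore_radius") <- r_p
  validate_dpd_system(sys)
}

#' Draw Maxwell--Boltzmann velocities
#'
#' Assigns Gaussian velocities at temperature `kBT` (mass 1 per bead) and
#' removes the centre-of-mass drift, so total momentum is exactly zero.
#'
#' @param system A `dpd_system`.
#' @param kBT Target temperature (reduced).
#' @param seed Optional integer seed.
#' @return The system with velocities set.
#' @export
init_velocities <- function(system, kBT = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(system$beads)
  if (n == 0) return(system)
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  v <- sweep(v, 2, colMeans(v))
  if (kBT == 0) v[] <- 0
  system$beads$vx <- v[, 1]
  system$beads$vy <- v[, 2]
  system$beads$vz <- v[, 3]
  system
}

#' Instantaneous kinetic temperature
#'
#' \eqn{T_{kin} = 2 E_{kin} / (3N - 3)}: three degrees of freedom per bead
#' less the three of the conserved centre of mass.
#'
#' @param system A `dpd_system`.
#' @return Kinetic temperature (reduced units).
#' @export
kinetic_temperature <- function(system) {
  b <- system$beads
  n <- nrow(b)
  if (n < 2) return(NA_real_)
  ke <- 0.5 * sum(b$vx^2 + b$vy^2 + b$vz^2)
  2 * ke / (3 * n - 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
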