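# builders for hand-placed micro-systems used across the force/observable tests

# a system of free beads at given positions (rows), optional velocities
bead_system <- function(pos, box_edge = 10, vel = NULL, species = NULL,
                        chain = NULL) {
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(species)) species <- rep("W", n)
  if (is.null(chain)) chain <- rep(NA_integer_, n)
  beads <- tibble::tibble(
    id = seq_len(n), species = species, chain = chain,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vx = vel[, 1], vy = vel[, 2], vz = vel[, 3]
  )
  dpdshear:::new_dpd_system(beads, rep(box_edge, 3))
}

# attach an explicit bond/angle table to a system
with_bonds <- function(system, i, j, k_bond = 100, r_bond = 0.7) {
  system$bonds <- tibble::tibble(i = as.integer(i), j = as.integer(j),
                                 k_bond = k_bond, r_bond = r_bond)
  system
}

with_angles <- function(system, i, j, k, k_angle = 6, theta0 = pi) {
  system$angles <- tibble::tibble(i = as.integer(i), j = as.integer(j),
                                  k = as.integer(k),
                                  k_angle = k_angle, theta0 = theta0)
  system
}

# force field with every channel off except the conservative one
ff_conservative <- function(a_like = 50, a_unlike = 200) {
  dpd_forcefield(a_like = a_like, a_unlike = a_unlike, sigma = 0)
}

# conservative + dissipative only (kBT = 0 keeps fluctuation-dissipation
# consistent with zero noise)
ff_no_noise <- function(gamma = 4.5, a_like = 50, a_unlike = 200) {
  dpd_forcefield(a_like = a_like, a_unlike = a_unlike, sigma = 0, kBT = 0,
                 gamma = gamma)
}

# bonded interactions only
ff_silent <- function() dpd_forcefield(a_like = 0, a_unlike = 0, sigma = 0)

force_matrix <- function(f) as.matrix(f$forces[, c("fx", "fy", "fz")])

# fabricate a minimal trajectory object carrying only a slab profile,
# for testing profile-based observables on constructed inputs
profile_trajectory <- function(slab_vx, box_edge, steps = 1L, n_per_slab = 100) {
  n_slabs <- length(slab_vx)
  zc <- (seq_len(n_slabs) - 0.5) * box_edge / n_slabs
  prof <- tidyr::expand_grid(step = steps, slab = seq_len(n_slabs) - 1L)
  prof$z <- rep(zc, length(steps))
  prof$vx <- rep(slab_vx, length(steps))
  prof$n <- n_per_slab
  structure(list(profile = prof,
                 params = list(dt = 0.01),
                 system = list(box = rep(box_edge, 3))),
            class = "dpd_trajectory")
}
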