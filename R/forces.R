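species_codes <- function(species) {
  match(species, SPECIES_LEVELS) - 1L
}

#' Evaluate all forces on a system
#'
#' Computes the full DPD force on every bead: soft conservative repulsion
#' \eqn{a_{ij} w(r) \hat r}, dissipative drag \eqn{-\gamma w^2(r) (\hat r
#' \cdot v_{ij}) \hat r}, random kicks \eqn{\sigma w(r) \zeta_{ij}
#' \Delta t^{-1/2} \hat r} with symmetric pair noise, plus harmonic bond and
#' angle forces, under periodic minimum-image geometry. Bonded beads also feel
#' the non-bonded forces (no exclusions; the soft cores make them harmless).
#'
#' The pair search uses a cell list when the box admits at least 3 cells per
#' axis, otherwise an O(N^2) loop; `method` forces one path (the two are
#' exactly equivalent, which the test suite asserts).
#'
#' @param system A `dpd_system`.
#' @param forcefield A [dpd_forcefield()].
#' @param dt Time step (enters the random-force amplitude as
#'   \eqn{\Delta t^{-1/2}}).
#' @param stream Integer noise-stream seed for the pairwise random force.
#' @param step Step index keying the pairwise noise.
#' @param method `"auto"`, `"cell"` or `"brute"`.
#' @return A list with `forces` (tibble `id`, `fx`, `fy`, `fz`), the
#'   potential-energy breakdown `u_pair`, `u_bond`, `u_angle`, and
#'   `n_overlap` (count of zero-separation pairs handled with a random
#'   direction).
#' @examples
#' sys <- water_box(4, seed = 1)
#' f <- compute_forces(sys, dpd_forcefield(sigma = 0))
#' colSums(f$forces[, c("fx", "fy", "fz")])  # Newton's third law
#' @export
compute_forces <- function(system, forcefield = dpd_forcefield(), dt = 0.01,
                           stream = 0, step = 0, method = c("auto", "cell", "brute")) {
  method <- match.arg(method)
  b <- system$beads
  brute <- method == "brute"
  if (method == "cell" && any(floor(system$box / forcefield$r_c) < 3)) {
    warn("box too small for a cell decomposition; falling back to brute force")
  }
  res <- .compute_forces_cpp(
    b$x, b$y, b$z, b$vx, b$vy, b$vz,
    species_codes(b$species), system$box,
    forcefield$a, forcefield$gamma, forcefield$sigma, forcefield$r_c, dt,
    system$bonds$i - 1L, system$bonds$j - 1L,
    system$bonds$k_bond, system$bonds$r_bond,
    system$angles$i - 1L, system$angles$j - 1L, system$angles$k - 1L,
    system$angles$k_angle, system$angles$theta0,
    as.numeric(stream), as.integer(step), brute
  )
  list(
    forces = tibble(id = b$id, fx = res$fx, fy = res$fy, fz = res$fz),
    u_pair = res$u_pair, u_bond = res$u_bond, u_angle = res$u_angle,
    n_overlap = res$n_overlap
  )
}

#' Neighbour pairs within the cutoff
#'
#' Enumerates every unordered bead pair whose minimum-image separation is
#' below `r_c`, via the cell list (or a brute-force double loop, the oracle
#' used by the property tests).
#'
#' @param system A `dpd_system`.
#' @param r_c Cutoff radius.
#' @param method `"cell"` or `"brute"`.
#' @return Tibble with columns `i`, `j` (`i < j`), sorted.
#' @export
neighbor_pairs <- function(system, r_c = 1, method = c("cell", "brute")) {
  method <- match.arg(method)
  b <- system$beads
  m <- .pairs_cpp(b$x, b$y, b$z, system$box, r_c, method == "brute")
  out <- tibble(i = m[, 1], j = m[, 2])
  dplyr::arrange(out, .data$i, .data$j)
}
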