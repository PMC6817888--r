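#' Build the coarse-grained double-tailed lipid architecture
#'
#' Constructs the bonded topology of one coarse-grained phospholipid: a linear
#' head chain of `n_head` hydrophilic (H) beads and two linear tails of
#' `n_tail` hydrophobic (T) beads each, both tails attached at the last head
#' bead. Every pair of consecutively bonded beads is joined by a harmonic
#' spring; every triple of consecutively bonded beads carries a harmonic
#' bending term. Within a tail the equilibrium angle is \eqn{\theta_0 = \pi}
#' (straight); the triple spanning each head--tail junction and the triples
#' internal to the head use \eqn{\theta_0 = 2\pi/3}.
#'
#' @param n_head Number of head (H) beads, at least 2.
#' @param n_tail Number of tail (T) beads per tail, at least 2.
#' @param k_bond Bond spring constant (reduced energy/length^2).
#' @param r_bond Equilibrium bond length (r_c units).
#' @param k_angle Bending constant (reduced energy/radian^2).
#' @param theta_tail Equilibrium angle for three consecutive tail beads
#'   (radians).
#' @param theta_junction Equilibrium angle for triples at the head--tail
#'   junction and within the head (radians).
#'
#' @return An object of class `lipid_topology`: a list with
#'   \describe{
#'     \item{species}{character vector (`"H"`/`"T"`), one entry per bead;
#'       beads are ordered head first, then tail 1, then tail 2}
#'     \item{bonds}{tibble with columns `i`, `j`, `k_bond`, `r_bond`}
#'     \item{angles}{tibble with columns `i`, `j`, `k` (centre bead `j`),
#'       `k_angle`, `theta0`}
#'     \item{n_head}{head bead count}
#'     \item{n_tail}{tail bead count per tail}
#'   }
#'
#' @examples
#' lip <- build_lipid(3, 4)
#' length(lip$species)   # 11 beads
#' nrow(lip$bonds)       # 10 bonds
#' @export
build_lipid <- function(n_head = 3, n_tail = 4,
                        k_bond = 100, r_bond = 0.7,
                        k_angle = 6,
                        theta_tail = pi, theta_junction = 2 * pi / 3) {
  if (length(n_head) != 1 || length(n_tail) != 1 ||
      !is.finite(n_head) || !is.finite(n_tail) ||
      n_head < 2 || n_tail < 2 || n_head != round(n_head) ||
      n_tail != round(n_tail)) {
    abort("`n_head` and `n_tail` must be integers >= 2")
  }
  n_head <- as.integer(n_head); n_tail <- as.integer(n_tail)
  n_beads <- n_head + 2L * n_tail
  species <- c(rep("H", n_head), rep("T", 2L * n_tail))

  head_ids  <- seq_len(n_head)
  tail1_ids <- n_head + seq_len(n_tail)
  tail2_ids <- n_head + n_tail + seq_len(n_tail)
  junction  <- n_head                           # last head bead

  consecutive <- function(ids) {
    if (length(ids) < 2) return(NULL)
    cbind(ids[-length(ids)], ids[-1])
  }
  bond_pairs <- rbind(
    consecutive(head_ids),
    cbind(junction, tail1_ids[1]),
    consecutive(tail1_ids),
    cbind(junction, tail2_ids[1]),
    consecutive(tail2_ids)
  )
  bonds <- tibble(
    i = as.integer(bond_pairs[, 1]), j = as.integer(bond_pairs[, 2]),
    k_bond = k_bond, r_bond = r_bond
  )

  triples <- function(ids, theta0) {
    if (length(ids) < 3) return(NULL)
    m <- length(ids) - 2L
    data.frame(i = ids[seq_len(m)], j = ids[seq_len(m) + 1L],
               k = ids[seq_len(m) + 2L], theta0 = theta0)
  }
  ang <- rbind(
    triples(head_ids, theta_junction),                # head-internal bending
    if (n_head >= 2) data.frame(i = junction - 1L, j = junction,
                                k = tail1_ids[1], theta0 = theta_junction),
    if (n_head >= 2) data.frame(i = junction - 1L, j = junction,
                                k = tail2_ids[1], theta0 = theta_junction),
    triples(tail1_ids, theta_tail),
    triples(tail2_ids, theta_tail)
  )
  angles <- tibble(
    i = as.integer(ang$i), j = as.integer(ang$j), k = as.integer(ang$k),
    k_angle = k_angle, theta0 = ang$theta0
  )

  structure(
    list(species = species, bonds = bonds, angles = angles,
         n_head = n_head, n_tail = n_tail, n_beads = n_beads),
    class = "lipid_topology"
  )
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat(sprintf(
    "<lipid_topology> %d beads (%d H + 2 x %d T), %d bonds, %d angles\n",
    x$n_beads, x$n_head, x$n_tail, nrow(x$bonds), nrow(x$angles)))
  invisible(x)
}

#' Lipid concentration of a bead mixture
#'
#' The lipid (volume) fraction is the fraction of all beads that belong to
#' lipid chains: \eqn{\varphi_P = (N_{HB} + 2 N_{TB}) / (N_{HB} + 2 N_{TB} +
#' N_{WB})}, counting one chain's beads against its share of water beads.
#'
#' @param n_head Head beads per chain.
#' @param n_tail Tail beads per tail (two tails per chain).
#' @param n_water Water beads per chain-equivalent.
#' @return The lipid bead fraction in `[0, 1]`.
#' @examples
#' lipid_concentration(3, 4, 11)  # 0.5
#' @export
lipid_concentration <- function(n_head, n_tail, n_water) {
  if (any(c(n_head, n_tail, n_water) < 0)) {
    abort("counts must be non-negative")
  }
  lipid <- n_head + 2 * n_tail
  total <- lipid + n_water
  if (any(total == 0)) abort("at least one bead count must be positive")
  lipid / total
}

#' Compose a solvated lipid system at a target concentration
#'
#' Converts a requested lipid fraction into integer chain and water counts for
#' a periodic cubic box at fixed bead density. The chain count is rounded to
#' nearest and the remaining beads become water, so the realized fraction
#' differs from the request by at most one chain-equivalent.
#'
#' @param phi Requested lipid bead fraction in `[0, 1]`.
#' @param box_edge Cubic box edge length (r_c units).
#' @param density Bead number density (beads per r_c^3); 3 is the standard
#'   DPD value.
#' @param n_head,n_tail Lipid architecture (see [build_lipid()]).
#' @return A one-row tibble of class `system_composition` with columns
#'   `phi`, `phi_realized`, `box_edge`, `density`, `total_beads`, `n_chains`,
#'   `n_water`, `beads_per_chain`.
#' @examples
#' compose_system(0.35, box_edge = 30)
#' @export
compose_system <- function(phi, box_edge, density = 3, n_head = 3, n_tail = 4) {
  if (length(phi) != 1 || !is.finite(phi) || phi < 0 || phi > 1) {
    abort("`phi` must be a single value in [0, 1]")
  }
  if (box_edge <= 0) abort("`box_edge` must be positive")
  beads_per_chain <- n_head + 2L * n_tail
  total <- round(density * box_edge^3)
  n_chains <- round(phi * total / beads_per_chain)
  n_water <- total - n_chains * beads_per_chain
  if (n_water < 0) {  # phi = 1 with non-divisible totals
    n_chains <- floor(total / beads_per_chain)
    n_water <- total - n_chains * beads_per_chain
  }
  out <- tibble(
    phi = phi,
    phi_realized = n_chains * beads_per_chain / total,
    box_edge = box_edge, density = density,
    total_beads = as.integer(total),
    n_chains = as.integer(n_chains),
    n_water = as.integer(n_water),
    beads_per_chain = as.integer(beads_per_chain)
  )
  class(out) <- c("system_composition", class(out))
  out
}
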