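#' DPD pair-interaction weight function
#'
#' The linear soft-core weight \eqn{w(r) = 1 - r/r_c} for \eqn{r < r_c} and 0
#' beyond the cutoff. The conservative force is \eqn{a_{ij} w(r)}, the
#' dissipative force uses \eqn{w^2(r)} and the random force \eqn{w(r)}, which
#' together satisfy the fluctuation--dissipation constraint.
#'
#' @param r Pair separation(s), non-negative (r_c units).
#' @param r_c Cutoff radius.
#' @return The weight: \eqn{1 - r/r_c} below the cutoff, 0 at and beyond it.
#' @examples
#' weight_function(c(0, 0.3, 1, 2))
#' @export
weight_function <- function(r, r_c = 1) {
  if (any(r < 0)) abort("`r` must be non-negative")
  ifelse(r < r_c, 1 - r / r_c, 0)
}

default_repulsion_matrix <- function(a_like = 50, a_unlike = 200) {
  a <- matrix(a_like, 3, 3, dimnames = list(SPECIES_LEVELS, SPECIES_LEVELS))
  # hydrophobic tails repel both water and heads; all other pairs are alike
  a["H", "T"] <- a["T", "H"] <- a_unlike
  a["W", "T"] <- a["T", "W"] <- a_unlike
  a
}

#' DPD force field (interaction table)
#'
#' Collects the pairwise interaction parameters: the species-by-species
#' maximum-repulsion matrix `a`, the friction coefficient `gamma`, the noise
#' amplitude `sigma`, the cutoff `r_c` and the thermostat temperature `kBT`.
#' The dissipative and random forces form the DPD thermostat and must obey the
#' fluctuation--dissipation relation \eqn{\sigma^2 = 2 \gamma k_B T};
#' `gamma` defaults to `sigma^2 / (2 * kBT)` so the relation holds by
#' construction, and any explicit override that violates it is rejected.
#'
#' The default repulsion matrix encodes hydrophobicity: incompatible pairs
#' (head--tail and water--tail) repel with `a_unlike`, all other pairs with
#' `a_like`.
#'
#' @param a Optional full 3x3 repulsion matrix with dimnames
#'   `c("H","T","W")`; overrides `a_like`/`a_unlike`.
#' @param a_like Repulsion between compatible species (H--H, T--T, W--W,
#'   H--W).
#' @param a_unlike Repulsion between incompatible species (H--T, W--T).
#' @param sigma Random-force amplitude.
#' @param kBT Thermostat temperature (reduced; 1 by convention).
#' @param gamma Friction coefficient; default enforces
#'   \eqn{\sigma^2 = 2\gamma k_B T}.
#' @param r_c Cutoff radius (the length unit).
#' @return An object of class `dpd_forcefield`.
#' @examples
#' ff <- dpd_forcefield()
#' ff$a
#' @export
dpd_forcefield <- function(a = NULL, a_like = 50, a_unlike = 200,
                           sigma = 3, kBT = 1,
                           gamma = sigma^2 / (2 * kBT), r_c = 1) {
  if (is.null(a)) {
    a <- default_repulsion_matrix(a_like, a_unlike)
  } else {
    if (!is.matrix(a) || any(dim(a) != 3)) abort("`a` must be a 3x3 matrix")
    if (is.null(dimnames(a))) dimnames(a) <- list(SPECIES_LEVELS, SPECIES_LEVELS)
    a <- a[SPECIES_LEVELS, SPECIES_LEVELS]
  }
  if (any(a < 0) || !isTRUE(all.equal(a, t(a)))) {
    abort("repulsion matrix `a` must be symmetric and non-negative")
  }
  if (r_c <= 0) abort("`r_c` must be positive")
  if (sigma < 0 || gamma < 0 || kBT < 0) {
    abort("`sigma`, `gamma` and `kBT` must be non-negative")
  }
  if (abs(sigma^2 - 2 * gamma * kBT) > 1e-10 * max(1, sigma^2)) {
    abort("fluctuation-dissipation violated: need sigma^2 = 2 * gamma * kBT")
  }
  structure(
    list(a = a, gamma = gamma, sigma = sigma, kBT = kBT, r_c = r_c),
    class = "dpd_forcefield"
  )
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat(sprintf(
    "<dpd_forcefield> sigma = %g, gamma = %g, kBT = %g, r_c = %g\n",
    x$sigma, x$gamma, x$kBT, x$r_c))
  print(x$a)
  invisible(x)
}
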