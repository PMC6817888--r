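#' Assign beads to z-slabs
#'
#' Bead with z in `[k L_z / n_slabs, (k+1) L_z / n_slabs)` gets slab index
#' `k` (0-based).
#'
#' @param system A `dpd_system` (positions wrapped).
#' @param n_slabs Number of slabs.
#' @return Integer slab index per bead.
#' @export
assign_slabs <- function(system, n_slabs = 20) {
  k <- floor(system$beads$z / system$box[3] * n_slabs)
  as.integer(pmin(pmax(k, 0), n_slabs - 1))
}

#' Execute one momentum swap
#'
#' The Mueller-Plathe flip: the bead with the most negative v_x in the slab
#' at z = 0 and the bead with the most positive v_x in the slab at
#' z = L_z/2 exchange their x-velocity components. With equal masses the
#' exchange conserves total momentum and kinetic energy exactly; positions
#' are untouched. The exchanged momentum `dpx = m (v_x^{upper} -
#' v_x^{lower})` accumulates into the imposed momentum flux.
#'
#' @param system A `dpd_system`.
#' @param protocol A [shear_protocol()].
#' @return List with the updated `system` and a one-row `swap` tibble
#'   (`i_lower`, `i_upper`, `dpx`); `dpx = 0` with `swap = NULL` if a
#'   designated slab is empty (a warning is raised).
#' @export
momentum_swap <- function(system, protocol) {
  slabs <- assign_slabs(system, protocol$n_slabs)
  lower <- which(slabs == 0L)
  upper <- which(slabs == protocol$n_slabs %/% 2L)
  if (length(lower) == 0 || length(upper) == 0) {
    warn("momentum swap skipped: empty designated slab")
    return(list(system = system, swap = NULL, dpx = 0))
  }
  vx <- system$beads$vx
  ilo <- lower[which.min(vx[lower])]
  iup <- upper[which.max(vx[upper])]
  dpx <- vx[iup] - vx[ilo]
  tmp <- vx[ilo]; vx[ilo] <- vx[iup]; vx[iup] <- tmp
  system$beads$vx <- vx
  list(system = system,
       swap = tibble(i_lower = ilo, i_upper = iup, dpx = dpx),
       dpx = dpx)
}

#' Imposed momentum flux
#'
#' The x-momentum flux through z-planes from the swap bookkeeping:
#' \eqn{j_z(p_x) = p_x / (2 t L_x L_y)}; the factor 2 accounts for the two
#' equivalent flux planes of the periodic box.
#'
#' @param px Total exchanged x-momentum.
#' @param t Elapsed time over which it was exchanged (tau units).
#' @param Lx,Ly Box cross-section edges.
#' @return The momentum flux.
#' @examples
#' momentum_flux(10, 1, 30, 30)
#' @export
momentum_flux <- function(px, t, Lx, Ly) {
  if (any(t <= 0)) abort("`t` must be positive")
  if (any(c(Lx, Ly) <= 0)) abort("box areas must be positive")
  px / (2 * t * Lx * Ly)
}

#' Aggregate a velocity profile over a trajectory window
#'
#' Averages the per-slab x-velocities recorded during a run over a fraction
#' of the trajectory (the late, steady part by default), weighting each
#' sample interval by its bead count.
#'
#' @param trajectory A `dpd_trajectory` run with slab profiling.
#' @param window Fraction of the run (from the end) to average over.
#' @return A tibble of class `dpd_profile`: `slab`, `z`, `vx`, `n`.
#' @export
velocity_profile <- function(trajectory, window = 0.5) {
  pr <- trajectory$profile
  if (nrow(pr) == 0) abort("trajectory carries no slab profile")
  smin <- max(pr$step) - window * (max(pr$step) - min(pr$step))
  pr <- dplyr::filter(pr, .data$step >= smin, .data$n > 0)
  out <- dplyr::summarise(
    dplyr::group_by(pr, .data$slab, .data$z),
    vx = sum(.data$vx * .data$n) / sum(.data$n),
    n = sum(.data$n), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$slab)
  class(out) <- c("dpd_profile", class(out))
  attr(out, "box") <- trajectory$system$box
  out
}

#' Measure the shear rate from a sawtooth velocity profile
#'
#' The steady Mueller-Plathe profile is piecewise linear between the two
#' swap slabs (at z = 0 and z = L_z/2). Each monotone branch is fitted by
#' least squares, excluding the two perturbed swap slabs; the shear rate is
#' the mean absolute slope \eqn{\dot\gamma = |\partial v_x / \partial z|}.
#'
#' @param profile A `dpd_profile` from [velocity_profile()], or any tibble
#'   with columns `slab`, `z`, `vx`.
#' @param n_slabs Number of slabs; defaults to the rows of `profile`.
#' @return An object of class `shear_fit`; see [tidy.shear_fit()] and
#'   [glance.shear_fit()].
#' @export
measure_shear_rate <- function(profile, n_slabs = nrow(profile)) {
  if (nrow(profile) < 6) abort("need at least 3 slabs per branch")
  if (sd(profile$z) == 0) abort("degenerate profile: no variation in z")
  half <- n_slabs %/% 2L
  branch1 <- dplyr::filter(profile, .data$slab > 0, .data$slab < half)
  branch2 <- dplyr::filter(profile, .data$slab > half)
  fit_branch <- function(d, name) {
    m <- lm(vx ~ z, data = d)
    res <- m$residuals
    ss_tot <- sum((d$vx - mean(d$vx))^2)
    r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1
    tibble(branch = name, slope = coef(m)[["z"]], r_squared = r2,
           n_slabs = nrow(d),
           residual_sd = sqrt(mean(res^2)))
  }
  fits <- dplyr::bind_rows(fit_branch(branch1, "descending"),
                           fit_branch(branch2, "ascending"))
  structure(list(branches = fits,
                 rate = mean(abs(fits$slope)),
                 r_squared = min(fits$r_squared)),
            class = "shear_fit")
}

#' @export
print.shear_fit <- function(x, ...) {
  cat(sprintf("<shear_fit> shear rate %.4g / tau (min branch R^2 = %.4f)\n",
              x$rate, x$r_squared))
  invisible(x)
}

#' Tidiers for shear-rate fits
#'
#' `tidy()` returns one row per fitted branch of the sawtooth profile;
#' `glance()` returns a one-row summary with the shear rate (mean absolute
#' branch slope) and the smaller branch R^2.
#'
#' @param x A `shear_fit` from [measure_shear_rate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy shear_fit
#' @export
tidy.shear_fit <- function(x, ...) x$branches

#' @rdname tidy.shear_fit
#' @method glance shear_fit
#' @export
glance.shear_fit <- function(x, ...) {
  tibble(shear_rate = x$rate, r_squared = x$r_squared,
         slope_descending = x$branches$slope[1],
         slope_ascending = x$branches$slope[2])
}
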