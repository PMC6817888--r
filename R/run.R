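#' Reverse non-equilibrium shear protocol
#'
#' Describes the Mueller-Plathe momentum-swap shear: every `swap_every`
#' integration steps, the bead with the most negative x-velocity in the slab
#' at z = 0 exchanges its x-velocity with the bead with the most positive
#' x-velocity in the slab at z = L_z/2. The swap conserves total momentum and
#' kinetic energy exactly while imposing a known x-momentum flux through the
#' z-planes; the fluid responds with a sawtooth velocity profile whose slope
#' is the shear rate. Smaller `swap_every` means stronger shear.
#'
#' @param swap_every Steps between swaps (W); 5, 2, 1 map to increasing shear
#'   rates.
#' @param n_slabs Number of equal z-slabs used for the swap end-points and
#'   the velocity profile; must be even and at least 2.
#' @return An object of class `shear_protocol`.
#' @export
shear_protocol <- function(swap_every, n_slabs = 20) {
  if (swap_every < 1 || swap_every != round(swap_every)) {
    abort("`swap_every` must be a positive integer")
  }
  if (n_slabs < 2 || n_slabs %% 2 != 0) {
    abort("`n_slabs` must be even and at least 2")
  }
  structure(list(swap_every = as.integer(swap_every),
                 n_slabs = as.integer(n_slabs)),
            class = "shear_protocol")
}

#' Run a DPD simulation
#'
#' Advances the system `n_steps` time steps of size `dt` with the modified
#' (Groot--Warren) velocity Verlet scheme under NVT conditions: positions
#' drift with the current forces, the dissipative force is evaluated at
#' lambda-predicted velocities, and velocities are corrected with the mean of
#' old and new forces. Forces are evaluated once per step. With a
#' `shear_protocol`, momentum swaps are executed before integration at steps
#' divisible by `swap_every`.
#'
#' The run is fully reproducible: the pairwise noise is a counter-based
#' Gaussian stream keyed on (`seed`, step, pair), so the same `(system,
#' seed)` gives bit-identical trajectories, including across restarts.
#'
#' @param system A `dpd_system` (velocities already initialized).
#' @param forcefield A [dpd_forcefield()].
#' @param n_steps Number of steps.
#' @param dt Time step (tau units; 0.01 is the standard choice).
#' @param seed Integer seed for the random-force stream.
#' @param lambda Velocity-prediction factor of the modified Verlet scheme
#'   (0.65 is the canonical value).
#' @param sample_every Observable cadence (steps).
#' @param frame_every Trajectory-frame cadence (steps); 0 stores no frames.
#' @param shear Optional [shear_protocol()].
#' @param n_slabs Slab count for velocity profiling when no shear is active.
#' @return A `dpd_trajectory`: list with the final `system`, `observables`
#'   (tibble: step, time, temperature, per-bead energy breakdown, total
#'   momentum, accumulated swapped momentum), `profile` (tibble of per-slab
#'   time-averaged x-velocities per sample interval), `swaps` (tibble swap
#'   log), `frames` (list of bead tibbles) and run metadata.
#' @examples
#' sys <- init_velocities(water_box(4, seed = 1), seed = 2)
#' tr <- dpd_run(sys, dpd_forcefield(), n_steps = 50, seed = 3)
#' tr$observables
#' @export
dpd_run <- function(system, forcefield = dpd_forcefield(), n_steps,
                    dt = 0.01, seed = 1, lambda = 0.65,
                    sample_every = 100, frame_every = 0,
                    shear = NULL, n_slabs = if (is.null(shear)) 20L else shear$n_slabs) {
  if (n_steps < 0) abort("`n_steps` must be non-negative")
  validate_dpd_system(system)
  b <- system$beads
  swap_every <- if (is.null(shear)) 0L else shear$swap_every

  if (n_steps == 0) {
    return(structure(list(
      system = system,
      observables = tibble(step = integer(), time = double(),
                           temperature = double(), e_kinetic = double(),
                           e_pair = double(), e_bond = double(),
                           e_angle = double(), e_total = double(),
                           px = double(), py = double(), pz = double(),
                           swap_px = double()),
      profile = tibble(step = integer(), slab = integer(), z = double(),
                       vx = double(), n = double()),
      swaps = tibble(), frames = list(),
      params = list(dt = dt, lambda = lambda, seed = seed,
                    swap_every = swap_every, n_slabs = n_slabs,
                    forcefield = forcefield)),
      class = "dpd_trajectory"))
  }

  res <- .dpd_run_cpp(
    b$x, b$y, b$z, b$vx, b$vy, b$vz,
    species_codes(b$species), system$box,
    forcefield$a, forcefield$gamma, forcefield$sigma, forcefield$r_c,
    system$bonds$i - 1L, system$bonds$j - 1L,
    system$bonds$k_bond, system$bonds$r_bond,
    system$angles$i - 1L, system$angles$j - 1L, system$angles$k - 1L,
    system$angles$k_angle, system$angles$theta0,
    as.integer(n_steps), dt, lambda,
    as.integer(sample_every), as.integer(frame_every),
    as.integer(swap_every), as.integer(n_slabs),
    as.numeric(seed), system$step,
    attr(system, "forces")$fx %||% numeric(),
    attr(system, "forces")$fy %||% numeric(),
    attr(system, "forces")$fz %||% numeric()
  )
  if (res$skipped_swaps > 0) {
    warn(sprintf("%d momentum swap(s) skipped: empty designated slab",
                 res$skipped_swaps))
  }
  if (res$n_overlap > 0) {
    warn(sprintf("%d zero-separation pair(s): random direction substituted",
                 res$n_overlap))
  }

  n <- nrow(b)
  out_sys <- system
  out_sys$beads$x <- res$x; out_sys$beads$y <- res$y; out_sys$beads$z <- res$z
  out_sys$beads$vx <- res$vx; out_sys$beads$vy <- res$vy; out_sys$beads$vz <- res$vz
  out_sys$step <- as.integer(res$step_end)
  out_sys$time <- res$step_end * dt
  # entering forces for an exact continuation (see write_checkpoint)
  attr(out_sys, "forces") <- list(fx = res$fx, fy = res$fy, fz = res$fz)

  obs <- as_tibble(as.data.frame(res$obs))
  obs <- dplyr::mutate(
    obs,
    temperature = 2 * .data$e_kinetic / (3 * n - 3),
    dplyr::across(c("e_kinetic", "e_pair", "e_bond", "e_angle"), ~ .x / n),
    e_total = .data$e_kinetic + .data$e_pair + .data$e_bond + .data$e_angle,
    step = as.integer(.data$step)
  )
  obs <- dplyr::select(obs, "step", "time", "temperature", "e_kinetic",
                       "e_pair", "e_bond", "e_angle", "e_total",
                       "px", "py", "pz", "swap_px")

  profile <- tibble(step = integer(), slab = integer(), z = double(),
                    vx = double(), n = double())
  if (n_slabs > 0 && nrow(res$profile_v) > 0) {
    zc <- (seq_len(n_slabs) - 0.5) * system$box[3] / n_slabs
    profile <- tibble(
      step = rep(as.integer(res$obs[, "step"]), each = n_slabs),
      slab = rep(seq_len(n_slabs) - 1L, nrow(res$profile_v)),
      z = rep(zc, nrow(res$profile_v)),
      vx = as.vector(t(res$profile_v)),
      n = as.vector(t(res$profile_n))
    )
  }

  swaps <- as_tibble(as.data.frame(res$swaps))
  frames <- purrr::map2(res$frames, res$frame_steps, function(m, s) {
    tibble(id = b$id, species = b$species, chain = b$chain,
           x = m[, 1], y = m[, 2], z = m[, 3],
           vx = m[, 4], vy = m[, 5], vz = m[, 6], step = s)
  })

  structure(list(
    system = out_sys, observables = obs, profile = profile, swaps = swaps,
    frames = frames,
    params = list(dt = dt, lambda = lambda, seed = seed,
                  swap_every = swap_every, n_slabs = n_slabs,
                  forcefield = forcefield)),
    class = "dpd_trajectory")
}

#' Advance the system by one time step
#'
#' Convenience wrapper over [dpd_run()] for a single `dt` advance (with the
#' momentum swap first when `shear` is active and the step index is
#' divisible by its `swap_every`).
#'
#' @inheritParams dpd_run
#' @return The advanced `dpd_system`.
#' @export
dpd_step <- function(system, forcefield = dpd_forcefield(), dt = 0.01,
                     seed = 1, lambda = 0.65, shear = NULL) {
  dpd_run(system, forcefield, n_steps = 1, dt = dt, seed = seed,
          lambda = lambda, sample_every = 1, shear = shear)$system
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf(
    "<dpd_trajectory> %d beads, %d observable samples, %d frames, %d swaps\n",
    nrow(x$system$beads), nrow(x$observables), length(x$frames),
    nrow(x$swaps)))
  invisible(x)
}

#' Write / read a checkpoint
#'
#' Serializes the full state needed to continue a run: positions, velocities,
#' topology, box, step counter. Continuation is exact because the noise
#' stream is keyed on the absolute step index.
#'
#' @param system A `dpd_system`.
#' @param path File path.
#' @return `write_checkpoint` the path invisibly; `read_checkpoint` the
#'   restored `dpd_system`.
#' @export
write_checkpoint <- function(system, path) {
  validate_dpd_system(system)
  saveRDS(system, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  sys <- readRDS(path)
  if (!inherits(sys, "dpd_system")) abort("not a dpd_system checkpoint")
  validate_dpd_system(sys)
}
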