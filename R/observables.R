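# analytic eigenvalues of symmetric 3x3 tensors, vectorized over chains
sym3_eigenvalues <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-14 * pmax(abs(q), 1)
  bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
  bxy <- xy / p; bxz <- xz / p; byz <- yz / p
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!ok] <- q[!ok]; e2[!ok] <- q[!ok]; e3[!ok] <- q[!ok]
  # ascending: e3 <= e2 <= e1
  cbind(l1 = e3, l2 = e2, l3 = e1)
}

unwrap_chain_array <- function(arr, local_bonds, box) {
  # arr: (n_chains, n_beads, 3) wrapped; walk the bond list (parent always
  # placed first) putting each bonded neighbour at its minimum image
  for (b in seq_len(nrow(local_bonds))) {
    i <- local_bonds$i[b]; j <- local_bonds$j[b]
    for (ax in 1:3) {
      d <- arr[, j, ax] - arr[, i, ax]
      d <- d - box[ax] * round(d / box[ax])
      arr[, j, ax] <- arr[, i, ax] + d
    }
  }
  arr
}

#' Per-chain gyration tensor, radius of gyration and shape factor
#'
#' For each lipid chain, computes the gyration tensor
#' \eqn{R^2_{g\alpha\beta} = \frac{1}{n}\sum_i (r_{i\alpha} -
#' r_{c\alpha})(r_{i\beta} - r_{c\beta})} about the chain mass centre
#' \eqn{r_c}, after unwrapping the chain across periodic images along its
#' bond graph (the tensor is meaningless on wrapped coordinates). The
#' eigenvalues \eqn{L_1^2 \le L_2^2 \le L_3^2} give the scalar radius of
#' gyration \eqn{R_g = \sqrt{\mathrm{tr}\, R_g^2}} and the shape factor
#' (relative asphericity) via [shape_factor()].
#'
#' @param x A `dpd_system`, or a frame tibble from a `dpd_trajectory`.
#' @param box Box edges (taken from the system when `x` is a `dpd_system`).
#' @param bonds Global bond table (ditto).
#' @param ... Unused.
#' @return Tibble with one row per chain: tensor components `rgxx` ...
#'   `rgyz` (squared, r_c^2 units), eigenvalues `l1sq`, `l2sq`, `l3sq`,
#'   scalar `rg`, and `delta`.
#' @examples
#' sys <- random_solution(0.5, box_edge = 5, seed = 1)
#' gyration_tensor(sys)
#' @export
gyration_tensor <- function(x, box = NULL, bonds = NULL, ...) {
  if (inherits(x, "dpd_system")) {
    box <- x$box; bonds <- x$bonds; beads <- x$beads
  } else {
    beads <- x
    if (is.null(box) || is.null(bonds)) {
      abort("supply `box` and `bonds` when `x` is a bare frame")
    }
  }
  lip <- beads[!is.na(beads$chain), , drop = FALSE]
  if (nrow(lip) == 0) abort("system contains no chains")
  nc <- length(unique(lip$chain))
  nb <- nrow(lip) / nc
  if (nb != round(nb)) abort("chains of unequal length are not supported")
  nb <- as.integer(nb)
  ord <- order(lip$chain, lip$id)
  lip <- lip[ord, ]
  arr <- array(0, dim = c(nc, nb, 3))
  pos <- as.matrix(lip[, c("x", "y", "z")])
  for (ax in 1:3) arr[, , ax] <- matrix(pos[, ax], nc, nb, byrow = TRUE)
  first_ids <- lip$id[seq_len(nb)]
  local_bonds <- dplyr::filter(bonds, .data$i %in% first_ids,
                               .data$j %in% first_ids)
  local_bonds <- dplyr::mutate(local_bonds,
                               i = match(.data$i, first_ids),
                               j = match(.data$j, first_ids))
  if (nb > 1) arr <- unwrap_chain_array(arr, local_bonds, box)
  cm <- apply(arr, c(1, 3), mean)
  dev <- sweep(arr, c(1, 3), cm)
  comp <- function(a, b) {
    rowMeans(matrix(dev[, , a], nrow = nc) * matrix(dev[, , b], nrow = nc))
  }
  if (nb == 1) comp <- function(a, b) rep(0, nc)
  xx <- comp(1, 1); yy <- comp(2, 2); zz <- comp(3, 3)
  xy <- comp(1, 2); xz <- comp(1, 3); yz <- comp(2, 3)
  ev <- sym3_eigenvalues(xx, yy, zz, xy, xz, yz)
  ev <- pmax(ev, 0)  # the tensor is PSD; negatives are eigen-solver roundoff
  tot <- xx + yy + zz
  delta <- rep(NA_real_, nc)
  pos_tot <- tot > 0
  if (any(pos_tot)) {
    delta[pos_tot] <- shape_factor(ev[pos_tot, 1], ev[pos_tot, 2],
                                   ev[pos_tot, 3])
  }
  tibble(
    chain = sort(unique(lip$chain)),
    rgxx = xx, rgyy = yy, rgzz = zz, rgxy = xy, rgxz = xz, rgyz = yz,
    l1sq = as.numeric(ev[, 1]), l2sq = as.numeric(ev[, 2]),
    l3sq = as.numeric(ev[, 3]),
    rg = sqrt(tot), delta = delta
  )
}

#' Shape factor (relative asphericity) from gyration eigenvalues
#'
#' \eqn{\delta = 1 - 3 (L_1^2 L_2^2 + L_2^2 L_3^2 + L_1^2 L_3^2) /
#' (L_1^2 + L_2^2 + L_3^2)^2}. A sphere (all eigenvalues equal) gives 0, an
#' ideal rod (one non-zero eigenvalue) gives 1; an ideal planar disc (two
#' equal, one zero) evaluates to 0.25.
#'
#' @param l1sq,l2sq,l3sq Non-negative eigenvalues of the squared gyration
#'   tensor (any order); vectorized.
#' @return `delta` in `[0, 1]`.
#' @examples
#' shape_factor(1, 1, 1)  # sphere: 0
#' shape_factor(0, 0, 2)  # rod: 1
#' @export
shape_factor <- function(l1sq, l2sq, l3sq) {
  if (any(c(l1sq, l2sq, l3sq) < 0)) abort("eigenvalues must be non-negative")
  s <- l1sq + l2sq + l3sq
  if (any(s == 0)) abort("all-zero eigenvalues: shape undefined for a point")
  1 - 3 * (l1sq * l2sq + l2sq * l3sq + l1sq * l3sq) / s^2
}

#' Mean radius of gyration over a trajectory
#'
#' Per frame, the chain-average of the scalar \eqn{R_g} and of the square
#' roots of the diagonal tensor components, plus the ensemble-mean shape
#' factor. The stationary level is the least-squares constant fitted over
#' the trailing `window` fraction of the series.
#'
#' @param trajectory A `dpd_trajectory` run with `frame_every > 0`.
#' @param window Trailing fraction of the series used for the level fit.
#' @return Tibble (`step`, `time`, `rg`, `rgxx`, `rgyy`, `rgzz`, `delta`)
#'   with attribute `"level"`: the fitted levels of the same quantities.
#' @export
mean_radius_of_gyration <- function(trajectory, window = 0.5) {
  if (length(trajectory$frames) == 0) {
    abort("trajectory has no stored frames; rerun with `frame_every > 0`")
  }
  box <- trajectory$system$box
  bonds <- trajectory$system$bonds
  dt <- trajectory$params$dt
  rows <- purrr::map_dfr(trajectory$frames, function(fr) {
    g <- gyration_tensor(fr, box = box, bonds = bonds)
    tibble(step = fr$step[1],
           rg = mean(g$rg),
           rgxx = mean(sqrt(g$rgxx)), rgyy = mean(sqrt(g$rgyy)),
           rgzz = mean(sqrt(g$rgzz)),
           delta = mean(g$delta, na.rm = TRUE))
  })
  rows <- dplyr::mutate(rows, time = .data$step * dt, .after = "step")
  smin <- max(rows$step) - window * (max(rows$step) - min(rows$step))
  late <- dplyr::filter(rows, .data$step >= smin)
  attr(rows, "level") <- c(
    rg = mean(late$rg), rgxx = mean(late$rgxx), rgyy = mean(late$rgyy),
    rgzz = mean(late$rgzz), delta = mean(late$delta)
  )
  rows
}

#' Mean flow velocity under shear
#'
#' The two halves of the sheared box stream in opposite x-directions, so a
#' raw mean of v_x vanishes. The flow speed is therefore sign-folded: slab
#' velocities are taken with `+` in the outer quarter-boxes around the z = 0
#' swap slab and `-` in the inner half around z = L_z/2, then averaged with
#' slab occupancies as weights. The saturation level is the mean over the
#' trailing `window` fraction of the series.
#'
#' @param trajectory A `dpd_trajectory` with slab profiling.
#' @param window Trailing fraction used for the saturation estimate.
#' @return Tibble (`step`, `time`, `v_flow`) with attribute `"saturation"`.
#' @export
mean_flow_velocity <- function(trajectory, window = 1 / 3) {
  pr <- trajectory$profile
  if (nrow(pr) == 0) abort("trajectory carries no slab profile")
  Lz <- trajectory$system$box[3]
  dt <- trajectory$params$dt
  pr <- dplyr::filter(pr, .data$n > 0)
  pr <- dplyr::mutate(
    pr, fold = ifelse(.data$z < Lz / 4 | .data$z >= 3 * Lz / 4, 1, -1))
  out <- dplyr::summarise(
    dplyr::group_by(pr, .data$step),
    v_flow = sum(.data$fold * .data$vx * .data$n) / sum(.data$n),
    .groups = "drop"
  )
  out <- dplyr::mutate(out, time = .data$step * dt, .after = "step")
  smin <- max(out$step) - window * (max(out$step) - min(out$step))
  attr(out, "saturation") <-
    mean(dplyr::filter(out, .data$step >= smin)$v_flow)
  out
}

#' Energy trace with plateau detection
#'
#' Returns the per-bead energy breakdown recorded during a run and locates
#' the stable stage: the earliest sample from which the sliding-window
#' least-squares slope of the total energy stays below `slope_tol`.
#'
#' @param trajectory A `dpd_trajectory` (or its observables tibble).
#' @param slope_tol Plateau threshold on |dE/dt| (energy per bead per tau).
#' @param window Sliding-window width (tau units).
#' @return The observables tibble with attributes `"plateau_onset"` (time),
#'   `"plateau_level"` (mean total energy per bead over the plateau), or
#'   `NA` if no plateau is found.
#' @export
energy_trace <- function(trajectory, slope_tol = 1e-4, window = 200) {
  obs <- if (inherits(trajectory, "dpd_trajectory")) {
    trajectory$observables
  } else {
    trajectory
  }
  pl <- detect_plateau(obs$time, obs$e_total, slope_tol = slope_tol,
                       window = window)
  attr(obs, "plateau_onset") <- pl$onset
  attr(obs, "plateau_level") <- pl$level
  obs
}

#' Locate a plateau in a time series
#'
#' Slides a window of width `window` along the series; at each start point
#' the least-squares slope over the window is computed, and the onset is the
#' earliest time from which every subsequent window slope stays below
#' `slope_tol` in magnitude. The level is the series mean from the onset on.
#'
#' @param time,value Numeric series (equal length, `time` increasing).
#' @param slope_tol Slope threshold.
#' @param window Window width in the units of `time`.
#' @return List with `onset`, `level`, `slopes` (per-start-point window
#'   slopes); `onset` is `NA` when no window qualifies.
#' @export
detect_plateau <- function(time, value, slope_tol = 1e-4, window = 200) {
  if (length(time) < 3) abort("series shorter than the detection window")
  if (max(time) - min(time) < window) {
    abort("series shorter than the detection window")
  }
  starts <- which(time <= max(time) - window)
  slopes <- vapply(starts, function(s) {
    sel <- time >= time[s] & time <= time[s] + window
    tt <- time[sel]; vv <- value[sel]
    if (length(tt) < 2 || sd(tt) == 0) return(NA_real_)
    stats::cov(tt, vv) / stats::var(tt)
  }, numeric(1))
  flat <- abs(slopes) < slope_tol
  flat[is.na(flat)] <- FALSE
  onset_idx <- NA_integer_
  if (any(flat)) {
    # earliest start from which all later windows remain flat
    ok_from <- rev(cumprod(rev(flat))) == 1
    if (any(ok_from)) onset_idx <- starts[which(ok_from)[1]]
  }
  if (is.na(onset_idx)) {
    list(onset = NA_real_, level = NA_real_, slopes = slopes)
  } else {
    onset <- time[onset_idx]
    list(onset = onset, level = mean(value[time >= onset]), slopes = slopes)
  }
}

#' Cluster hydrophobic aggregates
#'
#' Labels the connected components of the tail-bead contact graph: two T
#' beads are in contact when their minimum-image distance is below `cutoff`.
#' Component counts track how many separate aggregates (vesicles, lamella
#' fragments, cylinders) the system holds.
#'
#' @param system A `dpd_system`.
#' @param cutoff Contact distance (r_c units).
#' @param species Bead species to cluster (default `"T"`).
#' @return Tibble (`id`, `cluster`) for the selected beads, with attribute
#'   `"n_clusters"`.
#' @export
cluster_aggregates <- function(system, cutoff = 1, species = "T") {
  b <- system$beads[system$beads$species %in% species, , drop = FALSE]
  if (nrow(b) == 0) {
    out <- tibble(id = integer(), cluster = integer())
    attr(out, "n_clusters") <- 0L
    return(out)
  }
  labels <- .cluster_cpp(b$x, b$y, b$z, system$box, cutoff)
  out <- tibble(id = b$id, cluster = as.integer(labels))
  attr(out, "n_clusters") <- length(unique(labels))
  out
}
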