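test_that("slab assignment covers the box edges and is uniform for uniform beads", {
  sys <- bead_system(rbind(c(1, 1, 0), c(1, 1, 10 - 1e-9), c(1, 1, 5)),
                     box_edge = 10)
  expect_equal(assign_slabs(sys, 20), c(0L, 19L, 10L))

  unif <- water_box(10, seed = 1)
  counts <- table(assign_slabs(unif, 10))
  expect_length(counts, 10)
  expect_lt(max(abs(counts - 300)), 5 * sqrt(300))
})

test_that("a momentum swap exchanges the extreme x-velocities and conserves exactly", {
  pos <- rbind(c(5, 5, 0.1),   # lower swap slab
               c(5, 5, 0.2),
               c(5, 5, 5.1),   # upper swap slab (z = Lz/2)
               c(5, 5, 7.7))
  vel <- rbind(c(-1, 0.2, 0), c(-0.5, 0, 0), c(2, -0.1, 0), c(0.3, 0, 0))
  sys <- bead_system(pos, vel = vel)
  before_px <- sum(sys$beads$vx)
  before_ke <- sum(sys$beads$vx^2 + sys$beads$vy^2 + sys$beads$vz^2) / 2
  out <- momentum_swap(sys, shear_protocol(swap_every = 5, n_slabs = 20))
  expect_equal(out$dpx, 3)                       # m (v_up - v_lo) = 2 - (-1)
  expect_equal(out$system$beads$vx[1], 2)
  expect_equal(out$system$beads$vx[3], -1)
  expect_identical(out$system$beads$x, sys$beads$x)  # positions untouched
  after_px <- sum(out$system$beads$vx)
  after_ke <- sum(out$system$beads$vx^2 + out$system$beads$vy^2 +
                    out$system$beads$vz^2) / 2
  expect_identical(after_px, before_px)
  expect_identical(after_ke, before_ke)
})

test_that("swapping equal velocities changes nothing and empty slabs are skipped", {
  pos <- rbind(c(5, 5, 0.1), c(5, 5, 5.1))
  vel <- rbind(c(0.7, 0, 0), c(0.7, 0, 0))
  sys <- bead_system(pos, vel = vel)
  out <- momentum_swap(sys, shear_protocol(5, 20))
  expect_equal(out$dpx, 0)
  expect_equal(out$system$beads$vx, sys$beads$vx)

  lone <- bead_system(matrix(c(5, 5, 3), 1, 3))
  expect_warning(out2 <- momentum_swap(lone, shear_protocol(5, 20)),
                 "empty designated slab")
  expect_equal(out2$dpx, 0)
})

test_that("momentum flux follows the two-plane bookkeeping formula", {
  expect_equal(momentum_flux(0, 1, 30, 30), 0)
  expect_equal(momentum_flux(10, 1, 30, 30), 10 / 1800)
  expect_equal(momentum_flux(10, 2, 30, 30), momentum_flux(10, 1, 30, 30) / 2)
  expect_error(momentum_flux(1, 0, 30, 30), "positive")
})

test_that("shear-rate fitting recovers constructed profiles", {
  # linear profile v = 0.02 z on both branches of a 20-slab sawtooth
  L <- 10
  zc <- (1:20 - 0.5) * L / 20
  saw <- function(z, slope) {
    v <- ifelse(z < L / 2, slope * (L / 4 - z), slope * (z - 3 * L / 4))
    v
  }
  prof <- tibble::tibble(slab = 0:19, z = zc, vx = saw(zc, 0.02), n = 100)
  fit <- measure_shear_rate(prof)
  expect_equal(fit$rate, 0.02, tolerance = 1e-12)
  expect_gte(fit$r_squared, 0.999)

  prof2 <- tibble::tibble(slab = 0:19, z = zc, vx = saw(zc, 0.04), n = 100)
  expect_equal(measure_shear_rate(prof2)$rate, 0.04, tolerance = 1e-12)

  flat <- tibble::tibble(slab = 0:19, z = rep(1, 20), vx = rnorm(20), n = 100)
  expect_error(measure_shear_rate(flat), "degenerate")
  expect_error(measure_shear_rate(prof[1:4, ]), "at least 3 slabs")

  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  expect_lt(td$slope[td$branch == "descending"], 0)
  gl <- glance(fit)
  expect_named(gl, c("shear_rate", "r_squared", "slope_descending",
                     "slope_ascending"))
})

test_that("a sheared run keeps exact swap conservation and consistent bookkeeping", {
  sys <- init_velocities(water_box(5, seed = 1), seed = 2)
  tr <- dpd_run(sys, dpd_forcefield(), n_steps = 600, seed = 3,
                sample_every = 100, shear = shear_protocol(swap_every = 5,
                                                           n_slabs = 20))
  sw <- tr$swaps
  expect_gt(nrow(sw), 100)
  expect_equal(max(abs(sw$ke_pair_after - sw$ke_pair_before)), 0)
  expect_equal(max(abs(sw$px_pair_after - sw$px_pair_before)), 0)
  # system-wide momentum is still conserved exactly through the swaps
  expect_lt(max(abs(tr$observables$px)), 1e-9)
  # accumulated exchanged momentum equals the sum of the logged swaps
  expect_equal(max(tr$observables$swap_px), sum(sw$dpx), tolerance = 1e-12)
  # flux identity
  last <- tr$observables[nrow(tr$observables), ]
  expect_equal(momentum_flux(last$swap_px, last$time, 5, 5),
               last$swap_px / (2 * last$time * 25), tolerance = 1e-14)
})
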