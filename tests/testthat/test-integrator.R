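test_that("Maxwell-Boltzmann velocities have zero drift and the right spread", {
  sys <- init_velocities(water_box(10, seed = 1), kBT = 1, seed = 2)
  b <- sys$beads
  expect_lt(max(abs(c(sum(b$vx), sum(b$vy), sum(b$vz)))), 1e-10)
  expect_lt(abs(kinetic_temperature(sys) - 1), 3 / sqrt(nrow(b)))

  cold <- init_velocities(water_box(4, seed = 3), kBT = 0, seed = 4)
  expect_equal(max(abs(cold$beads$vx)), 0)
})

test_that("a free particle drifts ballistically and wraps at the boundary", {
  sys <- bead_system(matrix(c(5, 5, 5), 1, 3),
                     vel = matrix(c(1, 0, 0), 1, 3))
  tr <- dpd_run(sys, ff_silent(), n_steps = 1, dt = 0.01, seed = 1,
                sample_every = 1, n_slabs = 0)
  expect_equal(tr$system$beads$x, 5.01, tolerance = 1e-14)
  expect_equal(tr$system$beads$vx, 1, tolerance = 1e-14)

  edge <- bead_system(matrix(c(9.995, 5, 5), 1, 3),
                      vel = matrix(c(1, 0, 0), 1, 3))
  tr2 <- dpd_run(edge, ff_silent(), n_steps = 1, dt = 0.01, seed = 1,
                 sample_every = 1, n_slabs = 0)
  expect_equal(tr2$system$beads$x, 0.005, tolerance = 1e-12)
})

test_that("zero steps returns the system unchanged", {
  sys <- init_velocities(water_box(4, seed = 1), seed = 2)
  tr <- dpd_run(sys, dpd_forcefield(), n_steps = 0, seed = 3)
  expect_identical(tr$system, sys)
  expect_equal(nrow(tr$observables), 0)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  sys <- init_velocities(water_box(4, seed = 1), seed = 2)
  t1 <- dpd_run(sys, dpd_forcefield(), n_steps = 200, seed = 5,
                sample_every = 50)
  t2 <- dpd_run(sys, dpd_forcefield(), n_steps = 200, seed = 5,
                sample_every = 50)
  expect_identical(t1$observables, t2$observables)
  expect_identical(t1$system$beads, t2$system$beads)
  t3 <- dpd_run(sys, dpd_forcefield(), n_steps = 200, seed = 6,
                sample_every = 50)
  expect_false(identical(t3$system$beads$x, t1$system$beads$x))
})

test_that("total momentum is conserved without shear", {
  sys <- init_velocities(water_box(5, seed = 1), seed = 2)
  tr <- dpd_run(sys, dpd_forcefield(), n_steps = 1000, seed = 3,
                sample_every = 100)
  drift <- max(abs(as.matrix(tr$observables[, c("px", "py", "pz")])))
  expect_lt(drift / 1000, 1e-9)
})

test_that("conservative-only dynamics conserve energy at small time step", {
  sys <- init_velocities(water_box(4, seed = 1), kBT = 0.5, seed = 2)
  tr <- dpd_run(sys, ff_conservative(), n_steps = 1000, dt = 0.001,
                lambda = 0.5, seed = 3, sample_every = 50)
  e <- tr$observables$e_total
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 0.01)
})

test_that("the DPD thermostat holds the temperature near kBT = 1", {
  sys <- init_velocities(water_box(6, seed = 1), kBT = 0.7, seed = 2)
  tr <- dpd_run(sys, dpd_forcefield(), n_steps = 4000, seed = 3,
                sample_every = 100)
  late <- tr$observables$temperature[tr$observables$time > 20]
  expect_lt(abs(mean(late) - 1), 0.05)
  # stationary: first and second half agree
  n <- length(late)
  expect_lt(abs(mean(late[1:(n %/% 2)]) - mean(late[(n %/% 2 + 1):n])), 0.06)
})

test_that("a run continued from a checkpoint matches an uninterrupted run", {
  sys <- init_velocities(water_box(4, seed = 1), seed = 2)
  full <- dpd_run(sys, dpd_forcefield(), n_steps = 100, seed = 9,
                  sample_every = 100)
  half <- dpd_run(sys, dpd_forcefield(), n_steps = 50, seed = 9,
                  sample_every = 50)
  ck <- tempfile(fileext = ".rds")
  write_checkpoint(half$system, ck)
  resumed <- dpd_run(read_checkpoint(ck), dpd_forcefield(), n_steps = 50,
                     seed = 9, sample_every = 50)
  expect_equal(resumed$system$beads, full$system$beads, tolerance = 1e-14)
  expect_equal(resumed$system$step, 100L)
})
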