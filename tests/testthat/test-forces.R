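test_that("weight function is linear below the cutoff and zero beyond", {
  expect_equal(weight_function(0, 1), 1)
  expect_equal(weight_function(1, 1), 0)
  expect_equal(weight_function(0.3, 1), 0.7)
  expect_equal(weight_function(c(0.5, 2), 2), c(0.75, 0))
  expect_error(weight_function(-0.1), "non-negative")
})

test_that("conservative pair force matches the soft repulsion by hand", {
  sys <- bead_system(rbind(c(1, 1, 1), c(1.5, 1, 1)))
  f <- compute_forces(sys, ff_conservative(a_like = 50))
  fm <- force_matrix(f)
  # |F| = a w(0.5) = 25 along the line of centres, equal and opposite
  expect_equal(unname(fm[1, ]), c(-25, 0, 0), tolerance = 1e-12)
  expect_equal(unname(fm[2, ]), c(25, 0, 0), tolerance = 1e-12)
  # pair energy (a rc / 2) (1 - r/rc)^2 = 6.25
  expect_equal(f$u_pair, 6.25, tolerance = 1e-12)

  far <- bead_system(rbind(c(1, 1, 1), c(2.2, 1, 1)))
  ffar <- compute_forces(far, ff_conservative())
  expect_equal(max(abs(force_matrix(ffar))), 0)
  expect_equal(ffar$u_pair, 0)
})

test_that("all three force channels obey Newton's third law", {
  set.seed(42)
  sys <- water_box(5, seed = 7)
  sys <- init_velocities(sys, seed = 8)
  f <- compute_forces(sys, dpd_forcefield(), stream = 99, step = 3)
  expect_lt(max(abs(colSums(force_matrix(f)))), 1e-9)
})

test_that("dissipative force vanishes for co-moving beads", {
  pos <- rbind(c(1, 1, 1), c(1.6, 1.2, 1))
  vel <- rbind(c(0.3, -0.2, 0.5), c(0.3, -0.2, 0.5))
  sys <- bead_system(pos, vel = vel)
  f_cd <- compute_forces(sys, ff_no_noise(gamma = 4.5))
  f_c <- compute_forces(sys, ff_conservative())
  expect_equal(force_matrix(f_cd), force_matrix(f_c), tolerance = 1e-14)
})

test_that("bond force and energy follow the harmonic spring", {
  mk <- function(r) with_bonds(bead_system(rbind(c(2, 2, 2), c(2 + r, 2, 2))),
                               i = 1, j = 2, k_bond = 100, r_bond = 0.7)
  ff <- ff_silent()
  at_eq <- compute_forces(mk(0.7), ff)
  expect_equal(max(abs(force_matrix(at_eq))), 0, tolerance = 1e-12)

  sq <- compute_forces(mk(0.35), ff)
  fm <- force_matrix(sq)
  expect_equal(unname(fm[1, 1]), -50, tolerance = 1e-12)  # pushed apart
  expect_equal(unname(fm[2, 1]), 50, tolerance = 1e-12)
  expect_equal(sq$u_bond, (100 * 0.7 / 2) * 0.5^2, tolerance = 1e-12)

  st <- compute_forces(mk(1.4), ff)
  fm <- force_matrix(st)
  expect_equal(unname(fm[1, 1]), 100, tolerance = 1e-12)  # pulled together
  expect_equal(unname(fm[2, 1]), -100, tolerance = 1e-12)
})

test_that("angle force is zero at the minimum and energy is harmonic in theta", {
  place <- function(theta) {
    pos <- rbind(c(1, 0, 0), c(0, 0, 0), c(cos(theta), sin(theta), 0)) + 3
    with_angles(bead_system(pos), i = 1, j = 2, k = 3,
                k_angle = 6, theta0 = 2 * pi / 3)
  }
  ff <- ff_silent()
  f0 <- compute_forces(place(2 * pi / 3), ff)
  expect_lt(max(abs(force_matrix(f0))), 1e-10)
  expect_equal(f0$u_angle, 0, tolerance = 1e-12)

  f1 <- compute_forces(place(2 * pi / 3 + 0.1), ff)
  expect_equal(f1$u_angle, 6 * 0.1^2, tolerance = 1e-10)
  # translation invariance: net force vanishes
  expect_lt(max(abs(colSums(force_matrix(f1)))), 1e-12)
  # net torque about the origin vanishes too
  sys <- place(2 * pi / 3 + 0.1)
  pos <- as.matrix(sys$beads[, c("x", "y", "z")])
  fm <- force_matrix(f1)
  torque <- colSums(cbind(
    pos[, 2] * fm[, 3] - pos[, 3] * fm[, 2],
    pos[, 3] * fm[, 1] - pos[, 1] * fm[, 3],
    pos[, 1] * fm[, 2] - pos[, 2] * fm[, 1]))
  expect_lt(max(abs(torque)), 1e-12)
})

test_that("angle with a zero-length arm is rejected", {
  sys <- with_angles(bead_system(rbind(c(1, 1, 1), c(1, 1, 1), c(2, 1, 1))),
                     i = 1, j = 2, k = 3)
  expect_error(compute_forces(sys, ff_silent()), "zero-length arm")
})

test_that("cell list reproduces the brute-force pair set across random boxes", {
  set.seed(11)
  for (rep in 1:20) {
    L <- runif(1, 3.2, 8)
    n <- sample(30:120, 1)
    sys <- bead_system(matrix(runif(3 * n), n, 3) * L, box_edge = L)
    pc <- neighbor_pairs(sys, r_c = 1, method = "cell")
    pb <- neighbor_pairs(sys, r_c = 1, method = "brute")
    expect_identical(pc, pb)
  }
})

test_that("a pair across a periodic face is reported exactly once", {
  L <- 6
  sys <- bead_system(rbind(c(0.05, 3, 3), c(5.95, 3, 3)), box_edge = L)
  pc <- neighbor_pairs(sys, method = "cell")
  expect_equal(nrow(pc), 1)
  expect_equal(pc$i, 1)
  expect_equal(pc$j, 2)
  empty <- bead_system(matrix(0, 0, 3))
  expect_equal(nrow(neighbor_pairs(empty)), 0)
})

test_that("cell-list and brute-force forces agree on all channels", {
  set.seed(5)
  for (rep in 1:5) {
    sys <- water_box(4.5, seed = 100 + rep)
    sys <- init_velocities(sys, seed = 200 + rep)
    fc <- compute_forces(sys, dpd_forcefield(), stream = rep, step = rep,
                         method = "cell")
    fb <- compute_forces(sys, dpd_forcefield(), stream = rep, step = rep,
                         method = "brute")
    expect_lt(max(abs(force_matrix(fc) - force_matrix(fb))), 1e-10)
    expect_equal(fc$u_pair, fb$u_pair, tolerance = 1e-12)
  }
})

test_that("fluctuation-dissipation is enforced at construction", {
  expect_error(dpd_forcefield(sigma = 3, gamma = 1), "fluctuation-dissipation")
  ff <- dpd_forcefield(sigma = 3)
  expect_equal(ff$gamma, 4.5)
  expect_error(dpd_forcefield(a = matrix(-1, 3, 3)), "symmetric and non-negative")
})
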