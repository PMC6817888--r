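chain_system <- function(pos_list, box_edge = 100, bond = TRUE) {
  # each element of pos_list is one chain's bead positions (matrix rows)
  pos <- do.call(rbind, pos_list)
  chain <- rep(seq_along(pos_list), vapply(pos_list, nrow, 1L))
  sys <- bead_system(pos, box_edge = box_edge,
                     species = rep("T", nrow(pos)), chain = chain)
  if (bond) {
    bonds <- do.call(rbind, lapply(seq_along(pos_list), function(c) {
      nb <- nrow(pos_list[[c]])
      if (nb < 2) return(NULL)
      off <- sum(vapply(pos_list[seq_len(c - 1)], nrow, 1L))
      data.frame(i = off + seq_len(nb - 1), j = off + seq_len(nb - 1) + 1)
    }))
    if (!is.null(bonds)) {
      sys <- with_bonds(sys, bonds$i, bonds$j)
    }
  }
  sys
}

test_that("gyration tensor matches hand-computed point and dumbbell chains", {
  pt <- chain_system(list(matrix(c(3, 4, 5), 1, 3)), bond = FALSE)
  g <- gyration_tensor(pt)
  expect_equal(g$rg, 0)
  expect_equal(g$rgxx + g$rgyy + g$rgzz, 0)
  expect_true(is.na(g$delta))

  d <- 1.2
  db <- chain_system(list(rbind(c(10 - d / 2, 10, 10), c(10 + d / 2, 10, 10))))
  g2 <- gyration_tensor(db)
  expect_equal(g2$rgxx, d^2 / 4, tolerance = 1e-12)
  expect_equal(g2$rgyy, 0, tolerance = 1e-14)
  expect_equal(g2$rgzz, 0, tolerance = 1e-14)
  expect_equal(g2$rg, d / 2, tolerance = 1e-12)
  expect_equal(g2$delta, 1, tolerance = 1e-12)  # a dumbbell is a rod
})

test_that("trace identity holds for random chains", {
  set.seed(3)
  for (rep in 1:10) {
    nb <- sample(3:12, 1)
    pos <- 50 + matrix(rnorm(3 * nb, sd = 0.4), nb, 3)
    sys <- chain_system(list(pos))
    g <- gyration_tensor(sys)
    cm <- colMeans(pos)
    direct <- mean(rowSums(sweep(pos, 2, cm)^2))
    expect_equal(g$rgxx + g$rgyy + g$rgzz, direct, tolerance = 1e-10)
    expect_equal(g$rg^2, direct, tolerance = 1e-10)
    expect_equal(g$l1sq + g$l2sq + g$l3sq, direct, tolerance = 1e-8)
  }
})

test_that("analytic eigenvalues agree with eigen() on random tensors", {
  set.seed(8)
  for (rep in 1:25) {
    m <- matrix(rnorm(9), 3, 3)
    s <- crossprod(m)
    ev <- dpdshear:::sym3_eigenvalues(s[1, 1], s[2, 2], s[3, 3],
                                      s[1, 2], s[1, 3], s[2, 3])
    expect_equal(as.numeric(ev), sort(eigen(s, symmetric = TRUE)$values),
                 tolerance = 1e-8)
  }
})

test_that("shape factor hits the canonical geometries", {
  expect_equal(shape_factor(1, 1, 1), 0)            # sphere
  expect_equal(shape_factor(0, 0, 2), 1)            # rod
  expect_equal(shape_factor(0, 0.7, 0.7), 0.25)     # planar disc
  expect_error(shape_factor(0, 0, 0), "all-zero")
  expect_error(shape_factor(-1, 1, 1), "non-negative")
})

test_that("shape factor is invariant under rigid rotation of the chain", {
  set.seed(21)
  nb <- 8
  pos <- 50 + matrix(rnorm(3 * nb, sd = 0.5), nb, 3)
  g0 <- gyration_tensor(chain_system(list(pos)))
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    rot <- sweep(sweep(pos, 2, colMeans(pos)) %*% q, 2, c(50, 50, 50), "+")
    g1 <- gyration_tensor(chain_system(list(rot)))
    expect_equal(g1$delta, g0$delta, tolerance = 1e-8)
    expect_equal(g1$rg, g0$rg, tolerance = 1e-10)
  }
})

test_that("gyration is invariant under translation and periodic rewrap", {
  set.seed(5)
  L <- 10
  pos <- 5 + matrix(rnorm(3 * 6, sd = 0.3), 6, 3)
  base <- gyration_tensor(chain_system(list(pos), box_edge = L))
  for (shift in list(c(4, 0, 0), c(7.3, -2.1, 9.9), c(0, 0, 5))) {
    moved <- sweep(pos, 2, shift, "+") %% L
    g <- gyration_tensor(chain_system(list(moved), box_edge = L))
    expect_equal(g$rg, base$rg, tolerance = 1e-10)
    expect_equal(g$delta, base$delta, tolerance = 1e-8)
  }
})

test_that("chain-mean radius of gyration averages per-chain scalars", {
  # two rigid dumbbells with R_g = 1 and R_g = 3
  sys <- chain_system(list(
    rbind(c(10, 10, 10), c(12, 10, 10)),   # d = 2, R_g = 1
    rbind(c(30, 30, 30), c(36, 30, 30))    # d = 6, R_g = 3
  ))
  g <- gyration_tensor(sys)
  expect_equal(mean(g$rg), 2, tolerance = 1e-12)
})

test_that("folded mean flow velocity integrates the sawtooth correctly", {
  # steady Mueller-Plathe sawtooth with extrema +/- rate L/4 at the swap slabs
  L <- 10; rate <- 0.04
  zc <- (1:20 - 0.5) * L / 20
  vx <- ifelse(zc < L / 2, rate * (L / 4 - zc), rate * (zc - 3 * L / 4))
  tr <- profile_trajectory(vx, box_edge = L)
  series <- mean_flow_velocity(tr, window = 1)
  oracle <- mean(abs(vx))   # independent evaluation of the folded average
  expect_equal(series$v_flow, oracle, tolerance = 1e-12)
  expect_equal(attr(series, "saturation"), oracle, tolerance = 1e-12)
  # and the closed form for this geometry: rate * L / 8
  expect_equal(oracle, rate * L / 8, tolerance = 0.05 * rate * L / 8)

  flat <- profile_trajectory(rep(0, 20), box_edge = L)
  expect_equal(mean_flow_velocity(flat, window = 1)$v_flow, 0)
})

test_that("an ideal gas carries only kinetic energy near equipartition", {
  sys <- init_velocities(water_box(6, seed = 1), kBT = 1, seed = 2)
  tr <- dpd_run(sys, ff_silent(), n_steps = 100, seed = 3, sample_every = 50)
  o <- tr$observables
  expect_equal(o$e_pair, rep(0, nrow(o)))
  expect_equal(o$e_bond, rep(0, nrow(o)))
  expect_equal(o$e_total, o$e_kinetic)
  expect_lt(abs(mean(o$e_kinetic) - 1.5), 0.1)
})

test_that("plateau detection finds constructed levels and onsets", {
  tm <- seq(0, 1000, by = 5)
  set.seed(9)
  flat <- 7.6 + rnorm(length(tm), sd = 0.01)
  pf <- detect_plateau(tm, flat, slope_tol = 1e-3, window = 200)
  expect_equal(pf$onset, 0)
  expect_equal(pf$level, 7.6, tolerance = 0.01)

  knee <- 400
  val <- ifelse(tm < knee, 10 - (10 - 7.6) * tm / knee, 7.6) +
    rnorm(length(tm), sd = 0.005)
  pk <- detect_plateau(tm, val, slope_tol = 1e-3, window = 100)
  expect_lt(abs(pk$onset - knee), 0.05 * 1000)
  expect_equal(pk$level, 7.6, tolerance = 0.02)

  expect_error(detect_plateau(c(0, 1), c(1, 2), window = 200), "shorter")
})

test_that("aggregate clustering counts connected tail components", {
  two <- chain_system(list(rbind(c(10, 10, 10), c(10.6, 10, 10)),
                           rbind(c(40, 40, 40), c(40.6, 40, 40))))
  cl <- cluster_aggregates(two, cutoff = 1)
  expect_equal(attr(cl, "n_clusters"), 2L)

  near <- chain_system(list(rbind(c(10, 10, 10), c(10.6, 10, 10)),
                            rbind(c(10.9, 10, 10), c(11.5, 10, 10))))
  expect_equal(attr(cluster_aggregates(near, cutoff = 1), "n_clusters"), 1L)

  set.seed(4)
  n <- 40
  gas <- bead_system(matrix(runif(3 * n), n, 3) * 50, box_edge = 50,
                     species = rep("T", n))
  expect_equal(attr(cluster_aggregates(gas, cutoff = 1e-4), "n_clusters"), n)

  none <- water_box(3, seed = 1)
  expect_equal(attr(cluster_aggregates(none), "n_clusters"), 0L)
})
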