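test_that("bond energy is the harmonic spring with minimum at 2r", {
  p <- sim_params()
  eq <- bond_energy(2 * p$r, p)
  expect_equal(eq$energy, 0)
  expect_equal(eq$force, 0)

  p100 <- sim_params(K_bond = 100)
  e <- bond_energy(2 * p100$r + 0.1, p100)
  expect_equal(e$energy, 0.5) # 100 * 0.1^2 / 2 kBT
  # quadratic symmetry around the minimum
  expect_equal(bond_energy(2 * p$r - 0.1, p)$energy,
               bond_energy(2 * p$r + 0.1, p)$energy)
  # force is -dV/dd (central finite difference)
  d <- 2 * p100$r + 0.1
  h <- 1e-6
  fd <- -(bond_energy(d + h, p100)$energy -
            bond_energy(d - h, p100)$energy) / (2 * h)
  expect_equal(e$force, fd, tolerance = 1e-6)
  expect_error(bond_energy(0, p), "positive")
  expect_error(bond_energy(-1, p), "positive")
})

test_that("steric repulsion is truncated-shifted r^-12", {
  p <- sim_params()
  shift <- (p$sigma / p$d_cutoff)^12
  at_sigma <- repulsive_energy(p$sigma, p)
  expect_equal(at_sigma$energy, 4 * p$epsilon * (1 - shift))
  expect_equal(at_sigma$energy, 4 * p$epsilon, tolerance = 1e-4)
  # exactly zero at and beyond the cutoff
  expect_identical(repulsive_energy(p$d_cutoff, p)$energy, 0)
  expect_identical(repulsive_energy(10, p)$energy, 0)
  expect_identical(repulsive_energy(10, p)$force, 0)
  expect_equal(repulsive_energy(2, p)$energy, 4 * (2^-12 - shift))
  # strictly decreasing below the cutoff, force always repulsive
  d <- seq(0.8, p$d_cutoff - 1e-6, length.out = 50)
  re <- repulsive_energy(d, p)
  expect_true(all(diff(re$energy) < 0))
  expect_true(all(re$force > 0))
  # force unaffected by the shift: -dV/dd by finite differences
  h <- 1e-7
  fd <- -(repulsive_energy(1.3 + h, p)$energy -
            repulsive_energy(1.3 - h, p)$energy) / (2 * h)
  expect_equal(repulsive_energy(1.3, p)$force, fd, tolerance = 1e-6)
  expect_error(repulsive_energy(0, p), "overlap")
})

test_that("bending potential is quartic around 180 degrees and zero when flexible", {
  p <- sim_params(K_theta = 20)
  expect_equal(angle_energy(180, p)$energy, 0)
  expect_equal(angle_energy(90, p)$energy, p$K_theta / 2) # cos90 = 0, cos180 = -1
  expect_equal(angle_energy(90, p, flexible = TRUE)$energy, 0)
  expect_equal(angle_energy(c(0, 45, 90, 135, 180), p, flexible = TRUE)$energy,
               rep(0, 5))
  # torque = -dV/dtheta (radians), checked by finite differences
  th <- 117
  h <- 1e-5 # degrees
  fd <- -(angle_energy(th + h, p)$energy - angle_energy(th - h, p)$energy) /
    (2 * h * pi / 180)
  expect_equal(angle_energy(th, p)$torque, fd, tolerance = 1e-6)
  expect_error(angle_energy(-5, p), "0, 180")
  expect_error(angle_energy(185, p), "0, 180")
})

test_that("forces are the negative gradient of the total energy", {
  p <- sim_params(K_theta = 10)
  cfg <- random_walk_config(n_chains = 4, dp = 5, box = 6, seed = 3, params = p)
  f <- compute_forces(cfg, p)
  num <- f$forces * 0
  h <- 1e-6
  for (i in seq_len(n_beads(cfg))) {
    for (c in 1:3) {
      up <- cfg
      up$positions[i, c] <- up$positions[i, c] + h
      dn <- cfg
      dn$positions[i, c] <- dn$positions[i, c] - h
      num[i, c] <- -(compute_forces(up, p)$energy -
                       compute_forces(dn, p)$energy) / (2 * h)
    }
  }
  expect_equal(f$forces, num, tolerance = 1e-6)
  # Newton's third law: isolated cluster has zero net force
  expect_true(all(abs(colSums(f$forces)) < 1e-10 * max(abs(f$forces))))
})

test_that("two bonded beads at 2r feel no force; isolated bead is force-free", {
  p <- sim_params()
  pos <- rbind(c(4, 4, 4), c(4, 4, 4 + 2 * p$r))
  cfg <- polymer_config(pos, c(1L, 1L), 20)
  f <- compute_forces(cfg, p)
  expect_equal(max(abs(f$forces)), 0, tolerance = 1e-12)

  lone <- polymer_config(matrix(c(2, 2, 2), 1, 3), 1L, 10)
  fl <- compute_forces(lone, p)
  expect_equal(fl$forces, matrix(0, 1, 3))
  expect_equal(fl$virial, 0)
  expect_equal(fl$energy, 0)
})

test_that("steric repulsion is excluded for bonded neighbors but not crosslinks", {
  p <- sim_params()
  # bonded pair well inside the repulsion range: only bond energy remains
  pos <- rbind(c(5, 5, 5), c(5, 5, 5.8))
  cfg <- polymer_config(pos, c(1L, 1L), 20)
  f <- compute_forces(cfg, p)
  expect_equal(f$components$repulsive, 0)
  expect_equal(f$energy, bond_energy(0.8, p)$energy)
  # same geometry as two chains joined by a crosslink: repulsion present
  cfg2 <- polymer_config(pos, c(1L, 2L), 20, crosslinks = cbind(1L, 2L))
  f2 <- compute_forces(cfg2, p)
  expect_equal(f2$components$repulsive, repulsive_energy(0.8, p)$energy)
  expect_equal(f2$components$crosslink, bond_energy(0.8, p)$energy)
})

test_that("instantaneous pressure matches the ideal-gas and brute-force virial", {
  p <- sim_params()
  # far-apart beads: ideal gas
  pos <- rbind(c(1, 1, 1), c(9, 9, 9), c(1, 9, 1))
  cfg <- polymer_config(pos, 1:3, 20)
  f <- compute_forces(cfg, p)
  expect_equal(instantaneous_pressure(cfg, f$virial, p),
               3 * p$kBT / 20^3)
  # two beads inside the repulsion range push the pressure up
  pos2 <- rbind(c(5, 5, 5), c(5, 5, 6))
  cfg2 <- polymer_config(pos2, 1:2, 20)
  f2 <- compute_forces(cfg2, p)
  expect_gt(instantaneous_pressure(cfg2, f2$virial, p), 2 * p$kBT / 20^3)
  # brute-force pair-sum oracle on a bonded + repulsive system (no angles)
  cfg3 <- random_walk_config(n_chains = 3, dp = 2, box = 5, seed = 9, params = p)
  f3 <- compute_forces(cfg3, p)
  dm <- brute_distances(cfg3$positions, cfg3$box_edge)
  virial <- 0
  for (i in 1:5) {
    for (j in (i + 1):6) {
      d <- dm[i, j]
      bonded <- cfg3$chain_of[i] == cfg3$chain_of[j] && j - i == 1
      if (bonded) {
        virial <- virial + bond_energy(d, p)$force * d
      } else if (d < p$d_cutoff) {
        virial <- virial + repulsive_energy(d, p)$force * d
      }
    }
  }
  expect_equal(f3$virial, virial, tolerance = 1e-10)
  expect_equal(instantaneous_pressure(cfg3, f3$virial, p),
               (6 * p$kBT + virial / 3) / cfg3$box_edge^3)
})
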