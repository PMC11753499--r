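test_that("velocity of a force-free bead decays geometrically at (numerically) zero temperature", {
  # dt fixed explicitly: the default is tied to tau = (2r)^2/D, which
  # diverges as kBT -> 0
  p <- sim_params(kBT = 1e-12, K_theta = 0, dt = 2e-3)
  v0 <- c(0.7, -0.2, 0.4)
  cfg <- polymer_config(matrix(50, 1, 3), 1L, 100,
                        velocities = matrix(v0, 1, 3))
  out <- run_stage(cfg, stage_options(20, record_every = 20L, seed = 5), p)
  expect_equal(as.vector(out$final$velocities), v0 * exp(-p$gamma * p$dt)^20,
               tolerance = 1e-4)
})

test_that("free-bead diffusion matches the Einstein relation", {
  p <- sim_params()
  # independent free beads on a sparse grid in a huge box: no interactions
  g <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 1:6)) * 1000
  cfg <- polymer_config(g, seq_len(nrow(g)), 1e5)
  st <- run_stage(cfg, stage_options(4e5, record_every = 2e4,
                                     snapshot_every = 80, seed = 8), p)
  # long-time MSD slope between lags >> 1/gamma (inertial offset cancels)
  lag1 <- 60  # snapshots = 4800 steps = 9.6 time units
  lag2 <- 180
  D <- fit_diffusion(st$snapshots$positions, lag1, lag2, 80 * p$dt)
  expect_equal(D, p$D, tolerance = 0.05)
})

test_that("kinetic energy equipartitions to kBT/2 per degree of freedom", {
  p <- sim_params()
  # dense-ish interacting gas, NVT
  cfg <- random_walk_config(n_chains = 20, dp = 5, box = 10, seed = 4,
                            params = p)
  st <- run_stage(cfg, stage_options(3e4, record_every = 10, seed = 9), p)
  ke <- st$trace$kinetic[-seq_len(500)] # discard equilibration
  expect_equal(mean(ke) / (3 * n_beads(cfg)), p$kBT / 2, tolerance = 0.05)
  # a bound (harmonic) degree of freedom: bonded dimer, long run
  dimer <- polymer_config(rbind(c(10, 10, 10), c(10, 10, 10 + 2 * p$r)),
                          c(1L, 1L), 30)
  std <- run_stage(dimer, stage_options(1e6, record_every = 20, seed = 2), p)
  ke2 <- std$trace$kinetic[-seq_len(1000)]
  expect_equal(mean(ke2) / 6, p$kBT / 2, tolerance = 0.03)
})

test_that("berendsen rescale has the weak-coupling sign and fixed point", {
  p <- sim_params()
  cfg <- random_walk_config(n_chains = 2, dp = 4, box = 12, seed = 1,
                            params = p)
  same <- berendsen_rescale(cfg, p$p_target, p)
  expect_equal(same$box_edge, cfg$box_edge)
  expect_equal(same$positions, cfg$positions)
  up <- berendsen_rescale(cfg, p$p_target + 1, p)
  expect_gt(up$box_edge^3, cfg$box_edge^3)
  dn <- berendsen_rescale(cfg, p$p_target - 1, p)
  expect_lt(dn$box_edge^3, cfg$box_edge^3)
  expect_warning(berendsen_rescale(cfg, p$p_target + 1e5, p), "clamped")
})

test_that("a dilute repulsive gas relaxes to the target pressure", {
  p <- sim_params(p_target = 0.01)
  withr::with_seed(3, {
    pos <- matrix(runif(50 * 3, 0, 18), ncol = 3)
  })
  cfg <- polymer_config(pos, seq_len(50), 18)
  st <- run_stage(cfg, stage_options(4e4, barostat_on = TRUE,
                                     record_every = 10, seed = 6), p)
  n <- nrow(st$trace)
  pbar <- mean(st$trace$pressure[(n %/% 2):n])
  expect_equal(pbar, p$p_target, tolerance = 0.1)
})

test_that("neighbor list is a superset within cutoff identical to brute force", {
  p <- sim_params()
  for (seed in 1:3) {
    cfg <- random_walk_config(n_chains = 10, dp = 5, box = 7, seed = seed,
                              params = p)
    pairs <- neighbor_pairs(cfg, p$d_cutoff, p$skin)
    dm <- brute_distances(cfg$positions, cfg$box_edge)
    # pairs within cutoff from the list == brute-force enumeration
    keep <- dm[pairs] < p$d_cutoff
    listed <- pairs[keep, , drop = FALSE]
    listed <- listed[order(listed[, 1], listed[, 2]), , drop = FALSE]
    want <- which(upper.tri(dm) & dm < p$d_cutoff, arr.ind = TRUE)
    bonded <- cfg$chain_of[want[, 1]] == cfg$chain_of[want[, 2]] &
      abs(want[, 1] - want[, 2]) == 1
    want <- want[!bonded, , drop = FALSE]
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(listed), unname(want))
    # and everything listed is within cutoff + skin
    expect_true(all(dm[pairs] < p$d_cutoff + p$skin))
  }
})

test_that("neighbor list excludes bonded pairs and respects geometry limits", {
  p <- sim_params()
  # two beads farther apart than cutoff + skin: empty list
  far <- polymer_config(rbind(c(1, 1, 1), c(5, 5, 5)), 1:2, 20)
  expect_equal(nrow(neighbor_pairs(far, p$d_cutoff, p$skin)), 0)
  # bonded pair at close distance: absent
  dimer <- polymer_config(rbind(c(5, 5, 5), c(5, 5, 6)), c(1L, 1L), 20)
  expect_equal(nrow(neighbor_pairs(dimer, p$d_cutoff, p$skin)), 0)
  # same two beads on different chains: present
  pair <- polymer_config(rbind(c(5, 5, 5), c(5, 5, 6)), 1:2, 20)
  expect_equal(nrow(neighbor_pairs(pair, p$d_cutoff, p$skin)), 1)
  expect_error(neighbor_pairs(pair, 12, 0.3), "geometry")
})

test_that("stages are deterministic, bookkeep the trace, and hold the box in NVT", {
  p <- sim_params()
  cfg <- random_walk_config(n_chains = 4, dp = 6, box = 9, seed = 12,
                            params = p)
  a <- run_stage(cfg, stage_options(500, record_every = 50, seed = 77), p)
  b <- run_stage(cfg, stage_options(500, record_every = 50, seed = 77), p)
  expect_identical(a$final$positions, b$final$positions)
  expect_identical(a$final$velocities, b$final$velocities)
  c2 <- run_stage(cfg, stage_options(500, record_every = 50, seed = 78), p)
  expect_false(identical(a$final$positions, c2$final$positions))
  # trace has n_steps / record_every + 1 entries (step 0 included)
  expect_equal(nrow(a$trace), 11)
  expect_equal(a$trace$step[1], 0)
  # NVT: box constant
  expect_true(all(a$trace$volume == cfg$box_edge^3))
  # single step, single entry plus initial state
  one <- run_stage(cfg, stage_options(1, record_every = 1, seed = 1), p)
  expect_equal(nrow(one$trace), 2)
})

test_that("an oversized time step triggers the stability error", {
  p <- sim_params(dt = 0.5)
  cfg <- random_walk_config(n_chains = 2, dp = 5, box = 9, seed = 2,
                            params = p)
  expect_error(run_stage(cfg, stage_options(100, seed = 1), p),
               "stability|smaller dt")
})

test_that("langevin_step advances one step reproducibly", {
  p <- sim_params()
  cfg <- random_walk_config(n_chains = 2, dp = 4, box = 9, seed = 5,
                            params = p)
  s1 <- langevin_step(cfg, p, seed = 3)
  s2 <- langevin_step(cfg, p, seed = 3)
  expect_identical(s1$positions, s2$positions)
  expect_false(identical(s1$positions, cfg$positions))
})
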