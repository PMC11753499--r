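test_that("generated chains are straight, separated and thermally initialized", {
  p <- sim_params()
  spec <- system_spec(6, 8, 25)
  cfg <- generate_initial_chains(spec, p, seed = 3)
  expect_equal(n_beads(cfg), 48)
  expect_equal(nrow(cfg$bonds), 6 * 7)
  expect_equal(nrow(cfg$angles), 6 * 6)
  # consecutive bond vectors are exactly aligned (interior angles 180 degrees)
  for (a in seq_len(nrow(cfg$angles))) {
    tri <- cfg$angles[a, ]
    v1 <- cfg$positions[tri[2], ] - cfg$positions[tri[1], ]
    v2 <- cfg$positions[tri[3], ] - cfg$positions[tri[2], ]
    v1 <- v1 - spec$box_edge * round(v1 / spec$box_edge)
    v2 <- v2 - spec$box_edge * round(v2 / spec$box_edge)
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
  # bond spacing 2r
  d1 <- cfg$positions[cfg$bonds[, 1], ] - cfg$positions[cfg$bonds[, 2], ]
  d1 <- d1 - spec$box_edge * round(d1 / spec$box_edge)
  expect_equal(sqrt(rowSums(d1^2)), rep(2 * p$r, nrow(cfg$bonds)),
               tolerance = 1e-12)
  # brute-force minimum-distance oracle
  dm <- brute_distances(cfg$positions, spec$box_edge)
  expect_gte(min(dm[upper.tri(dm)]), min(spec$min_separation, 2 * p$r) - 1e-12)
  # thermal velocities at kBT: sane scale
  expect_equal(mean(cfg$velocities^2), p$kBT / p$m, tolerance = 0.3)
  # determinism
  cfg2 <- generate_initial_chains(spec, p, seed = 3)
  expect_identical(cfg$positions, cfg2$positions)
  expect_identical(cfg$velocities, cfg2$velocities)
})

test_that("placement fails loudly when the box cannot host the beads", {
  p <- sim_params()
  expect_error(system_spec(100, 10, 5), "terminate|too small")
  tight <- system_spec(12, 10, 8.2)
  expect_error(generate_initial_chains(tight, p, seed = 1, max_attempts = 5),
               "density|placement")
})

test_that("single-chain systems cannot interact with their periodic images", {
  p <- sim_params()
  ch <- single_chain_system(50, flexible = FALSE, p)
  expect_equal(n_beads(ch), 50)
  expect_equal(nrow(ch$bonds), 49)
  expect_equal(nrow(ch$angles), 48)
  contour <- 49 * 2 * p$r
  expect_gte(ch$box_edge, 2 * contour)
  # even fully extended, chain and image stay beyond the interaction range
  expect_gt(ch$box_edge - contour, p$d_cutoff + p$skin)
  fl <- single_chain_system(12, flexible = TRUE, p)
  expect_true(fl$flexible)
  expect_equal(compute_forces(fl, p)$components$angle, 0)
  expect_error(single_chain_system(5, FALSE, p), "dp")
})

test_that("presets encode the reference experiment and its reductions", {
  full <- preset("full")
  expect_equal(full$spec$n_chains * full$spec$dp, 10000)
  expect_equal(full$spec$box_edge, 399.6)
  expect_equal(full$plan$pcl_values, c(0, 0.05, 0.15, 0.25))
  expect_equal(full$plan$assembly_steps, 6e8)
  expect_equal(full$plan$stage_steps, 2e8)
  expect_equal(full$plan$n_replicas, 3)
  edges <- vapply(full$plan$compression_targets, `[[`, numeric(1),
                  "target_edge")
  expect_equal(edges, c(48, 30))
  # scaled presets preserve the stage number densities
  demo <- preset("demo")
  nb_demo <- demo$spec$n_chains * demo$spec$dp
  expect_equal(nb_demo / demo$spec$box_edge^3, 10000 / 399.6^3)
  dedges <- vapply(demo$plan$compression_targets, `[[`, numeric(1),
                   "target_edge")
  expect_equal(nb_demo / dedges^3, 10000 / c(48, 30)^3)
  ci <- preset("ci")
  # every preset satisfies the constructor invariants (validated on build)
  expect_s3_class(ci$spec, "system_spec")
  expect_s3_class(ci$plan, "protocol_plan")
  # neighbor-list geometry holds at the tightest compression
  last_edge <- min(vapply(ci$plan$compression_targets, `[[`, numeric(1),
                          "target_edge"))
  expect_lt(ci$params$d_cutoff + ci$params$skin, last_edge / 2)
  expect_error(preset("nope"), "preset")
  # deterministic seed derivation
  a <- preset("demo", seed = 42)
  b <- preset("demo", seed = 42)
  expect_identical(a$plan$seeds, b$plan$seeds)
})

test_that("the ci preset runs the entire pipeline in under a minute", {
  ci <- preset("ci")
  t0 <- Sys.time()
  res <- run_full_protocol(ci$plan, ci$params)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  expect_s3_class(res, "protocol_result")
  # control row + 2 conformations x 1 positive probability
  expect_equal(nrow(res$phase_map), 3)
  expect_true(all(res$phase_map$sv > 0))
})
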