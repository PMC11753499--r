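p_fast <- sim_params()

test_that("box compression reaches the target exactly with a monotone volume trace", {
  cfg <- random_walk_config(n_chains = 4, dp = 5, box = 14, seed = 6,
                            params = p_fast)
  st <- compress_to_volume(cfg, 9, 400, p_fast, record_every = 10, seed = 2)
  expect_identical(st$final$box_edge, 9)
  expect_true(all(diff(st$trace$volume) <= 0))
  expect_equal(st$trace$volume[nrow(st$trace)], 9^3)
  expect_error(compress_to_volume(st$final, 9, 100, p_fast), "smaller")
  expect_error(compress_to_volume(st$final, 12, 100, p_fast), "smaller")
})

test_that("self-assembly densifies under positive target pressure and books the trace", {
  cfg <- random_walk_config(n_chains = 12, dp = 8, box = 10, seed = 21,
                            params = p_fast)
  st <- self_assembly_stage(cfg, 4000, p_fast, record_every = 40,
                            snapshot_every = 100, seed = 3)
  expect_equal(nrow(st$trace), 4000 / 40 + 1)
  expect_equal(st$trace$normalized,
               st$trace$volume / closed_packing_volume(96, p_fast$r))
  # dilute straight-chain start well above the EOS volume: it contracts
  expect_lt(st$trace$normalized[nrow(st$trace)], st$trace$normalized[1])
})

test_that("conformation selection spans the volume range deterministically", {
  # synthetic stage with a monotone snapshot volume series
  edges <- seq(10, 6, length.out = 21)
  fake <- structure(list(
    label = "assemble",
    trace = tibble::tibble(step = seq_along(edges), volume = edges^3,
                           normalized = edges^3 / 100),
    final = polymer_config(matrix(c(1, 1, 1), 1, 3), 1L, edges[21]),
    snapshots = list(positions = replicate(21, matrix(c(1, 1, 1), 1, 3),
                                           simplify = FALSE),
                     box_edge = edges, step = seq_along(edges))),
    class = "stage_result")
  sel <- select_conformations(fake, 4)
  vols <- vapply(sel, function(cf) cf$box_edge^3, numeric(1))
  expect_named(sel, c("a", "b", "c", "d"))
  expect_true(all(diff(vols) < 0)) # a -> d strictly decreasing
  # evenly spaced quantiles of the observed range, within one stride
  targets <- seq(max(edges^3), min(edges^3), length.out = 4)
  stride <- max(abs(diff(edges^3)))
  expect_true(all(abs(vols - targets) <= stride))
  # k = 1: the final (lowest-volume) snapshot
  one <- select_conformations(fake, 1)
  expect_equal(one$a$box_edge, edges[21])
  expect_error(select_conformations(fake, 22), "at least")
  # deterministic
  expect_identical(vols,
                   vapply(select_conformations(fake, 4), function(cf)
                     cf$box_edge^3, numeric(1)))
})

test_that("crosslinking follows the Bernoulli rule on eligible close pairs", {
  cfg <- random_walk_config(n_chains = 10, dp = 10, box = 6.3, seed = 31,
                            params = p_fast)
  none <- assign_crosslinks(cfg, 0, p_fast, seed = 1)
  expect_equal(nrow(none$crosslinks), 0)
  all_links <- assign_crosslinks(cfg, 1, p_fast, seed = 1)
  expect_equal(nrow(all_links$crosslinks), attr(all_links, "eligible_pairs"))
  # eligibility oracle: brute-force inter-chain pairs at distance < 2r
  dm <- brute_distances(cfg$positions, cfg$box_edge)
  inter <- outer(cfg$chain_of, cfg$chain_of, `!=`)
  expect_equal(attr(all_links, "eligible_pairs"),
               sum(dm < 2 * p_fast$r & inter & upper.tri(dm)))
  # every link joins different chains
  expect_true(all(cfg$chain_of[all_links$crosslinks[, 1]] !=
                    cfg$chain_of[all_links$crosslinks[, 2]]))
  # binomial counts across seeds: within 4 sd of p * E
  E <- attr(all_links, "eligible_pairs")
  pcl <- 0.25
  counts <- vapply(1:20, function(s)
    attr(assign_crosslinks(cfg, pcl, p_fast, seed = s), "n_crosslinks"),
    numeric(1))
  bound <- 4 * sqrt(E * pcl * (1 - pcl))
  expect_true(all(abs(counts - pcl * E) <= bound))
  expect_gt(E, 20) # the fixture must actually have eligible pairs
})

test_that("zero bending constant makes the stiff stage identical to the flexible stage", {
  p0 <- sim_params(K_theta = 0)
  cfg <- random_walk_config(n_chains = 10, dp = 10, box = 8, seed = 41,
                            params = p0)
  cfg <- assign_crosslinks(cfg, 0.5, p0, seed = 2)
  st <- stiff_stage(cfg, 300, p0, record_every = 30, seed = 11)
  fl <- flexible_stage(cfg, 300, p0, record_every = 30, seed = 11)
  expect_identical(st$final$positions, fl$final$positions)
  expect_identical(st$trace$volume, fl$trace$volume)
})

test_that("crosslinks and bonded topology are immutable through both stages", {
  # moderate bending constant: a random-walk start with the fully calibrated
  # stiffness carries enormous bending energy and is not a sane NPT state
  p_soft <- sim_params(K_theta = 5)
  cfg <- random_walk_config(n_chains = 10, dp = 10, box = 8, seed = 51,
                            params = p_soft)
  cfgx <- assign_crosslinks(cfg, 0.4, p_soft, seed = 3)
  expect_gt(nrow(cfgx$crosslinks), 0)
  st <- stiff_stage(cfgx, 300, p_soft, record_every = 30, seed = 4)
  fl <- flexible_stage(st$final, 300, p_soft, record_every = 30, seed = 5)
  expect_identical(fl$final$crosslinks, cfgx$crosslinks)
  expect_identical(fl$final$bonds, cfg$bonds)
  expect_identical(fl$final$angles, cfg$angles)
  # the angular term is exactly zero throughout the flexible stage
  expect_identical(fl$energy_components$angle, 0)
  expect_true(fl$final$flexible)
})

test_that("the full protocol yields one phase-map entry per cell and is reproducible", {
  plan <- protocol_plan(
    n_chains = 8, dp = 12, initial_box = 72.6,
    compression_targets = list(list(target_edge = 10.2, n_steps = 400),
                               list(target_edge = 6.4, n_steps = 200)),
    assembly_steps = 800, n_conformations = 1, pcl_values = 0.25,
    stage_steps = 400, n_replicas = 1, seeds = 7)
  res <- run_full_protocol(plan, p_fast)
  expect_s3_class(res, "protocol_result")
  expect_equal(nrow(res$phase_map), 1)
  expect_equal(res$phase_map$pcl, 0.25)
  expect_true(res$phase_map$sv > 0)
  res2 <- run_full_protocol(plan, p_fast)
  expect_identical(res$phase_map$sv, res2$phase_map$sv)
  # adding the control contributes the P_CL = 0 row
  plan2 <- protocol_plan(
    n_chains = 8, dp = 12, initial_box = 72.6,
    compression_targets = list(list(target_edge = 10.2, n_steps = 400),
                               list(target_edge = 6.4, n_steps = 200)),
    assembly_steps = 800, n_conformations = 2, pcl_values = c(0, 0.25),
    stage_steps = 400, n_replicas = 1, seeds = 7)
  res3 <- run_full_protocol(plan2, p_fast)
  expect_equal(nrow(res3$phase_map), 3) # control + 2 conformations x 1 pcl
  expect_true(any(res3$phase_map$pcl == 0))
})
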