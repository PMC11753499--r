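#' Protocol plan
#'
#' The full experiment layout: gradual two-step box compression, NPT
#' self-assembly, selection of conformations with different volumes,
#' probabilistic crosslinking, and the stiff and flexible stages, repeated
#' over replicas.
#'
#' @param n_chains number of chains.
#' @param dp degree of polymerization (beads per chain).
#' @param initial_box starting cubic box edge.
#' @param compression_targets list of `list(target_edge =, n_steps =)`,
#'   strictly decreasing target edges.
#' @param assembly_steps NPT self-assembly length (steps).
#' @param n_conformations number of conformations selected per replica.
#' @param pcl_values crosslinking probabilities in `[0, 1]` (0 = uncrosslinked
#'   control).
#' @param stage_steps length of each of the stiff and flexible stages.
#' @param n_replicas number of replicas.
#' @param seeds per-replica integer seeds (length `n_replicas`).
#' @param min_separation placement rejection threshold for the initial chains.
#' @return object of class `protocol_plan`.
#' @export
protocol_plan <- function(n_chains, dp, initial_box, compression_targets,
                          assembly_steps, n_conformations = 4,
                          pcl_values = c(0, 0.05, 0.15, 0.25),
                          stage_steps, n_replicas = 3,
                          seeds = 1000 + seq_len(n_replicas),
                          min_separation = 1) {
  edges <- vapply(compression_targets, `[[`, numeric(1), "target_edge")
  stopifnot(n_chains >= 1, dp >= 3, initial_box > 0,
            all(diff(c(initial_box, edges)) < 0),
            assembly_steps > 0, n_conformations >= 1,
            all(pcl_values >= 0 & pcl_values <= 1),
            stage_steps > 0, n_replicas >= 1,
            length(seeds) == n_replicas)
  structure(
    list(n_chains = n_chains, dp = dp, initial_box = initial_box,
         compression_targets = compression_targets,
         assembly_steps = as.double(assembly_steps),
         n_conformations = as.integer(n_conformations),
         pcl_values = pcl_values, stage_steps = as.double(stage_steps),
         n_replicas = as.integer(n_replicas), seeds = as.double(seeds),
         min_separation = min_separation),
    class = "protocol_plan"
  )
}

#' @export
print.protocol_plan <- function(x, ...) {
  cat(sprintf("protocol_plan: %d chains x dp %d, box %.4g", x$n_chains, x$dp,
              x$initial_box))
  for (ct in x$compression_targets) {
    cat(sprintf(" -> %.4g (%g steps)", ct$target_edge, ct$n_steps))
  }
  cat(sprintf("\n  assembly %g steps, %d conformations, P_CL {%s}, stages %g steps, %d replicas\n",
              x$assembly_steps, x$n_conformations,
              paste(x$pcl_values, collapse = ", "), x$stage_steps, x$n_replicas))
  invisible(x)
}

#' Gradual box compression
#'
#' Linearly interpolates the box edge from its current value to `target_edge`
#' over `n_steps`, scaling all coordinates affinely each step while Langevin
#' dynamics runs. The final edge equals the target exactly.
#'
#' @inheritParams compute_forces
#' @param target_edge target box edge, smaller than the current one.
#' @param n_steps number of steps for the ramp.
#' @param record_every,seed see [stage_options()].
#' @return a [run_stage()] result labelled `"compress"`.
#' @export
compress_to_volume <- function(config, target_edge, n_steps, params,
                               record_every = max(1L, n_steps %/% 500),
                               seed = NULL) {
  if (target_edge >= config$box_edge) {
    stop("target_edge must be smaller than the current box edge")
  }
  run_stage(config,
            stage_options(n_steps,
                          box_schedule = list(target_edge = target_edge,
                                              n_steps = n_steps),
                          record_every = record_every, seed = seed,
                          label = "compress"),
            params)
}

#' NPT self-assembly stage
#'
#' Barostat-on dynamics during which the semiflexible mixture densifies toward
#' the target pressure. The volume trace is normalized by the close-packing
#' volume so conformations can be selected from it.
#'
#' @inheritParams compress_to_volume
#' @param snapshot_every stride of stored snapshots (needed by
#'   [select_conformations()]).
#' @return a [run_stage()] result labelled `"assemble"`.
#' @export
self_assembly_stage <- function(config, n_steps, params,
                                record_every = max(1L, n_steps %/% 1000),
                                snapshot_every = max(1L, n_steps %/% 200),
                                seed = NULL) {
  run_stage(config,
            stage_options(n_steps, barostat_on = TRUE, flexible = FALSE,
                          record_every = record_every,
                          snapshot_every = snapshot_every, seed = seed,
                          label = "assemble"),
            params)
}

#' Select conformations with distinct volumes
#'
#' Picks `k` stored snapshots whose volumes are spread evenly across the
#' observed volume range (largest labelled `a`, smallest `d`-style), the
#' deterministic counterpart of marking points on the self-assembly volume
#' trace. `k = 1` returns the final snapshot. Selected configurations carry no
#' velocities; stages started from them draw fresh thermal velocities from
#' their own seed.
#'
#' @param stage a `stage_result` with snapshots (see [self_assembly_stage()]).
#' @param k number of conformations.
#' @return named list (`a`, `b`, ...) of [polymer_config()] objects, ordered
#'   from largest to smallest volume.
#' @export
select_conformations <- function(stage, k) {
  stopifnot(inherits(stage, "stage_result"), k >= 1)
  sn <- stage$snapshots
  if (is.null(sn)) stop("stage has no snapshots; rerun with snapshot_every > 0")
  vols <- sn$box_edge^3
  if (length(unique(vols)) < k) {
    stop(sprintf("need at least %d snapshots with distinct volumes, have %d",
                 k, length(unique(vols))))
  }
  if (k == 1) {
    idx <- length(vols)
  } else {
    targets <- seq(max(vols), min(vols), length.out = k)
    idx <- integer(0)
    for (tg in targets) {
      ord <- order(abs(vols - tg))
      idx <- c(idx, ord[!(ord %in% idx)][1])
    }
    idx <- idx[order(-vols[idx])]
  }
  out <- lapply(idx, function(i) {
    cfg <- stage$final
    cfg$positions <- sn$positions[[i]]
    cfg$velocities <- NULL
    cfg$box_edge <- sn$box_edge[i]
    cfg$flexible <- FALSE
    cfg
  })
  names(out) <- letters[seq_len(k)]
  attr(out, "snapshot_index") <- idx
  attr(out, "snapshot_step") <- sn$step[idx]
  out
}

#' Probabilistic crosslinking
#'
#' Every pair of beads that belong to different chains and sit closer than
#' `2r` (minimum image, instantaneous snapshot geometry) is independently
#' joined with probability `p_cl` by a permanent harmonic spring with constant
#' `K_bond` and equilibrium distance `2r`. A bead may carry several
#' crosslinks.
#'
#' @inheritParams compute_forces
#' @param p_cl crosslinking probability in `[0, 1]`.
#' @param seed integer seed for the Bernoulli draws; `NULL` uses the session
#'   RNG state.
#' @return the configuration with `crosslinks` set; attributes
#'   `eligible_pairs` and `n_crosslinks` report the counts.
#' @export
assign_crosslinks <- function(config, p_cl, params, seed = NULL) {
  stopifnot(inherits(config, "polymer_config"), p_cl >= 0, p_cl <= 1)
  cand <- cpp_brute_pairs(config$positions, config$box_edge, 2 * params$r,
                          config$chain_of)
  inter <- config$chain_of[cand[, 1]] != config$chain_of[cand[, 2]]
  cand <- cand[inter, , drop = FALSE]
  # cpp_brute_pairs uses a strict "< rmax" test, so cand is exactly the
  # eligible set at distance < 2r
  draw <- function() runif(nrow(cand)) < p_cl
  keep <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  links <- cand[keep, , drop = FALSE]
  out <- config
  out$crosslinks <- rbind(config$crosslinks, links)
  attr(out, "eligible_pairs") <- nrow(cand)
  attr(out, "n_crosslinks") <- nrow(links)
  out
}

#' Stiff and flexible stages
#'
#' Barostat-on dynamics of the (crosslinked) mixture with the bending
#' potential active (`stiff_stage`) or identically zero (`flexible_stage`).
#' The crosslink list and the chain bonded topology are immutable through both
#' stages.
#'
#' @inheritParams compress_to_volume
#' @return a [run_stage()] result labelled `"stiff"` or `"flexible"`.
#' @export
stiff_stage <- function(config, n_steps, params,
                        record_every = max(1L, n_steps %/% 1000),
                        seed = NULL) {
  run_stage(config,
            stage_options(n_steps, barostat_on = TRUE, flexible = FALSE,
                          record_every = record_every, seed = seed,
                          label = "stiff"),
            params)
}

#' @rdname stiff_stage
#' @export
flexible_stage <- function(config, n_steps, params,
                           record_every = max(1L, n_steps %/% 1000),
                           seed = NULL) {
  run_stage(config,
            stage_options(n_steps, barostat_on = TRUE, flexible = TRUE,
                          record_every = record_every, seed = seed,
                          label = "flexible"),
            params)
}

#' Run the full shrink/swell protocol
#'
#' For each replica: generate initial chains, compress the box in the
#' configured steps, self-assemble under NPT, select `n_conformations`
#' snapshots, then for every conformation and every `p_cl > 0` crosslink and
#' run the stiff and flexible stages. For `p_cl = 0` the trailing
#' `stage_steps` window of the self-assembly serves as the stiff stage and a
#' bending-free continuation from the final assembled configuration as the
#' flexible stage. Swelling factors pool the trailing windows of all replicas.
#'
#' @param plan a [protocol_plan()].
#' @param params a [sim_params()].
#' @param window_fraction trailing fraction of each stage trace used for the
#'   time averages (see [swelling_factor()]).
#' @param record_every trace stride for the stiff/flexible stages.
#' @param progress logical; print per-cell progress lines.
#' @return object of class `protocol_result` with elements `phase_map`
#'   (tibble: `conformation`, `pcl`, `v_stiff_norm`, `sv`, `sv_se`,
#'   `n_replicas`, `eligible_pairs`, `n_crosslinks`), `cells` (per-cell traces
#'   and final configurations), `assembly` (per-replica assembly stage
#'   results), `plan`, `params`.
#' @export
run_full_protocol <- function(plan, params, window_fraction = 0.5,
                              record_every = max(1L, plan$stage_steps %/% 1000),
                              progress = FALSE) {
  stopifnot(inherits(plan, "protocol_plan"), inherits(params, "sim_params"))
  say <- function(...) if (progress) message(sprintf(...))
  spec <- system_spec(plan$n_chains, plan$dp, plan$initial_box,
                      min_separation = plan$min_separation)
  pcl_pos <- sort(plan$pcl_values[plan$pcl_values > 0])
  has_control <- any(plan$pcl_values == 0)
  assembly <- vector("list", plan$n_replicas)
  cells <- list()

  for (rep_i in seq_len(plan$n_replicas)) {
    base <- plan$seeds[rep_i]
    say("replica %d: generating and compressing", rep_i)
    cfg <- generate_initial_chains(spec, params, seed = derive_seed(base, 1))
    for (j in seq_along(plan$compression_targets)) {
      ct <- plan$compression_targets[[j]]
      cfg <- compress_to_volume(cfg, ct$target_edge, ct$n_steps, params,
                                seed = derive_seed(base, 10 + j))$final
    }
    say("replica %d: self-assembly (%g steps)", rep_i, plan$assembly_steps)
    asm <- self_assembly_stage(cfg, plan$assembly_steps, params,
                               seed = derive_seed(base, 20))
    assembly[[rep_i]] <- asm
    confs <- select_conformations(asm, plan$n_conformations)

    if (has_control) {
      tail_tr <- asm$trace[asm$trace$step >= plan$assembly_steps - plan$stage_steps, ]
      say("replica %d: P_CL = 0 control", rep_i)
      fl <- flexible_stage(asm$final, plan$stage_steps, params,
                           record_every = record_every,
                           seed = derive_seed(base, 30))
      key <- cell_key(0, "d")
      cells[[key]]$pcl <- 0
      cells[[key]]$conformation <- "d"
      cells[[key]]$stiff[[rep_i]] <- list(trace = tail_tr)
      cells[[key]]$flexible[[rep_i]] <- fl
      cells[[key]]$eligible[rep_i] <- NA_real_
      cells[[key]]$links[rep_i] <- 0
    }

    for (ci in seq_along(confs)) {
      for (pi in seq_along(pcl_pos)) {
        pcl <- pcl_pos[pi]
        lab <- names(confs)[ci]
        say("replica %d: conformation %s, P_CL = %g", rep_i, lab, pcl)
        off <- 100 * ci + 10 * pi
        cfgx <- assign_crosslinks(confs[[ci]], pcl, params,
                                  seed = derive_seed(base, off + 1))
        st <- tryCatch(
          stiff_stage(cfgx, plan$stage_steps, params,
                      record_every = record_every,
                      seed = derive_seed(base, off + 2)),
          error = function(e) e)
        if (inherits(st, "error")) {
          warning(sprintf("replica %d cell (%s, %g) stiff stage failed: %s",
                          rep_i, lab, pcl, conditionMessage(st)))
          next
        }
        fl <- tryCatch(
          flexible_stage(st$final, plan$stage_steps, params,
                         record_every = record_every,
                         seed = derive_seed(base, off + 3)),
          error = function(e) e)
        if (inherits(fl, "error")) {
          warning(sprintf("replica %d cell (%s, %g) flexible stage failed: %s",
                          rep_i, lab, pcl, conditionMessage(fl)))
          next
        }
        key <- cell_key(pcl, lab)
        cells[[key]]$pcl <- pcl
        cells[[key]]$conformation <- lab
        cells[[key]]$stiff[[rep_i]] <- st
        cells[[key]]$flexible[[rep_i]] <- fl
        cells[[key]]$eligible[rep_i] <- attr(cfgx, "eligible_pairs")
        cells[[key]]$links[rep_i] <- attr(cfgx, "n_crosslinks")
      }
    }
  }

  vcp <- closed_packing_volume(plan$n_chains * plan$dp, params$r)
  entries <- lapply(cells, function(cl) {
    st_traces <- lapply(cl$stiff, function(s) if (is.null(s)) NULL else s$trace)
    fl_traces <- lapply(cl$flexible, function(s) if (is.null(s)) NULL else s$trace)
    st_traces <- Filter(Negate(is.null), st_traces)
    fl_traces <- Filter(Negate(is.null), fl_traces)
    sv <- swelling_factor(st_traces, fl_traces, window_fraction)
    sv_rep <- mapply(function(s, f) swelling_factor(s, f, window_fraction),
                     st_traces, fl_traces)
    tibble::tibble(
      conformation = cl$conformation, pcl = cl$pcl,
      v_stiff_norm = attr(sv, "v_stiff") / vcp, sv = as.numeric(sv),
      sv_se = if (length(sv_rep) > 1) sd(sv_rep) / sqrt(length(sv_rep)) else NA_real_,
      n_replicas = length(st_traces),
      eligible_pairs = mean(cl$eligible, na.rm = TRUE),
      n_crosslinks = mean(cl$links))
  })
  pm <- dplyr::arrange(dplyr::bind_rows(entries), pcl, conformation)
  structure(list(phase_map = pm, cells = cells, assembly = assembly,
                 plan = plan, params = params, v_cp = vcp,
                 window_fraction = window_fraction),
            class = "protocol_result")
}

cell_key <- function(pcl, lab) sprintf("p%03d_%s", round(1000 * pcl), lab)

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("protocol_result: %d replicas, %d phase-map entries\n",
              x$plan$n_replicas, nrow(x$phase_map)))
  print(x$phase_map)
  invisible(x)
}
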