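#' Options for a dynamics stage
#'
#' @param n_steps number of integration steps (> 0).
#' @param barostat_on logical; apply the Berendsen rescale every step.
#' @param flexible logical or `NA`; `NA` inherits the configuration's flag.
#' @param box_schedule optional `list(target_edge =, n_steps =)` for gradual
#'   deterministic box compression (mutually exclusive with `barostat_on`).
#' @param record_every stride (steps) of the volume/kinetic/pressure trace.
#' @param snapshot_every stride of stored configuration snapshots; 0 disables.
#' @param seed integer RNG seed for the stage; `NULL` draws one from the R
#'   session RNG.
#' @param label short stage label (e.g. "assemble", "stiff").
#' @return object of class `stage_options`.
#' @export
stage_options <- function(n_steps, barostat_on = FALSE, flexible = NA,
                          box_schedule = NULL, record_every = 100L,
                          snapshot_every = 0L, seed = NULL, label = "stage") {
  stopifnot(length(n_steps) == 1, n_steps > 0, record_every >= 1,
            snapshot_every >= 0)
  if (!is.null(box_schedule)) {
    stopifnot(is.list(box_schedule), !is.null(box_schedule$target_edge),
              !is.null(box_schedule$n_steps), box_schedule$n_steps > 0)
    if (isTRUE(barostat_on)) {
      stop("box_schedule and barostat_on are mutually exclusive")
    }
  }
  structure(
    list(n_steps = as.double(n_steps), barostat_on = isTRUE(barostat_on),
         flexible = flexible, box_schedule = box_schedule,
         record_every = as.integer(record_every),
         snapshot_every = as.integer(snapshot_every),
         seed = if (is.null(seed)) NULL else as.double(seed), label = label),
    class = "stage_options"
  )
}

# Berendsen scale-factor clamp, applied per step (see berendsen_rescale)
MU_BOUNDS <- c(0.95, 1.05)

#' One Langevin (BAOAB) integration step
#'
#' Advances positions and velocities by a single discrete step of the Langevin
#' equation at temperature `kBT` with friction `m * gamma`, using the BAOAB
#' splitting. In the free-particle limit the long-time mean-square
#' displacement per dimension is `2 D t` with `D = kBT / (m * gamma)`, and a
#' bound degree of freedom equilibrates to mean kinetic energy `kBT / 2`.
#'
#' @inheritParams compute_forces
#' @param seed integer seed for the thermal noise of this step.
#' @return the updated [polymer_config()].
#' @export
langevin_step <- function(config, params, seed = NULL) {
  res <- run_stage(config, stage_options(1, record_every = 1L, seed = seed,
                                         label = "step"), params)
  res$final
}

#' Berendsen isotropic pressure rescale
#'
#' Applies the weak-coupling scale factor
#' `mu = (1 - kappa * (dt / tau_p) * (p_target - P_inst))^(1/3)` to the box
#' edge and all coordinates. `mu = 1` when the instantaneous pressure equals
#' the target; an excessive excursion is clamped to `[0.95, 1.05]` with a
#' warning.
#'
#' @inheritParams compute_forces
#' @param p_inst instantaneous pressure (see [instantaneous_pressure()]).
#' @return the rescaled [polymer_config()].
#' @export
berendsen_rescale <- function(config, p_inst, params) {
  stopifnot(inherits(config, "polymer_config"), inherits(params, "sim_params"))
  mu3 <- 1 - params$kappa * (params$dt / params$tau_p) *
    (params$p_target - p_inst)
  mu <- if (mu3 > 0) mu3^(1 / 3) else MU_BOUNDS[1]
  if (mu < MU_BOUNDS[1] || mu > MU_BOUNDS[2]) {
    warning(sprintf("Berendsen scale factor %.4f clamped to [%.2f, %.2f]",
                    mu, MU_BOUNDS[1], MU_BOUNDS[2]))
    mu <- min(max(mu, MU_BOUNDS[1]), MU_BOUNDS[2])
  }
  config$positions <- config$positions * mu
  config$box_edge <- config$box_edge * mu
  config$positions <- config$positions -
    config$box_edge * floor(config$positions / config$box_edge)
  config
}

#' Candidate interaction pairs (Verlet buffer)
#'
#' Returns every bead pair within `cutoff + skin` under minimum-image
#' distances — a superset of the pairs within `cutoff` — excluding directly
#' bonded neighbor pairs. Inside [run_stage()] the list is rebuilt whenever
#' any bead has moved more than `skin / 2` since the last build.
#'
#' @inheritParams compute_forces
#' @param cutoff interaction cutoff distance.
#' @param skin Verlet buffer width.
#' @return two-column integer matrix of bead index pairs (i < j).
#' @export
neighbor_pairs <- function(config, cutoff, skin) {
  stopifnot(inherits(config, "polymer_config"), cutoff > 0, skin >= 0)
  if (cutoff + skin >= config$box_edge / 2) {
    stop("geometry error: cutoff + skin must be smaller than half the box edge")
  }
  cpp_brute_pairs(config$positions, config$box_edge, cutoff + skin,
                  config$chain_of)
}

#' Run a dynamics stage
#'
#' Executes `n_steps` of BAOAB Langevin dynamics, applying the Berendsen
#' rescale each step when `barostat_on`, or the deterministic affine box
#' interpolation when `box_schedule` is set. Records the volume trace (plus
#' kinetic energy and pressure) every `record_every` steps, starting at step
#' 0, and optional configuration snapshots. Bit-reproducible for a fixed seed
#' on one platform.
#'
#' @inheritParams compute_forces
#' @param opts a [stage_options()] object.
#' @return object of class `stage_result`: `label`, `trace` (tibble with
#'   `step`, `volume`, `normalized`, `kinetic`, `pressure`), `final`
#'   configuration, `snapshots`, per-stage `means`, and the `seed` used.
#' @export
run_stage <- function(config, opts, params) {
  stopifnot(inherits(config, "polymer_config"),
            inherits(opts, "stage_options"),
            inherits(params, "sim_params"))
  flexible <- if (is.na(opts$flexible)) config$flexible else isTRUE(opts$flexible)
  if (params$d_cutoff + params$skin >= config$box_edge / 2) {
    stop("geometry error: cutoff + skin must be smaller than half the box edge")
  }
  seed <- opts$seed %||% sample.int(2147483646L, 1)
  sched <- opts$box_schedule
  res <- cpp_run_stage(
    config$positions, config$velocities, config$box_edge, config$chain_of,
    to0(config$bonds), to0(config$angles), to0(config$crosslinks),
    unclass(params), flexible,
    as.integer(opts$n_steps), opts$barostat_on, params$p_target, params$tau_p,
    params$kappa, MU_BOUNDS[1], MU_BOUNDS[2],
    if (is.null(sched)) -1 else sched$target_edge,
    if (is.null(sched)) -1L else as.integer(sched$n_steps),
    opts$record_every, opts$snapshot_every, seed
  )
  if (isTRUE(res$mu_clamped)) {
    warning("Berendsen scale factor was clamped during the stage")
  }
  vcp <- closed_packing_volume(n_beads(config), params$r)
  trace <- tibble::tibble(step = res$step, volume = res$volume,
                          normalized = res$volume / vcp,
                          kinetic = res$kinetic, pressure = res$pressure)
  final <- config
  final$positions <- res$positions
  final$velocities <- res$velocities
  final$box_edge <- res$box_edge
  final$flexible <- flexible
  snaps <- NULL
  if (opts$snapshot_every > 0 && length(res$snapshots) > 0) {
    snaps <- list(positions = res$snapshots, box_edge = res$snapshot_box,
                  step = res$snapshot_step)
  }
  structure(
    list(label = opts$label, trace = trace, final = final, snapshots = snaps,
         means = list(volume = mean(trace$volume),
                      normalized = mean(trace$normalized),
                      kinetic = mean(trace$kinetic),
                      pressure = mean(trace$pressure)),
         energy_components = res$energy_components,
         n_rebuilds = res$n_rebuilds, seed = seed, v_cp = vcp),
    class = "stage_result"
  )
}

#' @export
print.stage_result <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("stage_result '%s': %d trace points, final V = %.6g (V/V_CP = %.4g)\n",
              x$label, n, x$trace$volume[n], x$trace$normalized[n]))
  if (!is.null(x$snapshots)) {
    cat(sprintf("  %d snapshots\n", length(x$snapshots$positions)))
  }
  invisible(x)
}
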