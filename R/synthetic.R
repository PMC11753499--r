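#' System specification for synthetic initial configurations
#'
#' @param n_chains number of chains.
#' @param dp degree of polymerization (>= 3, so angle triads exist).
#' @param box_edge cubic box edge.
#' @param min_separation rejection threshold: no inter-bead distance in the
#'   generated configuration falls below this.
#' @param seed default seed for [generate_initial_chains()].
#' @return object of class `system_spec`.
#' @export
system_spec <- function(n_chains, dp, box_edge, min_separation = 1,
                        seed = NULL) {
  stopifnot(n_chains >= 1, dp >= 3, box_edge > 0, min_separation > 0)
  # crude terminability bound: beads at min_separation spacing must fit easily
  if (n_chains * dp * min_separation^3 > 0.3 * box_edge^3) {
    stop("placement cannot terminate: box too small for this bead count at min_separation")
  }
  structure(list(n_chains = as.integer(n_chains), dp = as.integer(dp),
                 box_edge = box_edge, min_separation = min_separation,
                 seed = seed),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("system_spec: %d chains x dp %d (%d beads), box %.4g, min separation %.3g\n",
              x$n_chains, x$dp, x$n_chains * x$dp, x$box_edge,
              x$min_separation))
  invisible(x)
}

#' Generate random initial chain configurations
#'
#' Places each chain as a straight segment of `dp` beads at spacing `2r`, with
#' uniformly random position and orientation in the periodic box, rejecting
#' placements that bring any bead closer than `min_separation` to an already
#' placed bead (minimum image). Velocities are drawn from the
#' Maxwell-Boltzmann distribution at `kBT`.
#'
#' @param spec a [system_spec()].
#' @param params a [sim_params()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @param max_attempts per-chain rejection attempts before giving up.
#' @return a [polymer_config()] with straight chains (all interior angles
#'   exactly 180 degrees).
#' @export
generate_initial_chains <- function(spec, params, seed = spec$seed,
                                    max_attempts = 2000) {
  stopifnot(inherits(spec, "system_spec"), inherits(params, "sim_params"))
  if ((spec$dp - 1) * 2 * params$r >= spec$box_edge / 2) {
    stop("density error: straight-chain contour exceeds half the box; use a larger box")
  }
  gen <- function() {
    n <- spec$n_chains * spec$dp
    pos <- matrix(NA_real_, n, 3)
    offs <- (seq_len(spec$dp) - (spec$dp + 1) / 2) * 2 * params$r
    placed <- 0L
    for (ch in seq_len(spec$n_chains)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        center <- runif(3, 0, spec$box_edge)
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        beads <- cbind(center[1] + offs * u[1], center[2] + offs * u[2],
                       center[3] + offs * u[3])
        beads <- beads - spec$box_edge * floor(beads / spec$box_edge)
        if (placed == 0L ||
            cpp_min_dist(beads, pos[seq_len(placed), , drop = FALSE],
                         spec$box_edge) >= spec$min_separation) {
          pos[placed + seq_len(spec$dp), ] <- beads
          placed <- placed + spec$dp
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("density error: chain placement failed; use a larger box or smaller min_separation")
      }
    }
    vel <- matrix(rnorm(3 * n, sd = sqrt(params$kBT / params$m)), n, 3)
    polymer_config(pos, rep(seq_len(spec$n_chains), each = spec$dp),
                   spec$box_edge, velocities = vel)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Single isolated chain
#'
#' One straight chain in a box at least 2.5 times its contour length, so
#' periodic images can never interact: the test system for persistence-length
#' measurements. Velocities are left unset; the stage that runs it draws them
#' from its own seed.
#'
#' @param dp beads in the chain (>= 10).
#' @param flexible logical; start with the bending potential switched off.
#' @param params a [sim_params()].
#' @return a [polymer_config()].
#' @export
single_chain_system <- function(dp, flexible = FALSE, params) {
  stopifnot(dp >= 10, inherits(params, "sim_params"))
  contour <- (dp - 1) * 2 * params$r
  edge <- 2.5 * contour
  z <- (seq_len(dp) - (dp + 1) / 2) * 2 * params$r + edge / 2
  pos <- cbind(rep(edge / 2, dp), rep(edge / 2, dp), z)
  polymer_config(pos, rep(1L, dp), edge, flexible = flexible)
}

#' Built-in experiment presets
#'
#' Bundles a [system_spec()], [protocol_plan()] and [sim_params()] for three
#' scales:
#' \describe{
#'   \item{full}{200 chains x dp 50 in a (399.6 sigma)^3 box, compression over
#'     1e7 steps to 48 sigma then 1e6 steps to 30 sigma, 6e8 assembly steps,
#'     2e8-step stiff and flexible stages, crosslinking probabilities 0, 0.05,
#'     0.15 and 0.25, 4 conformations, 3 replicas. The complete full-scale
#'     layout; far beyond desk scale.}
#'   \item{demo}{20 chains x dp 25 at the same number densities (box scaled by
#'     the cube root of 500/10000), compression 1e4 + 1e3 steps, assembly 2e5
#'     steps, stages 1e5 steps, same probability grid, 3 replicas. Minutes on
#'     one CPU.}
#'   \item{ci}{8 chains x dp 12, seconds-scale smoke test (2 conformations,
#'     probabilities 0 and 0.25, 1 replica).}
#' }
#'
#' @param name one of `"full"`, `"demo"`, `"ci"`.
#' @param seed optional base seed; replica seeds are derived from it
#'   deterministically. Default uses fixed per-preset seeds.
#' @return list with elements `spec`, `plan`, `params`.
#' @export
preset <- function(name = c("full", "demo", "ci"), seed = NULL) {
  if (!is.character(name) || !name[1] %in% c("full", "demo", "ci")) {
    stop("unknown preset; available: full, demo, ci")
  }
  name <- match.arg(name)
  params <- sim_params()
  scale_for <- function(nbeads) (nbeads / 10000)^(1 / 3)
  def <- switch(
    name,
    full = list(n_chains = 200L, dp = 50L, f = 1,
                comp_steps = c(1e7, 1e6), assembly = 6e8, stages = 2e8,
                pcl = c(0, 0.05, 0.15, 0.25), n_conf = 4L, n_rep = 3L),
    demo = list(n_chains = 20L, dp = 25L, f = scale_for(500),
                comp_steps = c(1e4, 1e3), assembly = 2e5, stages = 1e5,
                pcl = c(0, 0.05, 0.15, 0.25), n_conf = 4L, n_rep = 3L),
    ci = list(n_chains = 8L, dp = 12L, f = scale_for(96),
              comp_steps = c(2000, 500), assembly = 4000, stages = 2000,
              pcl = c(0, 0.25), n_conf = 2L, n_rep = 1L)
  )
  initial_box <- 399.6 * def$f
  targets <- list(
    list(target_edge = 48 * def$f, n_steps = def$comp_steps[1]),
    list(target_edge = 30 * def$f, n_steps = def$comp_steps[2])
  )
  seeds <- if (is.null(seed)) {
    1000 + seq_len(def$n_rep)
  } else {
    vapply(seq_len(def$n_rep), function(i) derive_seed(seed, i), numeric(1))
  }
  spec <- system_spec(def$n_chains, def$dp, initial_box,
                      seed = seeds[1])
  plan <- protocol_plan(def$n_chains, def$dp, initial_box, targets,
                        assembly_steps = def$assembly,
                        n_conformations = def$n_conf, pcl_values = def$pcl,
                        stage_steps = def$stages, n_replicas = def$n_rep,
                        seeds = seeds)
  list(spec = spec, plan = plan, params = params)
}
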