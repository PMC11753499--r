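#' Harmonic bond energy and force
#'
#' `V_bond(d) = K_bond * (d - 2r)^2 / 2`, the spring joining consecutive beads
#' of a chain (and, with the same constants, a crosslink). The signed scalar
#' force is `-dV/dd`: negative when the bond is stretched past `2r`, positive
#' when compressed.
#'
#' @param d inter-bead distance(s), > 0.
#' @param params a [sim_params()] object.
#' @return list with numeric vectors `energy` and `force`.
#' @examples
#' p <- sim_params()
#' bond_energy(2 * p$r, p) # zero energy, zero force at equilibrium
#' @export
bond_energy <- function(d, params) {
  stopifnot(inherits(params, "sim_params"))
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("invalid geometry: inter-bead distance must be positive")
  }
  dd <- d - 2 * params$r
  list(energy = 0.5 * params$K_bond * dd^2, force = -params$K_bond * dd)
}

#' Truncated-shifted steric repulsion
#'
#' The repulsive r^-12 term of a Lennard-Jones potential,
#' `V_rep(d) = 4 * epsilon * ((sigma/d)^12 - (sigma/d_cutoff)^12)` for
#' `d < d_cutoff` and exactly zero beyond. The constant shift makes the energy
#' continuous at the cutoff; the force (`-dV/dd`, always repulsive) is the
#' same as for the unshifted potential.
#'
#' @inheritParams bond_energy
#' @param d_ij pair distance(s), > 0.
#' @return list with numeric vectors `energy` and `force`.
#' @export
repulsive_energy <- function(d_ij, params) {
  stopifnot(inherits(params, "sim_params"))
  if (any(!is.finite(d_ij)) || any(d_ij <= 0)) {
    stop("overlap error: pair distance must be positive (divergent energy at 0)")
  }
  s12 <- (params$sigma / d_ij)^12
  shift <- (params$sigma / params$d_cutoff)^12
  inside <- d_ij < params$d_cutoff
  list(energy = ifelse(inside, 4 * params$epsilon * (s12 - shift), 0),
       force = ifelse(inside, 48 * params$epsilon * s12 / d_ij, 0))
}

#' Bending energy at an angle triad
#'
#' `V_angle(theta) = K_theta * (cos(theta) - cos(theta0))^2 / 2` where `theta`
#' is the interior angle at the vertex of three consecutive bonded beads
#' (180 degrees = straight chain). With `flexible = TRUE` the potential is
#' identically zero, emulating the loss of bending rigidity of a denatured
#' chain. The returned torque is `-dV/dtheta` (per radian).
#'
#' @inheritParams bond_energy
#' @param theta bond angle(s) in degrees, in `[0, 180]`.
#' @param flexible logical; zero out the potential.
#' @return list with numeric vectors `energy` and `torque`.
#' @export
angle_energy <- function(theta, params, flexible = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (any(theta < 0) || any(theta > 180)) {
    stop("theta must lie in [0, 180] degrees")
  }
  if (isTRUE(flexible)) {
    z <- numeric(length(theta))
    return(list(energy = z, torque = z))
  }
  th <- theta * pi / 180
  dc <- cos(th) - cos(params$theta0 * pi / 180)
  list(energy = 0.5 * params$K_theta * dc^2,
       torque = params$K_theta * dc * sin(th))
}

#' Forces, total potential energy and virial of a configuration
#'
#' Assembles the three interaction terms (bonds + crosslinks, steric
#' repulsion, bending) under periodic minimum-image distances. Steric
#' repulsion is excluded for directly bonded neighbor pairs. The scalar virial
#' is `sum over pairwise terms of f_ij . d_ij` (angle contributions are
#' decomposed relative to the triad vertex, which is the equivalent pairwise
#' form).
#'
#' @inheritParams bond_energy
#' @param config a [polymer_config()].
#' @return list with `forces` (N x 3), `energy`, `virial` and per-term
#'   `components`.
#' @export
compute_forces <- function(config, params) {
  stopifnot(inherits(config, "polymer_config"), inherits(params, "sim_params"))
  cpp_forces(config$positions, config$box_edge, config$chain_of,
             to0(config$bonds), to0(config$angles), to0(config$crosslinks),
             unclass(params), config$flexible)
}

to0 <- function(idx) {
  m <- matrix(as.integer(idx), ncol = ncol(idx))
  m - 1L
}

#' Instantaneous virial pressure
#'
#' `P = (N * kBT + virial / 3) / V` with `V = box_edge^3`: ideal-gas term at
#' the thermostat temperature plus the pairwise virial contribution.
#'
#' @inheritParams compute_forces
#' @param virial scalar virial computed for the same configuration (see
#'   [compute_forces()]).
#' @return pressure (energy / length^3).
#' @export
instantaneous_pressure <- function(config, virial, params) {
  stopifnot(inherits(config, "polymer_config"), inherits(params, "sim_params"))
  v <- config$box_edge^3
  if (v <= 0) stop("zero volume")
  (n_beads(config) * params$kBT + virial / 3) / v
}
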