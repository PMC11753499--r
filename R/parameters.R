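#' Simulation parameters in reduced units
#'
#' Collects every model constant of the coarse-grained bead-spring model.
#' Reduced units: lengths in the repulsion length `sigma`, energies in `kBT`,
#' masses in the bead mass `m`, and times in the bead diffusion time
#' `tau = (2r)^2 / D` with `D = kBT / (m * gamma)`. The bead radius is tied to
#' the repulsion length (`sigma * 2^(1/6) / 2`), so the bond equilibrium
#' distance `2r` sits at the minimum of the corresponding full Lennard-Jones
#' potential and the close-packing volume works out to `N * sigma^3` exactly.
#'
#' The repulsive potential is the r^-12 term of a Lennard-Jones potential,
#' truncated at `d_cutoff` and shifted so it is continuous (zero) at the
#' cutoff; forces are unaffected by the shift.
#'
#' @param kBT thermal energy (energy unit). Must be > 0.
#' @param sigma repulsion length (length unit). Must be > 0.
#' @param m bead mass (mass unit). Must be > 0.
#' @param gamma velocity relaxation rate of the Langevin thermostat (1/time);
#'   the friction coefficient is `m * gamma`.
#' @param K_bond bond (and crosslink) elastic constant, energy/length^2.
#' @param epsilon strength of the steric repulsion, energy.
#' @param d_cutoff repulsion cutoff distance; must be >= `sigma`.
#' @param K_theta bending constant of the angular potential
#'   `V = K_theta * (cos(theta) - cos(theta0))^2 / 2`. Default `NULL`
#'   calibrates it so an isolated stiff chain has persistence length `50 r`
#'   (see [calibrate_bending_constant()]).
#' @param theta0 reference bond angle in degrees (interior angle at the triad
#'   vertex; 180 means a straight chain).
#' @param dt integration time step. Default `1.587e-3 * tau`.
#' @param p_target barostat target pressure, energy/length^3.
#' @param tau_p barostat coupling time. Default `0.07937 * tau`.
#' @param kappa barostat compressibility factor entering the Berendsen scale
#'   factor `mu^3 = 1 - kappa * (dt/tau_p) * (p_target - P)`.
#' @param skin Verlet-buffer skin added to `d_cutoff` for the neighbor list.
#'
#' @return An object of class `sim_params`: a list with the arguments plus the
#'   derived quantities `r`, `D` and `tau`.
#' @examples
#' p <- sim_params()
#' p$r - p$sigma * 2^(1 / 6) / 2 # 0 by construction
#' @export
sim_params <- function(kBT = 1, sigma = 1, m = 1, gamma = 1,
                       K_bond = 200 * kBT / sigma^2, epsilon = kBT,
                       d_cutoff = 2.5 * sigma,
                       K_theta = NULL, theta0 = 180,
                       dt = NULL, p_target = 1.0 * kBT / sigma^3,
                       tau_p = NULL, kappa = sigma^3 / kBT,
                       skin = 0.3 * sigma) {
  stopifnot(kBT > 0, sigma > 0, m > 0, gamma > 0, K_bond > 0, epsilon > 0)
  if (d_cutoff < sigma) {
    stop("d_cutoff must be >= sigma")
  }
  r <- sigma * 2^(1 / 6) / 2
  D <- kBT / (m * gamma)
  tau <- (2 * r)^2 / D
  if (is.null(dt)) dt <- 1.587e-3 * tau
  if (is.null(tau_p)) tau_p <- 0.07937 * tau
  if (is.null(K_theta)) {
    K_theta <- calibrate_bending_constant(50 * r, 2 * r, kBT)$K_theta
  }
  stopifnot(dt > 0, K_theta >= 0, tau_p > 0, kappa > 0, skin > 0,
            p_target >= 0)
  structure(
    list(kBT = kBT, sigma = sigma, m = m, gamma = gamma, K_bond = K_bond,
         epsilon = epsilon, d_cutoff = d_cutoff, K_theta = K_theta,
         theta0 = theta0, dt = dt, p_target = p_target, tau_p = tau_p,
         kappa = kappa, skin = skin, r = r, D = D, tau = tau),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Coarse-grained simulation parameters (reduced units)\n")
  cat(sprintf("  kBT = %g, sigma = %g, m = %g, gamma = %g\n",
              x$kBT, x$sigma, x$m, x$gamma))
  cat(sprintf("  r = %.6g (= sigma 2^(1/6)/2), D = %g, tau = %.6g\n",
              x$r, x$D, x$tau))
  cat(sprintf("  K_bond = %g, epsilon = %g, d_cutoff = %g, skin = %g\n",
              x$K_bond, x$epsilon, x$d_cutoff, x$skin))
  cat(sprintf("  K_theta = %.6g, theta0 = %g deg\n", x$K_theta, x$theta0))
  cat(sprintf("  dt = %.6g (%.4g tau)\n", x$dt, x$dt / x$tau))
  cat(sprintf("  barostat: p_target = %g, tau_p = %.6g, kappa = %g\n",
              x$p_target, x$tau_p, x$kappa))
  invisible(x)
}

# settable (non-derived) fields, used by the run-configuration round trip
sim_params_fields <- function() {
  c("kBT", "sigma", "m", "gamma", "K_bond", "epsilon", "d_cutoff", "K_theta",
    "theta0", "dt", "p_target", "tau_p", "kappa", "skin")
}
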