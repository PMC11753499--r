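#' Boltzmann-average of cos(theta) for the bending potential
#'
#' Computes `<cos theta>` of a single angle triad governed by
#' `V_angle = K_theta (cos theta - cos theta0)^2 / 2` at thermal equilibrium:
#' the expectation over `theta in [0, pi]` with weight
#' `sin(theta) exp(-V/kBT)`. Note the potential is quartic (not harmonic) in
#' `theta` near `theta0 = 180` degrees, so no harmonic closed form applies;
#' the integral is evaluated by adaptive quadrature after the exact
#' substitution `x = cos theta` (where the weight is a truncated Gaussian),
#' with the peak factored out for numerical stability at large `K_theta`.
#'
#' @param K_theta bending constant, >= 0 (energy units).
#' @param kBT thermal energy.
#' @param theta0 reference angle in degrees.
#' @return `<cos theta>`, in `(-1, 0]` for `theta0 = 180`.
#' @examples
#' predicted_cos_theta(0) # 0: isotropic angles
#' @export
predicted_cos_theta <- function(K_theta, kBT = 1, theta0 = 180) {
  stopifnot(K_theta >= 0, kBT > 0)
  x0 <- cos(theta0 * pi / 180)
  a <- K_theta / (2 * kBT)
  xpeak <- min(max(x0, -1), 1)
  g <- function(x) exp(-a * ((x - x0)^2 - (xpeak - x0)^2))
  # clip to where the weight is numerically non-zero (exp(-745) underflows),
  # so the adaptive rule cannot miss a narrow peak at large K_theta
  delta <- if (a > 0) sqrt(745 / a) else Inf
  lo <- max(-1, xpeak - delta)
  hi <- min(1, xpeak + delta)
  num <- tryCatch(
    integrate(function(x) x * g(x), lo, hi, rel.tol = 1e-12,
              subdivisions = 500L),
    error = function(e) stop("quadrature non-convergence: ", conditionMessage(e)))
  den <- tryCatch(
    integrate(g, lo, hi, rel.tol = 1e-12, subdivisions = 500L),
    error = function(e) stop("quadrature non-convergence: ", conditionMessage(e)))
  num$value / den$value
}

#' Calibrate the bending constant against a target persistence length
#'
#' Under the interior-angle convention (a straight chain has `theta = 180`
#' degrees) the correlation of consecutive bond tangents is `-<cos theta>`,
#' so a worm-like chain with persistence length `l_p` and bond length `b`
#' satisfies `exp(-b / l_p) = -<cos theta>(K_theta)`. This solves that
#' equation for `K_theta` by root-finding on the quadrature oracle
#' [predicted_cos_theta()]. Excluded volume is ignored here (single-angle
#' factorization), so very small targets are meaningful only as limits.
#'
#' @param target_lp target persistence length (> 0), same length unit as
#'   `bond_length`.
#' @param bond_length inter-bead bond length (typically `2r`).
#' @param kBT thermal energy.
#' @return object of class `calibration_result`: `K_theta`, `target_lp`,
#'   `bond_length`, `predicted_cos` (`<cos theta>` at the solution),
#'   `achieved_lp`, and the relative `residual` (< 1e-6).
#' @examples
#' r <- 2^(1 / 6) / 2
#' calibrate_bending_constant(50 * r, 2 * r) # the stiff-stage target
#' @export
calibrate_bending_constant <- function(target_lp, bond_length, kBT = 1) {
  stopifnot(target_lp > 0, bond_length > 0, kBT > 0)
  target <- exp(-bond_length / target_lp) # required -<cos theta>, in (0, 1)
  if (target >= 1) stop("target unreachable: -<cos theta> < 1 for finite K_theta")
  f <- function(logk) -predicted_cos_theta(exp(logk), kBT) - target
  lo <- log(1e-8)
  hi <- log(1e10)
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibration error: target persistence length outside the reachable range")
  }
  root <- uniroot(f, c(lo, hi), tol = 1e-14)
  K <- exp(root$root)
  pc <- predicted_cos_theta(K, kBT)
  achieved <- -bond_length / log(-pc)
  residual <- abs((-pc) - target) / target
  if (residual > 1e-6) {
    stop(sprintf("calibration error: residual %.3g exceeds 1e-6", residual))
  }
  structure(
    list(K_theta = K, target_lp = target_lp, bond_length = bond_length,
         kBT = kBT, predicted_cos = pc, achieved_lp = achieved,
         residual = residual),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: K_theta = %.6g for l_p = %.4g (b = %.4g, kBT = %g)\n",
              x$K_theta, x$target_lp, x$bond_length, x$kBT))
  cat(sprintf("  <cos theta> = %.6f, achieved l_p = %.6g, residual %.2g\n",
              x$predicted_cos, x$achieved_lp, x$residual))
  invisible(x)
}

#' Audit the step-to-time conversion
#'
#' Derives the implied time step from a printed reference conversion
#' (`reference_steps` integration steps corresponding to `reference_tau` bead
#' diffusion times) and converts a step count to a duration; optionally checks
#' an independently stated duration for that step count, flagging
#' inconsistencies above 1%.
#'
#' @param steps step count to convert.
#' @param stage_tau optional independently stated duration of `steps`, in tau.
#' @param reference_steps,reference_tau the reference conversion pair.
#' @return object of class `time_audit`: `dt_tau` (implied time step in tau),
#'   `duration_tau`, `stage_tau`, `consistent`.
#' @examples
#' audit_time_units(2e8, reference_steps = 6e8, reference_tau = 0.952e6)
#' @export
audit_time_units <- function(steps, stage_tau = NULL, reference_steps,
                             reference_tau) {
  stopifnot(steps >= 0, reference_steps > 0, reference_tau > 0)
  dt_tau <- reference_tau / reference_steps
  duration <- steps * dt_tau
  consistent <- TRUE
  if (!is.null(stage_tau)) {
    stopifnot(stage_tau > 0)
    consistent <- abs(duration - stage_tau) / stage_tau <= 0.01
    if (!consistent) {
      warning(sprintf(
        "printed duration %.4g tau deviates from implied %.4g tau by more than 1%%",
        stage_tau, duration))
    }
  }
  structure(list(dt_tau = dt_tau, duration_tau = duration,
                 stage_tau = stage_tau, consistent = consistent),
            class = "time_audit")
}

#' @export
print.time_audit <- function(x, ...) {
  cat(sprintf("time audit: dt = %.6g tau; duration = %.6g tau%s\n",
              x$dt_tau, x$duration_tau,
              if (is.null(x$stage_tau)) "" else
                sprintf(" (stated %.6g tau, %s)", x$stage_tau,
                        if (x$consistent) "consistent" else "INCONSISTENT")))
  invisible(x)
}
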