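#' Theoretical close-packing volume
#'
#' The volume occupied by `N` beads of radius `r` at the maximal sphere
#' packing fraction `pi / (3 sqrt(2))`:
#' `V_CP = (3 sqrt(2) / pi) * V_mon * N = 4 sqrt(2) r^3 N` with
#' `V_mon = 4 pi r^3 / 3`. System volumes are reported as `V / V_CP`, so 1
#' marks the close-packed limit. For the tied bead radius
#' (`sigma * 2^(1/6) / 2`) this equals `N sigma^3` exactly.
#'
#' @param N monomer (bead) count, >= 0.
#' @param r bead radius, > 0.
#' @return the close-packing volume.
#' @examples
#' closed_packing_volume(10000, 2^(1 / 6) / 2) # = 10000 for sigma = 1
#' @export
closed_packing_volume <- function(N, r) {
  if (any(N < 0)) stop("N must be non-negative")
  stopifnot(r > 0)
  4 * sqrt(2) * r^3 * N
}

#' Swelling factor
#'
#' `S_V = <V_flexible> / <V_stiff>`, the ratio of time-averaged system volumes
#' over the trailing window of each stage. Replicas are pooled by
#' concatenating their trailing windows before averaging, so replicas of
#' unequal length contribute in proportion to their window sizes. `S_V < 1`
#' means the network shrank upon flexibilization.
#'
#' @param stiff,flexible a volume trace (tibble with a `volume` column, a
#'   `stage_result`, a bare numeric vector), or a list of such objects
#'   (replicas).
#' @param window_fraction trailing fraction of each trace to average over
#'   (default 0.5, mirroring averaging the last half of each stage).
#' @return `S_V` as a numeric scalar with attributes `v_flexible`, `v_stiff`
#'   and `n` (pooled window lengths).
#' @export
swelling_factor <- function(stiff, flexible, window_fraction = 0.5) {
  stopifnot(window_fraction > 0, window_fraction <= 1)
  vs <- pooled_tail(stiff, window_fraction)
  vf <- pooled_tail(flexible, window_fraction)
  if (length(vs) == 0 || length(vf) == 0) stop("empty averaging window")
  sv <- mean(vf) / mean(vs)
  attr(sv, "v_flexible") <- mean(vf)
  attr(sv, "v_stiff") <- mean(vs)
  attr(sv, "n") <- c(stiff = length(vs), flexible = length(vf))
  sv
}

as_volume_vector <- function(x) {
  if (inherits(x, "stage_result")) x <- x$trace
  if (is.data.frame(x)) x <- x$volume
  if (!is.numeric(x) || length(x) == 0) {
    stop("trace must be a non-empty volume series")
  }
  x
}

pooled_tail <- function(x, frac) {
  if (is.data.frame(x) || inherits(x, "stage_result") || !is.list(x)) x <- list(x)
  unlist(lapply(x, function(tr) {
    v <- as_volume_vector(tr)
    tail(v, max(1L, ceiling(frac * length(v))))
  }), use.names = FALSE)
}

#' Persistence length from tangent correlations
#'
#' Fits the exponential decay of the bond tangent correlation,
#' `<t_i . t_(i+s)> = exp(-s b / l_p)` with `b` the mean bond length, by
#' log-linear least squares, weighting each separation by the inverse
#' variance of `log C(s)` estimated from the snapshot ensemble (block-based,
#' so slowly decorrelating long-wavelength modes do not fool the weights):
#' long separations, whose correlations are dominated by the slowest bending
#' modes, carry little weight instead of dominating the slope.
#' The fit range starts at `s = 1` and extends over
#' the separations whose mean correlation exceeds `min_corr`, but only while
#' the observed decay stays consistent with the exponential extrapolated from
#' the first separation (`-log C(s)` within `exp_tol` of `s * (-log C(1))`):
#' worm-like decorrelation is exponential, whereas self-avoiding flexible
#' chains develop a slower power-law tail at long range that would otherwise
#' bias the fit upward. For exactly exponential ensembles the full above-floor
#' range is used. The confidence interval comes from a moving-block bootstrap
#' over snapshots, which is robust to the slow decorrelation of
#' long-wavelength bending modes between successive samples.
#'
#' @param snapshots an ensemble of conformations of one chain: a list of
#'   `n_beads x 3` matrices, or a `stage_result` carrying snapshots.
#' @param min_corr correlation floor defining the maximal fit range.
#' @param min_points minimum number of separations required for a fit.
#' @param exp_tol relative tolerance on the per-separation decay rate used to
#'   cap the fit range at the exponential regime.
#' @param n_boot bootstrap replicates.
#' @param block_len bootstrap block length; default `n_snapshots / 30`.
#' @param lp_cap persistence lengths above this cap (default `1e4 * b`) are
#'   reported as `Inf` ("effectively infinite", e.g. a perfectly straight
#'   chain).
#' @param conf confidence level of the bootstrap interval.
#' @param seed integer seed for the bootstrap resampling.
#' @return object of class `lp_fit`: `lp`, `ci`, `b` (mean bond length), the
#'   correlation profile (`s`, `corr`), the fit range, and `capped`.
#' @export
persistence_length <- function(snapshots, min_corr = 0.05, min_points = 1,
                               exp_tol = 0.15, n_boot = 200, block_len = NULL,
                               lp_cap = NULL, conf = 0.95, seed = NULL) {
  if (inherits(snapshots, "stage_result")) {
    if (is.null(snapshots$snapshots)) stop("stage has no snapshots")
    snapshots <- snapshots$snapshots$positions
  }
  stopifnot(is.list(snapshots))
  ns <- length(snapshots)
  if (ns < 100) stop("need at least 100 decorrelated snapshots")
  nb <- nrow(snapshots[[1]]) - 1L
  if (nb < 10) stop("need a chain with at least 10 bonds")

  # unit tangents per snapshot, stacked as ns x nb matrices per component
  tx <- ty <- tz <- matrix(0, ns, nb)
  blen <- 0
  for (q in seq_len(ns)) {
    dv <- diff(snapshots[[q]])
    ln <- sqrt(rowSums(dv^2))
    blen <- blen + mean(ln)
    tx[q, ] <- dv[, 1] / ln
    ty[q, ] <- dv[, 2] / ln
    tz[q, ] <- dv[, 3] / ln
  }
  b <- blen / ns
  if (is.null(lp_cap)) lp_cap <- 1e4 * b
  smax <- nb - 1L
  # per-snapshot mean correlation at each separation
  cmat <- vapply(seq_len(smax), function(s) {
    i <- seq_len(nb - s)
    rowMeans(tx[, i, drop = FALSE] * tx[, i + s, drop = FALSE] +
             ty[, i, drop = FALSE] * ty[, i + s, drop = FALSE] +
             tz[, i, drop = FALSE] * tz[, i + s, drop = FALSE])
  }, numeric(ns))

  fit_range_for <- function(corr) {
    below <- which(corr <= min_corr)
    last <- if (length(below)) min(below) - 1L else length(corr)
    if (last < 1L) return(integer(0))
    r1 <- -log(corr[1]) # per-separation decay rate at s = 1
    if (r1 <= 0) return(seq_len(last)) # non-decaying (straight chain)
    S <- last
    for (s in seq_len(last)) {
      if (abs(-log(corr[s]) - s * r1) > exp_tol * s * r1) {
        S <- s - 1L
        break
      }
    }
    seq_len(max(S, 1L))
  }

  bl <- block_len %||% max(1L, ns %/% 30L)

  # inverse-variance weights for log C(s): block-based standard errors of the
  # snapshot means, fixed from the full sample
  nb_blocks <- max(2L, ns %/% bl)
  grp <- rep(seq_len(nb_blocks), each = ceiling(ns / nb_blocks))[seq_len(ns)]
  block_means <- apply(cmat, 2, function(col) tapply(col, grp, mean))
  se <- apply(block_means, 2, sd) / sqrt(nb_blocks)
  corr_full <- colMeans(cmat)
  wts <- (corr_full / pmax(se, 1e-12))^2

  fit_lp <- function(corr) {
    s <- fit_range_for(corr)
    if (length(s) < min_points) return(NA_real_)
    w <- wts[s]
    # weighted through-origin LS on log C = slope * s
    slope <- sum(w * s * log(corr[s])) / sum(w * s^2)
    if (!is.finite(slope) || slope >= -b / lp_cap) return(Inf)
    -b / slope
  }

  corr <- corr_full
  lp <- fit_lp(corr)
  if (is.na(lp)) {
    stop(sprintf(
      "estimation error: no positive-correlation regime (C(1) = %.4f, floor %g, need %d separation(s))",
      corr[1], min_corr, min_points))
  }

  boot <- function() {
    vapply(seq_len(n_boot), function(i) {
      starts <- sample.int(ns - bl + 1L, ceiling(ns / bl), replace = TRUE)
      rows <- as.vector(outer(0:(bl - 1L), starts, `+`))[seq_len(ns)]
      fit_lp(colMeans(cmat[rows, , drop = FALSE]))
    }, numeric(1))
  }
  lps <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(lps, c(alpha, 1 - alpha), na.rm = TRUE, type = 6))

  structure(
    list(lp = lp, ci = ci, b = b, s = seq_len(smax), corr = corr,
         fit_range = fit_range_for(corr),
         capped = is.infinite(lp), lp_cap = lp_cap, n_snapshots = ns,
         n_boot = n_boot, boot = lps),
    class = "lp_fit"
  )
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("persistence length: l_p = %.4g (%.4g bond lengths)\n",
              x$lp, x$lp / x$b))
  cat(sprintf("  bootstrap CI [%.4g, %.4g], %d snapshots, fit over s = 1..%d\n",
              x$ci[1], x$ci[2], x$n_snapshots, length(x$fit_range)))
  if (x$capped) cat(sprintf("  above cap %.4g: effectively infinite\n", x$lp_cap))
  invisible(x)
}

#' Phase map over (volume, crosslinking probability)
#'
#' Tabulates swelling factors on the grid of stiff-stage volume
#' (`v_stiff_norm = <V_stiff> / V_CP`) and crosslinking probability. Cells
#' with `S_V < 1` are flagged `"shrink"`, `S_V > 1` `"swell"`. Values are the
#' input `S_V` exactly (no interpolation). `plot()` renders the heat map.
#'
#' @param entries a tibble/data.frame with columns `v_stiff_norm`, `pcl`, `sv`
#'   (and optionally `n_replicas`, `conformation`), or a `protocol_result`.
#' @return object of class `phase_map` wrapping the grid tibble.
#' @export
phase_map <- function(entries) {
  if (inherits(entries, "protocol_result")) entries <- entries$phase_map
  entries <- tibble::as_tibble(entries)
  stopifnot(nrow(entries) >= 1,
            all(c("v_stiff_norm", "pcl", "sv") %in% names(entries)))
  stopifnot(all(entries$sv > 0), all(entries$pcl >= 0 & entries$pcl <= 1))
  entries$flag <- ifelse(entries$sv < 1, "shrink",
                         ifelse(entries$sv > 1, "swell", "neutral"))
  structure(list(grid = entries), class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat("phase map (S_V over <V_stiff>/V_CP and P_CL):\n")
  print(x$grid)
  invisible(x)
}

#' @param x a `phase_map`.
#' @param ... ignored.
#' @rdname phase_map
#' @export
plot.phase_map <- function(x, ...) {
  g <- x$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$v_stiff_norm,
                                  y = factor(.data$pcl),
                                  fill = .data$sv)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$sv)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166AC",
                                  mid = "white", high = "#B2182B",
                                  name = expression(S[V])) +
    ggplot2::labs(x = expression("<" * V[stiff] * "> / " * V[CP]),
                  y = expression(P[CL]),
                  title = "Swelling factor: shrink (<1, blue) vs swell (>1, red)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
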