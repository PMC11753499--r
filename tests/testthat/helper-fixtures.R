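# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no stored data.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Chains laid out as random walks with bond-length steps: sane bond geometry,
# non-trivial angles and inter-chain contacts. Bead placements closer than
# min_sep to any existing bead are rejected so the initial energies stay
# integrable at the default time step. Deterministic given the seed.
random_walk_config <- function(n_chains = 2, dp = 5, box = 8, seed = 1,
                               params = sim_params(), step = 2 * params$r,
                               min_sep = 0.85) {
  withr::with_seed(seed, {
    pos <- matrix(0, n_chains * dp, 3)
    mi_dist <- function(a, b) {
      d <- sweep(b, 2, a)
      d <- d - box * round(d / box)
      sqrt(min(rowSums(d^2)))
    }
    k <- 0L
    for (ch in seq_len(n_chains)) {
      repeat {
        x <- runif(3, 0, box)
        if (k == 0L || mi_dist(x, pos[seq_len(k), , drop = FALSE]) >= min_sep) break
      }
      for (b in seq_len(dp)) {
        k <- k + 1L
        pos[k, ] <- x
        for (try in 1:500) {
          u <- rnorm(3)
          cand <- x + step * u / sqrt(sum(u^2))
          others <- pos[seq_len(k - 1L), , drop = FALSE]
          if (k == 1L || nrow(others) == 0 ||
              mi_dist(cand, others) >= min_sep) break
        }
        x <- cand
      }
    }
    vel <- matrix(rnorm(3 * nrow(pos), sd = sqrt(params$kBT / params$m)),
                  ncol = 3)
    polymer_config(pos, rep(seq_len(n_chains), each = dp), box,
                   velocities = vel)
  })
}

# Minimum-image distance matrix, plain R: the brute-force oracle.
brute_distances <- function(pos, box) {
  n <- nrow(pos)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dv <- pos[i, ] - pos[j, ]
      dv <- dv - box * round(dv / box)
      d[i, j] <- d[j, i] <- sqrt(sum(dv^2))
    }
  }
  d
}

# Ideal worm-like-chain ensemble: interior angles sampled directly from the
# single-angle Boltzmann weight (truncated Gaussian in cos(theta) via
# rejection), uniform azimuths, no excluded volume. Tangent correlations are
# exactly exponential, so it is an independent oracle for persistence_length.
wlc_chain_snapshots <- function(n_snap, n_beads, K_theta, b = 2^(1 / 6),
                                kBT = 1, seed = 1) {
  sample_cos <- function(n) {
    if (K_theta == 0) return(runif(n, -1, 1))
    out <- numeric(0)
    while (length(out) < n) {
      z <- rnorm(2 * n + 10, mean = -1, sd = sqrt(kBT / K_theta))
      z <- z[z >= -1 & z <= 1]
      out <- c(out, z)
    }
    out[seq_len(n)]
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_snap), function(q) {
      nb <- n_beads - 1L
      tang <- matrix(0, nb, 3)
      u <- rnorm(3)
      tang[1, ] <- u / sqrt(sum(u^2))
      cosx <- sample_cos(nb - 1L)
      psi <- runif(nb - 1L, 0, 2 * pi)
      for (k in 2:nb) {
        t0 <- tang[k - 1, ]
        # orthonormal frame around t0
        ref <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        e1 <- ref - sum(ref * t0) * t0
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(t0[2] * e1[3] - t0[3] * e1[2],
                t0[3] * e1[1] - t0[1] * e1[3],
                t0[1] * e1[2] - t0[2] * e1[1])
        cphi <- -cosx[k - 1] # tangent correlation = -cos(interior angle)
        sphi <- sqrt(max(0, 1 - cphi^2))
        tang[k, ] <- cphi * t0 +
          sphi * (cos(psi[k - 1]) * e1 + sin(psi[k - 1]) * e2)
      }
      rbind(c(0, 0, 0), apply(b * tang, 2, cumsum))
    })
  })
}

# Metropolis sampler of the same single-angle Boltzmann weight: the
# Monte-Carlo oracle for predicted_cos_theta.
metropolis_cos_theta <- function(K_theta, n = 2e5, kBT = 1, seed = 2) {
  withr::with_seed(seed, {
    a <- K_theta / (2 * kBT)
    x <- -0.5
    xs <- numeric(n)
    for (i in seq_len(n)) {
      prop <- x + runif(1, -0.4, 0.4)
      if (prop >= -1 && prop <= 1 &&
          log(runif(1)) < -a * ((prop + 1)^2 - (x + 1)^2)) {
        x <- prop
      }
      xs[i] <- x
    }
    mean(xs[-seq_len(n %/% 10)])
  })
}

# fast MSD-slope diffusion estimate from a multi-bead free run
fit_diffusion <- function(snapshots, lag1, lag2, dt_per_snap) {
  X <- lapply(snapshots, as.vector)
  X <- do.call(rbind, X)
  msd <- function(L) mean((X[-(seq_len(L)), , drop = FALSE] -
                           X[seq_len(nrow(X) - L), , drop = FALSE])^2)
  (msd(lag2) - msd(lag1)) / (2 * (lag2 - lag1) * dt_per_snap)
}
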