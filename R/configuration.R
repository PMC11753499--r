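#' Polymer configuration
#'
#' Positions, velocities and topology of a mixture of linear bead-spring
#' chains in a cubic periodic box. Bonds connect consecutive beads of a chain;
#' every interior bead is the vertex of exactly one angle triad; crosslinks
#' are unordered pairs of beads belonging to different chains. Positions are
#' wrapped into `[0, box_edge)`; all distances are evaluated under the
#' minimum-image convention.
#'
#' @param positions N x 3 matrix of bead coordinates (sigma units).
#' @param chain_of integer vector mapping each bead to its chain. Beads of a
#'   chain must occupy a consecutive index block, in order.
#' @param box_edge cubic box edge length (> 0).
#' @param velocities optional N x 3 matrix; `NULL` means "draw fresh thermal
#'   velocities when a stage starts".
#' @param crosslinks optional 2-column matrix of bead index pairs joining
#'   different chains.
#' @param flexible logical; when `TRUE` the angular potential is identically
#'   zero for this configuration.
#' @return An object of class `polymer_config` with elements `positions`,
#'   `velocities`, `chain_of`, `bonds`, `angles`, `crosslinks`, `box_edge`,
#'   `flexible`.
#' @export
polymer_config <- function(positions, chain_of, box_edge, velocities = NULL,
                           crosslinks = NULL, flexible = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(is.numeric(positions), ncol(positions) == 3,
            length(chain_of) == nrow(positions),
            is.numeric(box_edge), length(box_edge) == 1, box_edge > 0)
  chain_of <- as.integer(chain_of)
  n <- nrow(positions)
  # chains must be consecutive index blocks
  if (n > 1 && any(diff(chain_of) < 0)) {
    stop("chain_of must assign consecutive index blocks per chain")
  }
  positions <- positions - box_edge * floor(positions / box_edge)
  dimnames(positions) <- NULL
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(nrow(velocities) == n, ncol(velocities) == 3)
    dimnames(velocities) <- NULL
  }
  topo <- chain_topology(chain_of)
  if (is.null(crosslinks) || NROW(crosslinks) == 0) {
    crosslinks <- matrix(integer(0), ncol = 2)
  } else {
    crosslinks <- matrix(as.integer(crosslinks), ncol = 2)
    same <- chain_of[crosslinks[, 1]] == chain_of[crosslinks[, 2]]
    if (any(same)) stop("crosslinks must join beads of different chains")
  }
  structure(
    list(positions = positions, velocities = velocities, chain_of = chain_of,
         bonds = topo$bonds, angles = topo$angles, crosslinks = crosslinks,
         box_edge = box_edge, flexible = isTRUE(flexible)),
    class = "polymer_config"
  )
}

chain_topology <- function(chain_of) {
  n <- length(chain_of)
  if (n < 2) {
    return(list(bonds = matrix(integer(0), ncol = 2),
                angles = matrix(integer(0), ncol = 3)))
  }
  i <- seq_len(n - 1)
  keep <- chain_of[i] == chain_of[i + 1]
  bonds <- cbind(i[keep], i[keep] + 1L)
  j <- seq_len(max(n - 2, 0))
  keep3 <- if (n >= 3) chain_of[j] == chain_of[j + 2] else logical(0)
  angles <- cbind(j[keep3], j[keep3] + 1L, j[keep3] + 2L)
  list(bonds = bonds, angles = angles)
}

#' @export
print.polymer_config <- function(x, ...) {
  cat(sprintf(
    "polymer_config: %d beads, %d chains, %d bonds, %d angles, %d crosslinks\n",
    nrow(x$positions), length(unique(x$chain_of)), nrow(x$bonds),
    nrow(x$angles), nrow(x$crosslinks)))
  cat(sprintf("  box edge %.6g, %s, velocities %s\n", x$box_edge,
              if (x$flexible) "flexible" else "stiff",
              if (is.null(x$velocities)) "unset (drawn at stage start)" else "set"))
  invisible(x)
}

#' Number of beads in a configuration
#' @param config a [polymer_config()].
#' @return integer bead count.
#' @export
n_beads <- function(config) nrow(config$positions)
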