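#' Write configurations as extended-XYZ frames
#'
#' One frame per configuration: bead count, then a comment line carrying the
#' cubic lattice, the column layout (`Properties=...`), the step label, the
#' flexible flag and the crosslink list (`Crosslinks="i-j,..."`), then one
#' line per bead (`species x y z [vx vy vz] chain`). Velocities are written
#' only when present.
#'
#' @param configs a [polymer_config()] or a list of them (a trajectory).
#' @param path output file.
#' @param steps optional step labels, recycled over frames.
#' @param append logical; append to an existing file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(configs, path, steps = 0, append = FALSE) {
  if (inherits(configs, "polymer_config")) configs <- list(configs)
  steps <- rep_len(steps, length(configs))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (q in seq_along(configs)) {
    cfg <- configs[[q]]
    n <- n_beads(cfg)
    has_vel <- !is.null(cfg$velocities)
    props <- if (has_vel) {
      "Properties=species:S:1:pos:R:3:vel:R:3:chain:I:1"
    } else {
      "Properties=species:S:1:pos:R:3:chain:I:1"
    }
    xl <- if (nrow(cfg$crosslinks)) {
      paste(sprintf("%d-%d", cfg$crosslinks[, 1], cfg$crosslinks[, 2]),
            collapse = ",")
    } else ""
    e <- cfg$box_edge
    comment <- sprintf(
      'Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" %s Step=%s Flexible=%s Crosslinks="%s"',
      e, e, e, props, format(steps[q], scientific = FALSE),
      if (cfg$flexible) "T" else "F", xl)
    writeLines(c(as.character(n), comment), con)
    if (n == 0) next
    coords <- apply(cfg$positions, 1, function(p) sprintf("%.12g", p))
    lines <- paste("CG", coords[1, ], coords[2, ], coords[3, ])
    if (has_vel) {
      vels <- apply(cfg$velocities, 1, function(v) sprintf("%.12g", v))
      lines <- paste(lines, vels[1, ], vels[2, ], vels[3, ])
    }
    lines <- paste(lines, cfg$chain_of)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read extended-XYZ frames
#'
#' Parses frames written by [write_xyz()] back into [polymer_config()]
#' objects; positions round-trip to better than 1e-8 and topology (chains,
#' crosslinks, flexible flag) exactly.
#'
#' @param path file to read.
#' @return list of [polymer_config()] objects (length 1 for a single frame).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i])) {
      stop(sprintf("parse error at line %d: expected bead count", i))
    }
    n <- as.integer(lines[i])
    if (i + 1L > length(lines)) stop(sprintf("parse error at line %d: missing comment line", i + 1L))
    hdr <- parse_xyz_comment(lines[i + 1L], i + 1L)
    if (n == 0) {
      frames[[length(frames) + 1L]] <-
        polymer_config(matrix(numeric(0), 0, 3), integer(0), hdr$box_edge,
                       flexible = hdr$flexible)
      i <- i + 2L
      next
    }
    body <- lines[i + 1L + seq_len(n)]
    if (length(body) < n || anyNA(body)) {
      stop(sprintf("parse error at line %d: truncated frame", i))
    }
    toks <- strsplit(trimws(body), "\\s+")
    ncol_expect <- if (hdr$has_vel) 8L else 5L
    if (any(lengths(toks) != ncol_expect)) {
      bad <- which(lengths(toks) != ncol_expect)[1]
      stop(sprintf("parse error at line %d: expected %d fields",
                   i + 1L + bad, ncol_expect))
    }
    m <- matrix(unlist(toks), nrow = n, byrow = TRUE)
    pos <- matrix(as.numeric(m[, 2:4]), n, 3)
    vel <- if (hdr$has_vel) matrix(as.numeric(m[, 5:7]), n, 3) else NULL
    chain <- as.integer(m[, ncol_expect])
    frames[[length(frames) + 1L]] <-
      polymer_config(pos, chain, hdr$box_edge, velocities = vel,
                     crosslinks = hdr$crosslinks, flexible = hdr$flexible)
    i <- i + 2L + n
  }
  frames
}

parse_xyz_comment <- function(line, lineno) {
  lat <- regmatches(line, regexec('Lattice="([^"]*)"', line))[[1]]
  if (length(lat) < 2) stop(sprintf("parse error at line %d: missing Lattice", lineno))
  lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
  if (length(lv) != 9 || anyNA(lv)) {
    stop(sprintf("parse error at line %d: malformed Lattice", lineno))
  }
  xl <- regmatches(line, regexec('Crosslinks="([^"]*)"', line))[[1]]
  crosslinks <- NULL
  if (length(xl) >= 2 && nzchar(xl[2])) {
    pairs <- strsplit(strsplit(xl[2], ",")[[1]], "-")
    crosslinks <- matrix(as.integer(unlist(pairs)), ncol = 2, byrow = TRUE)
  }
  flex <- grepl("Flexible=T", line, fixed = TRUE)
  list(box_edge = lv[1], crosslinks = crosslinks, flexible = flex,
       has_vel = grepl(":vel:", line, fixed = TRUE))
}

#' Write and read a volume trace as CSV
#'
#' @param trace a trace tibble (from a `stage_result`) or a `stage_result`.
#' @param path CSV file path.
#' @return `path` invisibly / the trace tibble.
#' @export
write_volume_trace <- function(trace, path) {
  if (inherits(trace, "stage_result")) trace <- trace$trace
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume_trace
#' @export
read_volume_trace <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Serialize and restore a run configuration
#'
#' A self-describing YAML document holding the simulation parameters, system
#' spec, protocol plan, optional calibration result, output directory and base
#' seed. `read_run_config()` validates by reconstructing the typed objects
#' through their constructors, so every invariant is re-checked on load.
#'
#' @param run list with elements `params` ([sim_params()]), `spec`
#'   ([system_spec()]), `plan` ([protocol_plan()]), optional `calibration`
#'   ([calibrate_bending_constant()] result), `outdir`, `seed`.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   the validated run list.
#' @export
write_run_config <- function(run, path) {
  stopifnot(inherits(run$params, "sim_params"),
            inherits(run$spec, "system_spec"),
            inherits(run$plan, "protocol_plan"))
  doc <- list(
    format = "polyswell-run/1",
    parameters = unclass(run$params)[sim_params_fields()],
    system = unclass(run$spec),
    plan = unclass(run$plan),
    calibration = if (!is.null(run$calibration)) unclass(run$calibration),
    outdir = run$outdir %||% "polyswell-out",
    seed = run$seed
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "polyswell-run/1")) {
    stop("schema error: not a polyswell run configuration")
  }
  for (f in c("parameters", "system", "plan")) {
    if (is.null(doc[[f]])) stop(sprintf("schema error: missing '%s' block", f))
  }
  params <- do.call(sim_params, doc$parameters)
  sys <- doc$system
  spec <- system_spec(sys$n_chains, sys$dp, sys$box_edge,
                      min_separation = sys$min_separation,
                      seed = sys$seed)
  pl <- doc$plan
  plan <- protocol_plan(pl$n_chains, pl$dp, pl$initial_box,
                        lapply(pl$compression_targets, function(ct)
                          list(target_edge = ct$target_edge,
                               n_steps = ct$n_steps)),
                        assembly_steps = pl$assembly_steps,
                        n_conformations = pl$n_conformations,
                        pcl_values = unlist(pl$pcl_values),
                        stage_steps = pl$stage_steps,
                        n_replicas = pl$n_replicas,
                        seeds = unlist(pl$seeds),
                        min_separation = pl$min_separation)
  calibration <- if (!is.null(doc$calibration)) {
    structure(doc$calibration, class = "calibration_result")
  }
  list(params = params, spec = spec, plan = plan, calibration = calibration,
       outdir = doc$outdir, seed = doc$seed)
}
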