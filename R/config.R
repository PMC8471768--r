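#' Tracker configuration
#'
#' Collects every tunable of the tracking pipeline in one validated list.
#' Defaults follow the published operating point of the method
#' (`n_particles = 200`, `lambda_scale = 6`, `branch_angle = 50` degrees,
#' `stop_threshold = 5`); the remaining values are the package defaults for
#' quantities the method leaves open, documented in the methods vignette.
#'
#' @param n_particles number of particles retained after resampling (N_T).
#' @param step_size tracking step / successor-sphere radius gamma, mm.
#' @param lambda_scale scale factor applied to the Jensen-Shannon distance
#'   before the smoothstep weighting (lambda).
#' @param branch_angle bifurcation angle threshold alpha, degrees; a cluster
#'   split subtending more than this fires a branch.
#' @param stop_threshold stopping threshold beta on the summed candidate
#'   likelihood tau.
#' @param patch_pixels tangent-patch side length in pixels (the classifier
#'   input size).
#' @param patch_spacing in-plane sampling pitch of tangent patches, mm/pixel.
#' @param successor_count candidate successors drawn per particle per step.
#' @param histogram_bins bins of the patch intensity histogram.
#' @param dbscan_eps DBSCAN neighbourhood radius for bifurcation clustering,
#'   mm; defaults to `0.75 * step_size`.
#' @param dbscan_min_pts DBSCAN core-point minimum.
#' @param important_mass_fraction vesselness mass retained when selecting
#'   the "important" candidates clustered for bifurcation detection, in
#'   (0, 1].
#' @param proposal_prior_fraction fraction of successor candidates whose
#'   polar angle is drawn from the direction prior rather than uniformly
#'   over the forward cap (importance-corrected either way), in [0, 1).
#' @param max_steps hard per-vessel step bound.
#' @param rng_seed integer seed driving all tracker randomness.
#' @return A validated `tracker_config` list.
#' @examples
#' cfg <- tracker_config(step_size = 0.8)
#' cfg$dbscan_eps  # follows the step size
#' @export
tracker_config <- function(n_particles = 200L,
                           step_size = 1.0,
                           lambda_scale = 6,
                           branch_angle = 50,
                           stop_threshold = 5,
                           patch_pixels = 32L,
                           patch_spacing = 0.25,
                           successor_count = 5L,
                           histogram_bins = 32L,
                           dbscan_eps = NULL,
                           dbscan_min_pts = 4L,
                           important_mass_fraction = 0.8,
                           proposal_prior_fraction = 0.5,
                           max_steps = 500L,
                           rng_seed = 1L) {
  if (is.null(dbscan_eps)) dbscan_eps <- 0.75 * step_size
  cfg <- list(
    n_particles = as.integer(n_particles),
    step_size = as.numeric(step_size),
    lambda_scale = as.numeric(lambda_scale),
    branch_angle = as.numeric(branch_angle),
    stop_threshold = as.numeric(stop_threshold),
    patch_pixels = as.integer(patch_pixels),
    patch_spacing = as.numeric(patch_spacing),
    successor_count = as.integer(successor_count),
    histogram_bins = as.integer(histogram_bins),
    dbscan_eps = as.numeric(dbscan_eps),
    dbscan_min_pts = as.integer(dbscan_min_pts),
    important_mass_fraction = as.numeric(important_mass_fraction),
    proposal_prior_fraction = as.numeric(proposal_prior_fraction),
    max_steps = as.integer(max_steps),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "tracker_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_particles >= 2L,
    cfg$step_size > 0,
    cfg$lambda_scale > 0,
    cfg$branch_angle > 0, cfg$branch_angle < 180,
    cfg$stop_threshold >= 0,
    cfg$patch_pixels >= 2L,
    cfg$patch_spacing > 0,
    cfg$histogram_bins >= 2L,
    cfg$dbscan_eps > 0,
    cfg$dbscan_min_pts >= 1L,
    cfg$important_mass_fraction > 0, cfg$important_mass_fraction <= 1,
    cfg$proposal_prior_fraction >= 0, cfg$proposal_prior_fraction < 1,
    cfg$max_steps >= 1L
  )
  if (cfg$successor_count < 1L) {
    stop("successor_count must be at least 1", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.tracker_config <- function(x, ...) {
  cat("<tracker_config>\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read / write a tracker configuration as flat key = value text
#'
#' Keys mirror the [tracker_config()] argument names; unknown keys are an
#' error. Values in `...` (for `read_config`) override the file.
#'
#' @param path file to read or write.
#' @param ... overrides applied after reading.
#' @return `read_config()` a `tracker_config`; `write_config()` invisibly `NULL`.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed config line in ", path, call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2L)))
  known <- names(formals(tracker_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- stats::setNames(as.list(vals), keys)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(tracker_config, args)
}

#' @rdname read_config
#' @param cfg a [tracker_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tracker_config"))
  writeLines(sprintf("%s = %.9g", names(cfg), as.numeric(unlist(cfg))), path)
  invisible(NULL)
}
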