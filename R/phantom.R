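#' Specification of a synthetic vessel phantom
#'
#' Describes a CT-like test volume containing one bright tubular tree on a
#' darker background: a parent curve (straight, planar arc, or helix), a
#' linearly tapering radius profile, optional child branches, Gaussian
#' per-voxel intensity noise and a partial-volume-like Gaussian blur. All
#' randomness derives from `rng_seed` through two named substreams (geometry,
#' noise) so geometry can be held fixed while noise varies.
#'
#' Default intensities (vessel 400 +/- 30, background 50 +/- 30, blur sigma
#' 0.4 mm) mimic contrast-enhanced coronary lumen against myocardium/fat on
#' a HU-like scale without claiming calibration.
#'
#' @param shape volume size in voxels (length 3).
#' @param spacing voxel spacing, mm (length 3).
#' @param curve parent curve family: "straight", "curved" (planar arc) or
#'   "helix".
#' @param length parent vessel length, mm.
#' @param arc_angle total turning of the "curved" family, degrees.
#' @param helix_radius,helix_pitch helix geometry, mm (per turn for pitch).
#' @param radius_proximal,radius_distal lumen radius at the two ends, mm
#'   (linear taper in arclength); must lie in `[0.2, 5]`.
#' @param branches data frame with columns `at_frac` (arclength fraction of
#'   the parent in (0,1)), `angle` (branch angle off the parent tangent,
#'   degrees, in (0, 120)), `radius_factor` (child radius as a fraction of
#'   the local parent radius) and `length` (child length, mm).
#' @param vessel_mean,vessel_sd,bg_mean,bg_sd intensity model.
#' @param blur_sigma Gaussian blur, mm (0 disables).
#' @param rng_seed integer seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         spacing = c(0.35, 0.35, 0.35),
                         curve = c("straight", "curved", "helix"),
                         length = 26,
                         arc_angle = 60,
                         helix_radius = 4,
                         helix_pitch = 18,
                         radius_proximal = 1.5,
                         radius_distal = 1.5,
                         branches = NULL,
                         vessel_mean = 400, vessel_sd = 30,
                         bg_mean = 50, bg_sd = 30,
                         blur_sigma = 0.4,
                         rng_seed = 1L) {
  curve <- match.arg(curve)
  if (radius_proximal < 0.2 || radius_proximal > 5 ||
      radius_distal < 0.2 || radius_distal > 5) {
    stop("radii must lie in [0.2, 5] mm", call. = FALSE)
  }
  if (is.null(branches)) {
    branches <- tibble::tibble(at_frac = numeric(), angle = numeric(),
                               radius_factor = numeric(), length = numeric())
  }
  branches <- tibble::as_tibble(branches)
  if (nrow(branches)) {
    stopifnot(all(c("at_frac", "angle", "radius_factor", "length") %in%
                    names(branches)))
    if (any(branches$angle <= 0 | branches$angle >= 120)) {
      stop("branch angles must lie in (0, 120) degrees", call. = FALSE)
    }
    if (any(branches$at_frac <= 0 | branches$at_frac >= 1)) {
      stop("branch positions must be interior arclength fractions", call. = FALSE)
    }
  }
  structure(list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    curve = curve, length = length, arc_angle = arc_angle,
    helix_radius = helix_radius, helix_pitch = helix_pitch,
    radius_proximal = radius_proximal, radius_distal = radius_distal,
    branches = branches,
    vessel_mean = vessel_mean, vessel_sd = vessel_sd,
    bg_mean = bg_mean, bg_sd = bg_sd,
    blur_sigma = blur_sigma, rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
}

# GT sampling pitch along phantom centerlines (mm)
PHANTOM_GT_SPACING <- 0.2

phantom_parent_curve <- function(spec) {
  extent <- (spec$shape - 1) * spec$spacing
  center <- extent / 2
  L <- spec$length
  s <- seq(0, L, by = PHANTOM_GT_SPACING)
  if (s[length(s)] < L) s <- c(s, L)
  if (spec$curve == "straight") {
    dir <- c(0.3, 0.18, 1); dir <- dir / sqrt(sum(dir^2))
    start <- center - dir * L / 2
    xyz <- sweep(outer(s, dir), 2, start, "+")
  } else if (spec$curve == "curved") {
    # planar arc in the x-z plane turning arc_angle over length L
    phi_tot <- spec$arc_angle * pi / 180
    R <- L / phi_tot
    phi <- s / R
    xyz <- cbind(R * (1 - cos(phi)), 0, R * sin(phi))
    xyz <- sweep(xyz, 2, colMeans(xyz))
    xyz <- sweep(xyz, 2, center, "+")
  } else {
    a <- spec$helix_radius; pitch <- spec$helix_pitch
    # arclength parametrisation of a helix of radius a, pitch per turn
    b <- pitch / (2 * pi)
    c_ <- sqrt(a^2 + b^2)
    tt <- s / c_
    xyz <- cbind(a * cos(tt), a * sin(tt), b * tt)
    xyz <- sweep(xyz, 2, colMeans(xyz))
    xyz <- sweep(xyz, 2, center, "+")
  }
  r <- spec$radius_proximal + (spec$radius_distal - spec$radius_proximal) * s / L
  centerline(cbind(xyz, r), label = "parent")
}

rotate_about_axis <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Rasterises the tree by a signed-distance tube sweep (a voxel is in-vessel
#' iff its distance to the nearest centerline sample is below the local,
#' arclength-interpolated radius), draws per-voxel intensities from the
#' vessel / background normal models, and applies a Gaussian blur emulating
#' partial-volume averaging. Fully deterministic given `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_image()]), `tree` (a
#'   [vessel_tree()] with radii, sampled every 0.2 mm) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  seeds <- derive_seeds(spec$rng_seed, 2L)

  # -- geometry substream
  old <- .Random.seed_save()
  set.seed(seeds[1])
  parent <- phantom_parent_curve(spec)
  branches <- list(parent)
  links <- NULL
  if (nrow(spec$branches)) {
    pdir <- centerline_directions(parent)
    seg <- c(0, cumsum(sqrt(rowSums(diff(cl_xyz(parent))^2))))
    total <- seg[length(seg)]
    lk <- list()
    for (bi in seq_len(nrow(spec$branches))) {
      b <- spec$branches[bi, ]
      at_i <- which.min(abs(seg - b$at_frac * total))
      origin <- as.numeric(cl_xyz(parent)[at_i, ])
      d0 <- pdir[at_i, ]
      fr <- make_frame(d0)
      az <- stats::runif(1, 0, 2 * pi)
      perp <- cos(az) * fr$u + sin(az) * fr$v
      cdir <- rotate_about_axis(d0, cross3(d0, perp), b$angle * pi / 180)
      cdir <- cdir / sqrt(sum(cdir^2))
      sb <- seq(0, b$length, by = PHANTOM_GT_SPACING)
      if (sb[length(sb)] < b$length) sb <- c(sb, b$length)
      r0 <- parent$r[at_i] * b$radius_factor
      child_xyz <- sweep(outer(sb, cdir), 2, origin, "+")
      # drop the shared origin point so consecutive points stay distinct
      child <- centerline(cbind(child_xyz, r0)[-1, , drop = FALSE],
                          label = sprintf("branch_%d", bi))
      branches <- c(branches, list(child))
      lk[[bi]] <- tibble::tibble(parent_branch = 1L, parent_point = at_i,
                                 child_branch = length(branches))
    }
    links <- dplyr::bind_rows(lk)
  }
  tree <- vessel_tree(branches, links)

  # -- bounds check: tree must fit with a 2-radius margin
  extent <- (spec$shape - 1) * spec$spacing
  pts <- tree_points(tree)
  margin <- 2 * pts$r
  if (any(pts$x < margin - 1e-9) || any(pts$y < margin - 1e-9) ||
      any(pts$z < margin - 1e-9) ||
      any(pts$x > extent[1] - margin + 1e-9) ||
      any(pts$y > extent[2] - margin + 1e-9) ||
      any(pts$z > extent[3] - margin + 1e-9)) {
    .Random.seed_restore(old)
    stop("phantom tree does not fit inside the volume with a 2-radius margin",
         call. = FALSE)
  }

  # -- rasterise: min distance to tree + local radius, stamped per GT point
  d <- spec$shape
  dist2 <- array(Inf, d)
  radloc <- array(0, d)
  sp <- spec$spacing
  stamp_r <- max(pts$r) + 2 * spec$blur_sigma + 2 * max(sp)
  nx <- ceiling(stamp_r / sp[1]); ny <- ceiling(stamp_r / sp[2])
  nz <- ceiling(stamp_r / sp[3])
  gx <- (-nx):nx; gy <- (-ny):ny; gz <- (-nz):nz
  # voxel-offset grid around a stamp centre, world displacements
  offs <- as.matrix(expand.grid(ix = gx, iy = gy, iz = gz))
  disp2 <- (offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 + (offs[, 3] * sp[3])^2
  keep <- disp2 <= stamp_r^2
  offs <- offs[keep, , drop = FALSE]
  pxyz <- as.matrix(pts[, c("x", "y", "z")])
  vox <- round(sweep(pxyz, 2, sp, "/")) + 1   # nearest voxel index per GT point
  for (i in seq_len(nrow(pxyz))) {
    ci <- vox[i, ]
    ii <- offs[, 1] + ci[1]; jj <- offs[, 2] + ci[2]; kk <- offs[, 3] + ci[3]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    ii <- ii[ok]; jj <- jj[ok]; kk <- kk[ok]
    flat <- ii + d[1] * (jj - 1) + d[1] * d[2] * (kk - 1)
    wx <- (ii - 1) * sp[1] - pxyz[i, 1]
    wy <- (jj - 1) * sp[2] - pxyz[i, 2]
    wz <- (kk - 1) * sp[3] - pxyz[i, 3]
    dd <- wx * wx + wy * wy + wz * wz
    closer <- dd < dist2[flat]
    fc <- flat[closer]
    dist2[fc] <- dd[closer]
    radloc[fc] <- pts$r[i]
  }
  inside <- sqrt(dist2) < radloc

  # -- noise substream
  set.seed(seeds[2])
  vals <- array(stats::rnorm(prod(d), spec$bg_mean, spec$bg_sd), d)
  n_in <- sum(inside)
  if (n_in) vals[inside] <- stats::rnorm(n_in, spec$vessel_mean, spec$vessel_sd)
  if (spec$blur_sigma > 0) vals <- gaussian_blur3(vals, spec$blur_sigma, sp)
  .Random.seed_restore(old)

  list(volume = volume_image(vals, sp, c(0, 0, 0)), tree = tree, spec = spec)
}

# separable 3D Gaussian blur with zero-phase replicated-edge padding
gaussian_blur3 <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    half <- max(1L, ceiling(3 * sig))
    k <- stats::dnorm((-half):half, sd = sig)
    k <- k / sum(k)
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(arr, perm)
    da <- dim(a)
    m <- matrix(a, da[1], da[2] * da[3])
    pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
                 m[rep(da[1], half), , drop = FALSE])
    out <- matrix(0, da[1], ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[j:(j + da[1] - 1L), , drop = FALSE]
    }
    arr <- aperm(array(out, da), order(perm))
  }
  arr
}

derive_seeds <- function(seed, n) {
  old <- .Random.seed_save()
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  .Random.seed_restore(old)
  s
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Canonical ten-case phantom suite
#'
#' A fixed family of seeded phantoms spanning the geometries and image
#' conditions the tracker must handle: straight, gently curved and helical
#' tubes, a 2.5 to 0.8 mm taper, a tube ending mid-volume, Y-bifurcations at
#' 60 and 90 degrees, a two-bifurcation tree, a low-contrast tube and a
#' high-noise tube.
#'
#' @param rng_seed base seed; case seeds are derived from it.
#' @return named list of 10 entries, each `list(volume, tree, spec, name)`.
#' @export
default_phantom_suite <- function(rng_seed = 1L) {
  seeds <- derive_seeds(rng_seed, 10L)
  two_branch <- tibble::tibble(at_frac = c(0.4, 0.7), angle = c(55, 65),
                               radius_factor = c(0.7, 0.7), length = c(9, 8))
  specs <- list(
    straight = phantom_spec(rng_seed = seeds[1]),
    curved = phantom_spec(curve = "curved", arc_angle = 60, rng_seed = seeds[2]),
    helix = phantom_spec(curve = "helix", length = 30, helix_radius = 5,
                         helix_pitch = 22, radius_proximal = 1.2,
                         radius_distal = 1.2, rng_seed = seeds[3]),
    taper = phantom_spec(radius_proximal = 2.5, radius_distal = 0.8,
                         length = 22, rng_seed = seeds[4]),
    ends_mid = phantom_spec(length = 14, rng_seed = seeds[5]),
    y60 = phantom_spec(length = 24,
                       branches = tibble::tibble(at_frac = 0.55, angle = 60,
                                                 radius_factor = 0.75, length = 9),
                       rng_seed = seeds[6]),
    y90 = phantom_spec(length = 24,
                       branches = tibble::tibble(at_frac = 0.55, angle = 90,
                                                 radius_factor = 0.75, length = 8),
                       rng_seed = seeds[7]),
    tree2 = phantom_spec(length = 26, branches = two_branch,
                         rng_seed = seeds[8]),
    low_contrast = phantom_spec(vessel_mean = 150, rng_seed = seeds[9]),
    high_noise = phantom_spec(vessel_sd = 80, bg_sd = 80, rng_seed = seeds[10])
  )
  out <- lapply(names(specs), function(nm) {
    ph <- generate_phantom(specs[[nm]])
    ph$name <- nm
    ph
  })
  stats::setNames(out, names(specs))
}
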