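#' Deterministic orthonormal frame perpendicular to a direction
#'
#' Builds an in-plane basis (u, v) so that (u, v, normal) is a right-handed
#' orthonormal triad. u comes from Gram-Schmidt orthogonalisation of the
#' canonical axis least aligned with `normal` (ties broken by axis order),
#' then v = normal x u. The construction is deterministic and continuous in
#' `normal` except where the selected axis switches.
#'
#' @param normal non-zero 3-vector; normalised internally.
#' @return list with unit vectors `u`, `v`, `normal`.
#' @export
make_frame <- function(normal) {
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (!is.finite(nn) || nn == 0) stop("normal must be non-zero", call. = FALSE)
  n <- n / nn
  axis <- diag(3)[, which.min(abs(n)), drop = TRUE]
  u <- axis - sum(axis * n) * n
  u <- u / sqrt(sum(u^2))
  v <- cross3(n, u)
  list(u = u, v = v, normal = n)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise frames for an n x 3 matrix of unit normals (same construction as
# make_frame, vectorised). Returns list(u = n x 3, v = n x 3).
make_frames <- function(normals) {
  n <- normals / sqrt(rowSums(normals^2))
  pick <- max.col(-abs(n), ties.method = "first")
  axis <- matrix(0, nrow(n), 3)
  axis[cbind(seq_len(nrow(n)), pick)] <- 1
  u <- axis - rowSums(axis * n) * n
  u <- u / sqrt(rowSums(u^2))
  v <- cbind(n[, 2] * u[, 3] - n[, 3] * u[, 2],
             n[, 3] * u[, 1] - n[, 1] * u[, 3],
             n[, 1] * u[, 2] - n[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Extract a 2D tangent patch from a volume
#'
#' Resamples the plane through `centroid` orthogonal to `normal` on a regular
#' `patch_pixels` x `patch_pixels` grid with pitch `patch_spacing` mm/pixel,
#' by trilinear interpolation. When the tracking direction is well aligned
#' with the vessel, the lumen appears as a near-circular bright disc centred
#' in the patch; misaligned patches show elongated or irregular shapes.
#' Samples falling outside the volume take the volume's minimum intensity.
#'
#' @param vol a [volume_image()].
#' @param centroid patch centre, world mm; must lie inside the volume.
#' @param normal patch normal (the local tracking direction).
#' @param cfg a [tracker_config()] supplying `patch_pixels` and `patch_spacing`.
#' @return A `tangent_patch`: list with `pixels` (matrix), `centroid`,
#'   `normal`, `basis` (list u, v), `in_plane_spacing`.
#' @export
extract_tangent_patch <- function(vol, centroid, normal, cfg = tracker_config()) {
  centroid <- as.numeric(centroid)
  if (!in_volume(vol, centroid)) {
    stop("patch centroid lies outside the volume", call. = FALSE)
  }
  fr <- make_frame(normal)
  px <- extract_patches(vol, matrix(centroid, 1), matrix(fr$normal, 1), cfg)
  structure(list(
    pixels = matrix(px[1, ], cfg$patch_pixels, cfg$patch_pixels),
    centroid = centroid, normal = fr$normal,
    basis = list(u = fr$u, v = fr$v),
    in_plane_spacing = cfg$patch_spacing
  ), class = "tangent_patch")
}

# Batch tangent-patch sampling: one row of pixel intensities per centroid.
# pixels are ordered with the u-axis index fastest; row i reshapes to the
# patch_pixels x patch_pixels image of patch i.
extract_patches <- function(vol, centroids, normals, cfg) {
  P <- cfg$patch_pixels
  s <- cfg$patch_spacing
  n <- nrow(centroids)
  fr <- make_frames(normals)
  cc <- (P - 1) / 2
  g <- (seq_len(P) - 1 - cc) * s
  du <- rep(g, times = P)   # u offset, fastest index
  dv <- rep(g, each = P)
  P2 <- P * P
  ii <- rep(seq_len(n), each = P2)
  du_all <- rep(du, times = n)
  dv_all <- rep(dv, times = n)
  pos <- centroids[ii, , drop = FALSE] +
    du_all * fr$u[ii, , drop = FALSE] +
    dv_all * fr$v[ii, , drop = FALSE]
  vals <- interp_volume(vol, pos)
  matrix(vals, nrow = n, ncol = P2, byrow = TRUE)
}

#' @export
print.tangent_patch <- function(x, ...) {
  cat(sprintf("<tangent_patch> %d x %d px @ %.3g mm/px, centroid (%.2f, %.2f, %.2f) mm\n",
              nrow(x$pixels), ncol(x$pixels), x$in_plane_spacing,
              x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Draw candidate successor states on the step sphere
#'
#' Candidates lie on the sphere of radius `step_size` around `x`; their
#' directions are drawn uniformly over the forward hemispherical cap
#' (angle to `d_prev` at most 90 degrees). The proposal is deliberately
#' flat over the cap — the direction-change prior enters through the
#' importance weight, not the proposal, so it is not double-counted.
#'
#' @param x current position, mm.
#' @param d_prev current unit direction.
#' @param cfg a [tracker_config()] (`step_size`, `successor_count`).
#' @param count number of candidates; defaults to `cfg$successor_count`.
#' @return list with `x_next` (count x 3) and `d_next` (count x 3, unit rows).
#'   Uses the R random number generator; seed via [set.seed()].
#' @export
sample_successors <- function(x, d_prev, cfg = tracker_config(), count = NULL) {
  if (is.null(count)) count <- cfg$successor_count
  if (count < 1L) stop("successor count must be at least 1", call. = FALSE)
  res <- sample_successors_batch(matrix(as.numeric(x), 1),
                                 matrix(as.numeric(d_prev), 1), cfg,
                                 count_per = count)
  res
}

# Batch form: xs / ds are m x 3 (one row per particle); draws count_per
# candidates for every particle. Rows of the output are grouped by particle
# (particle 1's candidates first). Returns x_next, d_next, parent index.
#
# When a direction prior is supplied the proposal is a mixture: a fraction
# `mix` of candidates draw their polar angle from the prior histogram
# (truncated to the forward cap, uniform-in-cosine within a bin), the rest
# are uniform over the cap. `dir_weight` is then the exact importance
# factor p_prior(bin) / q(direction), so multiplying it into the particle
# weight neither double-counts the prior (for prior-guided draws) nor
# ignores it (for exploratory draws). Without a prior the proposal is the
# plain uniform cap and `dir_weight` is NULL.
sample_successors_batch <- function(xs, ds, cfg, count_per = cfg$successor_count,
                                    prior = NULL, mix = 0.5) {
  m <- nrow(xs)
  ds <- ds / sqrt(rowSums(ds^2))
  n <- m * count_per
  parent <- rep(seq_len(m), each = count_per)
  fr <- make_frames(ds)
  dir_weight <- NULL

  if (is.null(prior)) {
    z <- stats::runif(n)               # cos(angle) uniform on [0,1] = forward cap
  } else {
    # forward-cap truncation of the prior histogram
    breaks <- prior$breaks
    lo <- breaks[-length(breaks)]
    hi <- breaks[-1]
    cap_lo <- pmin(lo, 90)
    cap_hi <- pmin(hi, 90)
    band <- pmax(0, cos(cap_lo * pi / 180) - cos(cap_hi * pi / 180))
    p_trunc <- ifelse(band > 0, prior$prob, 0)
    p_trunc <- p_trunc / sum(p_trunc)
    from_prior <- stats::runif(n) < mix
    z <- stats::runif(n)               # uniform-cap draws by default
    np <- sum(from_prior)
    if (np) {
      bin <- sample.int(length(p_trunc), np, replace = TRUE, prob = p_trunc)
      zhi <- cos(cap_lo[bin] * pi / 180)
      zlo <- cos(cap_hi[bin] * pi / 180)
      z[from_prior] <- zlo + stats::runif(np) * (zhi - zlo)
    }
  }
  phi <- stats::runif(n, 0, 2 * pi)
  rho <- sqrt(pmax(0, 1 - z^2))
  d_next <- z * ds[parent, , drop = FALSE] +
    (rho * cos(phi)) * fr$u[parent, , drop = FALSE] +
    (rho * sin(phi)) * fr$v[parent, , drop = FALSE]
  d_next <- d_next / sqrt(rowSums(d_next^2))
  x_next <- xs[parent, , drop = FALSE] + cfg$step_size * d_next

  if (!is.null(prior)) {
    ang <- acos(pmin(1, pmax(0, z))) * 180 / pi
    bin_of <- findInterval(ang, prior$breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
    # densities per unit cos(angle) (azimuth uniform in both components)
    q_prior <- ifelse(band[bin_of] > 0, p_trunc[bin_of] / band[bin_of], 0)
    q <- mix * q_prior + (1 - mix) * 1   # uniform cap: density 1 over z in [0,1]
    dir_weight <- prior$prob[bin_of] / q
  }
  list(x_next = x_next, d_next = d_next, parent = parent,
       dir_weight = dir_weight)
}
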