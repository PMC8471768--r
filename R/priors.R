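#' Learn a direction-change histogram prior from reference centerlines
#'
#' Resamples each centerline to the tracking step size, measures the angle
#' between consecutive unit directions, and histograms those angles over
#' `[0, 180]` degrees. Empty bins receive a small floor and the histogram is
#' renormalised, so sharp turns unseen in training are strongly penalised
#' but never hard-forbidden. Coronary references concentrate almost all mass
#' below ~30 degrees per step, which is what makes this an effective
#' smoothness prior.
#'
#' @param centerlines list of [centerline()]s (>= 3 points each after
#'   resampling).
#' @param step arclength resampling spacing, mm — use the tracker step size
#'   so angles are scale-consistent with tracking.
#' @param n_bins number of equal-width bins over `[0, 180]` degrees.
#' @param floor probability floor given to empty bins before renormalisation.
#' @return A `direction_prior`: list with `breaks` (degrees, length
#'   `n_bins + 1`) and `prob` (per-bin probabilities summing to 1).
#' @export
learn_direction_prior <- function(centerlines, step = 1.0, n_bins = 36L,
                                  floor = 1e-4) {
  angles <- unlist(lapply(centerlines, function(cl) {
    rs <- resample_centerline(cl, step)
    xyz <- cl_xyz(rs)
    if (nrow(xyz) < 3L) return(numeric())
    d <- xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE]
    d <- d / sqrt(rowSums(d^2))
    dots <- rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
    acos(pmin(1, pmax(-1, dots))) * 180 / pi
  }))
  if (!length(angles)) {
    stop("no direction-change angles could be extracted", call. = FALSE)
  }
  breaks <- seq(0, 180, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(angles, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  prob <- counts / sum(counts)
  prob[prob == 0] <- floor
  prob <- prob / sum(prob)
  structure(list(breaks = breaks, prob = prob), class = "direction_prior")
}

#' @export
print.direction_prior <- function(x, ...) {
  nb <- length(x$prob)
  mode_bin <- which.max(x$prob)
  cat(sprintf("<direction_prior> %d bins of %.3g deg, mode bin [%g, %g) deg (p = %.3f)\n",
              nb, diff(x$breaks[1:2]), x$breaks[mode_bin], x$breaks[mode_bin + 1],
              x$prob[mode_bin]))
  invisible(x)
}

#' Evaluate the direction prior for a direction change
#'
#' Returns the probability of the histogram bin containing
#' `acos(<d_prev, d_next>)`.
#'
#' @param prior a `direction_prior` from [learn_direction_prior()].
#' @param d_prev,d_next unit 3-vectors (checked to 1e-6).
#' @return scalar bin probability.
#' @export
direction_prior_eval <- function(prior, d_prev, d_next) {
  check_unit(d_prev); check_unit(d_next)
  ang <- acos(min(1, max(-1, sum(d_prev * d_next)))) * 180 / pi
  prior$prob[angle_bin(prior, ang)]
}

check_unit <- function(v) {
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6) {
    stop("direction must be a unit vector", call. = FALSE)
  }
  invisible(v)
}

angle_bin <- function(prior, ang_deg) {
  findInterval(ang_deg, prior$breaks, rightmost.closed = TRUE, all.inside = TRUE)
}

# Vectorised bin-probability lookup for a vector of angles in degrees.
direction_prior_lookup <- function(prior, ang_deg) {
  prior$prob[findInterval(ang_deg, prior$breaks, rightmost.closed = TRUE,
                          all.inside = TRUE)]
}

#' Persist / load a direction prior as two-column text
#'
#' One `bin_lower_edge probability` row per bin (degrees).
#'
#' @param prior a `direction_prior`.
#' @param path file path.
#' @export
write_direction_prior <- function(prior, path) {
  writeLines(sprintf("%.9g %.17g", prior$breaks[-length(prior$breaks)],
                     prior$prob), path)
  invisible(NULL)
}

#' @rdname write_direction_prior
#' @export
read_direction_prior <- function(path) {
  m <- unname(as.matrix(utils::read.table(path)))
  nb <- nrow(m)
  width <- if (nb > 1) m[2, 1] - m[1, 1] else 180
  structure(list(breaks = c(m[, 1], m[nb, 1] + width), prob = m[, 2]),
            class = "direction_prior")
}

# ---- patch histograms and similarity --------------------------------------

#' Normalised intensity histogram of a tangent patch
#'
#' Bin edges are fixed globally (same `range` for every patch in a run) so
#' histograms of different patches are comparable; intensities outside the
#' range are clamped into the end bins.
#'
#' @param patch a `tangent_patch`, or any numeric vector/matrix of
#'   intensities.
#' @param n_bins number of bins (>= 2).
#' @param range length-2 intensity interval shared across the run; for CT
#'   volumes use [intensity_range()] of the volume.
#' @return A `patch_histogram`: list with `prob` (sums to 1) and `range`.
#' @export
patch_histogram <- function(patch, n_bins = 32L, range = c(0, 1)) {
  vals <- if (inherits(patch, "tangent_patch")) patch$pixels else patch
  vals <- as.numeric(vals)
  range <- as.numeric(range)
  if (length(range) != 2L || !all(is.finite(range)) || range[2] <= range[1]) {
    stop("degenerate intensity range for patch histogram", call. = FALSE)
  }
  if (n_bins < 2L) stop("patch histogram needs at least 2 bins", call. = FALSE)
  idx <- bin_index(vals, n_bins, range)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(prob = counts / length(vals), range = range),
            class = "patch_histogram")
}

bin_index <- function(vals, n_bins, range) {
  idx <- floor((vals - range[1]) / (range[2] - range[1]) * n_bins) + 1
  pmin(pmax(idx, 1L), n_bins)
}

# Batch histograms: one row of bin probabilities per row of `pixels`
# (n x P^2 intensity matrix). Used by the tracker hot loop.
patch_histograms <- function(pixels, n_bins, range) {
  n <- nrow(pixels)
  idx <- bin_index(as.numeric(pixels), n_bins, range)  # column-major over pixels
  row <- rep(seq_len(n), times = ncol(pixels))
  code <- row + n * (idx - 1L)
  counts <- matrix(tabulate(code, nbins = n * n_bins), n, n_bins)
  counts / ncol(pixels)
}

#' Robust global intensity range of a volume
#'
#' The 1st-99th intensity percentiles, used as the shared binning range for
#' all patch histograms of a run.
#'
#' @param vol a [volume_image()].
#' @param probs two quantile probabilities.
#' @return length-2 numeric.
#' @export
intensity_range <- function(vol, probs = c(0.01, 0.99)) {
  as.numeric(stats::quantile(vol$data, probs = probs, names = FALSE))
}

#' Jensen-Shannon divergence between two patch histograms
#'
#' `D(P||Q) = KL(P||M)/2 + KL(Q||M)/2` with `M = (P+Q)/2`, logarithms base 2
#' so the value lies exactly in `[0, 1]`: 0 for identical distributions, 1
#' for disjoint support. Terms with `P(x) = 0` contribute zero.
#'
#' @param P,Q `patch_histogram`s on the same binning, or bare probability
#'   vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
js_divergence <- function(P, Q) {
  p <- if (inherits(P, "patch_histogram")) P$prob else as.numeric(P)
  q <- if (inherits(Q, "patch_histogram")) Q$prob else as.numeric(Q)
  if (length(p) != length(q)) {
    stop("histograms must share a common binning", call. = FALSE)
  }
  m <- (p + q) / 2
  0.5 * kl_div2(p, m) + 0.5 * kl_div2(q, m)
}

kl_div2 <- function(p, m) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / m[nz]))
}

# Row-wise JS divergence between each row of P (n x B) and a single
# histogram q (length B); base-2 logs. Tracker hot loop helper.
js_divergence_rows <- function(P, q) {
  M <- 0.5 * sweep(P, 2, q, "+")
  termP <- P * log2(P / M); termP[P == 0] <- 0
  Qm <- matrix(q, nrow(P), length(q), byrow = TRUE)
  termQ <- Qm * log2(Qm / M); termQ[Qm == 0] <- 0
  0.5 * rowSums(termP) + 0.5 * rowSums(termQ)
}

#' Cubic smoothstep weighting of a similarity distance
#'
#' `w(x) = 2x^3 - 3x^2 + 1` on `[0, 1]` and 0 outside: a smooth monotone
#' ramp from `w(0) = 1` to `w(1) = 0` that converts a scaled divergence into
#' a probability-like weight.
#'
#' @param x numeric vector.
#' @return values in `[0, 1]`, same length as `x`.
#' @export
smoothstep_weight <- function(x) {
  out <- ifelse(x >= 0 & x <= 1, 2 * x^3 - 3 * x^2 + 1, 0)
  out[x < 0] <- 0
  out
}

#' Patch-similarity transition prior
#'
#' `p = w(lambda * D(next || prev))`: identical intensity distributions give
#' prior 1; once the scaled Jensen-Shannon distance reaches 1 the prior is 0.
#' The scale `lambda` (default 6 in the tracker) calibrates how much
#' distributional drift one tracking step may introduce.
#'
#' @param prev,next_ `patch_histogram`s on the same binning.
#' @param lambda positive scale factor.
#' @return scalar in `[0, 1]`.
#' @export
patch_prior <- function(prev, next_, lambda = 6) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  smoothstep_weight(lambda * js_divergence(next_, prev))
}

#' Full first-order Markov transition prior
#'
#' Product of the direction-change term (learned histogram) and the
#' patch-similarity term: the tracker prefers steps that neither turn
#' sharply nor change the local intensity distribution.
#'
#' @param d_prev,d_next unit directions before and after the step.
#' @param hist_prev,hist_next `patch_histogram`s of the previous and
#'   candidate tangent patches.
#' @param prior a `direction_prior`.
#' @param lambda patch-similarity scale.
#' @return scalar `>= 0` (at most the maximal direction-bin probability).
#' @export
transition_prior <- function(d_prev, d_next, hist_prev, hist_next,
                             prior, lambda = 6) {
  direction_prior_eval(prior, d_prev, d_next) *
    patch_prior(hist_prev, hist_next, lambda)
}
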