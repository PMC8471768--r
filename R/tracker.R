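#' Initialise the particle population from ostium seed points
#'
#' All particles start at `seed1` with the initial main direction
#' `(seed1 - seed0) / ||seed1 - seed0||` and uniform weights `1/N_T`; the
#' state estimate starts at `seed1`. The cached patch histogram of every
#' particle is the histogram of the tangent patch at the seed.
#'
#' @param vol a [volume_image()].
#' @param seed0,seed1 distinct world points (mm) inside the volume; for
#'   coronary tracking these are two points at the ostium defining the
#'   initial direction.
#' @param cfg a [tracker_config()].
#' @return A `particle_set`: list with `x` (N x 3), `d` (N x 3 unit rows),
#'   `w` (sums to 1), `hist` (N x bins), `t`, `estimate`, `intensity_range`.
#' @export
init_tracker <- function(vol, seed0, seed1, cfg = tracker_config()) {
  seed0 <- as.numeric(seed0); seed1 <- as.numeric(seed1)
  if (sqrt(sum((seed1 - seed0)^2)) < 1e-12) {
    stop("seed points must be distinct", call. = FALSE)
  }
  if (!in_volume(vol, seed0) || !in_volume(vol, seed1)) {
    stop("seed points must lie inside the volume", call. = FALSE)
  }
  d0 <- (seed1 - seed0) / sqrt(sum((seed1 - seed0)^2))
  particle_set_at(vol, seed1, d0, cfg)
}

particle_set_at <- function(vol, position, direction, cfg) {
  N <- cfg$n_particles
  direction <- direction / sqrt(sum(direction^2))
  rng <- intensity_range(vol)
  px <- extract_patches(vol, matrix(position, 1), matrix(direction, 1), cfg)
  h0 <- patch_histograms(px, cfg$histogram_bins, rng)
  structure(list(
    x = matrix(position, N, 3, byrow = TRUE),
    d = matrix(direction, N, 3, byrow = TRUE),
    w = rep(1 / N, N),
    hist = h0[rep(1L, N), , drop = FALSE],
    t = 0L,
    estimate = position,
    intensity_range = rng
  ), class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles at t = %d, estimate (%.2f, %.2f, %.2f) mm\n",
              nrow(x$x), x$t, x$estimate[1], x$estimate[2], x$estimate[3]))
  invisible(x)
}

#' Stopping statistic: summed candidate likelihoods
#'
#' The plain sum of the per-candidate vesselness probabilities evaluated at
#' one step. Deep inside a vessel most candidates score near 1 and the sum
#' is large; past the distal end it collapses towards 0. Tracking stops when
#' it falls below the configured threshold.
#'
#' @param candidate_likelihoods numeric vector of probabilities in `[0, 1]`.
#' @return scalar in `[0, length(candidate_likelihoods)]`.
#' @export
compute_tau <- function(candidate_likelihoods) {
  sum(candidate_likelihoods)
}

# JS divergence between paired rows of P and Q (both n x B), base-2 logs.
js_divergence_paired <- function(P, Q) {
  M <- (P + Q) / 2
  tp <- P * log2(P / M); tp[P == 0] <- 0
  tq <- Q * log2(Q / M); tq[Q == 0] <- 0
  0.5 * rowSums(tp) + 0.5 * rowSums(tq)
}

#' One prediction/update step of the SIR tracker
#'
#' Prediction draws `successor_count` candidates per particle on the step
#' sphere; update weights each candidate by
#' `w_parent * likelihood * transition_prior`, normalises, advances the
#' state estimate by the step size times the weight-averaged candidate
#' direction (pre-resampling weights), and systematically resamples back to
#' `n_particles` equal-weight particles.
#'
#' @param vol a [volume_image()].
#' @param S a `particle_set`.
#' @param model a `likelihood_model`.
#' @param prior a `direction_prior`.
#' @param cfg a [tracker_config()].
#' @return list with `set` (the resampled `particle_set`), `stopped`
#'   (TRUE when every candidate weight vanished), and `diag` — a list with
#'   `tau`, the pre-resampling candidate set (`x`, `d`, `w`, `hist`,
#'   `parent`, `lik`) and the previous/new estimates. Uses the R RNG.
#' @export
step_tracker <- function(vol, S, model, prior, cfg = tracker_config()) {
  cand <- sample_successors_batch(S$x, S$d, cfg, prior = prior,
                                  mix = cfg$proposal_prior_fraction)
  px <- extract_patches(vol, cand$x_next, cand$d_next, cfg)
  lik <- likelihood_batch(model, pixels = px, centroids = cand$x_next,
                          normals = cand$d_next)
  tau <- compute_tau(lik)

  hist_next <- patch_histograms(px, cfg$histogram_bins, S$intensity_range)
  jsd <- js_divergence_paired(hist_next, S$hist[cand$parent, , drop = FALSE])
  p_patch <- smoothstep_weight(cfg$lambda_scale * jsd)

  w_raw <- S$w[cand$parent] * lik * cand$dir_weight * p_patch
  tot <- sum(w_raw)
  diag_base <- list(tau = tau, estimate_prev = S$estimate)
  if (!is.finite(tot) || tot <= 0) {
    return(list(set = S, stopped = TRUE,
                diag = c(diag_base, list(estimate = S$estimate))))
  }
  w_norm <- w_raw / tot

  # state update: the estimate advances by the step size along the
  # weight-averaged candidate direction, anchored at the weighted parent
  # mean — algebraically the posterior-weighted mean successor position.
  # Anchoring at the particle cloud (rather than dead-reckoning from the
  # previous estimate) keeps the estimate centred in curved vessels.
  anchor <- colSums(w_norm * S$x[cand$parent, , drop = FALSE])
  est <- anchor + cfg$step_size * colSums(w_norm * cand$d_next)

  keep <- systematic_resample(w_norm, cfg$n_particles)
  new_set <- structure(list(
    x = cand$x_next[keep, , drop = FALSE],
    d = cand$d_next[keep, , drop = FALSE],
    w = rep(1 / cfg$n_particles, cfg$n_particles),
    hist = hist_next[keep, , drop = FALSE],
    t = S$t + 1L,
    estimate = est,
    intensity_range = S$intensity_range
  ), class = "particle_set")

  list(set = new_set, stopped = FALSE,
       diag = c(diag_base, list(
         estimate = est,
         candidates = list(x = cand$x_next, d = cand$d_next, w = w_norm,
                           hist = hist_next, parent = cand$parent, lik = lik))))
}

# Low-variance systematic resampling: n draws from normalised weights w.
systematic_resample <- function(w, n) {
  u <- (stats::runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w), left.open = TRUE) + 1L
}

# ---- DBSCAN ----------------------------------------------------------------

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN on Euclidean distances: points with at least `min_pts`
#' neighbours within `eps` (themselves included) are core points; clusters
#' are the connected components of density-reachability; non-core points
#' within `eps` of a core join its cluster, the rest are noise (label 0).
#'
#' @param x numeric matrix, one point per row (any dimension).
#' @param eps neighbourhood radius (mm).
#' @param min_pts minimum neighbourhood size for a core point.
#' @return integer labels, 0 for noise, 1..k for clusters.
#' @export
dbscan_cluster <- function(x, eps, min_pts) {
  n <- nrow(x)
  if (n == 0L) return(integer())
  d2 <- cross_dist2(x, x)
  nb <- d2 <= eps^2
  core <- rowSums(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      neigh <- which(nb[p, ])
      fresh <- neigh[labels[neigh] == 0L]
      labels[fresh] <- cl
      queue <- c(queue, fresh[core[fresh]])
    }
  }
  labels
}

#' Majority/minority bifurcation detection by particle clustering
#'
#' Selects the "important" candidates — those the vesselness classifier
#' itself calls in-vessel (likelihood at or above 0.5, the softmax decision
#' boundary) — and clusters their one-step look-ahead points
#' `x + step_size * d` (each candidate's predicted next position) with
#' DBSCAN. Right at a carina the two limb lumens still overlap spatially,
#' but the candidate headings split immediately, so the look-ahead points
#' separate one step's length down each limb; this resolves the minority
#' cluster at the branch point rather than several steps past it, without
#' introducing any additional metric parameter. When likelihoods are absent the fallback selection is the
#' smallest top-weight subset holding `important_mass_fraction` of the
#' posterior weight. Selection keys on the likelihood rather than the
#' posterior weight deliberately: at a branching site the vesselness field
#' has two lobes of comparable strength, while the direction-change prior
#' suppresses the posterior weight of the branch lobe by orders of
#' magnitude; weight-based selection would never admit the minority
#' cluster. If at least two clusters emerge, the two
#' heaviest (by summed weight) are kept; each cluster's limb direction is
#' the weighted mean heading of its members (its members are
#' alignment-filtered, so the mean heading points along the limb;
#' centroid-minus-estimate is the fallback without headings), and a
#' bifurcation is declared
#' when the angle between the limb directions exceeds `branch_angle`. The
#' heavier cluster is the majority (main vessel), the lighter the minority
#' (branch seed). Degenerate inputs yield `is_bifurcation = FALSE`.
#'
#' @param candidates list with `x` (n x 3 positions), `w` (normalised
#'   weights) and optionally `d` (unit directions) and `lik` (per-candidate
#'   vesselness), as produced in the step diagnostics.
#' @param x_hat current state estimate (the vertex of the angle).
#' @param cfg a [tracker_config()].
#' @return A `cluster_split`: list with `members` (list of index vectors),
#'   `weights` (per-cluster normalised weights), `centroids`, `directions`
#'   (unit rows), `theta` (degrees, NA when fewer than two clusters),
#'   `majority` (1 or 2), `is_bifurcation`.
#' @export
detect_bifurcation <- function(candidates, x_hat, cfg = tracker_config()) {
  w <- candidates$w
  stopifnot(length(w) == nrow(candidates$x))
  no_split <- structure(list(members = list(), weights = list(),
                             centroids = NULL, directions = NULL,
                             theta = NA_real_, majority = NA_integer_,
                             is_bifurcation = FALSE),
                        class = "cluster_split")
  if (!length(w) || sum(w) <= 0) return(no_split)

  if (!is.null(candidates$lik) && sum(candidates$lik) > 0) {
    imp <- which(candidates$lik >= 0.5)
    if (length(imp) < cfg$dbscan_min_pts) return(no_split)
  } else {
    ord <- order(w, decreasing = TRUE)
    cum <- cumsum(w[ord]) / sum(w)
    n_keep <- which(cum >= cfg$important_mass_fraction)[1]
    imp <- ord[seq_len(n_keep)]
  }
  xs <- candidates$x[imp, , drop = FALSE]
  ws <- w[imp]
  feat <- if (!is.null(candidates$d)) {
    xs + cfg$step_size * candidates$d[imp, , drop = FALSE]
  } else xs

  labels <- dbscan_cluster(feat, cfg$dbscan_eps, cfg$dbscan_min_pts)
  ks <- setdiff(unique(labels), 0L)
  if (length(ks) < 2L) return(no_split)

  mass <- vapply(ks, function(k) sum(ws[labels == k]), 1)
  top2 <- ks[order(mass, decreasing = TRUE)][1:2]
  members <- lapply(top2, function(k) imp[labels == k])
  weights <- lapply(top2, function(k) {
    wk <- ws[labels == k]; wk / sum(wk)
  })
  # cluster geometry (centroid, limb direction) uses vesselness weights:
  # inside the branch cluster the posterior weights are dominated by the
  # direction-change prior, which would drag the estimated limb direction
  # towards the main vessel and under-read the branching angle
  geom_w <- lapply(1:2, function(j) {
    gk <- if (!is.null(candidates$lik)) candidates$lik[members[[j]]]
      else w[members[[j]]]
    gk / sum(gk)
  })
  centroids <- t(vapply(1:2, function(j) {
    colSums(candidates$x[members[[j]], , drop = FALSE] * geom_w[[j]])
  }, numeric(3)))
  # limb directions: weighted mean member headings when available (each
  # cluster's members are alignment-filtered, so their mean heading points
  # along its limb, independent of how far down the limb the centroid
  # sits); fall back to centroid-minus-estimate otherwise
  if (!is.null(candidates$d)) {
    dirs <- t(vapply(1:2, function(j) {
      colSums(candidates$d[members[[j]], , drop = FALSE] * geom_w[[j]])
    }, numeric(3)))
  } else {
    dirs <- sweep(centroids, 2, x_hat)
  }
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm < 1e-9)) return(no_split)
  dirs <- dirs / nrm
  theta <- acos(min(1, max(-1, sum(dirs[1, ] * dirs[2, ])))) * 180 / pi
  structure(list(
    members = members, weights = weights, centroids = centroids,
    directions = dirs, theta = theta,
    majority = which.max(vapply(1:2, function(j)
      sum(candidates$w[members[[j]]]), 1)),
    is_bifurcation = theta > cfg$branch_angle
  ), class = "cluster_split")
}

# ---- single-vessel tracking ------------------------------------------------

#' Track one vessel from a seed state
#'
#' Iterates [step_tracker()] from a seed position/direction. Each step the
#' candidate population is checked for a majority/minority split: on a
#' bifurcation the filter resamples from the majority cluster and records
#' the minority centroid and direction as a branch seed (detection is then
#' suppressed for 3 steps so one anatomical bifurcation fires once).
#' Tracking terminates when the summed candidate likelihood falls below
#' `stop_threshold`, when the estimate leaves the volume, or at `max_steps`.
#'
#' @param vol a [volume_image()].
#' @param seed list with `position` and `direction` (world mm / unit vector),
#'   or a `particle_set` to continue from.
#' @param model a `likelihood_model`.
#' @param prior a `direction_prior`.
#' @param cfg a [tracker_config()].
#' @param rng_seed seed for this track; defaults to `cfg$rng_seed`.
#' @param detect_after step index before which bifurcation detection idles;
#'   the default 3 covers ostium starts, while tracks seeded at a branch
#'   use 6 so the pooled detection window fully clears the junction they
#'   emerged from.
#' @return A `track_result`: list with `centerline` (the estimate sequence),
#'   `tau_trace`, `theta_trace` (tibbles), `stop_reason` (one of
#'   "tau_below_beta", "out_of_bounds", "max_steps", "degenerate_weights"),
#'   `branch_seeds` (tibble of position/direction), `steps`.
#' @export
track_vessel <- function(vol, seed, model, prior, cfg = tracker_config(),
                         rng_seed = cfg$rng_seed, detect_after = 3L) {
  set.seed(rng_seed)
  S <- if (inherits(seed, "particle_set")) seed else {
    if (!in_volume(vol, seed$position)) {
      stop("seed position lies outside the volume", call. = FALSE)
    }
    particle_set_at(vol, as.numeric(seed$position),
                    as.numeric(seed$direction), cfg)
  }
  est_path <- list(S$estimate)
  tau_trace <- numeric()
  theta_trace <- numeric()
  branch_seeds <- list()
  stop_reason <- "max_steps"
  # detection idles for the first `detect_after` steps (a branch-seeded
  # track would otherwise re-detect the junction it just came from) and
  # for 3 steps after each firing (one anatomical bifurcation fires once)
  last_detect <- detect_after - 3L
  # sliding window of recent classifier-positive candidates: a single step
  # contributes only a handful of well-aligned candidates inside a freshly
  # opened branch, so detection pools the last 3 steps for statistics
  win <- list()

  for (t in seq_len(cfg$max_steps)) {
    res <- step_tracker(vol, S, model, prior, cfg)
    tau_trace <- c(tau_trace, res$diag$tau)
    if (res$stopped) {
      theta_trace <- c(theta_trace, NA_real_)
      stop_reason <- "degenerate_weights"
      break
    }
    if (res$diag$tau < cfg$stop_threshold) {
      theta_trace <- c(theta_trace, NA_real_)
      stop_reason <- "tau_below_beta"
      break
    }
    cand <- res$diag$candidates
    pos <- which(cand$lik >= 0.5)
    win <- c(win, list(list(x = cand$x[pos, , drop = FALSE],
                            d = cand$d[pos, , drop = FALSE],
                            w = cand$w[pos], lik = cand$lik[pos],
                            est_prev = res$diag$estimate_prev,
                            step = t)))
    if (length(win) > 3L) win <- win[-1]
    pooled <- list(x = do.call(rbind, lapply(win, `[[`, "x")),
                   d = do.call(rbind, lapply(win, `[[`, "d")),
                   w = unlist(lapply(win, `[[`, "w")),
                   lik = unlist(lapply(win, `[[`, "lik")))
    # the angle vertex is the estimate at the start of the pooled window,
    # so every pooled candidate lies forward of it and an along-track
    # front/back split cannot masquerade as a wide branching angle
    split <- detect_bifurcation(pooled, win[[1]]$est_prev, cfg)
    theta_trace <- c(theta_trace, split$theta)
    if (split$is_bifurcation && t > last_detect + 3) {
      minority <- 3L - split$majority
      # The minority centroid sits some way down the branch (the branch
      # population only separates from the main lumen after a step or
      # two), so back-project it along the minority axis to the closest
      # approach to the tracked path — the carina estimate — and emit the
      # seed 1.5 steps into the branch from there (clear of the parent
      # lumen, so duplicate suppression cannot swallow it).
      mu <- split$centroids[minority, ]
      v <- split$directions[minority, ]
      path <- do.call(rbind, est_path)
      s_grid <- seq(-6 * cfg$step_size, 0, by = 0.1 * cfg$step_size)
      line_pts <- outer(s_grid, v) + matrix(mu, length(s_grid), 3, byrow = TRUE)
      s_best <- s_grid[which.min(nearest_gt(line_pts, path)$dist)]
      seed_pos <- mu + (s_best + 1.5 * cfg$step_size) * v
      branch_seeds <- c(branch_seeds, list(tibble::tibble(
        x = seed_pos[1], y = seed_pos[2], z = seed_pos[3],
        dx = v[1], dy = v[2], dz = v[3],
        at_step = t)))
      last_detect <- t
      win <- list()   # one anatomical bifurcation fires once
      # continue along the majority cluster: resample from its members of
      # the current candidate set (fall back to the standard resample when
      # the intersection is too thin)
      cur_step_rows <- length(pooled$w) - length(pos) + seq_along(pos)
      mem <- intersect(split$members[[split$majority]], cur_step_rows)
      if (length(mem) >= cfg$dbscan_min_pts) {
        mem_cur <- pos[match(mem, cur_step_rows)]
        wk <- cand$w[mem_cur] / sum(cand$w[mem_cur])
        keep <- mem_cur[systematic_resample(wk, cfg$n_particles)]
        S <- structure(list(
          x = cand$x[keep, , drop = FALSE], d = cand$d[keep, , drop = FALSE],
          w = rep(1 / cfg$n_particles, cfg$n_particles),
          hist = res$diag$candidates$hist[keep, , drop = FALSE],
          t = S$t + 1L, estimate = res$diag$estimate,
          intensity_range = S$intensity_range
        ), class = "particle_set")
      } else {
        S <- res$set
      }
    } else {
      S <- res$set
    }
    if (!in_volume(vol, S$estimate)) {
      stop_reason <- "out_of_bounds"
      break
    }
    est_path <- c(est_path, list(S$estimate))
  }

  est <- do.call(rbind, est_path)
  cl <- if (nrow(est) >= 2) centerline(est, label = "tracked") else NULL
  structure(list(
    centerline = cl,
    tau_trace = tibble::tibble(step = seq_along(tau_trace), tau = tau_trace),
    theta_trace = tibble::tibble(step = seq_along(theta_trace),
                                 theta = theta_trace),
    stop_reason = stop_reason,
    branch_seeds = if (length(branch_seeds)) dplyr::bind_rows(branch_seeds)
      else tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          dx = numeric(), dy = numeric(), dz = numeric(),
                          at_step = integer()),
    steps = length(tau_trace)
  ), class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("<track_result> %d steps, stop: %s, %d branch seed(s)%s\n",
              x$steps, x$stop_reason, nrow(x$branch_seeds),
              if (!is.null(x$centerline))
                sprintf(", length %.1f mm", centerline_length(x$centerline))
              else ""))
  invisible(x)
}

# ---- whole-tree tracking ---------------------------------------------------

#' Track a full vessel tree from ostium seeds
#'
#' Depth-first over a seed stack: each ostium pair starts a vessel; every
#' bifurcation the tracker passes pushes a branch seed, popped until the
#' stack empties. Branch seeds landing within `dbscan_eps` of an
#' already-tracked centerline point are dropped as duplicates. Each tracked
#' branch is linked to the nearest point of its parent branch.
#'
#' @param vol a [volume_image()].
#' @param ostium_seeds list of `list(x0 = , x1 = )` world-mm seed pairs (the
#'   ostium and a second point defining the initial direction).
#' @param model a `likelihood_model`.
#' @param prior a `direction_prior`.
#' @param cfg a [tracker_config()].
#' @return A [vessel_tree()]; each branch additionally carries the
#'   `track_result` in attribute `"track"`.
#' @export
track_tree <- function(vol, ostium_seeds, model, prior,
                       cfg = tracker_config()) {
  if (!length(ostium_seeds)) return(vessel_tree())
  seeds <- derive_seeds(cfg$rng_seed, 1000L)
  stack <- lapply(ostium_seeds, function(s) {
    x0 <- as.numeric(s$x0); x1 <- as.numeric(s$x1)
    d <- (x1 - x0) / sqrt(sum((x1 - x0)^2))
    list(position = x1, direction = d, parent = NA_integer_)
  })
  branches <- list()
  links <- list()
  tracked_pts <- NULL
  vessel_i <- 0L

  while (length(stack)) {
    sd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    vessel_i <- vessel_i + 1L
    # duplicate suppression for branch seeds, against the tracked curves
    # (finely resampled, so the check does not depend on the step spacing):
    # a seed whose forward ray rides an already-tracked vessel would only
    # re-extract it, while a genuine branch seed dives away from every
    # tracked curve within a step or two
    if (!is.na(sd$parent) && !is.null(tracked_pts)) {
      probes <- matrix(sd$position, 3, 3, byrow = TRUE) +
        outer(c(0, 1, 2) * cfg$step_size, sd$direction)
      if (any(nearest_gt(probes, tracked_pts$xyz)$dist < cfg$dbscan_eps)) next
    }
    res <- track_vessel(vol, list(position = sd$position,
                                  direction = sd$direction),
                        model, prior, cfg, rng_seed = seeds[vessel_i],
                        detect_after = if (is.na(sd$parent)) 3L else 6L)
    if (is.null(res$centerline)) next
    bi <- length(branches) + 1L
    br <- res$centerline
    attr(br, "track") <- res
    attr(br, "label") <- if (is.na(sd$parent)) sprintf("vessel_%d", bi)
      else sprintf("branch_of_%d", sd$parent)
    branches[[bi]] <- br
    if (!is.na(sd$parent)) {
      nn <- nearest_gt(matrix(sd$position, 1), cl_xyz(branches[[sd$parent]]))
      links[[length(links) + 1L]] <- tibble::tibble(
        parent_branch = sd$parent, parent_point = nn$idx,
        child_branch = bi)
    }
    # register tracked points (finely resampled) before children are popped
    xyz <- cl_xyz(resample_centerline(br, 0.2))
    tracked_pts <- list(xyz = rbind(tracked_pts$xyz, xyz))
    if (nrow(res$branch_seeds)) {
      for (k in seq_len(nrow(res$branch_seeds))) {
        bs <- res$branch_seeds[k, ]
        stack[[length(stack) + 1L]] <- list(
          position = c(bs$x, bs$y, bs$z),
          direction = c(bs$dx, bs$dy, bs$dz),
          parent = bi)
      }
    }
  }
  vessel_tree(branches, if (length(links)) dplyr::bind_rows(links) else NULL)
}

# ---- broom-style accessors -------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a track result into its centerline points
#'
#' @param x a `track_result`.
#' @param ... unused.
#' @return tibble with `step`, `x`, `y`, `z`, `tau`, `theta`.
#' @export
tidy.track_result <- function(x, ...) {
  n <- if (is.null(x$centerline)) 0L else nrow(x$centerline)
  pts <- if (n) tibble::as_tibble(x$centerline[, c("x", "y", "z")])
    else tibble::tibble(x = numeric(), y = numeric(), z = numeric())
  pts$step <- seq_len(n) - 1L
  dplyr::left_join(
    dplyr::left_join(pts, x$tau_trace, by = "step"),
    x$theta_trace, by = "step")[, c("step", "x", "y", "z", "tau", "theta")]
}

#' One-row summary of a track result
#'
#' @param x a `track_result`.
#' @param ... unused.
#' @return tibble with step count, path length, stop reason, final tau and
#'   branch-seed count.
#' @export
glance.track_result <- function(x, ...) {
  tibble::tibble(
    steps = x$steps,
    length_mm = if (is.null(x$centerline)) 0 else centerline_length(x$centerline),
    stop_reason = x$stop_reason,
    final_tau = if (nrow(x$tau_trace)) x$tau_trace$tau[nrow(x$tau_trace)]
      else NA_real_,
    branch_seeds = nrow(x$branch_seeds)
  )
}
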