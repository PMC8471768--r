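#' Analytic oracle vesselness likelihood for phantoms
#'
#' A test double for the trained patch classifier, usable whenever the
#' ground-truth tree is known: the in-vessel probability is a logistic
#' function of the signed distance to the vessel surface,
#' `plogis(-sharpness * (dist(centroid, centerline) - local_radius))`.
#' It is smooth, close to 1 deep inside vessels, 0.5 exactly on the wall and
#' close to 0 far outside, and lets the particle filter be exercised
#' independently of CNN training.
#'
#' Like the patch classifier it stands in for, the oracle is
#' alignment-sensitive when the patch orientation is known: a tangent patch
#' whose normal is tilted away from the local vessel direction shows an
#' elongated, non-circular cross-section and scores low. This is modelled by
#' a `cos^8` factor on the angle between the patch normal and the
#' ground-truth tangent at the nearest centerline point (1 when aligned,
#' about 0.5 at 30 degrees — roughly two standard deviations of the tilt
#' noise the classifier is trained under — and 0 at 90 degrees).
#' Evaluations without an orientation (bare centroids) omit the factor.
#'
#' @param gt_tree a [vessel_tree()] whose branches carry radii.
#' @param sharpness logistic steepness, 1/mm; the default gives a 10-90%
#'   transition of about 0.7 mm across the wall, roughly twice the phantom
#'   partial-volume blur.
#' @param alignment_power exponent of the cosine alignment factor; 0
#'   disables alignment sensitivity.
#' @return A `likelihood_model` of subclass `oracle_likelihood`.
#' @export
oracle_likelihood <- function(gt_tree, sharpness = 6, alignment_power = 8) {
  stopifnot(inherits(gt_tree, "vessel_tree"))
  if (!length(gt_tree$branches)) {
    stop("oracle likelihood needs a non-empty ground-truth tree", call. = FALSE)
  }
  pts <- tree_points(gt_tree)
  if (!"r" %in% names(pts) || any(is.na(pts$r))) {
    stop("oracle likelihood needs ground-truth radii", call. = FALSE)
  }
  dirs <- do.call(rbind, lapply(gt_tree$branches, centerline_directions))
  structure(list(
    gt_xyz = as.matrix(pts[, c("x", "y", "z")]),
    gt_r = pts$r,
    gt_dir = dirs,
    sharpness = sharpness,
    alignment_power = alignment_power,
    metadata = "analytic signed-distance oracle with cos^8 alignment factor"
  ), class = c("oracle_likelihood", "likelihood_model"))
}

# squared distances between query rows (n x 3) and reference rows (m x 3)
cross_dist2 <- function(q, g) {
  d2 <- outer(rowSums(q^2), rep(1, nrow(g))) +
    outer(rep(1, nrow(q)), rowSums(g^2)) - 2 * q %*% t(g)
  pmax(d2, 0)
}

nearest_gt <- function(q, gt_xyz) {
  d2 <- cross_dist2(q, gt_xyz)
  idx <- max.col(-d2, ties.method = "first")
  list(idx = idx, dist = sqrt(d2[cbind(seq_len(nrow(q)), idx)]))
}

#' Evaluate a vesselness likelihood on a tangent patch
#'
#' Returns the in-vessel probability in `[0, 1]` used verbatim as the
#' particle-filter likelihood and in the stopping sum tau.
#'
#' @param model a `likelihood_model` (oracle or trained CNN).
#' @param patch a `tangent_patch` from [extract_tangent_patch()].
#' @return scalar probability.
#' @export
likelihood <- function(model, patch) {
  UseMethod("likelihood")
}

#' @export
likelihood.oracle_likelihood <- function(model, patch) {
  stopifnot(inherits(patch, "tangent_patch"))
  as.numeric(likelihood_batch(model, pixels = NULL,
                              centroids = matrix(patch$centroid, 1),
                              normals = matrix(patch$normal, 1)))
}

#' @export
likelihood.patch_cnn <- function(model, patch) {
  stopifnot(inherits(patch, "tangent_patch"))
  if (!isTRUE(model$trained)) {
    stop("patch CNN has not been trained; train it or use oracle_likelihood()",
         call. = FALSE)
  }
  as.numeric(likelihood_batch(model,
                              pixels = matrix(as.numeric(patch$pixels), 1)))
}

# Batch evaluation used in the tracker hot loop. `pixels` is n x P^2,
# `centroids` / `normals` n x 3; an oracle only needs geometry, a CNN only
# pixels.
likelihood_batch <- function(model, pixels = NULL, centroids = NULL,
                             normals = NULL) {
  UseMethod("likelihood_batch")
}

#' @export
likelihood_batch.oracle_likelihood <- function(model, pixels = NULL,
                                               centroids = NULL,
                                               normals = NULL) {
  stopifnot(!is.null(centroids))
  nn <- nearest_gt(centroids, model$gt_xyz)
  p <- stats::plogis(-model$sharpness * (nn$dist - model$gt_r[nn$idx]))
  if (!is.null(normals) && model$alignment_power > 0) {
    ca <- abs(rowSums(normals * model$gt_dir[nn$idx, , drop = FALSE]))
    p <- p * pmin(1, ca)^model$alignment_power
  }
  p
}

#' @export
likelihood_batch.patch_cnn <- function(model, pixels = NULL, centroids = NULL,
                                       normals = NULL) {
  stopifnot(!is.null(pixels))
  if (!isTRUE(model$trained)) {
    stop("patch CNN has not been trained; train it or use oracle_likelihood()",
         call. = FALSE)
  }
  n <- nrow(pixels)
  out <- numeric(n)
  chunk <- 256L   # bounds the im2col working set
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx] <- cnn_fwd(model$weights,
                        normalise_pixels(pixels[idx, , drop = FALSE]))$probs[, 2L]
  }
  out
}

# ---- training data ---------------------------------------------------------

#' Sample balanced in-vessel / out-of-vessel training patches
#'
#' Draws tangent patches along a reference centerline, uniformly in
#' arclength from proximal to distal. At each draw the patch normal is the
#' local centerline direction perturbed by an azimuth `phi ~ U[0, 2*pi)` and
#' a polar tilt `theta ~ N(0, sigma_theta^2)`; the patch centroid is
#' displaced radially off the axis — inside the lumen for the in-vessel
#' class; for the out-of-vessel class mostly between 1 and 3 local radii
#' (hard near-wall negatives), with a 30% share of far draws out to 10
#' radii so the classifier is also calibrated on plain background, which
#' the tracker queries whenever a hypothesis leaves the vessel. Labels are
#' then assigned from the actual distance to the nearest
#' centerline sample (1 iff within the local radius), so every stored label
#' is verified rather than assumed from the draw.
#'
#' A share of the out-of-vessel quota (`decoy_fraction`) consists of
#' "longitudinal decoys": patches whose centroid lies inside the lumen but
#' whose normal is tilted 60-90 degrees off the vessel direction, so the
#' lumen appears as an elongated slab instead of a cross-section. They are
#' labelled out-of-vessel — the patch does not show the cross-section the
#' tracker asks about — which gives the classifier the alignment
#' sensitivity that the stopping rule and bifurcation clustering rely on
#' (on real CT the same sensitivity arises naturally, because longitudinal
#' views show surrounding anatomy). Decoys carry `decoy = TRUE` in the
#' provenance; all other labels follow the verified distance rule.
#'
#' @param vol a [volume_image()].
#' @param gt a [centerline()] with radii (the reference for this volume).
#' @param n_per_class patches per class (total is `2 * n_per_class`).
#' @param sigma_theta polar tilt standard deviation, radians.
#' @param decoy_fraction share of the out-of-vessel class drawn as
#'   longitudinal decoys, in `[0, 1)`.
#' @param cfg a [tracker_config()] (patch geometry).
#' @param volume_id provenance tag recorded per patch.
#' @return A `training_patch_set`: list with `pixels`
#'   (`2 n_per_class` x `patch_pixels^2` matrix), `labels` (0/1) and
#'   `provenance` tibble. Uses the R RNG; seed with [set.seed()].
#' @export
sample_training_patches <- function(vol, gt, n_per_class,
                                    sigma_theta = 15 * pi / 180,
                                    decoy_fraction = 0.15,
                                    cfg = tracker_config(),
                                    volume_id = "vol") {
  stopifnot(inherits(gt, "centerline"))
  if (!"r" %in% names(gt)) {
    stop("training-patch sampling needs ground-truth radii", call. = FALSE)
  }
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  stopifnot(decoy_fraction >= 0, decoy_fraction < 1)
  dense <- resample_centerline(gt, PHANTOM_GT_SPACING)
  dirs <- centerline_directions(dense)
  xyz <- cl_xyz(dense)
  rr <- dense$r

  want <- c(`0` = n_per_class, `1` = n_per_class)
  got <- c(`0` = 0L, `1` = 0L)
  acc_pix <- vector("list", 0)
  acc_lab <- integer()
  acc_prov <- vector("list", 0)

  while (any(got < want)) {
    n_draw <- max(64L, 2L * sum(want - got))
    t_idx <- sample.int(nrow(xyz), n_draw, replace = TRUE)
    d <- dirs[t_idx, , drop = FALSE]
    fr <- make_frames(d)
    phi <- stats::runif(n_draw, 0, 2 * pi)
    theta <- stats::rnorm(n_draw, 0, sigma_theta)
    # longitudinal decoys: in-lumen centroid, near-orthogonal normal
    is_decoy <- stats::runif(n_draw) < decoy_fraction / 2
    theta[is_decoy] <- sample(c(-1, 1), sum(is_decoy), replace = TRUE) *
      stats::runif(sum(is_decoy), 60, 90) * pi / 180
    az <- cos(phi) * fr$u + sin(phi) * fr$v
    normals <- cos(theta) * d + sin(theta) * az
    normals <- normals / sqrt(rowSums(normals^2))
    # radial displacement: half the draws aimed inside, half outside;
    # outside draws mix near-wall (1-3 r) and far-background (3-10 r);
    # decoys always sit inside the lumen
    aim_in <- seq_len(n_draw) %% 2L == 0L | is_decoy
    r_t <- rr[t_idx]
    far <- stats::runif(n_draw) < 0.3
    out_mult <- ifelse(far, stats::runif(n_draw, 3, 10),
                       stats::runif(n_draw, 1, 3))
    delta <- ifelse(aim_in, stats::runif(n_draw, 0, 1) * r_t * 0.95,
                    out_mult * r_t)
    phi2 <- stats::runif(n_draw, 0, 2 * pi)
    radial <- cos(phi2) * fr$u + sin(phi2) * fr$v
    centroids <- xyz[t_idx, , drop = FALSE] + delta * radial
    ok <- in_volume(vol, centroids)
    if (!any(ok)) next
    centroids <- centroids[ok, , drop = FALSE]
    normals <- normals[ok, , drop = FALSE]
    t_idx <- t_idx[ok]; delta <- delta[ok]; theta <- theta[ok]
    is_decoy <- is_decoy[ok]
    # verified label: inside iff distance to nearest centerline sample < r;
    # decoys that truly landed inside are forced out-of-vessel
    nn <- nearest_gt(centroids, xyz)
    lab <- as.integer(nn$dist < rr[nn$idx])
    is_decoy <- is_decoy & lab == 1L
    lab[is_decoy] <- 0L
    for (cls in c(0L, 1L)) {
      need <- want[[as.character(cls)]] - got[[as.character(cls)]]
      if (need <= 0L) next
      pick <- which(lab == cls)
      if (!length(pick)) next
      pick <- pick[seq_len(min(need, length(pick)))]
      px <- extract_patches(vol, centroids[pick, , drop = FALSE],
                            normals[pick, , drop = FALSE], cfg)
      acc_pix <- c(acc_pix, list(px))
      acc_lab <- c(acc_lab, rep(cls, length(pick)))
      acc_prov <- c(acc_prov, list(tibble::tibble(
        volume_id = volume_id, t_index = t_idx[pick],
        offset_mm = delta[pick], tilt_deg = theta[pick] * 180 / pi,
        decoy = is_decoy[pick],
        cx = centroids[pick, 1], cy = centroids[pick, 2],
        cz = centroids[pick, 3])))
      got[[as.character(cls)]] <- got[[as.character(cls)]] + length(pick)
    }
  }
  structure(list(
    pixels = do.call(rbind, acc_pix),
    labels = acc_lab,
    provenance = dplyr::bind_rows(acc_prov)
  ), class = "training_patch_set")
}

#' @export
print.training_patch_set <- function(x, ...) {
  cat(sprintf("<training_patch_set> %d patches (%d in-vessel / %d out), %d px each\n",
              length(x$labels), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$pixels)))
  invisible(x)
}

#' Save / load a training patch set
#'
#' Single-file compressed archive of the patch intensity matrix, label
#' vector and provenance table.
#'
#' @param patches a `training_patch_set`.
#' @param path archive file path.
#' @return `load_patch_set()` returns the restored `training_patch_set`.
#' @export
save_patch_set <- function(patches, path) {
  stopifnot(inherits(patches, "training_patch_set"))
  saveRDS(list(format = "vesselpf-patch-set", version = 1L,
               pixels = patches$pixels, labels = patches$labels,
               provenance = patches$provenance),
          path, compress = "xz")
  invisible(NULL)
}

#' @rdname save_patch_set
#' @export
load_patch_set <- function(path) {
  ar <- readRDS(path)
  if (!identical(ar$format, "vesselpf-patch-set")) {
    stop("not a patch-set archive: ", path, call. = FALSE)
  }
  structure(list(pixels = ar$pixels, labels = ar$labels,
                 provenance = ar$provenance),
            class = "training_patch_set")
}

#' Combine training patch sets (e.g. from several volumes)
#'
#' @param ... `training_patch_set` objects.
#' @return A single `training_patch_set`.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  structure(list(
    pixels = do.call(rbind, lapply(sets, `[[`, "pixels")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    provenance = dplyr::bind_rows(lapply(sets, `[[`, "provenance"))
  ), class = "training_patch_set")
}

# ---- the patch CNN ---------------------------------------------------------

#' Build the tangent-patch vesselness classifier
#'
#' Architecture: 32 x 32 single-channel input; three 3 x 3 same-padded
#' convolution layers of 32, 64 and 128 channels, each followed by ReLU and
#' 2 x 2 max pooling; then fully connected layers of 512, 256 and 2 units
#' (ReLU on the hidden ones) and a 2-way softmax head. Weights are
#' He-initialised at build time; the model refuses to serve likelihoods
#' until trained.
#'
#' @param cfg a [tracker_config()]; `patch_pixels` must equal 32 (the input
#'   size the architecture is fixed to).
#' @return An untrained `patch_cnn` `likelihood_model`.
#' @export
build_patch_cnn <- function(cfg = tracker_config()) {
  if (cfg$patch_pixels != 32L) {
    stop("the patch CNN expects 32 x 32 patches (cfg$patch_pixels = 32)",
         call. = FALSE)
  }
  weights <- cnn_init_weights()
  structure(list(
    weights = weights,
    trained = FALSE,
    metadata = "untrained tangent-patch CNN (conv 32-64-128, fc 512-256-2)",
    history = NULL
  ), class = c("patch_cnn", "likelihood_model"))
}

#' @export
print.patch_cnn <- function(x, ...) {
  cat(sprintf("<patch_cnn> %s, %s parameters%s\n",
              if (isTRUE(x$trained)) "trained" else "untrained",
              format(n_parameters(x), big.mark = ","),
              if (!is.null(x$history))
                sprintf(", held-out accuracy %.3f", x$history$best_val_acc)
              else ""))
  invisible(x)
}

#' Number of trainable parameters of a patch CNN
#' @param model a `patch_cnn`.
#' @export
n_parameters <- function(model) {
  cnn_n_parameters(model$weights)
}

#' Raw class probabilities of the patch CNN
#'
#' Forward pass only (works on untrained models, e.g. to check the softmax
#' head); per-patch intensity standardisation is applied internally.
#'
#' @param model a `patch_cnn`.
#' @param pixels n x 1024 matrix, or a single `tangent_patch`.
#' @return n x 2 matrix of class probabilities (out-of-vessel, in-vessel),
#'   rows summing to 1.
#' @export
cnn_probabilities <- function(model, pixels) {
  stopifnot(inherits(model, "patch_cnn"))
  if (inherits(pixels, "tangent_patch")) {
    pixels <- matrix(as.numeric(pixels$pixels), 1)
  }
  cnn_fwd(model$weights, normalise_pixels(pixels))$probs
}

#' Train the patch CNN
#'
#' Mini-batch Adam on the softmax cross-entropy, with per-patch intensity
#' standardisation. Training and validation sets must come from different
#' volumes (checked through patch provenance). Early stopping monitors
#' validation accuracy; the weights of the best epoch are kept.
#' Deterministic given `rng_seed` (and a fixed BLAS thread count).
#'
#' @param model an untrained (or previously trained) `patch_cnn`.
#' @param train,val `training_patch_set`s, disjoint by provenance volume.
#' @param epochs maximum epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param patience epochs without validation improvement before stopping.
#' @param target_acc stop as soon as validation accuracy reaches this.
#' @param rng_seed seed for weight initialisation and shuffling.
#' @param verbose print per-epoch progress.
#' @return The trained `patch_cnn`; `$history` holds per-epoch loss and
#'   validation accuracy and `$history$best_val_acc` the held-out accuracy.
#' @export
train_likelihood <- function(model, train, val,
                             epochs = 20L, batch_size = 128L, lr = 1e-3,
                             patience = 2L, target_acc = 0.995,
                             rng_seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "patch_cnn"),
            inherits(train, "training_patch_set"),
            inherits(val, "training_patch_set"))
  if (length(unique(train$labels)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  shared <- intersect(unique(train$provenance$volume_id),
                      unique(val$provenance$volume_id))
  if (length(shared)) {
    stop("training and validation sets share provenance volume(s): ",
         paste(shared, collapse = ", "), call. = FALSE)
  }
  set.seed(rng_seed)
  w <- cnn_init_weights()
  st <- adam_init(w)
  Xtr <- normalise_pixels(train$pixels)
  ytr <- as.integer(train$labels)
  Xva <- normalise_pixels(val$pixels)
  yva <- as.integer(val$labels)
  n <- nrow(Xtr)
  best <- list(acc = -1, w = w, epoch = 0L)
  hist <- list(epoch = integer(), loss = numeric(), val_acc = numeric())
  stall <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      fwd <- cnn_fwd(w, Xtr[idx, , drop = FALSE], keep_cache = TRUE)
      p_true <- fwd$probs[cbind(seq_along(idx), ytr[idx] + 1L)]
      tot_loss <- tot_loss - sum(log(pmax(p_true, 1e-12)))
      g <- cnn_bwd(w, fwd, ytr[idx])
      upd <- adam_step(w, g, st, lr = lr)
      w <- upd$w; st <- upd$st
    }
    acc <- cnn_accuracy(w, Xva, yva)
    hist$epoch <- c(hist$epoch, ep)
    hist$loss <- c(hist$loss, tot_loss / n)
    hist$val_acc <- c(hist$val_acc, acc)
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val acc %.4f", ep, tot_loss / n, acc))
    }
    if (acc > best$acc) {
      best <- list(acc = acc, w = w, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (acc >= target_acc || stall >= patience) break
  }
  model$weights <- best$w
  model$trained <- TRUE
  model$metadata <- sprintf(
    "tangent-patch CNN trained on %d patches (%d epochs, best epoch %d)",
    n, length(hist$epoch), best$epoch)
  model$history <- c(tibble::as_tibble(hist),
                     list(best_val_acc = best$acc, best_epoch = best$epoch))
  model
}

#' Save / load a trained patch-CNN checkpoint
#'
#' Single-file checkpoint with a version field, containing the weights,
#' training metadata and history.
#'
#' @param model a `patch_cnn`.
#' @param path checkpoint file path.
#' @return `load_patch_cnn()` returns the restored `patch_cnn`.
#' @export
save_patch_cnn <- function(model, path) {
  stopifnot(inherits(model, "patch_cnn"))
  saveRDS(list(format = "vesselpf-patch-cnn", version = 1L,
               weights = model$weights, trained = model$trained,
               metadata = model$metadata, history = model$history),
          path)
  invisible(NULL)
}

#' @rdname save_patch_cnn
#' @export
load_patch_cnn <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "vesselpf-patch-cnn")) {
    stop("not a patch-CNN checkpoint: ", path, call. = FALSE)
  }
  if (!identical(ck$version, 1L)) {
    stop("unsupported checkpoint version ", ck$version, ": ", path, call. = FALSE)
  }
  structure(list(weights = ck$weights, trained = ck$trained,
                 metadata = ck$metadata, history = ck$history),
            class = c("patch_cnn", "likelihood_model"))
}

cnn_accuracy <- function(w, X, y, chunk = 512L) {
  n <- nrow(X)
  correct <- 0L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    p <- cnn_fwd(w, X[idx, , drop = FALSE])$probs
    correct <- correct + sum((p[, 2L] > 0.5) == (y[idx] == 1L))
  }
  correct / n
}
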