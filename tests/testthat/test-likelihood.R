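test_that("oracle likelihood is the logistic of the signed wall distance", {
  tree <- toy_line_tree(radius = 1)
  model <- oracle_likelihood(tree, sharpness = 6)
  lb <- function(p) as.numeric(vesselpf:::likelihood_batch(model, centroids = matrix(p, 1)))
  expect_gt(lb(c(0, 0, 10)), 0.5)                   # on the axis
  expect_equal(lb(c(1, 0, 10)), 0.5, tolerance = 1e-9)  # exactly on the wall
  expect_lt(lb(c(5, 0, 10)), 1e-6)                  # far outside
  # monotone decreasing along a ray leaving the vessel
  ds <- seq(0, 4, length.out = 20)
  vals <- vapply(ds, function(d) lb(c(d, 0, 10)), 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(oracle_likelihood(vessel_tree()), "non-empty")
})

test_that("oracle likelihood penalises misaligned patch normals", {
  tree <- toy_line_tree(radius = 1)
  model <- oracle_likelihood(tree)
  aligned <- vesselpf:::likelihood_batch(model, centroids = matrix(c(0, 0, 10), 1),
                                         normals = matrix(c(0, 0, 1), 1))
  tilted <- vesselpf:::likelihood_batch(model, centroids = matrix(c(0, 0, 10), 1),
                                        normals = matrix(c(sin(1), 0, cos(1)), 1))
  sideways <- vesselpf:::likelihood_batch(model, centroids = matrix(c(0, 0, 10), 1),
                                          normals = matrix(c(1, 0, 0), 1))
  expect_gt(aligned, 0.95)
  expect_lt(tilted, aligned)
  expect_lt(sideways, 1e-6)
  # patch flips leave the factor unchanged (same plane)
  flipped <- vesselpf:::likelihood_batch(model, centroids = matrix(c(0, 0, 10), 1),
                                         normals = matrix(c(0, 0, -1), 1))
  expect_equal(as.numeric(flipped), as.numeric(aligned))
})

test_that("oracle scores phantom patches like a good classifier would", {
  ph <- small_phantom()
  model <- oracle_likelihood(ph$tree)
  gt <- ph$tree$branches[[1]]
  i <- nrow(gt) %/% 2
  d <- centerline_directions(gt)[i, ]
  on_axis <- extract_tangent_patch(ph$volume, seed_of(gt, i), d)
  expect_gte(likelihood(model, on_axis), 0.9)
  bg <- extract_tangent_patch(ph$volume, seed_of(gt, i) + c(6, 6, 0), d)
  expect_lte(likelihood(model, bg), 0.1)
})

test_that("training patches are balanced, labelled by verified distance", {
  ph <- small_phantom()
  gt <- tree_paths(ph$tree)[[1]]
  set.seed(14)
  ts <- sample_training_patches(ph$volume, gt, n_per_class = 120,
                                volume_id = "p1")
  expect_equal(sum(ts$labels == 1), 120L)
  expect_equal(sum(ts$labels == 0), 120L)
  expect_equal(ncol(ts$pixels), 1024L)
  expect_equal(nrow(ts$provenance), 240L)
  expect_true(all(ts$provenance$volume_id == "p1"))
  # no radii -> precondition error
  bare <- centerline(as.matrix(gt[, c("x", "y", "z")]))
  expect_error(sample_training_patches(ph$volume, bare, 10), "radii")
})

test_that("patch labels match a brute-force nearest-point computation", {
  ph <- small_phantom()
  gt <- tree_paths(ph$tree)[[1]]
  dense <- resample_centerline(gt, 0.2)
  gxyz <- as.matrix(dense[, c("x", "y", "z")])
  set.seed(15)
  ts <- sample_training_patches(ph$volume, gt, n_per_class = 50,
                                volume_id = "p1")
  plain <- utils::head(which(!ts$provenance$decoy), 100)
  for (k in plain) {
    cen <- as.numeric(ts$provenance[k, c("cx", "cy", "cz")])
    dd <- sqrt(rowSums(sweep(gxyz, 2, cen)^2))
    j <- which.min(dd)
    expect_equal(ts$labels[k], as.integer(dd[j] < dense$r[j]))
  }
  # decoys are in-lumen but strongly tilted, and labelled out-of-vessel
  dec <- ts$provenance$decoy
  if (any(dec)) {
    expect_true(all(ts$labels[dec] == 0L))
    expect_true(all(abs(ts$provenance$tilt_deg[dec]) >= 60))
  }
})

test_that("patch sets and CNN checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  ph <- small_phantom()
  set.seed(22)
  ts <- sample_training_patches(ph$volume, tree_paths(ph$tree)[[1]], 20,
                                volume_id = "p1")
  p1 <- file.path(dir, "patches.bin")
  save_patch_set(ts, p1)
  back <- load_patch_set(p1)
  expect_identical(back$pixels, ts$pixels)
  expect_identical(back$labels, ts$labels)
  expect_identical(back$provenance, ts$provenance)

  model <- build_patch_cnn()
  model$trained <- TRUE
  p2 <- file.path(dir, "cnn.ckpt")
  save_patch_cnn(model, p2)
  restored <- load_patch_cnn(p2)
  set.seed(23)
  px <- matrix(rnorm(2 * 1024, 100, 40), 2, 1024)
  expect_identical(vesselpf:::likelihood_batch(restored, pixels = px),
                   vesselpf:::likelihood_batch(model, pixels = px))
  saveRDS(list(format = "other"), p2)
  expect_error(load_patch_cnn(p2), "checkpoint")
})

test_that("the patch CNN has the stated architecture", {
  model <- build_patch_cnn()
  # closed-form parameter count for conv 32/64/128 (3x3, same) + fc 512/256/2
  count <- (32 * 9 * 1 + 32) + (64 * 9 * 32 + 64) + (128 * 9 * 64 + 128) +
    (2048 * 512 + 512) + (512 * 256 + 256) + (256 * 2 + 2)
  expect_equal(n_parameters(model), count)
  expect_equal(count, 1273602)
  p <- cnn_probabilities(model, matrix(0, 1, 1024))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  set.seed(16)
  p2 <- cnn_probabilities(model, matrix(rnorm(3 * 1024, 200, 50), 3, 1024))
  expect_true(all(p2 >= 0 & p2 <= 1))
  expect_equal(rowSums(p2), rep(1, 3), tolerance = 1e-9)
  expect_error(build_patch_cnn(tracker_config(patch_pixels = 16)), "32")
})

test_that("an untrained CNN refuses to serve likelihoods", {
  model <- build_patch_cnn()
  patch <- structure(list(pixels = matrix(0, 32, 32), centroid = c(0, 0, 0),
                          normal = c(0, 0, 1),
                          basis = list(u = c(1, 0, 0), v = c(0, 1, 0)),
                          in_plane_spacing = 0.25), class = "tangent_patch")
  expect_error(likelihood(model, patch), "not been trained")
})

test_that("training demands two classes and disjoint provenance", {
  model <- build_patch_cnn()
  set.seed(17)
  mk <- function(n, label, vol) {
    structure(list(pixels = matrix(rnorm(n * 1024), n, 1024),
                   labels = rep(label, length.out = n),
                   provenance = tibble::tibble(volume_id = vol, t_index = 1,
                                               offset_mm = 0, tilt_deg = 0)[rep(1, n), ]),
              class = "training_patch_set")
  }
  expect_error(train_likelihood(model, mk(10, 1L, "a"), mk(10, 0:1, "b")),
               "single class")
  expect_error(train_likelihood(model, mk(10, 0:1, "a"), mk(10, 0:1, "a")),
               "provenance")
})

test_that("the CNN separates trivially separable classes perfectly", {
  # two constant-intensity classes differing in a bright centred disc
  set.seed(18)
  mk_px <- function(n, bright) {
    t(vapply(seq_len(n), function(i) {
      img <- matrix(rnorm(1024, 100, 5), 32, 32)
      if (bright) {
        d2 <- (row(img) - 16.5)^2 + (col(img) - 16.5)^2
        img[d2 < 36] <- rnorm(sum(d2 < 36), 300, 5)
      }
      as.numeric(img)
    }, numeric(1024)))
  }
  tr <- structure(list(
    pixels = rbind(mk_px(80, TRUE), mk_px(80, FALSE)),
    labels = rep(1:0, each = 80),
    provenance = tibble::tibble(volume_id = "a", t_index = 1,
                                offset_mm = 0, tilt_deg = 0)[rep(1, 160), ]),
    class = "training_patch_set")
  va <- structure(list(
    pixels = rbind(mk_px(40, TRUE), mk_px(40, FALSE)),
    labels = rep(1:0, each = 40),
    provenance = tibble::tibble(volume_id = "b", t_index = 1,
                                offset_mm = 0, tilt_deg = 0)[rep(1, 80), ]),
    class = "training_patch_set")
  model <- train_likelihood(build_patch_cnn(), tr, va, epochs = 6,
                            batch_size = 32, rng_seed = 2)
  expect_equal(model$history$best_val_acc, 1.0)
  # and served likelihoods are probabilities
  p <- vesselpf:::likelihood_batch(model, pixels = va$pixels[1:5, ])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("label-shuffled training stays at chance level", {
  set.seed(19)
  n <- 160
  px <- matrix(rnorm(n * 1024, 100, 30), n, 1024)
  lab <- sample(rep(0:1, n / 2))
  tr <- structure(list(pixels = px, labels = lab,
                       provenance = tibble::tibble(volume_id = "a", t_index = 1,
                                                   offset_mm = 0, tilt_deg = 0)[rep(1, n), ]),
                  class = "training_patch_set")
  va <- structure(list(pixels = matrix(rnorm(80 * 1024, 100, 30), 80, 1024),
                       labels = sample(rep(0:1, 40)),
                       provenance = tibble::tibble(volume_id = "b", t_index = 1,
                                                   offset_mm = 0, tilt_deg = 0)[rep(1, 80), ]),
                  class = "training_patch_set")
  model <- train_likelihood(build_patch_cnn(), tr, va, epochs = 2,
                            batch_size = 32, rng_seed = 3)
  expect_lt(abs(model$history$best_val_acc - 0.5), 0.12)
})

test_that("batch and pointwise CNN evaluation agree", {
  set.seed(20)
  px <- matrix(rnorm(4 * 1024, 150, 60), 4, 1024)
  model <- build_patch_cnn()
  model$trained <- TRUE   # weights are valid; only the gate is lifted
  batch <- vesselpf:::likelihood_batch(model, pixels = px)
  single <- vapply(1:4, function(i)
    vesselpf:::likelihood_batch(model, pixels = px[i, , drop = FALSE]), 1)
  expect_equal(batch, single, tolerance = 1e-6)
})
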