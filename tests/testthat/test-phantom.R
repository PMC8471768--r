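test_that("straight tube occupies the analytic capsule volume", {
  spec <- phantom_spec(shape = c(64, 64, 64), spacing = c(0.35, 0.35, 0.35),
                       length = 14, blur_sigma = 0, vessel_sd = 0, bg_sd = 0,
                       rng_seed = 2)
  ph <- generate_phantom(spec)
  n_in <- sum(ph$volume$data == spec$vessel_mean)
  # distance-to-centerline < r sweeps a capsule: cylinder + two end caps
  analytic <- (pi * 1.5^2 * 14 + 4 / 3 * pi * 1.5^3) / prod(spec$spacing)
  expect_lt(abs(n_in - analytic) / analytic, 0.05)
})

test_that("noise-free, blur-free phantoms are exactly two-valued", {
  ph <- generate_phantom(phantom_spec(shape = c(48, 48, 48), length = 10,
                                      blur_sigma = 0, vessel_sd = 0, bg_sd = 0,
                                      rng_seed = 3))
  expect_setequal(unique(as.numeric(ph$volume$data)), c(50, 400))
})

test_that("phantom generation is deterministic in the seed", {
  a <- generate_phantom(phantom_spec(shape = c(48, 48, 48), length = 10, rng_seed = 9))
  b <- generate_phantom(phantom_spec(shape = c(48, 48, 48), length = 10, rng_seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_equal(as.matrix(a$tree$branches[[1]]), as.matrix(b$tree$branches[[1]]),
               ignore_attr = TRUE)
  c <- generate_phantom(phantom_spec(shape = c(48, 48, 48), length = 10, rng_seed = 10))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("trees that do not fit with margin are rejected", {
  expect_error(generate_phantom(phantom_spec(shape = c(30, 30, 30),
                                             spacing = c(0.35, 0.35, 0.35),
                                             length = 30, rng_seed = 1)),
               "margin")
  expect_error(phantom_spec(radius_proximal = 0.1), "0.2")
  expect_error(phantom_spec(branches = tibble::tibble(
    at_frac = 0.5, angle = 130, radius_factor = 0.7, length = 5)), "120")
})

test_that("the canonical suite has ten cases with in-volume ground truth", {
  suite <- phantom_suite()
  expect_length(suite, 10L)
  for (ph in suite) {
    pts <- tree_points(ph$tree)
    expect_true(all(in_volume(ph$volume, as.matrix(pts[, c("x", "y", "z")]))),
                info = ph$name)
  }
  expect_equal(nrow(suite$y60$tree$links), 1L)
  expect_equal(nrow(suite$y90$tree$links), 1L)
  expect_equal(nrow(suite$tree2$tree$links), 2L)
  expect_equal(nrow(suite$straight$tree$links), 0L)
  # suites regenerate identically from the same seed
  again <- default_phantom_suite(1)
  expect_identical(suite$helix$volume$data, again$helix$volume$data)
})

test_that("cross-sections transverse to the vessel are near-circular", {
  # noise-free instance isolates the tube geometry from intensity noise;
  # the 2 mm radius keeps voxelisation artifacts small relative to the
  # cross-section, and the fine 64 x 64 / 0.1 mm measurement patch keeps
  # the disc inside the field of view with little pixelation
  ph <- generate_phantom(phantom_spec(shape = c(84, 84, 84), length = 14,
                                      curve = "curved", arc_angle = 40,
                                      radius_proximal = 2.0, radius_distal = 2.0,
                                      vessel_sd = 0, bg_sd = 0,
                                      rng_seed = 102))
  gt <- ph$tree$branches[[1]]
  dirs <- centerline_directions(gt)
  thr <- (ph$spec$vessel_mean + ph$spec$bg_mean) / 2
  cfg <- tracker_config(patch_pixels = 64, patch_spacing = 0.1)
  set.seed(21)
  stations <- sample(5:(nrow(gt) - 5), 20)
  for (i in stations) {
    p <- extract_tangent_patch(ph$volume, seed_of(gt, i), dirs[i, ], cfg)
    mask <- p$pixels > thr
    xs <- row(mask)[mask]; ys <- col(mask)[mask]
    ev <- eigen(cov(cbind(xs, ys)), symmetric = TRUE)$values
    ecc <- sqrt(1 - ev[2] / ev[1])
    expect_lt(ecc, 0.3)
  }
})

test_that("in-vessel intensities follow the specified normal model", {
  spec <- phantom_spec(shape = c(64, 64, 64), length = 16, blur_sigma = 0,
                       rng_seed = 31)
  ph <- generate_phantom(spec)
  gt <- ph$tree$branches[[1]]
  # voxels well inside the lumen (0.5 mm margin from the wall)
  d <- dim(ph$volume$data)
  idx <- expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3])
  w <- cbind((idx$i - 1) * 0.35, (idx$j - 1) * 0.35, (idx$k - 1) * 0.35)
  nn <- vesselpf:::nearest_gt(w, as.matrix(gt[, c("x", "y", "z")]))
  inside <- nn$dist < gt$r[1] - 0.5
  vals <- ph$volume$data[inside]
  set.seed(1)
  vals <- sample(vals, min(10000, length(vals)))
  ks <- suppressWarnings(stats::ks.test(vals, "pnorm", spec$vessel_mean,
                                        spec$vessel_sd))
  expect_gt(ks$p.value, 0.01)
})

test_that("geometry and noise flow through separate substreams", {
  # same seed, different noise level: identical centerlines
  a <- generate_phantom(phantom_spec(shape = c(48, 48, 48), length = 10,
                                     vessel_sd = 10, rng_seed = 12))
  b <- generate_phantom(phantom_spec(shape = c(48, 48, 48), length = 10,
                                     vessel_sd = 60, rng_seed = 12))
  expect_equal(as.matrix(a$tree$branches[[1]]), as.matrix(b$tree$branches[[1]]),
               ignore_attr = TRUE)
  expect_false(identical(a$volume$data, b$volume$data))
})

test_that("root-to-leaf paths thread through the attachment points", {
  suite <- phantom_suite()
  tree <- suite$y60$tree
  paths <- tree_paths(tree)
  expect_length(paths, 2L)   # the parent itself, and root-through-child
  # the child path starts at the parent's first point and ends at the
  # child's last
  expect_equal(as.numeric(as.matrix(paths[[2]][1, c("x", "y", "z")])),
               seed_of(tree$branches[[1]], 1))
  nlast <- nrow(paths[[2]])
  expect_equal(as.numeric(as.matrix(paths[[2]][nlast, c("x", "y", "z")])),
               seed_of(tree$branches[[2]], nrow(tree$branches[[2]])))
  # and it passes through the attachment point
  lk <- tree$links
  att <- seed_of(tree$branches[[1]], lk$parent_point[1])
  d2 <- min(sqrt(rowSums(sweep(as.matrix(paths[[2]][, c("x", "y", "z")]), 2, att)^2)))
  expect_lt(d2, 1e-9)
})
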