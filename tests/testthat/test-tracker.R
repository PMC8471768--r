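test_that("initialisation places equal-weight particles at the second seed", {
  ph <- small_phantom()
  gt <- ph$tree$branches[[1]]
  x0 <- seed_of(gt, 1); x1 <- seed_of(gt, 6)
  S <- init_tracker(ph$volume, x0, x1, tracker_config())
  expect_equal(nrow(S$x), 200L)
  expect_true(all(S$w == 1 / 200))
  expect_equal(unique(S$x)[1, ], x1)
  d <- S$d[1, ]
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-12)
  expect_equal(d, (x1 - x0) / sqrt(sum((x1 - x0)^2)), tolerance = 1e-12)
  expect_error(init_tracker(ph$volume, x0, x0, tracker_config()), "distinct")
  expect_error(init_tracker(ph$volume, x0, c(100, 0, 0), tracker_config()),
               "inside")
})

test_that("the stopping statistic is the plain likelihood sum", {
  expect_equal(compute_tau(rep(0, 50)), 0)
  expect_equal(compute_tau(rep(1, 200)), 200)
  expect_equal(compute_tau(c(0.2, 0.3)), 0.5)
  # stop fires iff tau < beta under the published threshold
  cfg <- tracker_config()
  expect_true(compute_tau(rep(0.004, 1000)) < cfg$stop_threshold)
  expect_false(compute_tau(rep(0.006, 1000)) < cfg$stop_threshold)
})

test_that("one step conserves weight mass and resamples to equal weights", {
  ph <- small_phantom()
  prior <- suite_prior()
  model <- oracle_likelihood(ph$tree)
  set.seed(30)
  S <- vesselpf:::particle_set_at(ph$volume, start_seed(ph)$position,
                                  start_seed(ph)$direction, tracker_config())
  for (t in 1:5) {
    res <- vesselpf:::step_tracker(ph$volume, S, model, prior, tracker_config())
    expect_equal(sum(res$diag$candidates$w), 1, tolerance = 1e-9)
    expect_true(all(res$set$w == 1 / 200))
    expect_equal(nrow(res$set$x), 200L)
    expect_lt(max(abs(sqrt(rowSums(res$set$d^2)) - 1)), 1e-9)
    S <- res$set
  }
})

test_that("a constant likelihood field leaves the expected trajectory straight", {
  # oracle with huge radius and no alignment term: likelihood ~ 1 everywhere
  big <- vessel_tree(list(centerline(cbind(0, 0, seq(-50, 80, by = 1), 40))))
  model <- oracle_likelihood(big, alignment_power = 0)
  flat_vol <- volume_image(array(100, c(40, 40, 40)), c(1, 1, 1))
  prior <- structure(list(breaks = seq(0, 180, by = 5),
                          prob = rep(1 / 36, 36)), class = "direction_prior")
  cfg <- tracker_config(n_particles = 40, successor_count = 5)
  d0 <- c(0, 0, 1)
  disp <- matrix(0, 60, 3)
  set.seed(33)
  for (r in seq_len(60)) {
    S <- vesselpf:::particle_set_at(flat_vol, c(20, 20, 10), d0, cfg)
    res <- vesselpf:::step_tracker(flat_vol, S, model, prior, cfg)
    disp[r, ] <- res$diag$estimate - c(20, 20, 10)
  }
  m <- colMeans(disp)
  se <- apply(disp, 2, sd) / sqrt(nrow(disp))
  expect_lt(abs(m[1]), 3 * se[1])
  expect_lt(abs(m[2]), 3 * se[2])
  expect_gt(m[3], 0.3)   # advances forward along d0
})

test_that("degenerate all-zero weights stop the filter instead of dividing", {
  # oracle far from everywhere: all candidate likelihoods ~ 0
  far <- vessel_tree(list(centerline(cbind(500, 500, seq(500, 520), 0.5))))
  model <- oracle_likelihood(far)
  ph <- small_phantom()
  set.seed(31)
  S <- vesselpf:::particle_set_at(ph$volume, c(8, 8, 8), c(0, 0, 1),
                                  tracker_config())
  res <- vesselpf:::step_tracker(ph$volume, S, model, suite_prior(),
                                 tracker_config())
  expect_true(res$stopped)
})

test_that("DBSCAN matches a brute-force density-reachability oracle", {
  set.seed(40)
  for (trial in 1:12) {
    n <- sample(8:20, 1)
    x <- matrix(rnorm(n * 3, sd = 2), n, 3)
    eps <- runif(1, 0.8, 2.5)
    mp <- sample(2:4, 1)
    got <- dbscan_cluster(x, eps, mp)
    want <- brute_dbscan(x, eps, mp)
    # compare partitions: same noise set, same grouping
    expect_equal(got == 0, want == 0)
    relabel <- function(l) match(l, unique(l[l != 0]))
    expect_equal(relabel(got)[got != 0], relabel(want)[want != 0])
  }
})

test_that("cluster splits fire on wide two-lobe candidate sets only", {
  cfg <- tracker_config()
  x_hat <- c(0, 0, 0)
  mk_cand <- function(angles_deg) {
    set.seed(44)
    dirs <- do.call(rbind, lapply(angles_deg, function(a) {
      th <- a * pi / 180
      cbind(sin(th) + rnorm(40, 0, 0.03), rnorm(40, 0, 0.03),
            cos(th) + rnorm(40, 0, 0.03))
    }))
    dirs <- dirs / sqrt(rowSums(dirs^2))
    x <- dirs * cfg$step_size
    n <- nrow(x)
    list(x = x, d = dirs, w = rep(1 / n, n), lik = rep(0.95, n))
  }
  # single tight blob: no bifurcation
  one <- detect_bifurcation(mk_cand(0), x_hat, cfg)
  expect_false(one$is_bifurcation)
  # two blobs subtending 90 degrees: bifurcation under alpha = 50
  two90 <- detect_bifurcation(mk_cand(c(-45, 45)), x_hat, cfg)
  expect_true(two90$is_bifurcation)
  expect_equal(two90$theta, 90, tolerance = 8)
  # two blobs subtending 30 degrees: below alpha, and usually one cluster
  two30 <- detect_bifurcation(mk_cand(c(-15, 15)), x_hat, cfg)
  expect_false(two30$is_bifurcation)
  # per-cluster weights renormalise
  expect_equal(sum(two90$weights[[1]]), 1, tolerance = 1e-12)
  expect_equal(sum(two90$weights[[2]]), 1, tolerance = 1e-12)
  # degenerate input
  empty <- detect_bifurcation(list(x = matrix(0, 0, 3), w = numeric()),
                              x_hat, cfg)
  expect_false(empty$is_bifurcation)
})

test_that("tracking a straight tube stays within half a radius of the axis", {
  ph <- small_phantom()
  gt <- ph$tree$branches[[1]]
  res <- track_vessel(ph$volume, start_seed(ph), oracle_likelihood(ph$tree),
                      suite_prior(), tracker_config(rng_seed = 7, max_steps = 20))
  gxyz <- as.matrix(resample_centerline(gt, 0.05)[, c("x", "y", "z")])
  dists <- vesselpf:::nearest_gt(as.matrix(res$centerline[, c("x", "y", "z")]),
                                 gxyz)$dist
  expect_lt(mean(dists), 0.5 * gt$r[1])
  expect_equal(nrow(res$branch_seeds), 0L)
})

test_that("tracking is bit-identical under a fixed seed", {
  ph <- small_phantom()
  model <- oracle_likelihood(ph$tree)
  cfg <- tracker_config(rng_seed = 11, max_steps = 8)
  a <- track_vessel(ph$volume, start_seed(ph), model, suite_prior(), cfg)
  b <- track_vessel(ph$volume, start_seed(ph), model, suite_prior(), cfg)
  expect_identical(as.matrix(a$centerline), as.matrix(b$centerline))
  expect_identical(a$tau_trace, b$tau_trace)
  c <- track_vessel(ph$volume, start_seed(ph), model, suite_prior(),
                    tracker_config(rng_seed = 12, max_steps = 8))
  expect_false(identical(as.matrix(a$centerline), as.matrix(c$centerline)))
})

test_that("track results tidy into stepwise tibbles", {
  ph <- small_phantom()
  res <- track_vessel(ph$volume, start_seed(ph), oracle_likelihood(ph$tree),
                      suite_prior(), tracker_config(rng_seed = 7, max_steps = 6))
  td <- tidy(res)
  expect_true(all(c("step", "x", "y", "z", "tau", "theta") %in% names(td)))
  expect_equal(td$step[1], 0L)
  gl <- glance(res)
  expect_equal(gl$steps, 6L)
  expect_equal(gl$stop_reason, "max_steps")
  expect_true(all(res$tau_trace$tau >= 0 &
                    res$tau_trace$tau <= 200 * 5))
})

test_that("whole-tree tracking of an unbranched tube yields one branch", {
  ph <- small_phantom()
  gt <- ph$tree$branches[[1]]
  tr <- track_tree(ph$volume,
                   list(list(x0 = seed_of(gt, 1), x1 = seed_of(gt, 4))),
                   oracle_likelihood(ph$tree), suite_prior(),
                   tracker_config(rng_seed = 2))
  expect_equal(length(tr$branches), 1L)
  expect_equal(nrow(tr$links), 0L)
  expect_identical(track_tree(ph$volume, list(), oracle_likelihood(ph$tree),
                              suite_prior(), tracker_config())$branches, list())
})
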