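test_that("direction prior concentrates where the training curves put it", {
  straight <- centerline(cbind(0, 0, seq(0, 30), NA)[, 1:3])
  pr <- learn_direction_prior(list(straight), step = 1, floor = 0)
  expect_equal(pr$prob[1], 1)
  expect_equal(sum(pr$prob), 1, tolerance = 1e-12)

  # planar arc of constant curvature, 12.5 degrees per 1 mm step
  phi <- seq(0, 150, by = 0.5) * pi / 180
  R <- 1 / (12.5 * pi / 180)   # step / angle
  arc <- centerline(cbind(R * cos(phi), R * sin(phi), 0))
  pr2 <- learn_direction_prior(list(arc), step = 1)
  bin <- findInterval(12.5, pr2$breaks, rightmost.closed = TRUE, all.inside = TRUE)
  expect_gt(pr2$prob[bin], 0.95)
})

test_that("empty bins are floored, never zero", {
  straight <- centerline(cbind(0, 0, seq(0, 30)))
  pr <- learn_direction_prior(list(straight), step = 1)
  expect_true(all(pr$prob > 0))
  expect_equal(sum(pr$prob), 1, tolerance = 1e-12)
  expect_error(learn_direction_prior(list(), step = 1), "no direction-change")
})

test_that("direction prior evaluates the bin of the enclosed angle", {
  straight <- centerline(cbind(0, 0, seq(0, 30)))
  pr <- learn_direction_prior(list(straight), step = 1)
  expect_equal(direction_prior_eval(pr, c(0, 0, 1), c(0, 0, 1)), pr$prob[1])
  expect_equal(direction_prior_eval(pr, c(0, 0, 1), c(1, 0, 0)),
               pr$prob[findInterval(90, pr$breaks, all.inside = TRUE)])
  anti <- direction_prior_eval(pr, c(0, 0, 1), c(0, 0, -1))
  expect_gt(anti, 0)           # floored tail, never exactly zero
  expect_error(direction_prior_eval(pr, c(0, 0, 2), c(0, 0, 1)), "unit")
})

test_that("direction prior persists as two-column text", {
  straight <- centerline(cbind(0, 0, seq(0, 30)))
  pr <- learn_direction_prior(list(straight), step = 1)
  p <- file.path(withr::local_tempdir(), "prior.txt")
  write_direction_prior(pr, p)
  back <- read_direction_prior(p)
  expect_equal(back$prob, pr$prob, tolerance = 1e-12)
  expect_equal(back$breaks, pr$breaks, tolerance = 1e-9)
})

test_that("patch histograms are normalised over fixed global bins", {
  h <- patch_histogram(rep(5, 100), n_bins = 8, range = c(0, 10))
  expect_equal(sum(h$prob), 1, tolerance = 1e-12)
  expect_equal(sum(h$prob > 0), 1L)       # constant patch: one occupied bin

  two <- patch_histogram(c(rep(1, 50), rep(9, 50)), n_bins = 8, range = c(0, 10))
  expect_equal(sort(two$prob[two$prob > 0]), c(0.5, 0.5))
  expect_error(patch_histogram(1:5, n_bins = 8, range = c(3, 3)), "degenerate")
  expect_error(patch_histogram(1:5, n_bins = 1, range = c(0, 1)), "at least 2")
  # out-of-range intensities clamp into the end bins
  clamped <- patch_histogram(c(-5, 15), n_bins = 4, range = c(0, 10))
  expect_equal(clamped$prob, c(0.5, 0, 0, 0.5))
})

test_that("batched patch histograms match the scalar path", {
  set.seed(3)
  px <- matrix(runif(5 * 64, 0, 10), 5, 64)
  H <- vesselpf:::patch_histograms(px, 8, c(0, 10))
  for (i in 1:5) {
    expect_equal(H[i, ], patch_histogram(px[i, ], 8, c(0, 10))$prob)
  }
})

test_that("Jensen-Shannon divergence has its exact landmark values", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), 1)
  # hand evaluation: P=(1,0), Q=(1/2,1/2), M=(3/4,1/4)
  hand <- 0.5 * log2(4 / 3) + 0.5 * (0.5 * log2(2 / 3) + 0.5 * log2(2))
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), hand, tolerance = 1e-12)
  expect_equal(round(hand, 4), 0.3113)
  expect_error(js_divergence(c(1, 0), c(1, 0, 0)), "binning")
})

test_that("JS divergence matches brute-force summation on random histograms", {
  set.seed(7)
  for (i in 1:100) {
    p <- runif(8); p <- p / sum(p)
    q <- runif(8); q <- q / sum(q)
    if (i %% 3 == 0) p[sample(8, 3)] <- 0; p <- p / sum(p)
    expect_equal(js_divergence(p, q), js_brute(p, q), tolerance = 1e-12)
    expect_equal(js_divergence(p, q), js_divergence(q, p), tolerance = 1e-12)
    expect_gte(js_divergence(p, q), 0)
    expect_lte(js_divergence(p, q), 1)
  }
})

test_that("paired row-wise JS agrees with the scalar implementation", {
  set.seed(8)
  P <- matrix(runif(40), 5, 8); P <- P / rowSums(P)
  Q <- matrix(runif(40), 5, 8); Q <- Q / rowSums(Q)
  P[2, c(1, 5)] <- 0; P <- P / rowSums(P)
  d <- vesselpf:::js_divergence_paired(P, Q)
  for (i in 1:5) expect_equal(d[i], js_divergence(P[i, ], Q[i, ]), tolerance = 1e-12)
})

test_that("smoothstep weighting is the exact cubic with hard clamps", {
  expect_equal(smoothstep_weight(0), 1)
  expect_equal(smoothstep_weight(1), 0)
  expect_equal(smoothstep_weight(0.5), 0.5)
  expect_equal(smoothstep_weight(0.25), 2 * 0.25^3 - 3 * 0.25^2 + 1)
  expect_equal(smoothstep_weight(c(-1, 2, 1.5)), c(0, 0, 0))
  # monotone non-increasing on [0, 1], continuous at the upper clamp
  x <- seq(0, 1, by = 1e-3)
  w <- smoothstep_weight(x)
  expect_true(all(diff(w) <= 1e-12))
  expect_lt(abs(smoothstep_weight(1e-9) - 1), 1e-8)
  expect_lt(smoothstep_weight(1 - 1e-9), 1e-8)
  expect_equal(smoothstep_weight(1 + 1e-9), 0)
})

test_that("patch prior composes scale and smoothstep", {
  h <- patch_histogram(rep(1, 10), 8, c(0, 2))
  expect_equal(patch_prior(h, h, lambda = 6), 1)
  # D = 0.3113 with lambda 6 exceeds the clamp
  expect_equal(smoothstep_weight(6 * js_divergence(c(1, 0), c(0.5, 0.5))), 0)
  # D = 1/12 with lambda 6 lands exactly on the half-way point
  expect_equal(smoothstep_weight(6 * (1 / 12)), 0.5)
  expect_error(patch_prior(h, h, lambda = 0), "positive")
})

test_that("transition prior factorises into its two terms", {
  straight <- centerline(cbind(0, 0, seq(0, 30)))
  pr <- learn_direction_prior(list(straight), step = 1)
  set.seed(4)
  a <- runif(8); a <- a / sum(a)
  b <- runif(8); b <- b / sum(b)
  ha <- structure(list(prob = a, range = c(0, 1)), class = "patch_histogram")
  hb <- structure(list(prob = b, range = c(0, 1)), class = "patch_histogram")
  d1 <- c(0, 0, 1); d2 <- c(sin(0.1), 0, cos(0.1))
  got <- transition_prior(d1, d2, ha, hb, pr, lambda = 6)
  want <- direction_prior_eval(pr, d1, d2) * patch_prior(ha, hb, lambda = 6)
  expect_equal(got, want, tolerance = 1e-12)
  expect_gte(got, 0)
})

test_that("suite-learned prior concentrates at small angles", {
  pr <- suite_prior()
  below30 <- sum(pr$prob[pr$breaks[-length(pr$breaks)] < 30])
  expect_gt(below30, 0.8)
})
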