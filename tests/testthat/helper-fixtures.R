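# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small, fast phantom for unit tests: straight tube, ~16 mm
small_phantom <- function() {
  fixture("small_phantom", function() {
    generate_phantom(phantom_spec(shape = c(64, 64, 64), spacing = c(0.35, 0.35, 0.35),
                                  length = 14, rng_seed = 101))
  })
}

# the canonical 10-case suite (seeded)
phantom_suite <- function() {
  fixture("phantom_suite", function() default_phantom_suite(1))
}

# direction prior learned from the suite's root-to-leaf paths
suite_prior <- function() {
  fixture("suite_prior", function() {
    paths <- unlist(lapply(phantom_suite(), function(p) tree_paths(p$tree)),
                    recursive = FALSE)
    learn_direction_prior(paths, step = 1.0)
  })
}

# straight ground-truth line along +z with constant radius, as a vessel tree
toy_line_tree <- function(radius = 1, len = 20) {
  z <- seq(0, len, by = 0.2)
  cl <- centerline(cbind(0, 0, z, radius), label = "line")
  vessel_tree(list(cl))
}

seed_of <- function(cl, k = 1L) {
  as.numeric(as.matrix(cl[k, c("x", "y", "z")]))
}

start_seed <- function(ph) {
  gt <- ph$tree$branches[[1]]
  list(position = seed_of(gt, 1L),
       direction = centerline_directions(gt)[1, ])
}

# independent brute-force Jensen-Shannon divergence (plain summation, base 2)
js_brute <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

# independent brute-force CAT08 marking on resampled point sets
brute_marks <- function(ref_xyz, ref_r, met_xyz) {
  nr <- nrow(ref_xyz); nm <- nrow(met_xyz)
  ref_mark <- character(nr); met_mark <- character(nm)
  for (i in seq_len(nr)) {
    ok <- FALSE
    for (j in seq_len(nm)) {
      if (sqrt(sum((ref_xyz[i, ] - met_xyz[j, ])^2)) < ref_r[i]) { ok <- TRUE; break }
    }
    ref_mark[i] <- if (ok) "TPR" else "FN"
  }
  for (j in seq_len(nm)) {
    ok <- FALSE
    for (i in seq_len(nr)) {
      if (sqrt(sum((ref_xyz[i, ] - met_xyz[j, ])^2)) < ref_r[i]) { ok <- TRUE; break }
    }
    met_mark[j] <- if (ok) "TPM" else "FP"
  }
  list(ref = ref_mark, method = met_mark)
}

brute_ov <- function(marks) {
  (sum(marks$method == "TPM") + sum(marks$ref == "TPR")) /
    (length(marks$method) + length(marks$ref))
}

# brute-force density-reachability DBSCAN oracle for small point sets
brute_dbscan <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  # adjacency between cores that are eps-close; expand closures
  labels <- integer(n)
  cl <- 0L
  repeat {
    i <- which(core & labels == 0L)[1]
    if (is.na(i)) break
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & labels == 0L &
                      apply(nb[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    labels[comp] <- cl
    # border points: non-core within eps of this component's cores
    border <- which(!core & labels == 0L &
                      apply(nb[, comp, drop = FALSE], 1, any))
    labels[border] <- cl
  }
  labels
}
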