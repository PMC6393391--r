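# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Fold-line phantom under the standard study conditions.
fold_phantom <- function(angle, noise_sd, seed = 101) {
  cached(sprintf("fold_%g_%g_%d", angle, noise_sd, seed), function() {
    make_fold_line_stack(fold_line_spec(angle, noise_sd, seed = seed))
  })
}

# Initial skeleton for the fold-line experiments: the densely sampled ground
# truth perturbed by +-2 um per axis (endpoints fixed). A non-NULL spacing
# first resamples the truth to a tracer-like node spacing.
fold_initial <- function(phantom, seed = 7, magnitude = 2, spacing = NULL,
                         axes = c("x", "y", "z")) {
  base <- if (is.null(spacing)) phantom$ground_truth
          else resample_path(phantom$ground_truth, spacing)
  perturb_polyline(base, magnitude, seed = seed, axes = axes)
}

# Noiseless symmetric Y phantom.
y_phantom <- function(noise_sd = 0, seed = 101) {
  cached(sprintf("y_%g_%d", noise_sd, seed), function() {
    make_branch_phantom(branch_phantom_spec(noise_sd = noise_sd, seed = seed))
  })
}

# Segment fit on a fold phantom, cached by condition.
fold_fit <- function(angle, noise_sd, penalty = "l1", seed = 101, pseed = 7) {
  cached(sprintf("fit_%g_%g_%s_%d_%d", angle, noise_sd, penalty, seed, pseed), function() {
    ph <- fold_phantom(angle, noise_sd, seed)
    init <- fold_initial(ph, seed = pseed)
    if (penalty == "l1") optimize_segment(init, ph$image)
    else l2_comparator(init, ph$image)
  })
}

# Displace one node of a tree by a vector.
displace_node <- function(tree, id, offset) {
  i <- match(id, tree$id)
  tree$x[i] <- tree$x[i] + offset[1]
  tree$y[i] <- tree$y[i] + offset[2]
  tree$z[i] <- tree$z[i] + offset[3]
  tree
}

# Small deterministic random polyline with bounded turning, for resampling
# and metric property tests.
random_polyline <- function(n, seed, step_range = c(2, 5), max_turn_deg = 60,
                            start = c(0, 0, 0)) {
  with_seed_(seed, {
    dir <- c(1, 0, 0)
    pts <- matrix(0, n, 3)
    pts[1, ] <- start
    for (i in 2:n) {
      ang <- runif(1, 0, max_turn_deg) * pi / 180
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      # rotate dir by ang about a random axis (Rodrigues)
      dir <- dir * cos(ang) + pracma_cross(axis, dir) * sin(ang) +
        axis * sum(axis * dir) * (1 - cos(ang))
      dir <- dir / sqrt(sum(dir^2))
      pts[i, ] <- pts[i - 1, ] + runif(1, step_range[1], step_range[2]) * dir
    }
    skeleton_path(pts)
  })
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Random x-monotone polyline spanning > 55 um in x.
random_monotone_polyline <- function(seed, n = 40) {
  with_seed_(seed, {
    xs <- cumsum(runif(n, 1.2, 2.5))
    skeleton_path(xs, cumsum(runif(n, -1, 1)), cumsum(runif(n, -1, 1)))
  })
}

norms <- function(M) sqrt(rowSums(M^2))

second_diff_norms <- function(path) {
  P <- cbind(path$x, path$y, path$z)
  n <- nrow(P)
  norms(2 * P[2:(n - 1), , drop = FALSE] - P[1:(n - 2), , drop = FALSE] - P[3:n, , drop = FALSE])
}

mean_dist_to_truth <- function(path, truth) {
  P <- cbind(path$x, path$y, path$z)
  Tm <- cbind(truth$x, truth$y, truth$z)
  n <- nrow(Tm)
  best <- rep(Inf, nrow(P))
  for (s in seq_len(n - 1)) {
    a <- Tm[s, ]; d <- Tm[s + 1, ] - a
    dd <- sum(d * d)
    w <- sweep(P, 2, a)
    t <- if (dd > 0) pmin(pmax((w %*% d) / dd, 0), 1) else 0
    best <- pmin(best, sqrt(rowSums((w - outer(as.vector(t), d))^2)))
  }
  mean(best)
}
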