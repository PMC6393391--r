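test_that("intensity score matches hand summation and trivial cases", {
  zero <- volume_image(array(0, c(9, 9, 9)))
  expect_equal(intensity_score_g(zero, c(4.5, 4.5, 4.5)), 0)
  expect_equal(intensity_score_gradient(zero, c(4.5, 4.5, 4.5)), c(0, 0, 0))

  arr <- array(0, c(9, 9, 9)); arr[5, 5, 5] <- 100
  one <- volume_image(arr)
  expect_equal(intensity_score_g(one, c(4.5, 4.5, 4.5)), -100)

  # two nonzero voxels: term-by-term hand summation
  arr2 <- array(0, c(9, 9, 9)); arr2[5, 5, 5] <- 10; arr2[6, 5, 5] <- 20
  img2 <- volume_image(arr2)
  p <- c(4.7, 4.5, 4.4)
  s <- 1.73
  hand <- -(10 * exp(-sum((c(4.5, 4.5, 4.5) - p)^2) / (2 * s^2)) +
              20 * exp(-sum((c(5.5, 4.5, 4.5) - p)^2) / (2 * s^2)))
  expect_equal(intensity_score_g(img2, p, s, 1), hand, tolerance = 1e-12)
})

test_that("score is non-positive and zero out of the volume", {
  ph <- fold_phantom(30, 50)
  set.seed(5)
  for (i in 1:10) {
    p <- c(runif(1, 0, 156), runif(1, 0, 156), runif(1, 0, 57))
    expect_lte(intensity_score_g(ph$image, p), 0)
  }
  expect_equal(intensity_score_g(ph$image, c(-50, 10, 10)), 0)
})

test_that("a bright voxel beside a point pulls the score gradient toward it", {
  arr <- array(0, c(9, 9, 9)); arr[6, 5, 5] <- 200
  img <- volume_image(arr)
  gr <- intensity_score_gradient(img, c(4.5, 4.5, 4.5))
  expect_gt(-gr[1], 0)  # descending g moves +x, toward the voxel
  expect_equal(gr[2:3], c(0, 0), tolerance = 1e-12)
})

test_that("the analytic gradient agrees with central finite differences", {
  ph <- fold_phantom(30, 50)
  cfg <- solver_config()
  set.seed(11)
  eps <- 1e-4
  for (i in 1:20) {
    # generic positions away from voxel boundaries, near the structure
    p <- c(runif(1, 40, 110), runif(1, 35, 130), runif(1, 20, 38))
    p <- floor(p) + runif(3, 0.3, 0.7)
    an <- intensity_score_gradient(ph$image, p, cfg$sigma, cfg$neighborhood_halfwidth)
    fd <- vapply(1:3, function(a) {
      e <- c(0, 0, 0); e[a] <- eps
      (intensity_score_g(ph$image, p + e, cfg$sigma, cfg$neighborhood_halfwidth) -
         intensity_score_g(ph$image, p - e, cfg$sigma, cfg$neighborhood_halfwidth)) /
        (2 * eps)
    }, double(1))
    expect_lt(sqrt(sum((an - fd)^2)) / max(sqrt(sum(fd^2)), 1e-8), 1e-4)
  }
})

test_that("the gradient respects anisotropic voxel sizes", {
  arr <- array(0, c(9, 9, 9)); arr[6, 6, 6] <- 150
  img <- volume_image(arr, voxel_size = c(0.5, 0.5, 2))
  p <- c(2.6, 2.7, 10.4)
  eps <- 1e-5
  an <- intensity_score_gradient(img, p, 1.73, 4)
  fd <- vapply(1:3, function(a) {
    e <- c(0, 0, 0); e[a] <- eps
    (intensity_score_g(img, p + e, 1.73, 4) -
       intensity_score_g(img, p - e, 1.73, 4)) / (2 * eps)
  }, double(1))
  expect_equal(an, fd, tolerance = 1e-4)
})

test_that("soft_threshold matches its closed form and the grid-search oracle", {
  expect_equal(soft_threshold(c(2, -0.5, 1.5), 0), c(2, -0.5, 1.5))
  expect_equal(soft_threshold(c(0.5, -0.5, 0), 1), c(0, 0, 0))
  expect_equal(soft_threshold(c(3, -4, 0.2), 1), c(2, -3, 0))
  # 1-D grid minimization of lam*|d| + (1/(2*mu))*(d - v)^2, t = lam*mu
  set.seed(33)
  for (i in 1:100) {
    v <- runif(1, -5, 5)
    lam <- runif(1, 0.05, 2)
    mu <- runif(1, 0.2, 2)
    grid <- seq(-6, 6, by = 5e-4)
    oracle <- grid[which.min(lam * abs(grid) + (grid - v)^2 / (2 * mu))]
    expect_lt(abs(soft_threshold(v, lam * mu) - oracle), 1e-3)
  }
})

test_that("a straight path on a straight bright ridge is already stationary", {
  shape <- c(60, 21, 21)
  tube <- rasterize_polyline(skeleton_path(c(5.5, 54.5), c(10.5, 10.5), c(10.5, 10.5)),
                             shape)
  img <- convolve_normalize(tube, 1.73)
  path <- skeleton_path(seq(15.5, 45.5, by = 2), rep(10.5, 16), rep(10.5, 16))
  cfg <- solver_config()
  st <- skelasso:::new_bregman_state(path, img, cfg)
  st2 <- split_bregman_iteration(st, img, cfg)
  expect_lt(max(abs(st2$p - st$p)), 1e-3)
})

test_that("a huge sparsity weight shrinks every split variable to zero", {
  ph <- fold_phantom(30, 50)
  init <- fold_initial(ph)
  cfg <- solver_config(lam = 1e6)
  st <- skelasso:::new_bregman_state(init, ph$image, cfg)
  st2 <- split_bregman_iteration(st, ph$image, cfg)
  expect_true(all(st2$d == 0))
})

test_that("optimize_segment freezes endpoints bitwise and runs 5 outer iterations", {
  ph <- fold_phantom(30, 50)
  init <- fold_initial(ph)
  fit <- fold_fit(30, 50)
  expect_identical(unlist(fit[1, ]), unlist(init[1, ]))
  expect_identical(unlist(fit[nrow(fit), ]), unlist(init[nrow(init), ]))
  expect_equal(tidy(fit)$iteration, 0:5)
})

test_that("optimize_segment returns short inputs unchanged with a warning", {
  img <- volume_image(array(1, c(5, 5, 5)))
  two <- skeleton_path(c(1, 3), c(1, 1), c(1, 1))
  expect_warning(out <- optimize_segment(two, img), "nothing to optimize")
  expect_equal(as.data.frame(out)[, 1:3], as.data.frame(two), ignore_attr = TRUE)
})

test_that("coincident consecutive points are deduplicated before optimization", {
  img <- volume_image(array(1, c(8, 8, 8)))
  p <- skeleton_path(c(1, 2, 2, 3, 4), c(1, 1, 1, 1, 1), c(1, 1, 1, 1, 1))
  fit <- optimize_segment(p, img, solver_config(outer_iters = 1, inner_grad_steps = 1))
  expect_equal(nrow(fit), 4)
})

test_that("the objective decreases on the fixed-seed phantom fixtures", {
  for (cond in list(c(30, 50), c(90, 100))) {
    fit <- fold_fit(cond[1], cond[2])
    gl <- glance(fit)
    expect_lte(gl$objective_final, gl$objective_initial)
  }
})

test_that("interior second differences are sparse after optimization", {
  fit <- fold_fit(30, 50)
  s <- second_diff_norms(fit)
  expect_gte(mean(s < 0.2 * max(s)), 0.8)
})

test_that("the ridge comparator drifts little on a straight ridge and kills d as lam grows", {
  shape <- c(60, 21, 21)
  tube <- rasterize_polyline(skeleton_path(c(5.5, 54.5), c(10.5, 10.5), c(10.5, 10.5)),
                             shape)
  img <- convolve_normalize(tube, 1.73)
  path <- skeleton_path(seq(15.5, 45.5, by = 2), rep(10.5, 16), rep(10.5, 16))
  out <- l2_comparator(path, img)
  expect_lt(max(abs(as.matrix(out) - as.matrix(path))), 1e-3)
  cfg <- solver_config(lam = 1e8)
  st <- skelasso:::new_bregman_state(path, img, cfg)
  st2 <- split_bregman_iteration(st, img, cfg, penalty = "l2")
  expect_lt(max(abs(st2$d)), 1e-6)
})

test_that("the divergence guard names the offending parameters", {
  ph <- fold_phantom(30, 50)
  init <- fold_initial(ph)
  err <- tryCatch(
    optimize_segment(init, ph$image, solver_config(step_size = 1e160)),
    error = function(e) e)
  expect_s3_class(err, "skelasso_divergence_error")
  expect_match(conditionMessage(err), "step_size")
})
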