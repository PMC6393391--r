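test_that("rasterize_polyline marks exactly the spanned voxels on an axis line", {
  p <- skeleton_path(c(2.5, 11.5), c(3.5, 3.5), c(4.5, 4.5))
  vol <- rasterize_polyline(p, c(16, 8, 8))
  expect_equal(sum(vol), 10)
  expect_true(all(vol[3:12, 4, 5] == 1))
  expect_true(all(vol %in% c(0, 1)))
})

test_that("a single-point path at a voxel centre rasterizes to that voxel alone", {
  vol <- rasterize_polyline(skeleton_path(3.5, 4.5, 2.5), c(8, 8, 8))
  expect_equal(sum(vol), 1)
  expect_equal(vol[4, 5, 3], 1)
})

test_that("diagonal rasterization equals the brute-force centre-distance rule", {
  a <- c(1.2, 1.7, 2.1); b <- c(9.8, 8.3, 7.9)
  vol <- rasterize_polyline(skeleton_path(rbind(a, b)), c(12, 12, 12))
  idx <- as.matrix(expand.grid(0:11, 0:11, 0:11))
  ctr <- idx + 0.5
  d <- b - a; dd <- sum(d * d)
  w <- sweep(ctr, 2, a)
  t <- pmin(pmax((w %*% d) / dd, 0), 1)
  dist <- sqrt(rowSums((w - outer(as.vector(t), d))^2))
  expected <- as.numeric(dist <= sqrt(3) / 2)
  expect_identical(as.vector(vol[idx + 1]), expected)
})

test_that("rasterize_polyline rejects out-of-volume polylines", {
  expect_error(rasterize_polyline(skeleton_path(c(2, 40), c(2, 2), c(2, 2)), c(8, 8, 8)),
               class = "skelasso_bounds_error")
})

test_that("convolve_normalize peaks at exactly 255 and follows the Gaussian profile", {
  arr <- array(0, c(15, 15, 15)); arr[8, 8, 8] <- 1
  out <- convolve_normalize(volume_image(arr), 1.73)
  expect_equal(max(out), 255)
  expect_equal(which(out == 255, arr.ind = TRUE)[1, ], c(dim1 = 8, dim2 = 8, dim3 = 8))
  ratio <- out[8, 8, 8] / out[9, 8, 8]
  expect_equal(ratio, exp(1 / (2 * 1.73^2)), tolerance = 1e-6)
  expect_error(convolve_normalize(volume_image(array(0, c(4, 4, 4)))),
               class = "skelasso_degenerate_input")
})

test_that("convolve_normalize commutes with mirroring", {
  set.seed(9)
  arr <- array(0, c(10, 9, 8))
  arr[sample(length(arr), 25)] <- 1
  out <- convolve_normalize(volume_image(arr), 1.5)
  mirrored_in <- volume_image(arr[10:1, , ])
  out_m <- convolve_normalize(mirrored_in, 1.5)
  expect_equal(unclass(out_m), unclass(out)[10:1, , ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("add_noise is deterministic, clipped at zero, with the clipped-normal mean", {
  vol <- volume_image(array(0, c(50, 50, 50)))
  expect_identical(add_noise(vol, 0, 0, 1), vol)
  n1 <- add_noise(vol, 0, 50, seed = 21)
  n2 <- add_noise(vol, 0, 50, seed = 21)
  expect_identical(unclass(n1), unclass(n2))
  expect_gte(min(n1), 0)
  # E[max(X, 0)] = sd / sqrt(2*pi) for X ~ N(0, sd)
  expected <- 50 / sqrt(2 * pi)
  se <- sqrt(50^2 * (1 / 2 - 1 / (2 * pi)) - 0) / sqrt(length(vol))
  se <- sqrt(50^2 / 2 - expected^2) / sqrt(length(vol))
  expect_lt(abs(mean(n1) - expected), 3 * se)
})

test_that("fold-line stacks have the declared size, corner angle and ridge", {
  spec <- fold_line_spec(90, 0)
  ph <- fold_phantom(90, 0)
  expect_equal(dim(ph$image), c(156L, 156L, 57L))
  expect_equal(max(ph$image), 255)
  # corner angle from the ground truth geometry
  u <- spec$endpoint_a - spec$corner; v <- spec$endpoint_b - spec$corner
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_lt(abs(ang - 90), 0.5)
  # truth is densely sampled
  gaps <- sqrt(diff(ph$ground_truth$x)^2 + diff(ph$ground_truth$y)^2 +
                 diff(ph$ground_truth$z)^2)
  expect_lte(max(gaps), 0.5 + 1e-9)
  # noiseless ridge: per-y-plane argmax lies on the fold line +-1 voxel
  Tm <- as.matrix(ph$ground_truth)
  for (yy in c(60, 70, 80)) {
    sl <- unclass(ph$image)[, yy + 1, ]
    am <- which(sl == max(sl), arr.ind = TRUE)[1, ] - 1 + 0.5
    near <- Tm[abs(Tm[, 2] - (yy + 0.5)) < 0.6, , drop = FALSE]
    expect_lt(min(abs(near[, 1] - am[1])), 1.1)
    expect_lt(min(abs(near[, 3] - am[2])), 1.1)
  }
})

test_that("fold-line generation is a pure function of its spec", {
  a <- make_fold_line_stack(fold_line_spec(30, 50, seed = 77))
  b <- make_fold_line_stack(fold_line_spec(30, 50, seed = 77))
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(as.data.frame(a$ground_truth), as.data.frame(b$ground_truth))
})

test_that("branch phantoms have their junction, intensity ordering and topology", {
  ph <- y_phantom()
  am <- which(unclass(ph$image) == max(ph$image), arr.ind = TRUE)[1, ] - 1 + 0.5
  expect_lt(sqrt(sum((am - c(32, 32, 16))^2)), sqrt(3))
  br <- find_branch_nodes(ph$ground_truth)
  expect_equal(nrow(br), 1)
  expect_equal(br$n_children, 2L)
  expect_equal(skelasso:::node_position(ph$ground_truth, br$id), c(32, 32, 16))

  spec2 <- branch_phantom_spec(arm_intensities = c(255, 128, 128))
  ph2 <- make_branch_phantom(spec2)
  sample_arm <- function(k) {
    tt <- seq(4, 20, by = 1)
    pts <- outer(tt, spec2$arm_directions[k, ]) +
      matrix(spec2$junction, length(tt), 3, byrow = TRUE)
    idx <- floor(pts)
    mean(unclass(ph2$image)[idx + 1])
  }
  expect_gt(sample_arm(1), sample_arm(2))
})

test_that("the noiseless ground truth outscores laterally displaced copies", {
  ph <- fold_phantom(90, 0)
  cfg <- solver_config()
  gt_path <- resample_path(ph$ground_truth, 1)
  score <- function(p) {
    sum(skelasso:::g_batch(ph$image, as.matrix(p), cfg$sigma,
                           cfg$neighborhood_halfwidth)$g)
  }
  s0 <- score(gt_path)
  for (off in list(c(0, 0, 2), c(0, 0, -2), c(2, 0, 0))) {
    shifted <- skeleton_path(sweep(as.matrix(gt_path), 2, -off))
    expect_lt(s0, score(shifted))
  }
})
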