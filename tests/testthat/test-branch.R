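straight_tube_image <- function() {
  cached("straight_tube_60", function() {
    tube <- rasterize_polyline(
      skeleton_path(c(4.5, 55.5), c(20.5, 20.5), c(10.5, 10.5)), c(60, 41, 21))
    convolve_normalize(tube, 1.73)
  })
}

# A cross: tube along x at y = 20.5 plus a perpendicular tube along y at
# x = 30.5, meeting at the true junction (30.5, 20.5, 10.5).
cross_image <- function() {
  cached("cross_60", function() {
    arr <- unclass(rasterize_polyline(
      skeleton_path(c(4.5, 55.5), c(20.5, 20.5), c(10.5, 10.5)), c(60, 41, 21)))
    arr2 <- unclass(rasterize_polyline(
      skeleton_path(c(30.5, 30.5), c(20.5, 38.5), c(10.5, 10.5)), c(60, 41, 21)))
    convolve_normalize(volume_image(pmax(arr, arr2)), 1.73)
  })
}

test_that("build_frame reproduces the orientation arithmetic", {
  S1 <- skeleton_path(seq(0, 30), rep(0, 31), rep(0, 31))
  # S2 leaves the branch point at (15, 0, 0) along +y
  S2 <- skeleton_path(rep(15, 11), seq(0, 10), rep(0, 11))
  fo <- build_frame(S2, c(1, 1, 1), S1)
  expect_equal(as.numeric(fo$dv1), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(sqrt(sum((fo$projector %*% fo$dv1)^2)), 1e-9)
  # projector is symmetric idempotent
  expect_equal(fo$projector, t(fo$projector))
  expect_equal(fo$projector %*% fo$projector, fo$projector, tolerance = 1e-12)
  # p_fx clears S1 by more than 3 voxels, p_v1 clears p_fx
  expect_gt(min(sqrt((fo$p_fx[1] - S1$x)^2 + fo$p_fx[2]^2)), 3)
  expect_gt(sqrt(sum((fo$p_v1 - fo$p_fx)^2)), 3)
})

test_that("explicit Gram-Schmidt completions reproduce the projector", {
  set.seed(17)
  for (i in 1:100) {
    dv1 <- rnorm(3); dv1 <- dv1 / sqrt(sum(dv1^2))
    aux <- rnorm(3)
    dv2 <- aux - sum(aux * dv1) * dv1; dv2 <- dv2 / sqrt(sum(dv2^2))
    dv3 <- c(dv1[2] * dv2[3] - dv1[3] * dv2[2],
             dv1[3] * dv2[1] - dv1[1] * dv2[3],
             dv1[1] * dv2[2] - dv1[2] * dv2[1])
    completion <- tcrossprod(dv2) + tcrossprod(dv3)
    expect_equal(completion, diag(3) - tcrossprod(dv1), tolerance = 1e-9)
  }
})

test_that("branch_objective computes the perpendicular-offset quadratic", {
  fo <- structure(list(p_fx = c(0, 0, 0), p_v1 = c(3, 0, 0), dv1 = c(1, 0, 0),
                       projector = diag(3) - tcrossprod(c(1, 0, 0)),
                       lam = 1, template = NULL, g_scale = 1),
                  class = "frame_objective")
  expect_equal(branch_objective(fo, c(5, 2, 0)), 4)
  expect_equal(branch_objective(fo, c(-7, 0, 0)), 0)
  set.seed(4)
  for (i in 1:20) {
    dv1 <- rnorm(3); dv1 <- dv1 / sqrt(sum(dv1^2))
    p_fx <- rnorm(3, sd = 5); p <- rnorm(3, sd = 5)
    lam <- runif(1, 0.1, 3)
    fo2 <- structure(list(p_fx = p_fx, p_v1 = p_fx + 3 * dv1, dv1 = dv1,
                          projector = diag(3) - tcrossprod(dv1),
                          lam = lam, template = NULL, g_scale = 1),
                     class = "frame_objective")
    w <- p_fx - p
    expect_equal(branch_objective(fo2, p),
                 lam * as.numeric(t(w) %*% (diag(3) - tcrossprod(dv1)) %*% w),
                 tolerance = 1e-12)
  }
})

test_that("skeleton templates are flat along the path and peaked against offsets", {
  tp <- resample_path(skeleton_path(c(5, 55), c(10.3, 10.3), c(9.8, 9.8)), 1)
  tmpl <- skeleton_template_image(tp, 1.73)
  P <- as.matrix(tp)
  idx <- skelasso:::voxel_index(tmpl, P)
  v <- unclass(tmpl)[idx + 1]
  interior <- v[4:(length(v) - 3)]
  expect_equal(max(unclass(tmpl)), 255)
  expect_true(all(interior >= 0.85 * 255))
  # on-path intensity beats a 3-sigma lateral offset everywhere
  off <- P; off[, 2] <- off[, 2] + 3 * 1.73
  v_off <- unclass(tmpl)[skelasso:::voxel_index(tmpl, off) + 1]
  expect_true(all(v > v_off))
})

test_that("a single-point template is a Gaussian blob peaking at the point", {
  tmpl <- skeleton_template_image(skeleton_path(10.5, 10.5, 10.5), 1.73,
                                  shape = c(21, 21, 21))
  expect_equal(max(unclass(tmpl)), 255)
  am <- which(unclass(tmpl) == 255, arr.ind = TRUE)[1, ]
  expect_equal(as.integer(am), c(11L, 11L, 11L))
})

test_that("optimize_attachment matches the exhaustive objective scan on a cross", {
  img <- cross_image()
  # through path along the horizontal tube; the side tube meets it at x = 30.5
  S1 <- skeleton_path(seq(10.5, 50.5, by = 2), rep(20.5, 21), rep(10.5, 21))
  # initial branch point displaced 5 um along the through tube; the rest of
  # the side path is traced on the true perpendicular tube
  bp0 <- c(35.5, 20.5, 10.5)
  S2 <- skeleton_path(rbind(bp0, cbind(rep(30.5, 9), 20.5 + seq(2, 18, by = 2), 10.5)))
  cfg <- solver_config()
  res <- optimize_attachment(S1, S2, img, cfg)
  expect_lt(abs(res[1] - 30.5), cfg$resample_spacing + 1e-9)
  expect_lt(abs(res[2] - 20.5), 1)
  # independent exhaustive scan of the same objective over the resampled path
  S1s <- resample_path(suppressWarnings(optimize_segment(S1, img, cfg)),
                       cfg$resample_spacing)
  tmpl <- skeleton_template_image(S1s, cfg$template_sigma,
                                  voxel_size = voxel_size(img))
  fo <- build_frame(S2, voxel_size(img), S1s, cfg$branch_lam)
  fo$template <- tmpl
  C <- as.matrix(S1s)
  g_all <- skelasso:::g_batch(tmpl, C, cfg$sigma, cfg$neighborhood_halfwidth)$g
  fo$g_scale <- max(abs(g_all), 1e-12)
  scan <- vapply(seq_len(nrow(C)), function(i)
    branch_objective(fo, C[i, ], cfg$sigma, cfg$neighborhood_halfwidth), double(1))
  best <- C[which.min(scan), ]
  # first fixed-point update must coincide with the independent scan
  one_iter <- solver_config(branch_max_iters = 1, branch_tol = 1e-9)
  res1 <- suppressWarnings(optimize_attachment(S1, S2, img, one_iter))
  expect_equal(as.numeric(res1), as.numeric(best), tolerance = 1e-9)
})

test_that("an attachment starting at its fixed point stays there", {
  img <- cross_image()
  S1 <- skeleton_path(seq(10.5, 50.5, by = 2), rep(20.5, 21), rep(10.5, 21))
  bp <- c(30.5, 20.5, 10.5)
  S2 <- skeleton_path(rbind(bp, cbind(rep(30.5, 9), 20.5 + seq(2, 18, by = 2), 10.5)))
  cfg <- solver_config()
  res <- optimize_attachment(S1, S2, img, cfg)
  expect_lt(sqrt(sum((as.numeric(res) - bp)^2)), cfg$resample_spacing + 1e-9)
  expect_true(attr(res, "converged"))
})

test_that("a side path too short for a frame returns the input with a warning", {
  img <- straight_tube_image()
  S1 <- skeleton_path(seq(10.5, 50.5, by = 2), rep(20.5, 21), rep(10.5, 21))
  bp <- c(30.5, 20.5, 10.5)
  S2 <- skeleton_path(rbind(bp, bp + c(0, 1, 0), bp + c(0, 2, 0)))
  expect_warning(res <- optimize_attachment(S1, S2, img, solver_config()),
                 "degenerate")
  expect_equal(as.numeric(res), bp)
})

test_that("branch-point recombination recovers a displaced Y junction", {
  ph <- y_phantom()
  tr <- ph$ground_truth
  jid <- find_branch_nodes(tr)$id
  true_j <- skelasso:::node_position(tr, jid)
  cfg <- solver_config()
  spec <- branch_phantom_spec()
  tr2 <- displace_node(tr, jid, 5 * spec$arm_directions[2, ])
  trip <- extract_branch_triplet(tr2, jid, cfg)
  res <- suppressWarnings(optimize_branch_point(trip, ph$image, cfg))
  expect_lt(sqrt(sum((as.numeric(res) - true_j)^2)), 2)
  expect_gte(attr(res, "n_passes"), 1)
})

test_that("an undisplaced Y junction is a fixed point of the recombination", {
  ph <- y_phantom()
  tr <- ph$ground_truth
  jid <- find_branch_nodes(tr)$id
  true_j <- skelasso:::node_position(tr, jid)
  cfg <- solver_config()
  trip <- extract_branch_triplet(tr, jid, cfg)
  res <- suppressWarnings(optimize_branch_point(trip, ph$image, cfg))
  expect_lt(sqrt(sum((as.numeric(res) - true_j)^2)), cfg$resample_spacing)
})
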