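#' Specification of a fold-line neurite phantom
#'
#' Describes a synthetic tortuous neurite: two terminal points joined to a
#' corner point by straight legs (a fold line), rasterized into a binary
#' stack, blurred with a 3-D Gaussian kernel, normalized to a maximum of
#' 255, and polluted with additive Gaussian white noise. The corner angle
#' (the included angle between the two legs) sets the tortuosity: 30
#' degrees is a sharp corner, 90 degrees a weak one. When the three points
#' are not given they are placed symmetrically inside the stack from the
#' requested angle: corner low in y, legs opening upward, so the 90-degree
#' phantom is monotone in x (which the x-resampling consistency metric
#' requires).
#'
#' @param corner_angle_deg included angle between the two legs, degrees in
#'   (0, 180); 30 and 90 are the standard study conditions.
#' @param noise_sd standard deviation of the additive Gaussian noise; 50
#'   and 100 are the standard study conditions.
#' @param shape stack size in voxels (default `c(156, 156, 57)`).
#' @param voxel_size micrometres per voxel (default isotropic 1).
#' @param kernel_width Gaussian blur standard deviation in voxels
#'   (default 1.73).
#' @param noise_mean mean of the additive noise (default 0).
#' @param seed integer RNG seed for the noise.
#' @param endpoint_a,endpoint_b,corner optional explicit micrometre
#'   coordinates overriding the default geometry.
#' @param margin_vox margin kept between the default geometry and the
#'   stack faces, voxels.
#' @return A `fold_line_spec` list.
#' @export
fold_line_spec <- function(corner_angle_deg = 30, noise_sd = 50,
                           shape = c(156, 156, 57), voxel_size = c(1, 1, 1),
                           kernel_width = 1.73, noise_mean = 0, seed = 1,
                           endpoint_a = NULL, endpoint_b = NULL, corner = NULL,
                           margin_vox = 15) {
  assert_that(corner_angle_deg > 0 && corner_angle_deg < 180,
              "corner_angle_deg must lie in (0, 180)")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  ext <- shape * voxel_size
  if (is.null(corner) || is.null(endpoint_a) || is.null(endpoint_b)) {
    half <- corner_angle_deg / 2 * pi / 180
    margin <- margin_vox * max(voxel_size)
    corner <- c(ext[1] / 2, margin * 2, ext[3] / 2)
    L <- min((ext[2] - margin - corner[2]) / cos(half),
             (corner[1] - margin) / max(sin(half), 1e-9))
    endpoint_a <- corner + L * c(-sin(half), cos(half), 0)
    endpoint_b <- corner + L * c(sin(half), cos(half), 0)
  }
  u <- endpoint_a - corner; v <- endpoint_b - corner
  ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  assert_that(abs(ang - corner_angle_deg) <= 0.5,
              sprintf("corner geometry gives %.2f deg, not %.1f", ang, corner_angle_deg))
  structure(list(shape = shape, voxel_size = voxel_size,
                 endpoint_a = endpoint_a, endpoint_b = endpoint_b, corner = corner,
                 corner_angle_deg = corner_angle_deg, kernel_width = kernel_width,
                 noise_sd = noise_sd, noise_mean = noise_mean, seed = as.integer(seed)),
            class = "fold_line_spec")
}

#' Rasterize a polyline into a binary volume
#'
#' A voxel gets value 1 exactly when its centre lies within half a voxel
#' diagonal of the polyline, which yields a 26-connected one-voxel-wide
#' trace; every other voxel is 0.
#'
#' @param points a [skeleton_path()] (micrometre coordinates).
#' @param shape volume size in voxels.
#' @param voxel_size micrometres per voxel.
#' @param origin physical origin of the volume, micrometres.
#' @return A binary [volume_image()].
#' @export
rasterize_polyline <- function(points, shape, voxel_size = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  P <- as_path_matrix(points)
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  ext_lo <- origin
  ext_hi <- origin + shape * voxel_size
  inside <- P >= matrix(ext_lo, nrow(P), 3, byrow = TRUE) &
            P <= matrix(ext_hi, nrow(P), 3, byrow = TRUE)
  if (!all(inside)) {
    stop_skelasso("polyline exits the volume", "skelasso_bounds_error")
  }
  arr <- array(0, shape)
  vol <- volume_image(arr, voxel_size, origin)
  thr <- sqrt(sum(voxel_size^2)) / 2
  segs <- if (nrow(P) == 1) list(list(a = P[1, ], b = P[1, ])) else
    lapply(seq_len(nrow(P) - 1), function(s) list(a = P[s, ], b = P[s + 1, ]))
  for (sg in segs) {
    lo_um <- pmin(sg$a, sg$b) - thr - voxel_size
    hi_um <- pmax(sg$a, sg$b) + thr + voxel_size
    lo <- pmax(as.integer(floor((lo_um - origin) / voxel_size)), 0L)
    hi <- pmin(as.integer(floor((hi_um - origin) / voxel_size)), shape - 1L)
    if (any(lo > hi)) next
    xr <- lo[1]:hi[1]; yr <- lo[2]:hi[2]; zr <- lo[3]:hi[3]
    idx <- as.matrix(expand.grid(x = xr, y = yr, z = zr))
    ctr <- voxel_center(vol, idx)
    d <- sg$b - sg$a
    dd <- sum(d * d)
    w <- sweep(ctr, 2, sg$a)
    t <- if (dd > 0) pmin(pmax((w %*% d) / dd, 0), 1) else rep(0, nrow(ctr))
    dist <- sqrt(rowSums((w - outer(as.vector(t), d))^2))
    hit <- idx[dist <= thr, , drop = FALSE]
    if (nrow(hit)) arr[hit + 1L] <- 1
  }
  volume_image(arr, voxel_size, origin)
}

# Separable Gaussian correlation along one axis, zero boundary, normalized
# weights, truncated at 4 sigma (sigma in voxels).
blur_axis <- function(arr, axis, sigma) {
  h <- ceiling(4 * sigma)
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- w / sum(w)
  perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
  a <- aperm(arr, perm)
  d <- dim(a)
  n <- d[1]
  K <- matrix(0, n, n)
  for (k in -h:h) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- w[k + h + 1]
  }
  out <- array(K %*% matrix(a, n), d)
  aperm(out, order(perm))
}

# 3-D Gaussian blur, sigma in voxels (isotropic in voxel units).
gaussian_blur <- function(arr, sigma) {
  for (ax in 1:3) arr <- blur_axis(arr, ax, sigma)
  arr
}

#' Gaussian blur and peak normalization
#'
#' Convolves a binary (or any non-negative) volume with a 3-D Gaussian
#' kernel of standard deviation `kernel_width` voxels, then rescales
#' linearly so the maximum intensity is exactly 255. This is the forward
#' model used to turn a rasterized centerline into a light-microscopy-like
#' tube.
#'
#' @param binary a [volume_image()] with at least one nonzero voxel.
#' @param kernel_width Gaussian standard deviation in voxels (default 1.73).
#' @return A [volume_image()] with maximum 255.
#' @export
convolve_normalize <- function(binary, kernel_width = 1.73) {
  assert_that(kernel_width > 0, "kernel_width must be positive")
  if (max(binary) <= 0) {
    stop_skelasso("cannot normalize an all-zero volume", "skelasso_degenerate_input")
  }
  sm <- gaussian_blur(unclass(binary), kernel_width)
  sm <- sm * (255 / max(sm))
  volume_image(pmax(sm, 0), voxel_size(binary), volume_origin(binary))
}

#' Add Gaussian white noise to a volume
#'
#' Adds i.i.d. Gaussian noise per voxel and clips the result below at 0
#' (intensities stay non-negative; no upper clip and no re-quantization).
#' Deterministic for a given `seed`.
#'
#' @param image a [volume_image()].
#' @param mean noise mean (default 0).
#' @param sd noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @return A noisy [volume_image()].
#' @export
add_noise <- function(image, mean = 0, sd, seed = 1) {
  assert_that(sd >= 0, "sd must be >= 0")
  if (sd == 0 && mean == 0) return(image)
  n <- length(image)
  noise <- if (sd == 0) rep(mean, n) else
    with_local_seed(seed, stats::rnorm(n, mean, sd))
  volume_image(array(pmax(unclass(image) + noise, 0), dim(image)),
               voxel_size(image), volume_origin(image))
}

#' Generate a fold-line phantom stack with ground truth
#'
#' Composes [rasterize_polyline()], [convolve_normalize()] and
#' [add_noise()] for a [fold_line_spec()]. The ground truth is the fold
#' line densely resampled at 0.5 micrometre spacing, finer than the 1
#' micrometre working resolution so distance-to-truth metrics are not
#' resolution-limited.
#'
#' @param spec a [fold_line_spec()].
#' @return A list with elements `image` (a [volume_image()]) and
#'   `ground_truth` (a [skeleton_path()]).
#' @export
make_fold_line_stack <- function(spec) {
  stopifnot(inherits(spec, "fold_line_spec"))
  fold <- skeleton_path(rbind(spec$endpoint_a, spec$corner, spec$endpoint_b))
  binary <- rasterize_polyline(fold, spec$shape, spec$voxel_size)
  img <- convolve_normalize(binary, spec$kernel_width)
  img <- add_noise(img, spec$noise_mean, spec$noise_sd, spec$seed)
  truth <- resample_path(fold, 0.5)
  list(image = img, ground_truth = truth)
}

#' Specification of a synthetic Y-junction phantom
#'
#' Three straight arms radiating from a junction point, each rasterized and
#' blurred with its own kernel width and scaled to its own peak intensity
#' before summation and noise, so arm diameter and brightness can differ
#' the way they do around real branch points. The ground-truth tree has
#' exactly one branch node, at the junction.
#'
#' @param shape stack size in voxels.
#' @param junction junction coordinates, micrometres.
#' @param arm_directions 3 x 3 matrix of unit row vectors (pairwise
#'   non-parallel).
#' @param arm_lengths three arm lengths, micrometres.
#' @param arm_intensities three peak intensities.
#' @param arm_kernel_widths three Gaussian widths (voxels), setting the
#'   apparent radius of each arm.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param node_spacing spacing of ground-truth tree nodes along the arms,
#'   micrometres.
#' @param voxel_size micrometres per voxel.
#' @param seed integer RNG seed for the noise.
#' @return A `branch_phantom_spec` list.
#' @export
branch_phantom_spec <- function(shape = c(64, 64, 32),
                                junction = c(32, 32, 16),
                                arm_directions = rbind(c(0, -1, 0),
                                                       c(-sin(pi / 3), cos(pi / 3), 0),
                                                       c(sin(pi / 3), cos(pi / 3), 0)),
                                arm_lengths = c(22, 22, 22),
                                arm_intensities = c(255, 255, 255),
                                arm_kernel_widths = c(1.73, 1.73, 1.73),
                                noise_sd = 0, node_spacing = 1.5,
                                voxel_size = c(1, 1, 1), seed = 1) {
  arm_directions <- t(apply(arm_directions, 1, function(v) v / sqrt(sum(v^2))))
  for (i in 1:2) for (j in (i + 1):3) {
    cang <- abs(sum(arm_directions[i, ] * arm_directions[j, ]))
    assert_that(cang < 1 - 1e-6, sprintf("arms %d and %d are parallel", i, j))
  }
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  ext <- shape * voxel_size
  for (k in 1:3) {
    tip <- junction + arm_lengths[k] * arm_directions[k, ]
    assert_that(all(tip >= 0) && all(tip <= ext),
                sprintf("arm %d leaves the volume", k), class = "skelasso_bounds_error")
  }
  structure(list(shape = shape, junction = junction,
                 arm_directions = arm_directions, arm_lengths = arm_lengths,
                 arm_intensities = arm_intensities,
                 arm_kernel_widths = arm_kernel_widths,
                 noise_sd = noise_sd, node_spacing = node_spacing,
                 voxel_size = voxel_size, seed = as.integer(seed)),
            class = "branch_phantom_spec")
}

#' Generate a Y-junction phantom with its ground-truth tree
#'
#' @param spec a [branch_phantom_spec()].
#' @return A list with elements `image` (a [volume_image()]) and
#'   `ground_truth` (a `neuron_tree` tibble whose single branch node sits at
#'   the junction).
#' @export
make_branch_phantom <- function(spec) {
  stopifnot(inherits(spec, "branch_phantom_spec"))
  acc <- array(0, spec$shape)
  for (k in 1:3) {
    tip <- spec$junction + spec$arm_lengths[k] * spec$arm_directions[k, ]
    seg <- skeleton_path(rbind(spec$junction, tip))
    b <- rasterize_polyline(seg, spec$shape, spec$voxel_size)
    sm <- gaussian_blur(unclass(b), spec$arm_kernel_widths[k])
    acc <- acc + sm * (spec$arm_intensities[k] / max(sm))
  }
  img <- volume_image(acc, spec$voxel_size)
  img <- add_noise(img, 0, spec$noise_sd, spec$seed)

  arm_nodes <- function(k) {
    n_nodes <- max(2, floor(spec$arm_lengths[k] / spec$node_spacing) + 1)
    tt <- seq(0, spec$arm_lengths[k], length.out = n_nodes)
    outer(tt, spec$arm_directions[k, ]) +
      matrix(spec$junction, n_nodes, 3, byrow = TRUE)
  }
  a1 <- arm_nodes(1); a2 <- arm_nodes(2); a3 <- arm_nodes(3)
  # root at the tip of arm 1, chain to the junction, then two child chains
  pos <- rbind(a1[rev(seq_len(nrow(a1))[-1]), , drop = FALSE],  # tip .. next-to-junction
               spec$junction,
               a2[-1, , drop = FALSE],
               a3[-1, , drop = FALSE])
  n1 <- nrow(a1) - 1; n2 <- nrow(a2) - 1; n3 <- nrow(a3) - 1
  jid <- n1 + 1L
  parent <- c(-1L, seq_len(n1 - 1),                 # down arm 1 to junction
              jid - 1L,                             # junction's parent
              c(jid, jid + seq_len(n2 - 1)),        # arm 2 chain
              c(jid, jid + n2 + seq_len(n3 - 1)))   # arm 3 chain
  parent <- parent[seq_len(nrow(pos))]
  parent[jid] <- jid - 1L
  tree <- neuron_tree(tibble::tibble(
    id = seq_len(nrow(pos)), type = 3L,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius = 1, parent = as.integer(parent)))
  list(image = img, ground_truth = tree)
}
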