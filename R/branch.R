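#' Gaussian skeleton-template image of a path
#'
#' Rasterizes a (resampled) skeleton into a local volume and blurs it with
#' a 3-D Gaussian of width `sigma`, normalizing the maximum to 255. Along
#' the path, away from its two ends, every skeleton point then has nearly
#' the same, near-maximal intensity, so a score computed on this template
#' is almost flat along the skeleton and cannot favour one skeleton
#' position over another for brightness reasons — exactly the property the
#' branch-point search needs. By default the volume is the bounding box of
#' the path padded by 4 `sigma` voxels, carried in local coordinates via
#' the volume origin.
#'
#' @param path a [skeleton_path()] (resample it first for even coverage).
#' @param sigma template Gaussian width in voxels (default 1.73).
#' @param shape optional explicit volume shape in voxels; when given, the
#'   volume starts at the world origin and the path must fit inside.
#' @param voxel_size micrometres per voxel.
#' @return A [volume_image()] with maximum 255.
#' @export
skeleton_template_image <- function(path, sigma = 1.73, shape = NULL,
                                    voxel_size = c(1, 1, 1)) {
  P <- as_path_matrix(path)
  voxel_size <- as.numeric(voxel_size)
  if (is.null(shape)) {
    pad <- (4 * sigma + 1) * voxel_size
    lo <- floor((apply(P, 2, min) - pad) / voxel_size) * voxel_size
    hi <- apply(P, 2, max) + pad
    shape <- as.integer(ceiling((hi - lo) / voxel_size))
    origin <- lo
  } else {
    shape <- as.integer(shape)
    origin <- c(0, 0, 0)
  }
  binary <- rasterize_polyline(P, shape, voxel_size, origin)
  convolve_normalize(binary, sigma)
}

#' Build the orientation frame of the branch objective
#'
#' Walking along `S2` from the branch end, the reference point `p_fx` is
#' the first point farther than three times the (largest) voxel size from
#' every point of `S1`, and `p_v1` the first subsequent point farther than
#' the same distance from `p_fx`. The unit vector `dv1` points from `p_fx`
#' toward `p_v1`; the objective only ever uses the projector
#' `I - dv1 dv1^T` onto the plane normal to `dv1`, which equals
#' `dv2 dv2^T + dv3 dv3^T` for any orthonormal completion `(dv2, dv3)`,
#' so no explicit completion is needed (or chosen).
#'
#' @param S2 side path, first point at the branch point.
#' @param voxel_size micrometres per voxel of the working image.
#' @param S1 through path.
#' @param lam orientation-prior weight stored in the frame (default 1).
#' @return A `frame_objective` list with `p_fx`, `p_v1`, `dv1`,
#'   `projector`, `lam`, and slots `template` / `g_scale` filled by the
#'   caller.
#' @export
build_frame <- function(S2, voxel_size, S1, lam = 1.0) {
  P2 <- as_path_matrix(S2)
  P1 <- as_path_matrix(S1)
  thr <- 3 * max(as.numeric(voxel_size))
  dmin <- apply(P2, 1, function(q) min(sqrt(colSums((t(P1) - q)^2))))
  i_fx <- which(dmin > thr)[1]
  if (is.na(i_fx)) {
    stop_skelasso("no reference point on S2 clears the through path",
                  "skelasso_degenerate_branch")
  }
  p_fx <- P2[i_fx, ]
  if (i_fx < nrow(P2)) {
    rest <- P2[(i_fx + 1):nrow(P2), , drop = FALSE]
    dfx <- sqrt(rowSums(sweep(rest, 2, p_fx)^2))
    i_v1 <- which(dfx > thr)[1]
  } else {
    i_v1 <- NA_integer_
  }
  if (is.na(i_v1)) {
    stop_skelasso("no orientation point on S2 clears the reference point",
                  "skelasso_degenerate_branch")
  }
  p_v1 <- P2[i_fx + i_v1, ]
  dv1 <- (p_v1 - p_fx) / sqrt(sum((p_v1 - p_fx)^2))
  structure(list(p_fx = p_fx, p_v1 = p_v1, dv1 = dv1,
                 projector = diag(3) - tcrossprod(dv1),
                 lam = lam, template = NULL, g_scale = 1),
            class = "frame_objective")
}

#' Branch-point objective at a candidate position
#'
#' The sum of the (scaled) skeleton-template intensity score at `p` and
#' `lam` times the squared perpendicular distance of `p` from the line
#' through `p_fx` along `dv1`. The first term keeps the branch point on
#' the skeleton; the second pulls it toward the continuation of the side
#' branch. With a `NULL` template only the orientation term is returned.
#'
#' @param fo a [build_frame()] result (optionally with `template` and
#'   `g_scale` set).
#' @param p candidate position, micrometres.
#' @param sigma Gaussian width of the intensity score, voxels.
#' @param halfwidth score neighbourhood half-width, voxels.
#' @return A single number (smaller is better).
#' @export
branch_objective <- function(fo, p, sigma = 1.73, halfwidth = ceiling(3 * sigma)) {
  stopifnot(inherits(fo, "frame_objective"))
  w <- fo$p_fx - p
  quad <- as.numeric(t(w) %*% fo$projector %*% w)
  gterm <- if (is.null(fo$template)) 0 else
    intensity_score_g(fo$template, p, sigma, halfwidth) / fo$g_scale
  gterm + fo$lam * quad
}

#' Fixed-point refinement of one branch attachment
#'
#' One recombination pass: the through path `S1` is optimized against the
#' real image and resampled at `cfg$resample_spacing`; a skeleton template
#' is built from it; then, alternately, the branch point is moved to the
#' resampled point minimizing [branch_objective()] (ties broken toward the
#' smaller index) and the side path `S2` is re-optimized on the real image
#' with the new branch point and its far end fixed, until the branch point
#' moves less than `cfg$branch_tol` micrometres or `cfg$branch_max_iters`
#' iterations are reached.
#'
#' @param S1 through path containing the current branch point.
#' @param S2 side path whose first point is the branch point.
#' @param image the real [volume_image()].
#' @param cfg a [solver_config()].
#' @return The converged branch point (length-3 numeric) with attributes
#'   `iterations` and `converged`; on a degenerate frame the input branch
#'   point is returned with a warning.
#' @export
optimize_attachment <- function(S1, S2, image, cfg = solver_config()) {
  P2 <- as_path_matrix(S2)
  bp <- P2[1, ]
  S1_opt <- suppressWarnings(optimize_segment(S1, image, cfg))
  S1s <- resample_path(S1_opt, cfg$resample_spacing)
  C <- as_path_matrix(S1s)
  tmpl <- skeleton_template_image(S1s, cfg$template_sigma,
                                  voxel_size = voxel_size(image))
  g_all <- g_batch(tmpl, C, cfg$sigma, cfg$neighborhood_halfwidth)$g
  g_scale <- max(abs(g_all), 1e-12)
  S2cur <- P2
  converged <- FALSE
  it <- 0L
  while (it < cfg$branch_max_iters) {
    it <- it + 1L
    fo <- tryCatch(
      build_frame(skeleton_path(S2cur), voxel_size(image), S1s, cfg$branch_lam),
      skelasso_degenerate_branch = function(e) e)
    if (inherits(fo, "condition")) {
      warning(sprintf("degenerate branch frame (%s); keeping the input branch point",
                      conditionMessage(fo)))
      out <- P2[1, ]
      attr(out, "iterations") <- it - 1L
      attr(out, "converged") <- FALSE
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    W <- sweep(C, 2, fo$p_fx, "-")
    quad <- rowSums((W %*% fo$projector) * W)
    obj <- g_all / g_scale + fo$lam * quad
    new_bp <- C[which.min(obj), ]
    disp <- sqrt(sum((new_bp - bp)^2))
    bp <- new_bp
    S2cur[1, ] <- bp
    if (nrow(S2cur) >= 3) {
      S2fit <- suppressWarnings(optimize_segment(skeleton_path(S2cur), image, cfg))
      S2cur <- as_path_matrix(S2fit)
    }
    if (disp < cfg$branch_tol) { converged <- TRUE; break }
  }
  out <- bp
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "degenerate") <- FALSE
  out
}

#' Optimize a branch point by three-way recombination
#'
#' Runs [optimize_attachment()] three times, once for each pairing of the
#' three incident segments — (S11+S12 with side S2), (S12+S2 with side
#' S11), (S11+S2 with side S12), each recombined path rejoined at the
#' branch point — and returns the arithmetic mean of the three refined
#' positions. Passes whose frame degenerates are dropped from the average;
#' if all three degenerate the input branch point is returned with a
#' warning.
#'
#' @param triplet a [branch_triplet()].
#' @param image the real [volume_image()].
#' @param cfg a [solver_config()].
#' @return The optimized branch point (length-3 numeric) with attributes
#'   `iterations` (total) and `n_passes` (passes averaged).
#' @export
optimize_branch_point <- function(triplet, image, cfg = solver_config()) {
  stopifnot(inherits(triplet, "branch_triplet"))
  A <- as_path_matrix(triplet$S11)   # ends at bp
  B <- as_path_matrix(triplet$S12)   # starts at bp
  C <- as_path_matrix(triplet$S2)    # starts at bp
  rev_path <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]
  join_at_bp <- function(first_to_bp, from_bp) {
    skeleton_path(rbind(first_to_bp, from_bp[-1, , drop = FALSE]))
  }
  passes <- list(
    list(S1 = join_at_bp(A, B), S2 = skeleton_path(C)),
    list(S1 = join_at_bp(rev_path(B), C), S2 = skeleton_path(rev_path(A))),
    list(S1 = join_at_bp(rev_path(A), C), S2 = skeleton_path(rev_path(B))))
  pts <- list()
  iters <- 0L
  for (ps in passes) {
    res <- withCallingHandlers(
      optimize_attachment(ps$S1, ps$S2, image, cfg),
      warning = function(w) invokeRestart("muffleWarning"))
    iters <- iters + (attr(res, "iterations") %||% 0L)
    if (!isTRUE(attr(res, "degenerate"))) pts[[length(pts) + 1L]] <- as.numeric(res)
  }
  if (length(pts) == 0) {
    warning("all three recombination passes degenerated; keeping the input branch point")
    out <- A[nrow(A), ]
  } else {
    out <- colMeans(do.call(rbind, pts))
  }
  attr(out, "iterations") <- iters
  attr(out, "n_passes") <- length(pts)
  out
}
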