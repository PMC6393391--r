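#' Total cable length of a reconstruction
#'
#' Sum of Euclidean lengths of all parent-child edges, in micrometres.
#'
#' @param tree a [neuron_tree()].
#' @return Total length, micrometres.
#' @examples
#' tr <- neuron_tree(tibble::tibble(id = 1:2, type = 3, x = c(0, 3),
#'                                  y = c(0, 4), z = 0, radius = 1,
#'                                  parent = c(-1L, 1L)))
#' total_length(tr) # 5
#' @export
total_length <- function(tree) {
  validate_tree(tree)
  nonroot <- which(tree$parent != -1L)
  if (length(nonroot) == 0) return(0)
  pi <- match(tree$parent[nonroot], tree$id)
  dx <- tree$x[nonroot] - tree$x[pi]
  dy <- tree$y[nonroot] - tree$y[pi]
  dz <- tree$z[nonroot] - tree$z[pi]
  sum(sqrt(dx^2 + dy^2 + dz^2))
}

# Position arm_length um of arc down a child chain from the branch node.
walk_arc <- function(tree, node_id, child_id, arm_length) {
  ids <- walk_down(tree, node_id, child_id, k = nrow(tree))
  P <- as_path_matrix(ids_to_path(tree, ids))
  remaining <- arm_length
  for (s in seq_len(nrow(P) - 1)) {
    step <- sqrt(sum((P[s + 1, ] - P[s, ])^2))
    if (step >= remaining) {
      return(list(point = P[s, ] + (remaining / step) * (P[s + 1, ] - P[s, ]),
                  short = FALSE))
    }
    remaining <- remaining - step
  }
  list(point = P[nrow(P), ], short = TRUE)
}

#' Local branch angle at a bifurcation
#'
#' For each of the two child arms, walks `arm_length` micrometres of arc
#' from the branch point along the traced polyline and takes the chord
#' from the branch point to the reached position; the angle between the
#' two chords, in degrees, is returned. An arm shorter than `arm_length`
#' is used whole, with a warning.
#'
#' @param tree a [neuron_tree()].
#' @param node_id id of a bifurcation node.
#' @param arm_length chord arc length in micrometres (default 10).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
branch_angle <- function(tree, node_id, arm_length = 10) {
  cm <- children_map(tree)
  ch <- sort(cm[[as.character(node_id)]])
  assert_that(length(ch) >= 2, sprintf("node %d is not a branch node", node_id),
              class = "skelasso_structure_error")
  bp <- node_position(tree, node_id)
  chords <- lapply(ch[1:2], function(cid) {
    w <- walk_arc(tree, node_id, cid, arm_length)
    if (w$short) warning(sprintf("arm through node %d shorter than %g um; using it whole",
                                 cid, arm_length))
    w$point - bp
  })
  u <- chords[[1]]; v <- chords[[2]]
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Resample a path at fixed x-coordinate steps
#'
#' Returns `count` points whose x-coordinates are `start_x + k * dx`,
#' positions linearly interpolated on the polyline. This is the protocol
#' used for cross-reconstruction consistency comparisons; it requires the
#' path to be monotone in x over the sampled range and errors otherwise (a
#' documented limitation of the protocol).
#'
#' @param path a [skeleton_path()].
#' @param dx x-step, micrometres (default 1).
#' @param count number of points (default 51).
#' @return A resampled `skeleton_path`.
#' @export
resample_by_x <- function(path, dx = 1, count = 51) {
  P <- as_path_matrix(path)
  xs <- P[, 1]
  sgn <- sign(xs[length(xs)] - xs[1])
  if (sgn < 0) { P <- P[rev(seq_len(nrow(P))), , drop = FALSE]; xs <- P[, 1] }
  want <- xs[1] + (seq_len(count) - 1) * dx
  k <- which(xs >= max(want) - 1e-9)[1]
  if (is.na(k)) {
    stop_skelasso(sprintf("requested %d points at dx = %g exceed the path's x-range", count, dx),
                  "skelasso_metric_inapplicable")
  }
  if (any(diff(xs[1:k]) <= 0)) {
    stop_skelasso("path is not x-monotone over the requested range; the x-resampling metric does not apply",
                  "skelasso_metric_inapplicable")
  }
  y <- stats::approx(xs[1:k], P[1:k, 2], xout = want)$y
  z <- stats::approx(xs[1:k], P[1:k, 3], xout = want)$y
  skeleton_path(want, y, z)
}

# Minimum Euclidean distance between two 3-D line segments [p1,p2], [q1,q2].
segment_segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  eps <- 1e-12
  if (a <= eps && e <= eps) return(sqrt(sum(r * r)))
  if (a <= eps) {
    t <- min(max(f / e, 0), 1)
    return(sqrt(sum((r - t * d2)^2)))
  }
  c1 <- sum(d1 * r)
  if (e <= eps) {
    s <- min(max(-c1 / a, 0), 1)
    return(sqrt(sum((r + s * d1)^2)))
  }
  b <- sum(d1 * d2)
  den <- a * e - b * b
  s <- if (den > eps) min(max((b * f - c1 * e) / den, 0), 1) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
  else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
  sqrt(sum((r + s * d1 - t * d2)^2))
}

#' Matched-pair segment distances between two skeletons
#'
#' Both paths are x-resampled ([resample_by_x()]); consecutive points form
#' segments; each segment of `a` is paired with the segment of `b` at
#' minimum segment-to-segment distance (ties toward the smaller index) and
#' that distance recorded. The mean of the recorded distances is the
#' consistency measure between two reconstructions of the same neurite.
#'
#' @param a,b [skeleton_path()]s, both x-monotone over the sampled range.
#' @param dx x-step, micrometres (default 1).
#' @param count resampled point count (default 51).
#' @return A `matched_pairs` object: tibble of per-segment distances with
#'   `mean` / `max` attributes; [glance()] returns the summary row.
#' @export
matched_pair_distances <- function(a, b, dx = 1, count = 51) {
  A <- as_path_matrix(resample_by_x(a, dx, count))
  B <- as_path_matrix(resample_by_x(b, dx, count))
  nseg <- nrow(A) - 1
  dist <- numeric(nseg)
  match_idx <- integer(nseg)
  for (i in seq_len(nseg)) {
    best <- Inf; besti <- 1L
    for (j in seq_len(nrow(B) - 1)) {
      dd <- segment_segment_distance(A[i, ], A[i + 1, ], B[j, ], B[j + 1, ])
      if (dd < best - 1e-15) { best <- dd; besti <- j }
    }
    dist[i] <- best; match_idx[i] <- besti
  }
  out <- tibble::tibble(segment = seq_len(nseg), matched = match_idx,
                        distance = dist)
  structure(out, mean = mean(dist), max = max(dist),
            class = c("matched_pairs", class(out)))
}

#' @export
glance.matched_pairs <- function(x, ...) {
  tibble::tibble(n_segments = nrow(x), mean_distance = attr(x, "mean"),
                 max_distance = attr(x, "max"))
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs> %d segments, mean %.4g um, max %.4g um\n",
              nrow(x), attr(x, "mean"), attr(x, "max")))
  NextMethod()
}
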