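#' Skeleton path: an ordered sequence of 3-D points
#'
#' A skeleton path is a tibble with columns `x`, `y`, `z` (physical
#' micrometre coordinates), one row per point, in traversal order.
#' Consecutive points must be distinct. Most functions in this package
#' accept any data frame with these columns and return a `skeleton_path`
#' tibble, so calls chain with the pipe.
#'
#' @param x numeric vector of x coordinates, or a 2-column-plus data frame /
#'   3-column matrix holding all coordinates.
#' @param y,z numeric vectors (ignored when `x` is a matrix or data frame).
#' @return A tibble of class `skeleton_path` with columns `x`, `y`, `z`.
#' @examples
#' skeleton_path(c(0, 1, 2), c(0, 0, 1), c(0, 0, 0))
#' @export
skeleton_path <- function(x, y = NULL, z = NULL) {
  if (is.matrix(x)) {
    assert_that(ncol(x) == 3, "matrix input must have 3 columns")
    xx <- as.numeric(x[, 1]); yy <- as.numeric(x[, 2]); zz <- as.numeric(x[, 3])
    pts <- tibble::tibble(x = xx, y = yy, z = zz)
  } else if (is.data.frame(x)) {
    assert_that(all(c("x", "y", "z") %in% names(x)),
                "data frame input must have columns x, y, z")
    xx <- as.numeric(x$x); yy <- as.numeric(x$y); zz <- as.numeric(x$z)
    pts <- tibble::tibble(x = xx, y = yy, z = zz)
  } else {
    xx <- as.numeric(x); yy <- as.numeric(y); zz <- as.numeric(z)
    pts <- tibble::tibble(x = xx, y = yy, z = zz)
  }
  assert_that(all(is.finite(as.matrix(pts))), "path coordinates must be finite")
  class(pts) <- c("skeleton_path", class(tibble::tibble()))
  pts
}

as_path_matrix <- function(path) {
  if (is.matrix(path)) return(path)
  cbind(x = as.numeric(path$x), y = as.numeric(path$y), z = as.numeric(path$z))
}

# Drop consecutive duplicate points (closer than tol um).
dedupe_path <- function(path, tol = 1e-6) {
  P <- as_path_matrix(path)
  if (nrow(P) < 2) return(skeleton_path(P))
  step <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  keep <- c(TRUE, step > tol)
  skeleton_path(P[keep, , drop = FALSE])
}

#' Arc length of a path
#' @param path a [skeleton_path()] or data frame with `x`, `y`, `z`.
#' @return Total polyline length in micrometres.
#' @export
path_length <- function(path) {
  P <- as_path_matrix(path)
  if (nrow(P) < 2) return(0)
  sum(sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

#' Discrete second difference at an interior point
#'
#' `2 p_i - p_{i-1} - p_{i+1}` for 1-based interior index `i`
#' (`2 <= i <= n - 1`). Its norm is the discrete curvature proxy the
#' sparsity penalty acts on: near zero on smooth stretches, large at
#' genuine corners.
#'
#' @param path a [skeleton_path()].
#' @param i interior index.
#' @return Numeric length-3 vector.
#' @examples
#' p <- skeleton_path(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0))
#' second_difference(p, 2) # c(1, -1, 0)
#' @export
second_difference <- function(path, i) {
  P <- as_path_matrix(path)
  n <- nrow(P)
  assert_that(i >= 2 && i <= n - 1, sprintf("index %d is not interior (n = %d)", i, n),
              class = "skelasso_index_error")
  as.numeric(2 * P[i, ] - P[i - 1, ] - P[i + 1, ])
}

# All interior second differences as an (n-2) x 3 matrix.
second_differences <- function(path) {
  P <- as_path_matrix(path)
  n <- nrow(P)
  if (n < 3) return(matrix(numeric(0), ncol = 3))
  2 * P[2:(n - 1), , drop = FALSE] - P[1:(n - 2), , drop = FALSE] - P[3:n, , drop = FALSE]
}

#' Resample a path at fixed Euclidean spacing
#'
#' Walks the polyline placing each new point at Euclidean distance
#' `spacing` from the previous new point (the intersection of a sphere of
#' radius `spacing` with the polyline ahead), so consecutive output points
#' are `spacing` apart even across corners. The first input point is kept
#' exactly; the last input point is always appended, so the final gap may
#' be shorter.
#'
#' @param path a [skeleton_path()].
#' @param spacing positive spacing in micrometres (default 1).
#' @return A resampled `skeleton_path`.
#' @examples
#' p <- skeleton_path(c(0, 20), c(0, 0), c(0, 0))
#' nrow(resample_path(p, 1)) # 21
#' @export
resample_path <- function(path, spacing = 1) {
  assert_that(is.numeric(spacing) && spacing > 0, "spacing must be positive")
  P <- as_path_matrix(dedupe_path(path))
  n <- nrow(P)
  if (n < 2 || path_length(P) < spacing) {
    warning("path arc length below spacing; returning the two endpoints")
    return(skeleton_path(P[c(1, n), , drop = FALSE]))
  }
  out <- list(P[1, ])
  cur <- P[1, ]
  seg <- 1L            # current segment index (cur lies on segment seg)
  t0 <- 0              # parameter of cur within segment seg, in [0, 1]
  repeat {
    hit <- NULL
    s <- seg; ts <- t0
    while (s <= n - 1) {
      a <- P[s, ]; b <- P[s + 1, ]
      d <- b - a
      # first t in (ts, 1] with |a + t d - cur| = spacing
      aa <- sum(d * d)
      bb <- 2 * sum(d * (a - cur))
      cc <- sum((a - cur)^2) - spacing^2
      disc <- bb^2 - 4 * aa * cc
      if (aa > 0 && disc >= 0) {
        r <- sqrt(disc)
        for (t in sort(c((-bb - r) / (2 * aa), (-bb + r) / (2 * aa)))) {
          if (t > ts + 1e-12 && t <= 1 + 1e-12) { hit <- list(s = s, t = min(t, 1)); break }
        }
      }
      if (!is.null(hit)) break
      s <- s + 1L; ts <- 0
    }
    if (is.null(hit)) break
    seg <- hit$s; t0 <- hit$t
    cur <- P[seg, ] + t0 * (P[seg + 1, ] - P[seg, ])
    out[[length(out) + 1L]] <- cur
  }
  last <- P[n, ]
  if (sqrt(sum((out[[length(out)]] - last)^2)) > 1e-9) out[[length(out) + 1L]] <- last
  skeleton_path(do.call(rbind, out))
}

#' Perturb the interior of a path
#'
#' Displaces each point by an independent uniform offset in
#' `[-magnitude, magnitude]` per axis, used to emulate tracing error when
#' building initial skeletons for the phantom experiments. With
#' `fix_ends = TRUE` (default) the first and last points are returned
#' bit-for-bit unchanged. Deterministic for a given `seed`.
#'
#' @param path a [skeleton_path()].
#' @param magnitude maximum per-axis displacement, micrometres.
#' @param seed integer RNG seed.
#' @param fix_ends keep both endpoints fixed (default `TRUE`).
#' @param axes which coordinate axes to perturb (default all three);
#'   restricting to `c("y", "z")` gives displacements transverse to an
#'   x-monotone parametrization, which the x-resampling consistency
#'   protocol needs.
#' @return A perturbed `skeleton_path`.
#' @export
perturb_polyline <- function(path, magnitude, seed = 1, fix_ends = TRUE,
                             axes = c("x", "y", "z")) {
  assert_that(is.numeric(magnitude) && magnitude >= 0, "magnitude must be >= 0")
  axes <- match.arg(axes, several.ok = TRUE)
  P <- as_path_matrix(path)
  n <- nrow(P)
  if (n == 0 || magnitude == 0) return(skeleton_path(P))
  off <- with_local_seed(seed, matrix(stats::runif(3 * n, -magnitude, magnitude), ncol = 3))
  off[, setdiff(1:3, match(axes, c("x", "y", "z")))] <- 0
  if (fix_ends) off[c(1, n), ] <- 0
  skeleton_path(P + off)
}

# Distance from each of a set of points to a polyline (min over segments).
# points: k x 3 matrix; path: polyline. Returns length-k vector.
point_to_path_distance <- function(points, path) {
  Q <- matrix(as.numeric(as_path_matrix(points)), ncol = 3)
  P <- as_path_matrix(path)
  n <- nrow(P)
  if (n == 1) return(sqrt(rowSums(sweep(Q, 2, P[1, ])^2)))
  best <- rep(Inf, nrow(Q))
  for (s in seq_len(n - 1)) {
    a <- P[s, ]; d <- P[s + 1, ] - P[s, ]
    dd <- sum(d * d)
    w <- sweep(Q, 2, a)
    t <- if (dd > 0) pmin(pmax((w %*% d) / dd, 0), 1) else rep(0, nrow(Q))
    proj <- w - outer(as.vector(t), d)
    best <- pmin(best, sqrt(rowSums(proj^2)))
  }
  best
}
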