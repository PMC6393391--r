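#' @importFrom rlang .data
NULL

#' Plot the objective trace of a segment fit
#'
#' @param object a `segment_fit` from [optimize_segment()] or
#'   [l2_comparator()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.segment_fit <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "split-Bregman iteration", y = "objective",
                  title = sprintf("Segment optimization (%s penalty)",
                                  attr(object, "penalty"))) +
    ggplot2::theme_minimal()
}

#' Plot a skeleton path and an optional reference, projected on x-y
#'
#' @param path a [skeleton_path()].
#' @param reference optional second path (e.g. ground truth) drawn behind.
#' @return A ggplot.
#' @export
plot_path <- function(path, reference = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_path(
      data = tibble::as_tibble(as_path_matrix(reference)),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "grey60")
  }
  p + ggplot2::geom_path(data = tibble::as_tibble(as_path_matrix(path)),
                         ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot branch displacements of a tree fit
#'
#' @param object a `tree_fit` from [optimize_tree()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.tree_fit <- function(object, ...) {
  br <- tidy(object, "branches")
  ggplot2::ggplot(br, ggplot2::aes(x = factor(.data$id), y = .data$displacement)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "branch node id", y = "displacement (um)",
                  title = "Branch-point displacements") +
    ggplot2::theme_minimal()
}

#' Plot matched-pair segment distances
#'
#' @param object a `matched_pairs` result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.matched_pairs <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$segment, y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "mean"), linetype = 2) +
    ggplot2::labs(x = "segment", y = "distance (um)",
                  title = "Matched-pair segment distances") +
    ggplot2::theme_minimal()
}
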