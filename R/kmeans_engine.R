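# K-means engine.  Written in-package because its SSE objective doubles as
# the swarm fitness function and the refinement step of the hybrid; tests
# cross-check it against exhaustive partition enumeration and stats::kmeans.

# n x k matrix of squared Euclidean distances from each point to each center
sqdist_to_centers <- function(x, centers) {
  if (ncol(x) != ncol(centers)) {
    stop(sprintf("dimension mismatch: points have %d columns, centers %d",
                 ncol(x), ncol(centers)), call. = FALSE)
  }
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, `+`) - 2 * x %*% t(centers)
  pmax(d2, 0)  # clip tiny negative values from cancellation
}

as_point_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop("points must be finite and non-missing", call. = FALSE)
  }
  x
}

#' Sum-of-squared-errors clustering objective
#'
#' Sum over all points of the squared Euclidean distance to the nearest
#' centroid. This is the quantity K-means minimizes and the fitness
#' function the particle swarm minimizes in the hybrid.
#'
#' @param x Numeric point matrix (rows are points).
#' @param centers Numeric centroid matrix (rows are centroids, same number
#'   of columns as `x`).
#' @return A single non-negative number.
#' @examples
#' sse_objective(matrix(c(0, 2)), matrix(1))  # 1^2 + 1^2 = 2
#' @export
sse_objective <- function(x, centers) {
  x <- as_point_matrix(x); centers <- as_point_matrix(centers)
  d2 <- sqdist_to_centers(x, centers)
  sum(apply(d2, 1, min))
}

#' Assign points to their nearest centroid
#'
#' Squared-Euclidean nearest-centroid assignment; ties go to the
#' lowest-indexed centroid, deterministically.
#'
#' @inheritParams sse_objective
#' @return Integer vector of centroid indices, one per point.
#' @export
nearest_centroid <- function(x, centers) {
  x <- as_point_matrix(x); centers <- as_point_matrix(centers)
  d2 <- sqdist_to_centers(x, centers)
  max.col(-d2, ties.method = "first")
}

#' K-means clustering (Lloyd iterations)
#'
#' Alternates nearest-centroid assignment and centroid-mean update until
#' the assignment stabilizes, the relative SSE improvement drops below
#' `tol`, or `max_iter` is reached. An empty cluster is repaired by moving
#' its centroid to the point farthest from it. The SSE is non-increasing
#' across iterations.
#'
#' @param x Numeric point matrix.
#' @param k Number of clusters (at most the number of distinct points).
#' @param centers Optional initial centroid matrix (`k` rows). If `NULL`,
#'   `k` distinct data points are sampled uniformly using `seed`.
#' @param max_iter Maximum number of iterations (default 300).
#' @param tol Relative SSE improvement below which iteration stops
#'   (default `1e-6`).
#' @param seed Integer seed for random initialization.
#' @return An object of class `"km_fit"`: list with `cluster` (integer
#'   assignment), `centers`, `sse`, `sse_history`, `iterations`,
#'   `converged`.
#' @examples
#' fit <- km_fit(matrix(c(0, 1, 2, 10, 11, 12)), k = 2, seed = 1)
#' fit$centers
#' @export
km_fit <- function(x, k, centers = NULL, max_iter = 300L, tol = 1e-6,
                   seed = NULL) {
  x <- as_point_matrix(x)
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be >= 1", call. = FALSE)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the number of distinct points (%d)",
                 k, n_distinct), call. = FALSE)
  }
  if (is.null(centers)) {
    centers <- with_seed(seed, {
      ux <- unique(x)
      ux[sample.int(nrow(ux), k), , drop = FALSE]
    })
  } else {
    centers <- as_point_matrix(centers)
    if (nrow(centers) != k) stop("'centers' must have k rows", call. = FALSE)
  }

  assignment <- NULL
  sse_history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    new_assign <- nearest_centroid(x, centers)
    # empty-cluster repair: re-seed at the point farthest from the centroid
    repairs <- 0L
    repeat {
      empties <- which(tabulate(new_assign, nbins = k) == 0L)
      if (!length(empties) || repairs >= k) break
      j <- empties[1]
      d2j <- rowSums(sweep(x, 2, centers[j, ], `-`)^2)
      centers[j, ] <- x[which.max(d2j), ]
      new_assign <- nearest_centroid(x, centers)
      repairs <- repairs + 1L
    }
    sse <- sum(rowSums((x - centers[new_assign, , drop = FALSE])^2))
    sse_history <- c(sse_history, sse)
    stable <- !is.null(assignment) && identical(new_assign, assignment)
    small_gain <- length(sse_history) > 1 &&
      (sse_history[length(sse_history) - 1] - sse) <=
        tol * max(sse_history[length(sse_history) - 1], .Machine$double.eps)
    assignment <- new_assign
    if (stable || small_gain) { converged <- TRUE; break }
    if (iter >= max_iter) break
    # centroid update: mean of assigned points (empty clusters keep theirs)
    for (j in which(tabulate(assignment, nbins = k) > 0L)) {
      centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
    }
  }
  # make centers consistent with the final assignment
  for (j in which(tabulate(assignment, nbins = k) > 0L)) {
    centers[j, ] <- colMeans(x[assignment == j, , drop = FALSE])
  }
  final_assign <- nearest_centroid(x, centers)
  sse <- sum(rowSums((x - centers[final_assign, , drop = FALSE])^2))
  structure(list(cluster = final_assign, centers = centers, sse = sse,
                 sse_history = sse_history, iterations = iter,
                 converged = converged, k = k),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("K-means fit: k = %d, n = %d, SSE = %.6g (%d iterations%s)\n",
              x$k, length(x$cluster), x$sse, x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}
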