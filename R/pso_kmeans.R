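#' Fit a clustering by hybrid PSO + K-means (or plain K-means)
#'
#' The hybrid (`method = "psokm"`) runs a particle swarm over centroid
#' space — each particle is a flattened `k` x `d` centroid set, bounded by
#' the per-dimension data range, with the clustering sum of squared errors
#' as fitness — and then refines the swarm-best centroids with K-means.
#' Refinement never increases the SSE. `method = "km"` runs plain K-means
#' from a seeded random initialization, the baseline the hybrid is
#' compared against.
#'
#' Features are z-score standardized by default before clustering, since
#' raw anthropometric features mix scales (meters against kilograms and
#' years); `scale = FALSE` clusters the raw features.
#'
#' @param x Numeric matrix or data frame of features (rows are subjects).
#'   For a subject table use [subject_features()] to extract
#'   (age, weight, height).
#' @param k Number of clusters (default 3).
#' @param method `"psokm"` (hybrid, default) or `"km"` (plain K-means).
#' @param scale Standardize columns to zero mean / unit variance before
#'   clustering (default `TRUE`).
#' @param control A [pso_control()] object for the swarm stage.
#' @param km_max_iter,km_tol K-means iteration cap and relative SSE
#'   tolerance.
#' @param seed Integer seed fixing the whole fit.
#' @return An object of class `"pso_kmeans"` with components `cluster`
#'   (integer assignments), `centers` (centroids on the original feature
#'   scale), `centers_scaled`, `sse` (in the clustered space), `method`,
#'   `k`, `pso` (the swarm stage fit, `NULL` for `method = "km"`), `km`
#'   (the K-means stage), and the data/scaling needed by `predict` and
#'   `plot`.
#' @examples
#' coh <- simulate_cohort(cohort_config(separated = TRUE), seed = 1)
#' fit <- pso_kmeans(subject_features(coh$subjects), k = 3, seed = 1)
#' fit
#' table(fit$cluster, coh$group)
#' @seealso [evaluate_partition()], [km_fit()], [pso_optimize()]
#' @export
pso_kmeans <- function(x, k = 3L, method = c("psokm", "km"), scale = TRUE,
                       control = pso_control(), km_max_iter = 300L,
                       km_tol = 1e-6, seed = NULL) {
  method <- match.arg(method)
  x <- as_point_matrix(x)
  k <- as.integer(k)
  xs <- if (scale) base::scale(x) else x
  # constant columns scale to NaN; treat as zero deviation
  if (scale) xs[is.nan(xs)] <- 0
  ctr <- if (scale) attr(xs, "scaled:center") else rep(0, ncol(x))
  scl <- if (scale) attr(xs, "scaled:scale") else rep(1, ncol(x))
  scl[scl == 0] <- 1
  xs <- matrix(as.numeric(xs), nrow = nrow(x),
               dimnames = dimnames(x))

  pso <- NULL
  if (method == "psokm") {
    d <- ncol(xs)
    lo <- apply(xs, 2, min); hi <- apply(xs, 2, max)
    # degenerate (constant) dimensions still need a nonempty search box
    flat <- hi - lo <= 0
    lo[flat] <- lo[flat] - 0.5
    hi[flat] <- hi[flat] + 0.5
    fitness <- function(z) {
      sse_objective(xs, matrix(z, nrow = k, byrow = TRUE))
    }
    pso <- pso_optimize(fitness, dim = k * d,
                        lower = rep(lo, times = k),
                        upper = rep(hi, times = k),
                        control = control, seed = seed)
    init_centers <- matrix(pso$par, nrow = k, byrow = TRUE)
    km <- km_fit(xs, k, centers = init_centers, max_iter = km_max_iter,
                 tol = km_tol)
  } else {
    km <- km_fit(xs, k, max_iter = km_max_iter, tol = km_tol, seed = seed)
  }

  centers <- sweep(sweep(km$centers, 2, scl, `*`), 2, ctr, `+`)
  colnames(centers) <- colnames(x)
  structure(list(cluster = km$cluster, centers = centers,
                 centers_scaled = km$centers, sse = km$sse,
                 method = method, k = k, pso = pso, km = km,
                 scaled = isTRUE(scale), center = ctr, scale = scl,
                 data = x, seed = seed, call = match.call()),
            class = "pso_kmeans")
}

#' @export
print.pso_kmeans <- function(x, digits = 4, ...) {
  label <- if (x$method == "psokm") "Hybrid PSO + K-means" else "K-means"
  cat(sprintf("%s clustering, k = %d, n = %d\n", label, x$k, length(x$cluster)))
  cat(sprintf("SSE (%s features): %.*g\n",
              if (x$scaled) "standardized" else "raw", digits, x$sse))
  cat("Cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pso_kmeans <- function(object, ...) {
  structure(list(fit = object), class = "summary.pso_kmeans")
}

#' @export
print.summary.pso_kmeans <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nCentroids (original feature scale):\n")
  print(round(f$centers, digits))
  if (!is.null(f$pso)) {
    h <- f$pso$history
    cat(sprintf("\nSwarm stage: %d particles, %d iterations; best fitness %.6g -> %.6g\n",
                f$pso$control$swarm, f$pso$iterations, h[1], h[length(h)]))
    cat(sprintf("K-means refinement: SSE %.6g -> %.6g\n",
                f$pso$value, f$sse))
  }
  invisible(x)
}

#' @export
coef.pso_kmeans <- function(object, ...) object$centers

#' @export
fitted.pso_kmeans <- function(object, ...) object$cluster

#' Assign new observations to fitted clusters
#'
#' @param object A fitted [pso_kmeans()] object.
#' @param newdata Feature matrix with the same columns as the training
#'   data; defaults to the training data.
#' @param ... Unused.
#' @return Integer cluster assignments (nearest fitted centroid, in the
#'   space the model was fitted in).
#' @export
predict.pso_kmeans <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$cluster)
  nd <- as_point_matrix(newdata)
  nds <- sweep(sweep(nd, 2, object$center, `-`), 2, object$scale, `/`)
  nearest_centroid(nds, object$centers_scaled)
}

#' Plot a fitted clustering
#'
#' Scatter-plot matrix of the features colored by cluster, with centroids
#' overplotted; for a hybrid fit, optionally the swarm-best fitness trace.
#'
#' @param x A fitted [pso_kmeans()] object.
#' @param which `"clusters"`, `"history"`, or both.
#' @param ... Passed to [graphics::pairs()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pso_kmeans <- function(x, which = "clusters", ...) {
  which <- match.arg(which, c("clusters", "history"), several.ok = TRUE)
  pal <- grDevices::hcl.colors(x$k, "Dark 3")
  if ("clusters" %in% which) {
    if (ncol(x$data) == 2) {
      graphics::plot(x$data, col = pal[x$cluster], pch = 16, ...)
      graphics::points(x$centers, pch = 8, cex = 2, lwd = 2)
    } else {
      graphics::pairs(rbind(x$data, x$centers),
                      col = c(pal[x$cluster], rep("black", x$k)),
                      pch = c(rep(16, nrow(x$data)), rep(8, x$k)), ...)
    }
  }
  if ("history" %in% which && !is.null(x$pso)) {
    graphics::plot(seq_along(x$pso$history) - 1, x$pso$history, type = "s",
                   xlab = "iteration", ylab = "swarm-best SSE", ...)
  }
  invisible(x)
}
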