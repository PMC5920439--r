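# Independent oracles used across the suite.  Each is a direct, naive
# computation kept deliberately separate from the package implementation.

# double-loop SSE: for each point, scan every centroid
oracle_sse <- function(x, centers) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    best <- Inf
    for (j in seq_len(nrow(centers))) {
      d <- sum((x[i, ] - centers[j, ])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  total
}

# naive nearest-centroid search with lowest-index tie-breaking
oracle_nearest <- function(x, centers) {
  vapply(seq_len(nrow(x)), function(i) {
    d <- vapply(seq_len(nrow(centers)),
                function(j) sum((x[i, ] - centers[j, ])^2), 0)
    which(d == min(d))[1]
  }, 0L)
}

# global optimum of the k-means objective by exhaustive enumeration of all
# assignments of n points to at most k clusters (centroid = cluster mean)
oracle_kmeans_optimum <- function(x, k) {
  n <- nrow(x)
  stopifnot(k^n <= 2e5)
  best <- Inf
  for (code in 0:(k^n - 1)) {
    assign <- integer(n)
    c0 <- code
    for (i in seq_len(n)) {
      assign[i] <- c0 %% k + 1L
      c0 <- c0 %/% k
    }
    sse <- 0
    for (j in unique(assign)) {
      pts <- x[assign == j, , drop = FALSE]
      mu <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, mu)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# pair-by-pair Rand index
oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0L; total <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1L
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1L
    }
  }
  agree / total
}

# a tiny valid subject table
make_subjects <- function(n = 3) {
  data.frame(
    id = sprintf("P%02d", seq_len(n)),
    age = seq(22, 40, length.out = n),
    weight = seq(50, 80, length.out = n),
    height = seq(1.60, 1.85, length.out = n),
    rter = rep(40, n), rtir = rep(35, n),
    lter = rep(45, n), ltir = rep(30, n),
    stringsAsFactors = FALSE
  )
}

# fraction of points whose true label matches the fitted clusters after
# optimal relabeling
label_agreement <- function(cluster, truth) {
  m <- match_clusters(cluster, truth)
  pred <- m[as.integer(factor(cluster))]
  mean(pred == as.integer(factor(truth)))
}
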