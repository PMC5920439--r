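test_that("SSE objective matches the double-loop oracle", {
  expect_equal(sse_objective(matrix(c(0, 2)), matrix(1)), 2)
  x <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(sse_objective(x, x), 0)

  set.seed(5)
  pts <- matrix(rnorm(20 * 3), 20)
  ctr <- matrix(rnorm(4 * 3), 4)
  expect_equal(sse_objective(pts, ctr), oracle_sse(pts, ctr))
  expect_error(sse_objective(pts, matrix(rnorm(4), 2)), "dimension mismatch")
})

test_that("nearest-centroid assignment breaks ties toward the lowest index", {
  ctr <- rbind(c(0, 0), c(2, 0))
  expect_equal(nearest_centroid(rbind(c(0, 0), c(2, 0)), ctr), c(1L, 2L))
  # equidistant point goes to centroid 1
  expect_equal(nearest_centroid(rbind(c(1, 0)), ctr), 1L)

  set.seed(6)
  pts <- matrix(rnorm(40 * 2), 40)
  cs <- matrix(rnorm(3 * 2), 3)
  expect_equal(nearest_centroid(pts, cs), oracle_nearest(pts, cs))
})

test_that("k-means finds the obvious partition of two tight triples", {
  x <- matrix(c(0, 1, 2, 10, 11, 12))
  fit <- km_fit(x, k = 2, seed = 1)
  expect_setequal(as.vector(fit$centers), c(1, 11))
  expect_equal(length(unique(fit$cluster[1:3])), 1L)
  expect_equal(length(unique(fit$cluster[4:6])), 1L)
  # exhaustive enumeration confirms this is the optimum
  expect_equal(fit$sse, oracle_kmeans_optimum(x, 2))
})

test_that("k = n gives a zero-SSE singleton partition; k too large errors", {
  x <- matrix(c(1, 5, 9, 13), 4)
  fit <- km_fit(x, k = 4, seed = 2)
  expect_equal(fit$sse, 0)
  expect_equal(sort(fit$cluster), 1:4)
  expect_error(km_fit(x, k = 5), "distinct points")
})

test_that("SSE is non-increasing across iterations and beats its start", {
  set.seed(8)
  for (rep in 1:5) {
    pts <- matrix(rnorm(60 * 2), 60)
    fit <- km_fit(pts, k = 3, seed = rep)
    expect_true(all(diff(fit$sse_history) <= 1e-9))
    expect_lte(fit$sse, fit$sse_history[1] + 1e-9)
  }
})

test_that("on tiny instances the engine's best restart attains the enumerated optimum", {
  set.seed(9)
  for (case in 1:3) {
    n <- sample(7:10, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n)
    opt <- oracle_kmeans_optimum(pts, k)
    sses <- vapply(1:50, function(s) km_fit(pts, k, seed = s)$sse, 0)
    # the enumerated optimum lower-bounds every restart ...
    expect_true(all(sses >= opt - 1e-9))
    # ... and the best of 50 restarts reaches it
    expect_lt(min(sses) - opt, 1e-9)
  }
})

test_that("k-means recovers well-separated mixture components", {
  mu <- rbind(c(0, 0, 0), c(15, 0, 0), c(0, 15, 0))
  mix <- simulate_mixture(mu, sds = 1, sizes = c(60, 70, 80), seed = 4)
  fit <- km_fit(mix$points, k = 3, seed = 1)
  expect_gte(label_agreement(fit$cluster, mix$labels), 0.99)
})

test_that("an empty cluster is repaired rather than dropped", {
  set.seed(10)
  pts <- matrix(rnorm(30 * 2), 30)
  # third centroid absurdly far away: it captures nothing at first
  init <- rbind(pts[1, ], pts[2, ], c(1e6, 1e6))
  fit <- km_fit(pts, k = 3, centers = init)
  expect_equal(sort(unique(fit$cluster)), 1:3)
  expect_true(is.finite(fit$sse))
  expect_true(all(diff(fit$sse_history) <= 1e-9))
})

test_that("engine agrees with stats::kmeans on an easy instance", {
  mix <- simulate_mixture(rbind(c(0, 0), c(12, 12)), sds = 1,
                          sizes = c(40, 40), seed = 5)
  ours <- km_fit(mix$points, k = 2, seed = 1)
  ref <- stats::kmeans(mix$points, centers = 2, nstart = 5)
  expect_equal(ours$sse, ref$tot.withinss, tolerance = 1e-8)
})
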