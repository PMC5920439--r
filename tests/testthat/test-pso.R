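test_that("velocity update follows the inertia + cognitive + social rule", {
  # all coefficients zero: no motion
  expect_equal(pso_velocity_update(c(1, 2), c(0, 0), c(1, 1), c(2, 2),
                                   w = 0, c1 = 0, c2 = 0, r1 = 0.5, r2 = 0.5),
               c(0, 0))
  # at both bests: only inertia survives
  x <- c(3, -1)
  expect_equal(pso_velocity_update(c(1, 2), x, x, x,
                                   w = 0.73, c1 = 1.49, c2 = 1.49,
                                   r1 = 0.4, r2 = 0.9),
               0.73 * c(1, 2))
  # hand-evaluated fixture: 0.5*1 + 1*0.5*(2-0) + 1*0.5*(4-0) = 3.5
  expect_equal(pso_velocity_update(v = c(1, 0), x = c(0, 0),
                                   pbest = c(2, 0), gbest = c(4, 0),
                                   w = 0.5, c1 = 1, c2 = 1,
                                   r1 = 0.5, r2 = 0.5),
               c(3.5, 0))
  # clamped to +/- v_max
  expect_equal(pso_velocity_update(c(1, 0), c(0, 0), c(2, 0), c(4, 0),
                                   0.5, 1, 1, 0.5, 0.5, v_max = c(2, 2)),
               c(2, 0))
  expect_error(pso_velocity_update(c(1, 0), c(0, 0, 0), c(2, 0), c(4, 0),
                                   0.5, 1, 1, 0.5, 0.5),
               "equal length")
})

test_that("position update adds velocity and reflects at the bounds", {
  still <- pso_position_update(c(1, 1), c(0, 0), c(0, 0), c(2, 2))
  expect_equal(still$position, c(1, 1))
  moved <- pso_position_update(c(1, 1), c(0.5, -0.5), c(0, 0), c(2, 2))
  expect_equal(moved$position, c(1.5, 0.5))
  expect_equal(moved$velocity, c(0.5, -0.5))
  # 0.9 + 0.3 = 1.2 reflects off the upper bound 1 to 0.8, velocity flips
  refl <- pso_position_update(c(0.9), c(0.3), 0, 1)
  expect_equal(refl$position, 0.8)
  expect_equal(refl$velocity, -0.3)
})

test_that("the swarm minimizes the sphere function", {
  finals <- vapply(1:20, function(s) {
    pso_optimize(function(z) sum(z^2), dim = 2, lower = -5, upper = 5,
                 seed = s)$value
  }, 0)
  expect_lt(median(finals), 1e-3)
})

test_that("degenerate swarms still return their best", {
  one <- pso_optimize(function(z) sum(z^2), dim = 2, lower = -5, upper = 5,
                      control = pso_control(swarm = 1), seed = 3)
  expect_true(is.finite(one$value))
  expect_equal(one$value, sum(one$par^2))

  const <- pso_optimize(function(z) 7, dim = 3, lower = 0, upper = 1, seed = 1)
  expect_equal(const$value, 7)
})

test_that("swarm-best and personal-best fitnesses are monotone non-increasing", {
  fit <- pso_optimize(function(z) sum((z - 1)^2), dim = 4, lower = -3,
                      upper = 3, seed = 12, trace = TRUE)
  expect_true(all(diff(fit$history) <= 0))
  expect_true(all(apply(fit$pbest_trace, 2, function(col) all(diff(col) <= 0))))
  expect_equal(fit$value, min(fit$pbest_trace))
})

test_that("a fixed seed makes the full trajectory bit-reproducible", {
  a <- pso_optimize(function(z) sum(z^2), dim = 3, lower = -2, upper = 2,
                    seed = 77, trace = TRUE)
  b <- pso_optimize(function(z) sum(z^2), dim = 3, lower = -2, upper = 2,
                    seed = 77, trace = TRUE)
  expect_identical(a, b)
})

test_that("per-dimension stochasticity is available behind a flag", {
  fit <- pso_optimize(function(z) sum(z^2), dim = 2, lower = -5, upper = 5,
                      control = pso_control(per_dimension = TRUE), seed = 5)
  expect_lt(fit$value, fit$history[1] + 1e-12)
})

test_that("non-finite fitness aborts with a diagnostic", {
  expect_error(pso_optimize(function(z) NaN, dim = 2, lower = 0, upper = 1,
                            seed = 1),
               "non-finite")
})

test_that("control parameters are validated", {
  expect_error(pso_control(w = 1.5), "\\[0, 1\\]")
  expect_error(pso_control(c1 = -1), ">= 0")
  expect_error(pso_control(swarm = 0), "swarm")
  expect_error(pso_optimize(function(z) 0, dim = 1, lower = 1, upper = 0),
               "lower < upper")
})
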