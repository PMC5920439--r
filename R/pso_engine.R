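# Particle swarm optimizer.  Particles move under the canonical velocity
# rule v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x), x' = x + v',
# minimizing a user fitness.  In the hybrid, a particle position is a
# flattened k x d centroid set and the fitness is the clustering SSE.

#' Control parameters for the particle swarm optimizer
#'
#' @param w Inertia factor in `[0, 1]` (default 0.73, the value experimental
#'   PSO studies converged on).
#' @param c1 Cognitive (personal-best attraction) parameter, non-negative
#'   (default 1.49).
#' @param c2 Social (swarm-best attraction) parameter, non-negative
#'   (default 1.49).
#' @param iterations Number of swarm iterations (default 30; typical
#'   practice is 20-30).
#' @param swarm Number of particles (default 30).
#' @param v_max Optional per-dimension velocity cap; defaults to half the
#'   search-box width in each dimension.
#' @param per_dimension If `TRUE`, draw independent `r1`, `r2` per
#'   dimension instead of one scalar pair per particle per iteration.
#' @return An object of class `"pso_control"`.
#' @export
pso_control <- function(w = 0.73, c1 = 1.49, c2 = 1.49,
                        iterations = 30L, swarm = 30L,
                        v_max = NULL, per_dimension = FALSE) {
  stopifnot_scalar_number(w, "w")
  stopifnot_scalar_number(c1, "c1")
  stopifnot_scalar_number(c2, "c2")
  if (w < 0 || w > 1) stop("'w' must be in [0, 1]", call. = FALSE)
  if (c1 < 0 || c2 < 0) stop("'c1' and 'c2' must be >= 0", call. = FALSE)
  iterations <- as.integer(iterations); swarm <- as.integer(swarm)
  if (iterations < 1L) stop("'iterations' must be >= 1", call. = FALSE)
  if (swarm < 1L) stop("'swarm' must be >= 1", call. = FALSE)
  structure(list(w = w, c1 = c1, c2 = c2, iterations = iterations,
                 swarm = swarm, v_max = v_max,
                 per_dimension = isTRUE(per_dimension)),
            class = "pso_control")
}

#' Particle velocity update
#'
#' One application of the swarm velocity rule: inertia plus stochastic
#' attraction toward the particle's personal best and the swarm best,
#' componentwise, then clamped to `v_max`.
#'
#' @param v Current velocity vector.
#' @param x Current position vector.
#' @param pbest Particle's personal-best position.
#' @param gbest Swarm-best position.
#' @param w,c1,c2 Inertia, cognitive and social parameters.
#' @param r1,r2 Random draws in (0, 1); scalars, or vectors of the
#'   position's length for per-dimension stochasticity.
#' @param v_max Optional per-dimension absolute velocity cap.
#' @return The new velocity vector.
#' @examples
#' pso_velocity_update(v = c(1, 0), x = c(0, 0), pbest = c(2, 0),
#'                     gbest = c(4, 0), w = 0.5, c1 = 1, c2 = 1,
#'                     r1 = 0.5, r2 = 0.5)  # (3.5, 0)
#' @export
pso_velocity_update <- function(v, x, pbest, gbest, w, c1, c2, r1, r2,
                                v_max = NULL) {
  n <- length(x)
  if (length(v) != n || length(pbest) != n || length(gbest) != n) {
    stop("velocity, position, pbest and gbest must have equal length",
         call. = FALSE)
  }
  v_new <- w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
  if (!is.null(v_max)) v_new <- pmin(pmax(v_new, -v_max), v_max)
  v_new
}

#' Particle position update with reflecting bounds
#'
#' Moves the particle by its velocity; a component leaving the search box
#' is reflected back inside and its velocity component negated.
#'
#' @param x Current position vector.
#' @param v Velocity vector (already updated).
#' @param lower,upper Per-dimension search bounds.
#' @return List with `position` and (possibly sign-flipped) `velocity`.
#' @export
pso_position_update <- function(x, v, lower, upper) {
  if (length(x) != length(v)) {
    stop("position and velocity must have equal length", call. = FALSE)
  }
  p <- x + v
  for (reflections in 1:100) {
    below <- p < lower; above <- p > upper
    if (!any(below) && !any(above)) break
    p[below] <- 2 * lower[below] - p[below]
    p[above] <- 2 * upper[above] - p[above]
    v[below | above] <- -v[below | above]
  }
  # pathological velocities: clamp whatever is still outside
  p <- pmin(pmax(p, lower), upper)
  list(position = p, velocity = v)
}

#' Particle swarm optimization of a fitness function
#'
#' Minimizes `fn` over a box. The swarm starts uniformly inside the
#' bounds with zero velocities; each iteration updates every particle's
#' velocity and position, re-evaluates the fitness, updates personal
#' bests on improvement, and takes the best personal best as the swarm
#' best at the end of the iteration. Runs for a fixed number of
#' iterations.
#'
#' @param fn Fitness function: numeric vector of length `dim` to a single
#'   finite number (minimized).
#' @param dim Dimensionality of the search space.
#' @param lower,upper Per-dimension bounds (recycled to length `dim`).
#' @param control A [pso_control()] object.
#' @param seed Integer seed; fixes the full trajectory.
#' @param trace If `TRUE`, also return the per-iteration matrix of
#'   personal-best fitnesses.
#' @return A list of class `"pso_fit"`: `par` (best position), `value`
#'   (best fitness), `history` (swarm-best fitness after initialization
#'   and after each iteration), `iterations`, and optionally
#'   `pbest_trace`.
#' @examples
#' sphere <- function(z) sum(z^2)
#' fit <- pso_optimize(sphere, dim = 2, lower = -5, upper = 5, seed = 1)
#' fit$value
#' @export
pso_optimize <- function(fn, dim, lower, upper, control = pso_control(),
                         seed = NULL, trace = FALSE) {
  dim <- as.integer(dim)
  if (dim < 1L) stop("'dim' must be >= 1", call. = FALSE)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper)) stop("bounds must satisfy lower < upper", call. = FALSE)
  v_max <- if (is.null(control$v_max)) (upper - lower) / 2 else
    rep_len(as.numeric(control$v_max), dim)

  eval_fit <- function(z) {
    val <- fn(z)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("fitness function returned a non-finite value", call. = FALSE)
    }
    val
  }

  with_seed(seed, {
    ns <- control$swarm
    pos <- matrix(stats::runif(ns * dim, rep(lower, each = ns),
                               rep(upper, each = ns)), nrow = ns)
    vel <- matrix(0, nrow = ns, ncol = dim)
    fit <- apply(pos, 1, eval_fit)
    pbest <- pos
    pbest_fit <- fit
    g <- which.min(pbest_fit)
    gbest <- pbest[g, ]
    gbest_fit <- pbest_fit[g]
    history <- gbest_fit
    pbest_trace <- if (trace) matrix(pbest_fit, nrow = 1) else NULL

    for (t in seq_len(control$iterations)) {
      for (i in seq_len(ns)) {
        if (control$per_dimension) {
          r1 <- stats::runif(dim); r2 <- stats::runif(dim)
        } else {
          r1 <- stats::runif(1); r2 <- stats::runif(1)
        }
        v_new <- pso_velocity_update(vel[i, ], pos[i, ], pbest[i, ], gbest,
                                     control$w, control$c1, control$c2,
                                     r1, r2, v_max)
        upd <- pso_position_update(pos[i, ], v_new, lower, upper)
        pos[i, ] <- upd$position
        vel[i, ] <- upd$velocity
        f <- eval_fit(pos[i, ])
        if (f < pbest_fit[i]) {
          pbest_fit[i] <- f
          pbest[i, ] <- pos[i, ]
        }
      }
      # synchronous swarm-best update at iteration end
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest_fit <- pbest_fit[g]
        gbest <- pbest[g, ]
      }
      history <- c(history, gbest_fit)
      if (trace) pbest_trace <- rbind(pbest_trace, pbest_fit)
    }
    out <- list(par = gbest, value = gbest_fit, history = history,
                iterations = control$iterations, control = control)
    if (trace) out$pbest_trace <- pbest_trace
    structure(out, class = "pso_fit")
  })
}

#' @export
print.pso_fit <- function(x, ...) {
  cat(sprintf("PSO fit: %d particles, %d iterations, best fitness %.6g\n",
              x$control$swarm, x$iterations, x$value))
  invisible(x)
}
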