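#' Linearly decaying contraction-expansion coefficient
#'
#' QPSO's single step-size control: `alpha = 0.5 + 0.5 * (Tmax - t) / Tmax`,
#' decaying from 1.0 at the start of the run to 0.5 at the final iteration.
#'
#' @param t current iteration, `0 <= t <= t_max`.
#' @param t_max maximum number of iterations (> 0).
#' @return scalar in `[0.5, 1]`.
#' @export
contraction_coefficient <- function(t, t_max) {
  if (t_max <= 0) stop("`t_max` must be positive")
  if (t < 0 || t > t_max) stop("`t` must lie in [0, t_max]")
  0.5 + 0.5 * (t_max - t) / t_max
}

.check_bounds <- function(bounds) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stop("`bounds` must be a D x 2 matrix (min, max)")
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[, 1] >= bounds[, 2])) {
    stop("each dimension needs min < max (degenerate or inverted bounds)")
  }
  bounds
}

#' Initialise a QPSO swarm
#'
#' Positions are sampled uniformly within the box bounds; personal bests are
#' the initial positions. If an objective is supplied the initial fitnesses
#' and the global best are evaluated immediately.
#'
#' @param bounds D x 2 numeric matrix of per-dimension (min, max).
#' @param n_particles swarm size (>= 2).
#' @param seed integer seed; the swarm and any subsequent steps are fully
#'   reproducible given the seed.
#' @param objective optional function of a position vector returning a scalar
#'   fitness (minimisation convention).
#' @param t_max maximum iteration count used by the contraction schedule.
#' @return an object of class `qpso_swarm`.
#' @export
init_swarm <- function(bounds, n_particles, seed = NULL, objective = NULL,
                       t_max = 200L) {
  bounds <- .check_bounds(bounds)
  if (n_particles < 2L) stop("`n_particles` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  D <- nrow(bounds)
  positions <- matrix(stats::runif(n_particles * D), n_particles, D)
  positions <- sweep(positions, 2L, bounds[, 2] - bounds[, 1], "*")
  positions <- sweep(positions, 2L, bounds[, 1], "+")
  pbest_fit <- rep(NA_real_, n_particles)
  gbest <- NULL
  gbest_fit <- NA_real_
  if (!is.null(objective)) {
    pbest_fit <- .eval_fitness(objective, positions)
    k <- which.min(pbest_fit)
    gbest <- positions[k, ]
    gbest_fit <- pbest_fit[k]
  }
  structure(
    list(positions = positions, pbest = positions, pbest_fit = pbest_fit,
         gbest = gbest, gbest_fit = gbest_fit, bounds = bounds,
         t = 0L, t_max = as.integer(t_max), n = n_particles, d = D,
         history = numeric(0)),
    class = "qpso_swarm"
  )
}

.eval_fitness <- function(objective, positions) {
  f <- apply(positions, 1L, objective)
  bad <- !is.finite(f)
  if (any(bad)) {
    warning("objective returned non-finite fitness for ", sum(bad),
            " particle(s); treated as +Inf", call. = FALSE)
    f[bad] <- Inf
  }
  f
}

#' Advance a QPSO swarm by one iteration
#'
#' Per particle and dimension the stochastic attractor is
#' `P = phi * pbest + (1 - phi) * gbest` with `phi ~ U(0,1)`; `mbest` is the
#' mean of all personal bests; the new position is
#' `P +/- alpha * |mbest - x| * ln(1/u)` with `u ~ U(0,1)`, the sign negative
#' when an independent `r ~ U(0,1)` is `>= 0.5`. Positions are clamped to the
#' bounds, personal and global bests updated on strict improvement, and the
#' iteration counter advanced.
#'
#' @param swarm a `qpso_swarm` whose fitnesses have been initialised.
#' @param objective scalar objective (minimisation).
#' @param draws optional list with matrices/scalars `phi`, `u`, `r` (each
#'   recycled to `n x d`) overriding the random draws -- used for exact
#'   hand-checked updates in tests.
#' @return the updated `qpso_swarm`.
#' @export
qpso_step <- function(swarm, objective, draws = NULL) {
  stopifnot(inherits(swarm, "qpso_swarm"))
  if (swarm$t >= swarm$t_max) stop("swarm already at t_max iterations")
  if (anyNA(swarm$pbest_fit)) {
    swarm$pbest_fit <- .eval_fitness(objective, swarm$positions)
    k <- which.min(swarm$pbest_fit)
    swarm$gbest <- swarm$positions[k, ]
    swarm$gbest_fit <- swarm$pbest_fit[k]
  }
  n <- swarm$n; D <- swarm$d
  rng_mat <- function(which) {
    if (!is.null(draws) && !is.null(draws[[which]])) {
      matrix(draws[[which]], n, D)
    } else {
      matrix(stats::runif(n * D), n, D)
    }
  }
  phi <- rng_mat("phi")
  u <- pmax(rng_mat("u"), 1e-12)  # guard ln(1/u)
  r <- rng_mat("r")

  t_new <- swarm$t + 1L
  alpha <- contraction_coefficient(t_new, swarm$t_max)
  P <- phi * swarm$pbest + (1 - phi) * matrix(swarm$gbest, n, D, byrow = TRUE)
  mbest <- colMeans(swarm$pbest)
  spread <- alpha * abs(sweep(-swarm$positions, 2L, mbest, "+")) * log(1 / u)
  newpos <- P + ifelse(r >= 0.5, -1, 1) * spread
  # clamp to the box
  newpos <- pmin(pmax(newpos, matrix(swarm$bounds[, 1], n, D, byrow = TRUE)),
                 matrix(swarm$bounds[, 2], n, D, byrow = TRUE))

  fit <- .eval_fitness(objective, newpos)
  improved <- fit < swarm$pbest_fit
  swarm$pbest[improved, ] <- newpos[improved, , drop = FALSE]
  swarm$pbest_fit[improved] <- fit[improved]
  k <- which.min(swarm$pbest_fit)
  if (swarm$pbest_fit[k] < swarm$gbest_fit) {
    swarm$gbest <- swarm$pbest[k, ]
    swarm$gbest_fit <- swarm$pbest_fit[k]
  }
  swarm$positions <- newpos
  swarm$t <- t_new
  swarm$history <- c(swarm$history, swarm$gbest_fit)
  swarm
}

#' Quantum-behaved particle swarm optimisation over a box
#'
#' Runs `t_max` QPSO iterations (see [qpso_step()]) from a uniform random
#' initialisation. The optimizer natively minimises; `sense = "maximize"`
#' negates the objective internally and reports results on the original scale.
#'
#' @param objective function of a position vector returning a scalar.
#' @param bounds D x 2 matrix of per-dimension (min, max).
#' @param n_particles swarm size (default 200).
#' @param t_max iterations (default 200).
#' @param seed integer seed for full reproducibility.
#' @param sense `"minimize"` (default) or `"maximize"`.
#' @return an object of class `qpso_result`: `best_position`, `best_fitness`,
#'   and `history` (per-iteration global best, length `t_max`; non-increasing
#'   when minimising, non-decreasing when maximising).
#' @export
qpso_optimize <- function(objective, bounds, n_particles = 200L,
                          t_max = 200L, seed = NULL,
                          sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  obj <- if (sense == "maximize") function(p) -objective(p) else objective
  swarm <- init_swarm(bounds, n_particles, seed = seed, objective = obj,
                      t_max = t_max)
  for (i in seq_len(t_max)) swarm <- qpso_step(swarm, obj)
  sign <- if (sense == "maximize") -1 else 1
  structure(
    list(best_position = swarm$gbest,
         best_fitness = sign * swarm$gbest_fit,
         history = sign * swarm$history,
         sense = sense, n_particles = n_particles, t_max = t_max),
    class = "qpso_result"
  )
}

#' @export
print.qpso_result <- function(x, ...) {
  cat(sprintf("<qpso_result> best fitness %.6g after %d iterations (%s, %d particles)\n",
              x$best_fitness, x$t_max, x$sense, x$n_particles))
  invisible(x)
}
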