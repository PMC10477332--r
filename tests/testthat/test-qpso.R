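test_that("contraction coefficient decays linearly from 1.0 to 0.5", {
  expect_equal(contraction_coefficient(0, 200), 1.0)
  expect_equal(contraction_coefficient(100, 200), 0.75)
  expect_equal(contraction_coefficient(200, 200), 0.5)
  expect_error(contraction_coefficient(-1, 200), "\\[0, t_max\\]")
  expect_error(contraction_coefficient(201, 200), "\\[0, t_max\\]")
  expect_error(contraction_coefficient(1, 0), "positive")
})

test_that("swarm initialisation is uniform within bounds and reproducible", {
  b <- matrix(c(0, 1), 4, 2, byrow = TRUE)
  s <- init_swarm(b, 100, seed = 1)
  expect_true(all(s$positions >= 0 & s$positions <= 1))
  expect_true(all(colMeans(s$positions) > 0.4 & colMeans(s$positions) < 0.6))
  s2 <- init_swarm(b, 100, seed = 1)
  expect_identical(s$positions, s2$positions)
  expect_error(init_swarm(matrix(c(1, 1), 1, 2), 10, seed = 1), "min < max")
  expect_error(init_swarm(matrix(c(2, 1), 1, 2), 10, seed = 1), "min < max")
  expect_error(init_swarm(b, 1, seed = 1), ">= 2")
})

test_that("a hand-fixed step reproduces the quantum position update", {
  obj <- function(p) p[1]^2
  s <- init_swarm(matrix(c(-100, 100), 1, 2), 2, seed = 1, objective = obj,
                  t_max = 10)
  # overwrite state with hand-picked values
  s$positions <- matrix(c(2, -3), 2, 1)
  s$pbest <- matrix(c(1, -2), 2, 1)
  s$pbest_fit <- c(1, 4)
  s$gbest <- 1
  s$gbest_fit <- 1
  s2 <- qpso_step(s, obj, draws = list(phi = 0.5, u = 0.5, r = 0.6))
  # by hand: mbest = (1 + -2)/2 = -0.5; alpha(t=1, Tmax=10) = 0.95
  # P1 = 0.5*1 + 0.5*1 = 1;  x1 = 1 - 0.95*|-0.5-2|*ln(2)  = -0.64623...
  # P2 = 0.5*-2 + 0.5*1 = -0.5; x2 = -0.5 - 0.95*|-0.5+3|*ln(2) = -2.14623...
  ln2 <- log(2)
  expect_equal(s2$positions[1, 1], 1 - 0.95 * 2.5 * ln2)
  expect_equal(s2$positions[2, 1], -0.5 - 0.95 * 2.5 * ln2)
  expect_equal(s2$t, 1L)
})

test_that("mbest is the pbest centroid and gbest never worsens", {
  obj <- function(p) sum(p^2)
  s <- init_swarm(matrix(c(-5, 5), 3, 2, byrow = TRUE), 10, seed = 2,
                  objective = obj, t_max = 50)
  g0 <- s$gbest_fit
  for (i in 1:20) {
    g_before <- s$gbest_fit
    s <- qpso_step(s, obj)
    expect_lte(s$gbest_fit, g_before)
  }
  expect_lte(s$gbest_fit, g0)
  expect_false(is.unsorted(rev(s$history)))
})

test_that("non-finite objectives are demoted to +Inf with a warning", {
  obj <- function(p) if (p[1] > 0) NaN else sum(p^2)
  expect_warning(
    s <- init_swarm(matrix(c(-1, 1), 1, 2), 10, seed = 3, objective = obj,
                    t_max = 5),
    "non-finite"
  )
  expect_true(is.finite(s$gbest_fit))
})

test_that("QPSO minimises the 5-D sphere to high precision", {
  r <- qpso_optimize(function(p) sum(p^2),
                     matrix(c(-5, 5), 5, 2, byrow = TRUE),
                     n_particles = 30, t_max = 200, seed = 1)
  expect_lt(r$best_fitness, 1e-3)
  expect_length(r$history, 200)
  expect_false(is.unsorted(rev(r$history)))
  expect_true(all(abs(r$best_position) <= 5))
})

test_that("a constant objective yields a flat history at that constant", {
  r <- qpso_optimize(function(p) 7, matrix(c(0, 1), 2, 2, byrow = TRUE),
                     n_particles = 5, t_max = 20, seed = 4)
  expect_equal(r$best_fitness, 7)
  expect_true(all(r$history == 7))
})

test_that("maximisation negates internally and reports a non-decreasing history", {
  r <- qpso_optimize(function(p) -sum((p - 0.3)^2),
                     matrix(c(0, 1), 2, 2, byrow = TRUE),
                     n_particles = 20, t_max = 100, seed = 5,
                     sense = "maximize")
  expect_gt(r$best_fitness, -1e-4)
  expect_false(is.unsorted(r$history))
})

test_that("QPSO beats random search on the 2-D Rastrigin at equal budget", {
  ras <- function(p) sum(p^2 - 10 * cos(2 * pi * p) + 10)
  b <- matrix(c(-5.12, 5.12), 2, 2, byrow = TRUE)
  qpso_best <- vapply(1:10, function(s) {
    qpso_optimize(ras, b, n_particles = 40, t_max = 300, seed = s)$best_fitness
  }, numeric(1))
  random_best <- vapply(1:10, function(s) {
    set.seed(s + 10000)
    m <- matrix(runif(40 * 300 * 2, -5.12, 5.12), ncol = 2)
    min(apply(m, 1, ras))
  }, numeric(1))
  expect_lt(median(qpso_best), median(random_best))
})

test_that("identical seeds reproduce identical optimisation runs", {
  obj <- function(p) sum(abs(p))
  b <- matrix(c(-2, 2), 3, 2, byrow = TRUE)
  r1 <- qpso_optimize(obj, b, 15, 30, seed = 42)
  r2 <- qpso_optimize(obj, b, 15, 30, seed = 42)
  expect_identical(r1, r2)
})
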