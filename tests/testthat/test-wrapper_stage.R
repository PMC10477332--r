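test_that("particles decode to mask and SVM parameters by the 0.5 rule", {
  cfg <- fitness_config(d_original = 4)
  d <- decode_particle(c(0.7, 0.2, 0.5, 0.49, 12.3, 0.8), 4, cfg)
  expect_equal(d$mask, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(d$svm$C, 12.3)
  expect_equal(d$svm$sigma, 0.8)
  # boundary 0.5 counts as selected; 0.49 does not
  full <- decode_particle(c(rep(0.5, 4), 1, 1), 4, cfg)
  expect_true(all(full$mask))
  none <- decode_particle(c(rep(0.49, 4), 1, 1), 4, cfg)
  expect_false(any(none$mask))
  expect_error(decode_particle(c(0.5, 1, 1), 4, cfg), "length")
})

test_that("the accuracy weight phi(d) is (9 + exp(-d/100))/10", {
  expect_equal(phi_weight(0), 1.0)
  expect_equal(phi_weight(100), (9 + exp(-1)) / 10, tolerance = 1e-5)
  expect_gte(phi_weight(1e6), 0.9)
  expect_lt(phi_weight(1e6) - 0.9, 1e-6)
  expect_error(phi_weight(-1), "nonnegative")
  grid <- phi_weight(seq(0, 1e5, by = 100))
  expect_true(all(diff(grid) <= 0))
  expect_true(all(grid >= 0.9 & grid <= 1))
  # strictly decreasing until the exponential tail falls below double precision
  expect_true(all(diff(phi_weight(seq(0, 3000, by = 100))) < 0))
})

test_that("cross-validated SVM accuracy separates planted Gaussian classes", {
  F <- separable_gaussians(n = 200, gap = 4, seed = 1)
  acc <- svm_cv_accuracy(F, c(TRUE, TRUE), svm_params(1, 1), k = 3, seed = 1)
  expect_gte(acc, 0.95)
  # chance level on permuted labels
  set.seed(2)
  accs <- vapply(1:20, function(i) {
    Fp <- feature_matrix(F$values, sample(F$labels))
    svm_cv_accuracy(Fp, c(TRUE, TRUE), svm_params(1, 1), k = 3, seed = i)
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("duplicating a selected feature barely changes the CV accuracy", {
  F <- separable_gaussians(n = 200, gap = 2, seed = 3)
  X2 <- cbind(F$values, dup = F$values[, 1])
  F2 <- feature_matrix(X2, F$labels)
  a1 <- svm_cv_accuracy(F, c(TRUE, TRUE), svm_params(1, 1), 3, seed = 5)
  a2 <- svm_cv_accuracy(F2, c(TRUE, TRUE, TRUE), svm_params(1, 1), 3, seed = 5)
  expect_lte(abs(a1 - a2), 0.05)
})

test_that("CV accuracy validates masks and fold counts", {
  F <- separable_gaussians(n = 30, seed = 4)
  expect_error(svm_cv_accuracy(F, c(FALSE, FALSE), svm_params(1, 1), 3, 1),
               "empty mask")
  expect_error(svm_cv_accuracy(F, c(TRUE, TRUE), svm_params(1, 1), k = 20, 1),
               "fewer samples")
  expect_error(svm_params(-1, 1), "positive")
})

test_that("fitness combines accuracy and dimension reduction with phi(d_original)", {
  # pure arithmetic at the documented operating point
  expect_equal(weighted_score(0.9, 0.8, 665), 0.89001, tolerance = 1e-4)
  F <- separable_gaussians(n = 60, seed = 6)
  cfg <- fitness_config(d_original = 10, fold_seed = 3)
  pos <- c(0.9, 0.1, 5, 1)  # mask = (T, F), C = 5, sigma = 1
  f <- wrapper_fitness(pos, F, cfg)
  CA <- svm_cv_accuracy(F, c(TRUE, FALSE), svm_params(5, 1), 3, seed = 3)
  phi <- phi_weight(10)
  expect_equal(f, phi * CA + (1 - phi) * 0.5, tolerance = 1e-12)
  # empty mask scores zero under the default policy
  expect_equal(wrapper_fitness(c(0.1, 0.1, 5, 1), F, cfg), 0)
  cfg_err <- fitness_config(d_original = 10, empty_mask_policy = "error")
  expect_error(wrapper_fitness(c(0.1, 0.1, 5, 1), F, cfg_err), "empty")
})

test_that("fitness is deterministic in the particle (fixed inner folds)", {
  F <- separable_gaussians(n = 60, seed = 7)
  cfg <- fitness_config(d_original = 5)
  pos <- c(0.8, 0.8, 2, 1)
  expect_identical(wrapper_fitness(pos, F, cfg), wrapper_fitness(pos, F, cfg))
})

test_that("a single perfectly informative candidate is selected with CA 1", {
  set.seed(8)
  y <- rep(0:1, each = 30)
  X <- cbind(perfect = as.numeric(y) + 0.01 * rnorm(60))
  F <- feature_matrix(X, y)
  cfg <- fitness_config(d_original = 1)
  sel <- qpso_select(F, cfg, n_particles = 10, t_max = 20, seed = 1)
  expect_true(sel$mask)
  expect_gte(sel$CA, 0.95)
})

test_that("selection on a planted table recovers the relevant features compactly", {
  tab <- gen_feature_table(seed = 1)
  cfg <- fitness_config(d_original = 20)
  sel <- qpso_select(tab$features, cfg, n_particles = 30, t_max = 60, seed = 11)
  planted <- colnames(tab$features$values)[tab$roles == "relevant"]
  expect_gte(mean(planted %in% sel$names), 0.8)
  expect_lte(sum(sel$mask), 10)
  expect_false(is.unsorted(sel$history))
  # stored parts reproduce the fitness exactly
  phi <- phi_weight(sel$d_original)
  expect_equal(sel$fitness, phi * sel$CA + (1 - phi) * sel$DR,
               tolerance = 1e-12)
})

test_that("with the accuracy weight saturated, selection does not lose accuracy", {
  tab <- gen_feature_table(n_samples = 200, n_relevant = 3, n_redundant = 0,
                           n_irrelevant = 5, seed = 23)
  F <- tab$features
  # d_original = 1 puts ~all weight on accuracy
  cfg <- fitness_config(d_original = 1, fold_seed = 2)
  sel <- qpso_select(F, cfg, n_particles = 20, t_max = 40, seed = 3)
  ca_all <- svm_cv_accuracy(F, rep(TRUE, ncol(F$values)), svm_params(1, 1),
                            3, seed = 2)
  expect_gte(sel$CA, ca_all - 0.05)
})
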