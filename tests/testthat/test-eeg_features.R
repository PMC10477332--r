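test_that("band decomposition is an exact additive partition of the epoch", {
  set.seed(11)
  for (n in c(64, 1000, 2560)) {
    x <- rnorm(n)
    bands <- decompose_bands(x)
    expect_named(bands, c("delta", "theta", "alpha", "beta", "gamma"))
    expect_true(all(vapply(bands, length, 1L) == n))
    recon <- Reduce(`+`, bands)
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-8)
  }
})

test_that("a pure 10 Hz sinusoid concentrates its energy in the alpha band", {
  t <- (0:2559) / 256
  bands <- decompose_bands(sin(2 * pi * 10 * t), fs = 256)
  energy <- vapply(bands, function(b) sum(b^2), numeric(1))
  expect_gte(energy[["alpha"]] / sum(energy), 0.90)
})

test_that("band decomposition is linear and rejects short epochs", {
  z <- decompose_bands(numeric(128))
  expect_true(all(vapply(z, function(b) all(b == 0), logical(1))))
  expect_error(decompose_bands(numeric(63)), "64")
  expect_error(decompose_bands(rep(NaN, 128)), "finite")
})

test_that("approximate entropy matches its defining properties", {
  expect_equal(approximate_entropy(rep(3, 60), m = 2, r = 0.2), 0)
  # strictly periodic alternation: almost every template has a unique
  # continuation, so the entropy is ~0 (small finite-size correction)
  expect_lt(abs(approximate_entropy(rep(c(0, 1), 50), m = 2, r = 0.1)), 1e-3)
  set.seed(5)
  wn <- rnorm(1024)
  sine <- sin(2 * pi * 5 * (0:1023) / 1024)
  expect_gt(approximate_entropy(wn, 2, 0.2 * sd(wn)),
            approximate_entropy(sine, 2, 0.2 * sd(sine)))
  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "short")
  expect_error(approximate_entropy(rnorm(50), m = 2, r = -1), "positive")
})

test_that("mean PSD follows Parseval's identity", {
  expect_equal(psd_mean(c(1, 0, 0, 0)), 1.0)
  expect_equal(psd_mean(c(1, 1, 1, 1)), 4.0)
  expect_equal(psd_mean(numeric(16)), 0.0)
  set.seed(1)
  x <- rnorm(100)
  expect_equal(psd_mean(x), sum(x^2))
  expect_error(psd_mean(numeric(0)), "empty")
})

test_that("Hjorth parameters match hand-computed values", {
  expect_equal(unname(hjorth(c(1, 2, 3))["activity"]), 2 / 3)
  h <- hjorth(c(1, -1, 1, -1))
  expect_equal(unname(h["mobility"]), 2.0)
  expect_equal(unname(h["complexity"]), 1.0)
  expect_equal(unname(hjorth(rep(5, 10), which = "activity")), 0)
  expect_error(hjorth(rep(5, 10), which = "mobility"), "degenerate")
  expect_error(hjorth(c(1, 2)), "short")
})

test_that("C0 complexity is 0 for pure dominant-line signals and in (0,1) for noise", {
  n <- 128
  s <- sin(2 * pi * 8 * (0:(n - 1)) / n)  # exactly on a DFT bin
  expect_lt(c0_complexity(s), 1e-10)
  expect_equal(c0_complexity(rep(3, 64)), 0)
  set.seed(9)
  v <- c0_complexity(rnorm(1024))
  expect_gt(v, 0)
  expect_lt(v, 1)
  expect_error(c0_complexity(numeric(32)), "zero")
})

test_that("Higuchi fractal dimension recovers known limits and is scale invariant", {
  expect_equal(higuchi_fd(as.numeric(1:1000), kmax = 8), 1.0, tolerance = 0.05)
  set.seed(3)
  expect_equal(higuchi_fd(rnorm(4096), kmax = 8), 2.0, tolerance = 0.05)
  set.seed(4)
  x <- rnorm(200)
  expect_equal(higuchi_fd(7.3 * x), higuchi_fd(x))
  expect_error(higuchi_fd(rnorm(50), kmax = 8), "short")
})

test_that("every scalar feature agrees with its naive loop oracle on short series", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(30:64, 1)
    x <- rnorm(n)
    expect_lt(abs(psd_mean(x) - psd_naive(x)), 1e-9)
    expect_lt(max(abs(hjorth(x) - hjorth_naive(x))), 1e-9)
    expect_lt(abs(c0_complexity(x) - c0_naive(x)), 1e-9)
    expect_lt(abs(approximate_entropy(x, 2, 0.2 * sd(x)) -
                    apen_naive(x, 2, 0.2 * sd(x))), 1e-9)
    expect_lt(abs(higuchi_fd(x, kmax = 3) - higuchi_naive(x, 3)), 1e-9)
  }
})

test_that("feature matrix layout matches the channel x band x family design", {
  eeg <- tiny_eeg()
  expect_equal(dim(eeg$data)[2], 19)
  f_psd <- extract_feature_matrix(eeg, families = "PSD")
  expect_equal(ncol(f_psd$values), 95)
  f_hj <- extract_feature_matrix(eeg, families = "Hjorth")
  expect_equal(ncol(f_hj$values), 285)
  f_all <- extract_feature_matrix(eeg)
  expect_equal(ncol(f_all$values), 665)
  expect_true(all(is.finite(f_all$values)))
  expect_false(anyDuplicated(colnames(f_all$values)) > 0)
  expect_identical(f_all$labels, eeg$labels)
  # names are deterministic channel.band.family identifiers
  expect_true("Fp1.alpha.psd" %in% colnames(f_psd$values))
  expect_true(all(c("Cz.beta.hjorth_mobility", "Pz.gamma.hjorth_complexity")
                  %in% colnames(f_hj$values)))
  expect_error(extract_feature_matrix(eeg, families = "nope"), "subset")
})

test_that("degenerate epochs follow the configured error policy", {
  dat <- array(0, c(2, 2, 128))
  dat[, , ] <- 0  # all-zero signal: C0 and FD are undefined
  es <- epoch_set(dat, fs = 256, labels = c(0, 1))
  expect_error(extract_feature_matrix(es, families = "CO"), "zero")
  suppressWarnings(expect_warning(
    f <- extract_feature_matrix(es, families = "CO", on_degenerate = "zero"),
    "degenerate"
  ))
  expect_true(all(f$values == 0))
})

test_that("epoch_set and feature_matrix validate their invariants", {
  expect_error(epoch_set(matrix(0, 2, 2), 256, 0:1), "3-d")
  dat <- array(rnorm(2 * 3 * 64), c(2, 3, 64))
  expect_error(epoch_set(dat, fs = -1, labels = 0:1), "positive")
  expect_error(epoch_set(dat, fs = 256, labels = 0L), "per epoch")
  expect_error(epoch_set(dat, 256, 0:1, channel_names = "one"), "per channel")
  m <- matrix(1:4, 2, 2)
  expect_error(feature_matrix(m, 0:1), "column names")
  colnames(m) <- c("a", "a")
  expect_error(feature_matrix(m, 0:1), "column names")
  colnames(m) <- c("a", "b")
  expect_error(feature_matrix(cbind(m[, 1], c(NA, 1)), 0:1), "column names|finite")
})
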