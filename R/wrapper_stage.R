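#' Accuracy weight of the dimension-aware fitness
#'
#' `phi(d) = (9 + exp(-d/100)) / 10`: the share of the fitness carried by
#' classification accuracy, strictly decreasing from 1 at `d = 0` towards the
#' limit 0.9 as the original feature dimension `d` grows, so dimensionality
#' reduction gains weight (never more than 10%) on high-dimensional problems.
#'
#' @param d original feature dimension, `d >= 0`.
#' @return scalar in `(0.9, 1]`.
#' @export
phi_weight <- function(d) {
  if (any(d < 0)) stop("`d` must be nonnegative")
  (9 + exp(-d / 100)) / 10
}

#' Wrapper-stage fitness configuration
#'
#' @param d_original the original (pre-filter) feature dimension used by
#'   [phi_weight()].
#' @param k_folds inner cross-validation folds for accuracy estimation
#'   (default 3).
#' @param svm_bounds numeric vector `c(C_min, C_max, sigma_min, sigma_max)`
#'   bounding the SVM regularisation constant and Gaussian-kernel bandwidth.
#' @param log_scale if `TRUE`, particle coordinates for (C, sigma) live on a
#'   log10 scale between the bounds.
#' @param selection_threshold mask threshold: a coordinate `>=` this value
#'   selects its feature (default 0.5; the boundary counts as selected).
#' @param empty_mask_policy `"zero"` (empty mask scores fitness 0; default)
#'   or `"error"`.
#' @param fold_seed seed for the stratified inner folds, fixed per fitness
#'   call so the fitness is a deterministic function of the particle.
#' @return an object of class `fitness_config`.
#' @export
fitness_config <- function(d_original,
                           k_folds = 3L,
                           svm_bounds = c(C_min = 0.01, C_max = 100,
                                          sigma_min = 0.01, sigma_max = 100),
                           log_scale = FALSE,
                           selection_threshold = 0.5,
                           empty_mask_policy = c("zero", "error"),
                           fold_seed = 1L) {
  if (d_original < 1) stop("`d_original` must be >= 1")
  if (k_folds < 2L) stop("`k_folds` must be >= 2")
  svm_bounds <- unname(as.numeric(svm_bounds))
  if (length(svm_bounds) != 4L || svm_bounds[1] <= 0 || svm_bounds[3] <= 0 ||
      svm_bounds[1] >= svm_bounds[2] || svm_bounds[3] >= svm_bounds[4]) {
    stop("`svm_bounds` must be c(C_min, C_max, sigma_min, sigma_max) with ",
         "0 < min < max for both parameters")
  }
  structure(list(d_original = as.integer(d_original),
                 k_folds = as.integer(k_folds),
                 svm_bounds = svm_bounds,
                 log_scale = isTRUE(log_scale),
                 selection_threshold = selection_threshold,
                 empty_mask_policy = match.arg(empty_mask_policy),
                 fold_seed = as.integer(fold_seed)),
            class = "fitness_config")
}

#' SVM hyperparameters
#'
#' @param C regularisation constant (> 0).
#' @param sigma Gaussian kernel bandwidth (> 0); the kernel is
#'   `exp(-||x - z||^2 / (2 sigma^2))`.
#' @return an object of class `svm_params`.
#' @export
svm_params <- function(C, sigma) {
  if (C <= 0 || sigma <= 0) stop("`C` and `sigma` must be strictly positive")
  structure(list(C = C, sigma = sigma), class = "svm_params")
}

#' Decode a QPSO particle into a feature mask and SVM parameters
#'
#' The first `n_features` coordinates encode the mask (a coordinate `>= 0.5`
#' selects the feature); the last two are the SVM `C` and `sigma`.
#'
#' @param position numeric vector of length `n_features + 2`.
#' @param n_features number of candidate features.
#' @param config a [fitness_config()] (supplies the threshold and, if
#'   `log_scale`, the back-transform for C and sigma).
#' @return list with `mask` (logical) and `svm` ([svm_params()]).
#' @export
decode_particle <- function(position, n_features, config) {
  if (length(position) != n_features + 2L) {
    stop("position must have length n_features + 2 = ", n_features + 2L)
  }
  mask <- position[seq_len(n_features)] >= config$selection_threshold
  C <- position[n_features + 1L]
  sigma <- position[n_features + 2L]
  if (config$log_scale) {
    C <- 10^C
    sigma <- 10^sigma
  }
  list(mask = mask, svm = svm_params(C, sigma))
}

# Stratified fold assignment: one fold id per sample, every class spread
# across all k folds.
.stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  rng <- .seeded_rng(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop("class ", cl, " has fewer samples (", length(idx),
           ") than folds (", k, ")")
    }
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  rng()
  folds
}

# Evaluate `expr`-style RNG use under a local seed, restoring the global
# RNG state afterwards so fitness calls do not perturb the optimizer stream.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Cross-validated accuracy of a Gaussian-kernel SVM on masked features
#'
#' Mean accuracy over `k` stratified folds. Within each fold the selected
#' feature columns are standardised with statistics fitted on the training
#' portion only, then a soft-margin SVM with kernel
#' `exp(-||x - z||^2 / (2 sigma^2))` is trained and scored on the held-out
#' fold. Deterministic given `seed`.
#'
#' @param F a [feature_matrix()].
#' @param mask logical (or 0/1) vector selecting at least one feature.
#' @param params an [svm_params()].
#' @param k number of folds (default 3).
#' @param seed fold-assignment seed.
#' @return mean held-out accuracy in `[0, 1]`.
#' @export
svm_cv_accuracy <- function(F, mask, params, k = 3L, seed = 1L) {
  stopifnot(inherits(F, "feature_matrix"))
  mask <- as.logical(mask)
  if (length(mask) != ncol(F$values)) stop("`mask` length must match feature count")
  if (!any(mask)) stop("empty mask: no features selected")
  folds <- .stratified_folds(F$labels, k, seed)
  X <- F$values[, mask, drop = FALSE]
  y <- factor(F$labels)
  acc <- numeric(k)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdev[!is.finite(sdev) | sdev == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sdev, "/")
    fit <- e1071::svm(x = Xs[tr, , drop = FALSE], y = y[tr],
                      type = "C-classification", kernel = "radial",
                      cost = params$C, gamma = 1 / (2 * params$sigma^2),
                      scale = FALSE)
    pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
    acc[fold] <- mean(pred == y[!tr])
  }
  mean(acc)
}

#' Dimension-aware wrapper fitness of an encoded particle
#'
#' Decodes the particle, estimates the classification accuracy CA by inner
#' cross-validation, computes the dimension reduction rate
#' `DR = 1 - selected / candidates`, and returns
#' `phi(d_original) * CA + (1 - phi(d_original)) * DR`. An empty mask scores
#' 0 under the default policy.
#'
#' @param position encoded particle (see [decode_particle()]).
#' @param F a [feature_matrix()] of the candidate features.
#' @param config a [fitness_config()].
#' @return fitness in `[0, 1]` (to be maximised).
#' @export
wrapper_fitness <- function(position, F, config) {
  nf <- ncol(F$values)
  dec <- decode_particle(position, nf, config)
  if (!any(dec$mask)) {
    if (config$empty_mask_policy == "error") stop("empty mask")
    return(0)
  }
  CA <- svm_cv_accuracy(F, dec$mask, dec$svm, k = config$k_folds,
                        seed = config$fold_seed)
  DR <- 1 - sum(dec$mask) / nf
  phi <- phi_weight(config$d_original)
  phi * CA + (1 - phi) * DR
}

#' Jointly select features and SVM hyperparameters with QPSO
#'
#' Encodes the feature mask and the SVM (C, sigma) in one particle and
#' maximises the dimension-aware fitness (see [wrapper_fitness()]) with QPSO
#' over the `(n_features + 2)`-dimensional box.
#'
#' @param F a [feature_matrix()] of candidate features (>= 2 features,
#'   >= 2 classes).
#' @param config a [fitness_config()].
#' @param n_particles,t_max QPSO budget (defaults 200/200).
#' @param seed optimizer seed.
#' @return an object of class `selection_result`: logical `mask`, `svm`
#'   parameters, `fitness`, `CA`, `DR`, per-iteration `history`
#'   (non-decreasing), and the kept feature `names`.
#' @export
qpso_select <- function(F, config, n_particles = 200L, t_max = 200L,
                        seed = NULL) {
  stopifnot(inherits(F, "feature_matrix"))
  nf <- ncol(F$values)
  if (nf < 1L) stop("need at least one candidate feature")
  if (length(unique(F$labels)) < 2L) stop("need at least two classes")
  b <- config$svm_bounds
  if (config$log_scale) b <- log10(b)
  bounds <- rbind(matrix(c(0, 1), nf, 2, byrow = TRUE),
                  c(b[1], b[2]),
                  c(b[3], b[4]))
  objective <- function(pos) wrapper_fitness(pos, F, config)
  res <- qpso_optimize(objective, bounds, n_particles = n_particles,
                       t_max = t_max, seed = seed, sense = "maximize")
  dec <- decode_particle(res$best_position, nf, config)
  CA <- if (any(dec$mask)) {
    svm_cv_accuracy(F, dec$mask, dec$svm, k = config$k_folds,
                    seed = config$fold_seed)
  } else {
    0
  }
  DR <- 1 - sum(dec$mask) / nf
  structure(
    list(mask = dec$mask, svm = dec$svm, fitness = res$best_fitness,
         CA = CA, DR = DR, history = res$history,
         names = F$names[dec$mask], d_original = config$d_original),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features selected (DR = %.3f), CA = %.3f, fitness = %.4f\n",
              sum(x$mask), x$DR, x$CA, x$fitness))
  cat(sprintf("  SVM: C = %.4g, sigma = %.4g\n", x$svm$C, x$svm$sigma))
  invisible(x)
}
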