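#' Weighted score of a feature subset
#'
#' Combines classification accuracy and dimension reduction with the
#' dimension-aware weight: `phi(d) * CA + (1 - phi(d)) * DR` (see
#' [phi_weight()]). Both CA and DR are on the `[0, 1]` scale; multiply by 100
#' for a percentage-scale report.
#'
#' @param CA classification accuracy in `[0, 1]`.
#' @param DR dimension reduction rate in `[0, 1]`.
#' @param d original feature dimension.
#' @return scalar in `[0, 1]`.
#' @export
weighted_score <- function(CA, DR, d) {
  if (any(CA < 0 | CA > 1) || any(DR < 0 | DR > 1)) {
    stop("`CA` and `DR` must lie in [0, 1]")
  }
  phi <- phi_weight(d)
  phi * CA + (1 - phi) * DR
}

# Train on the full training portion with the selected mask / parameters and
# score on held-out data. Standardisation statistics come from training only.
.validation_accuracy <- function(F_train, F_val, mask, params) {
  Xtr <- F_train$values[, mask, drop = FALSE]
  Xva <- F_val$values[, mask, drop = FALSE]
  mu <- colMeans(Xtr)
  sdev <- apply(Xtr, 2L, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, mu, "-"), 2L, sdev, "/")
  Xva <- sweep(sweep(Xva, 2L, mu, "-"), 2L, sdev, "/")
  ytr <- factor(F_train$labels)
  fit <- e1071::svm(x = Xtr, y = ytr, type = "C-classification",
                    kernel = "radial", cost = params$C,
                    gamma = 1 / (2 * params$sigma^2), scale = FALSE)
  pred <- stats::predict(fit, Xva)
  mean(as.character(pred) == as.character(F_val$labels))
}

#' Run the full two-stage feature-selection pipeline with outer cross-validation
#'
#' Outer `outer_folds`-fold stratified cross-validation (default 5). Within
#' each outer fold the MIC prefilter and the QPSO wrapper are fit on the
#' training portion only; the selected mask and SVM parameters are then scored
#' once on the held-out fold, so no validation information leaks into feature
#' selection or fitness evaluation. Inner model training uses
#' `k_folds`-fold cross-validation (default 3).
#'
#' @param F a [feature_matrix()].
#' @param outer_folds outer cross-validation folds (default 5).
#' @param stages character subset of `c("prefilter", "select")`; dropping
#'   `"select"` gives a filter-only report.
#' @param t_irr,t_red prefilter thresholds (see [mic_prefilter()]).
#' @param n_particles,t_max QPSO budget for the wrapper stage.
#' @param k_folds inner cross-validation folds.
#' @param d_original dimension fed to [phi_weight()]; defaults to the original
#'   (pre-filter) feature count of `F`.
#' @param seed master seed; outer folds, wrapper optimisation, and inner folds
#'   are all derived from it, so identical configurations reproduce byte-
#'   identical reports.
#' @param refit_prefilter if `TRUE` (default) the prefilter is re-fit on each
#'   outer training fold (leak-free); `FALSE` fits it once on all data, a
#'   compatibility mode.
#' @param mic_cfg a [mic_config()].
#' @return an object of class `miqfs_report`: per-fold results (kept
#'   dimension, selected dimension, validation CA, DR, weighted value, SVM
#'   parameters, removal audit) and their means.
#' @export
run_pipeline <- function(F, outer_folds = 5L,
                         stages = c("prefilter", "select"),
                         t_irr = 0.2, t_red = 0.8,
                         n_particles = 200L, t_max = 200L,
                         k_folds = 3L, d_original = NULL,
                         seed = 1L, refit_prefilter = TRUE,
                         mic_cfg = mic_config()) {
  stopifnot(inherits(F, "feature_matrix"))
  stages <- match.arg(stages, several.ok = TRUE)
  m <- ncol(F$values)
  if (is.null(d_original)) d_original <- m
  folds <- .stratified_folds(F$labels, outer_folds, seed)

  global_pre <- if (!refit_prefilter && "prefilter" %in% stages) {
    mic_prefilter(F, t_irr, t_red, mic_cfg)
  } else {
    NULL
  }

  fold_results <- vector("list", outer_folds)
  for (fold in seq_len(outer_folds)) {
    tr <- folds != fold
    F_train <- feature_matrix(F$values[tr, , drop = FALSE], F$labels[tr])
    F_val <- feature_matrix(F$values[!tr, , drop = FALSE], F$labels[!tr])

    if ("prefilter" %in% stages) {
      pre <- if (refit_prefilter) {
        mic_prefilter(F_train, t_irr, t_red, mic_cfg)
      } else {
        global_pre
      }
      kept <- pre$kept
    } else {
      pre <- NULL
      kept <- seq_len(m)
    }

    entry <- list(
      fold = fold,
      kept = kept,
      kept_dim = length(kept),
      prefilter = if (is.null(pre)) NULL else list(
        relevance = unname(pre$relevance),
        removed_irrelevant = pre$removed_irrelevant,
        removed_redundant = pre$removed_redundant,
        thresholds = pre$thresholds
      )
    )

    if ("select" %in% stages) {
      Ftr_kept <- feature_matrix(F_train$values[, kept, drop = FALSE],
                                 F_train$labels)
      Fva_kept <- feature_matrix(F_val$values[, kept, drop = FALSE],
                                 F_val$labels)
      cfg <- fitness_config(d_original = d_original, k_folds = k_folds,
                            fold_seed = seed + fold)
      sel <- qpso_select(Ftr_kept, cfg, n_particles = n_particles,
                         t_max = t_max, seed = seed * 1000L + fold)
      if (!any(sel$mask)) stop("wrapper stage selected no features in fold ", fold)
      val_ca <- .validation_accuracy(Ftr_kept, Fva_kept, sel$mask, sel$svm)
      DR <- 1 - sum(sel$mask) / length(kept)
      entry <- c(entry, list(
        selected = kept[sel$mask],
        selected_names = sel$names,
        selected_dim = sum(sel$mask),
        svm = c(C = sel$svm$C, sigma = sel$svm$sigma),
        fitness = sel$fitness,
        validation_CA = val_ca,
        DR = DR,
        weighted_value = weighted_score(val_ca, DR, d_original)
      ))
    }
    fold_results[[fold]] <- entry
  }

  means <- list(kept_dim = mean(vapply(fold_results, `[[`, 1, "kept_dim")))
  if ("select" %in% stages) {
    for (f in c("selected_dim", "validation_CA", "DR", "weighted_value")) {
      means[[f]] <- mean(vapply(fold_results, `[[`, 1, f))
    }
  }
  structure(
    list(folds = fold_results, means = means,
         config = list(outer_folds = outer_folds, stages = stages,
                       t_irr = t_irr, t_red = t_red,
                       n_particles = n_particles, t_max = t_max,
                       k_folds = k_folds, d_original = d_original,
                       seed = seed, refit_prefilter = refit_prefilter)),
    class = "miqfs_report"
  )
}

#' @export
print.miqfs_report <- function(x, ...) {
  cat(sprintf("<miqfs_report> %d outer folds, stages: %s\n",
              x$config$outer_folds, paste(x$config$stages, collapse = " + ")))
  cat(sprintf("  mean kept dimension after prefilter: %.1f\n", x$means$kept_dim))
  if (!is.null(x$means$validation_CA)) {
    cat(sprintf("  mean selected dimension: %.1f\n", x$means$selected_dim))
    cat(sprintf("  mean validation CA: %.4f   mean DR: %.4f   mean weighted value: %.4f\n",
                x$means$validation_CA, x$means$DR, x$means$weighted_value))
  }
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' @param report a `miqfs_report` from [run_pipeline()].
#' @param path output JSON file.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "miqfs_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
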