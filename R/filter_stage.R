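#' MIC-based feature pre-selection
#'
#' Two-rule filter. Relevance rule: features whose MIC with the class label is
#' strictly below `t_irr` are removed as irrelevant. Redundancy rule: among
#' the survivors, any pair with pairwise MIC strictly above `t_red` is
#' redundant and the member with the smaller label-relevance is dropped.
#' Redundancy chains are resolved by a greedy sweep in descending relevance
#' order: each accepted feature eliminates all not-yet-accepted features whose
#' MIC with it exceeds `t_red`, so the most relevant representative of every
#' redundancy group survives. Exact relevance ties are broken towards the
#' lower column index.
#'
#' @param F a [feature_matrix()].
#' @param t_irr irrelevance threshold in `[0, 1)`; default 0.2.
#' @param t_red redundancy threshold in `(0, 1]`; default 0.8.
#' @param config a [mic_config()] used for every MIC evaluation.
#' @return an object of class `prefilter_result` with fields `kept` (indices
#'   sorted by descending relevance), `relevance` (per original feature),
#'   `removed_irrelevant`, `removed_redundant` (two-column matrix: dropped
#'   index, kept partner), and `thresholds`.
#' @export
mic_prefilter <- function(F, t_irr = 0.2, t_red = 0.8, config = mic_config()) {
  stopifnot(inherits(F, "feature_matrix"))
  if (t_irr < 0 || t_irr >= 1) stop("`t_irr` must lie in [0, 1)")
  if (t_red <= 0 || t_red > 1) stop("`t_red` must lie in (0, 1]")
  m <- ncol(F$values)
  relevance <- relevance_scores(F, config)

  removed_irrelevant <- which(relevance < t_irr)
  candidates <- setdiff(seq_len(m), removed_irrelevant)
  if (length(candidates) == 0L) {
    stop("all ", m, " features fall below the irrelevance threshold ",
         t_irr, "; relax `t_irr` to keep any features")
  }

  # greedy sweep in descending relevance (ties: lower index first)
  ord <- candidates[order(-relevance[candidates], candidates)]
  accepted <- integer(0)
  dropped <- integer(0)
  partner <- integer(0)
  for (j in ord) {
    redundant_with <- NA_integer_
    for (a in accepted) {
      pm <- compute_mic(F$values[, j], F$values[, a], config)$value
      if (pm > t_red) { redundant_with <- a; break }
    }
    if (is.na(redundant_with)) {
      accepted <- c(accepted, j)
    } else {
      dropped <- c(dropped, j)
      partner <- c(partner, redundant_with)
    }
  }
  if (length(accepted) == 0L) {
    stop("all surviving features were removed as redundant; relax `t_red`")
  }
  structure(
    list(kept = accepted,
         relevance = relevance,
         removed_irrelevant = removed_irrelevant,
         removed_redundant = cbind(dropped = dropped, kept_partner = partner),
         thresholds = c(t_irr = t_irr, t_red = t_red)),
    class = "prefilter_result"
  )
}

#' @export
print.prefilter_result <- function(x, ...) {
  m <- length(x$relevance)
  cat(sprintf("<prefilter_result> kept %d / %d features (thresholds: irrelevant < %g, redundant > %g)\n",
              length(x$kept), m, x$thresholds["t_irr"], x$thresholds["t_red"]))
  cat(sprintf("  removed: %d irrelevant, %d redundant\n",
              length(x$removed_irrelevant), nrow(x$removed_redundant)))
  invisible(x)
}

#' Restrict a feature matrix to the features kept by a prefilter
#'
#' @param F a [feature_matrix()].
#' @param result a `prefilter_result` from [mic_prefilter()] (or an integer
#'   vector of column indices).
#' @return a [feature_matrix()] with the kept columns, in kept order.
#' @export
apply_prefilter <- function(F, result) {
  stopifnot(inherits(F, "feature_matrix"))
  kept <- if (inherits(result, "prefilter_result")) result$kept else as.integer(result)
  feature_matrix(F$values[, kept, drop = FALSE], F$labels)
}
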