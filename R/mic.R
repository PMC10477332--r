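#' Configuration for the MIC estimator
#'
#' The maximal information coefficient searches over grid partitions whose
#' cell count `X * Y` is below a budget `B = n^B_exponent`. The default
#' exponent 0.6 follows the original MINE recommendation. A 2x2 grid is always
#' admitted so that tiny samples still get a meaningful score.
#'
#' @param B_exponent grid budget exponent in (0, 1); `B = floor(n^B_exponent)`.
#' @param estimator `"dp_approx"` (equipartition one axis, dynamic-programming
#'   optimisation of the other, both orientations; default) or
#'   `"exhaustive"` (exact enumeration, only feasible for `n <= 14`).
#' @param clump_factor superclump factor: the number of candidate cut points
#'   on the optimised axis is capped at `clump_factor * max_columns`.
#' @return an object of class `mic_config`.
#' @export
mic_config <- function(B_exponent = 0.6,
                       estimator = c("dp_approx", "exhaustive"),
                       clump_factor = 15L) {
  if (!is.numeric(B_exponent) || B_exponent <= 0 || B_exponent >= 1) {
    stop("`B_exponent` must lie strictly between 0 and 1")
  }
  estimator <- match.arg(estimator)
  if (clump_factor < 1) stop("`clump_factor` must be >= 1")
  structure(list(B_exponent = B_exponent, estimator = estimator,
                 clump_factor = as.integer(clump_factor)),
            class = "mic_config")
}

# x * log2(x) with the 0 log 0 = 0 convention.
.xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# Equipartition sorted values into at most q bins without splitting ties.
# Returns an integer bin id per element of `v` (original order).
.equipartition_bins <- function(v, q) {
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]
  # run lengths of tied groups in sorted order
  grp_len <- rle(vs)$lengths
  G <- length(grp_len)
  bins_per_group <- integer(G)
  assigned <- 0L
  row <- 1L
  cursize <- 0L
  for (g in seq_len(G)) {
    bins_per_group[g] <- row
    cursize <- cursize + grp_len[g]
    assigned <- assigned + grp_len[g]
    remaining_rows <- q - row + 1L
    # desired share of the points not yet committed to closed rows
    desired <- (n - assigned + cursize) / remaining_rows
    if (cursize >= desired && row < q && g < G) {
      row <- row + 1L
      cursize <- 0L
    }
  }
  bin_sorted <- rep.int(bins_per_group, grp_len)
  bins <- integer(n)
  bins[ord] <- bin_sorted
  bins
}

# Candidate cut structure on the optimised axis: clumps are maximal runs of
# equal x values in sorted order (cuts never split ties); if there are more
# clumps than `khat`, they are merged into ~khat superclumps by count
# equipartition. Returns cumulative per-row counts at each clump boundary.
.clump_cumulants <- function(x, rowbin, q, khat) {
  ord <- order(x)
  xs <- x[ord]
  rows <- rowbin[ord]
  lens <- rle(xs)$lengths
  G <- length(lens)
  clump_id <- rep.int(seq_len(G), lens)
  if (G > khat) {
    # merge clumps into superclumps of roughly equal point counts
    csum <- cumsum(lens)
    n <- length(x)
    super <- integer(G)
    row <- 1L
    assigned <- 0L
    cursize <- 0L
    for (g in seq_len(G)) {
      super[g] <- row
      cursize <- cursize + lens[g]
      assigned <- assigned + lens[g]
      remaining <- khat - row + 1L
      if (cursize >= (n - assigned + cursize) / remaining && row < khat && g < G) {
        row <- row + 1L
        cursize <- 0L
      }
    }
    clump_id <- super[clump_id]
    G <- max(clump_id)
  }
  # counts per (clump, row)
  tab <- matrix(0L, G, q)
  for (i in seq_along(rows)) {
    tab[clump_id[i], rows[i]] <- tab[clump_id[i], rows[i]] + 1L
  }
  cumR <- rbind(0L, apply(tab, 2L, cumsum))       # (G+1) x q
  list(cumR = cumR, cumN = c(0L, cumsum(rowSums(tab))), G = G)
}

# Dynamic program: for a fixed row partition (q rows), find for each column
# count l = 2..kmax the maximum of H(cols) - H(cols, rows) over column
# partitions at clump boundaries. Additive column weights make this a classic
# segmentation DP. Returns max mutual information per l (vector length kmax).
.optimize_axis <- function(cums, q, kmax, n) {
  G <- cums$G
  cumR <- cums$cumR
  cumN <- cums$cumN
  # row-marginal entropy
  p <- cumR[G + 1L, ] / n
  Hq <- -sum(.xlog2x(p))
  if (G < 2L) return(rep(NA_real_, kmax))
  # weight of a column spanning clump boundaries (s, t], 0 <= s < t <= G:
  # w = (sum_r rr*log2(rr) - cnt*log2(cnt)) / n
  W <- matrix(-Inf, G + 1L, G + 1L)  # [s+1, t+1]
  for (t in seq_len(G)) {
    s <- 0:(t - 1L)
    cnt <- cumN[t + 1L] - cumN[s + 1L]
    rr <- matrix(cumR[t + 1L, ], t, q, byrow = TRUE) - cumR[s + 1L, , drop = FALSE]
    term <- rowSums(matrix(.xlog2x(rr), t, q)) - .xlog2x(cnt)
    W[s + 1L, t + 1L] <- term / n
  }
  kk <- min(kmax, G)
  # F[t, l]: best sum of weights partitioning clumps 1..t into l columns
  Fm <- matrix(-Inf, G, kk)
  Fm[, 1L] <- W[1L, 2L:(G + 1L)]
  if (kk >= 2L) {
    for (l in 2L:kk) {
      for (t in l:G) {
        s <- (l - 1L):(t - 1L)
        Fm[t, l] <- max(Fm[s, l - 1L] + W[s + 1L, t + 1L])
      }
    }
  }
  best <- rep(NA_real_, kmax)
  run <- -Inf
  for (l in seq_len(kk)) {
    run <- max(run, Fm[G, l])   # grids with <= l columns
    best[l] <- Hq + run
  }
  if (kk < kmax) best[(kk + 1L):kmax] <- best[kk]
  best
}

# One orientation: rows are an equipartition of `yv`, columns optimised on
# `xv`. Returns the best normalised MI with its grid and raw MI.
.mic_orientation <- function(xv, yv, B, clump_factor) {
  n <- length(xv)
  best <- list(value = 0, grid = c(2L, 2L), mi = 0)
  q_max <- max(2L, floor(B / 2))
  for (q in 2L:q_max) {
    kmax <- floor((B - 1) / q)
    if (q == 2L) kmax <- max(kmax, 2L)  # the 2x2 grid is always admitted
    if (kmax < 2L) next
    rowbin <- .equipartition_bins(yv, q)
    q_eff <- max(rowbin)
    if (q_eff < 2L) next
    cums <- .clump_cumulants(xv, rowbin, q_eff, khat = clump_factor * kmax)
    mi <- .optimize_axis(cums, q_eff, kmax, n)
    for (l in 2L:kmax) {
      if (!is.finite(mi[l])) next
      if (l * q >= B && !(l == 2L && q == 2L)) next
      norm <- mi[l] / log2(min(l, q_eff))
      if (norm > best$value) {
        best <- list(value = norm, grid = c(l, q_eff), mi = mi[l])
      }
    }
  }
  best
}

#' Maximal information coefficient of two sequences
#'
#' Estimates MIC: the maximum over grid partitions (with `X * Y < B` cells,
#' `B = floor(n^0.6)` by default) of the grid mutual information normalised by
#' `log2(min(X, Y))`. The search follows the MINE approximation: one axis is
#' equipartitioned, the other optimised by dynamic programming over
#' tie-respecting cut points, and both orientations are searched, which makes
#' the estimate exactly symmetric in `x` and `y`.
#'
#' @param x,y numeric vectors of equal length `n >= 8`.
#' @param config a [mic_config()].
#' @return an object of class `mic_result`: `value` in `[0, 1]`, `best_grid`
#'   (columns, rows), `mutual_information` in bits, and `degenerate`
#'   (`TRUE` when an axis is constant, forcing value 0).
#' @export
compute_mic <- function(x, y, config = mic_config()) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 8L) stop("need at least 8 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  B <- max(floor(n^config$B_exponent), 4L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(structure(list(value = 0, best_grid = c(NA_integer_, NA_integer_),
                          mutual_information = 0, degenerate = TRUE, B = B),
                     class = "mic_result"))
  }
  if (config$estimator == "exhaustive") {
    val <- mic_exhaustive(x, y, B)
    return(structure(list(value = val, best_grid = c(NA_integer_, NA_integer_),
                          mutual_information = NA_real_, degenerate = FALSE,
                          B = B),
                     class = "mic_result"))
  }
  o1 <- .mic_orientation(x, y, B, config$clump_factor)
  o2 <- .mic_orientation(y, x, B, config$clump_factor)
  best <- if (o2$value > o1$value) {
    list(value = o2$value, grid = rev(o2$grid), mi = o2$mi)
  } else {
    o1
  }
  structure(list(value = min(max(best$value, 0), 1),
                 best_grid = best$grid,
                 mutual_information = best$mi,
                 degenerate = FALSE, B = B),
            class = "mic_result")
}

#' @export
print.mic_result <- function(x, ...) {
  cat(sprintf("<mic_result> value = %.6f (grid %s x %s, MI = %.4f bits)%s\n",
              x$value, x$best_grid[1], x$best_grid[2], x$mutual_information,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Mutual information in bits of a contingency table.
.table_mi <- function(tab) {
  n <- sum(tab)
  pj <- .xlog2x(tab / n)
  px <- .xlog2x(rowSums(tab) / n)
  py <- .xlog2x(colSums(tab) / n)
  sum(pj) - sum(px) - sum(py)
}

#' Exact MIC by exhaustive partition enumeration (testing oracle)
#'
#' Enumerates every pair of axis partitions with cut points between distinct
#' sorted values and cell count within the budget (`X * Y < B`, with the 2x2
#' grid always admitted), and returns the exact maximum normalised mutual
#' information. Exponential cost: only allowed for `n <= 14`.
#'
#' @param x,y numeric vectors of equal length `n <= 14`.
#' @param B grid cell budget (default `floor(n^0.6)`).
#' @return exact MIC value in `[0, 1]`.
#' @export
mic_exhaustive <- function(x, y, B = NULL) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n > 14L) stop("exhaustive enumeration only supported for n <= 14")
  if (is.null(B)) B <- max(floor(n^0.6), 4L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(0)

  gaps <- function(v) {
    vs <- sort(unique(v))
    (vs[-1] + vs[-length(vs)]) / 2  # one candidate cut between distinct values
  }
  gx <- gaps(x)
  gy <- gaps(y)

  partitions <- function(g, k) {
    # all ways to choose k-1 cut points -> list of bin-assignment functions
    if (k - 1L > length(g)) return(list())
    ch <- utils::combn(length(g), k - 1L, simplify = FALSE)
    lapply(ch, function(ii) g[ii])
  }

  best <- 0
  kx_max <- min(length(gx) + 1L, max(2L, floor((B - 1) / 2)))
  for (kx in 2L:max(2L, kx_max)) {
    cutx_sets <- partitions(gx, kx)
    if (length(cutx_sets) == 0L) next
    ky_hi <- floor((B - 1) / kx)
    if (kx == 2L) ky_hi <- max(ky_hi, 2L)
    if (ky_hi < 2L) next
    for (ky in 2L:ky_hi) {
      if (kx * ky >= B && !(kx == 2L && ky == 2L)) next
      cuty_sets <- partitions(gy, ky)
      if (length(cuty_sets) == 0L) next
      for (cx in cutx_sets) {
        bx <- findInterval(x, cx)
        for (cy in cuty_sets) {
          by <- findInterval(y, cy)
          tab <- table(bx, by)
          val <- .table_mi(tab) / log2(min(kx, ky))
          if (val > best) best <- val
        }
      }
    }
  }
  min(max(best, 0), 1)
}

#' MIC relevance of every feature against the class label
#'
#' @param F a [feature_matrix()] with at least two classes.
#' @param config a [mic_config()].
#' @return numeric vector, one MIC value per feature column (order preserved,
#'   named by feature).
#' @export
relevance_scores <- function(F, config = mic_config()) {
  stopifnot(inherits(F, "feature_matrix"))
  if (length(unique(F$labels)) < 2L) {
    stop("labels contain a single class; relevance is undefined")
  }
  y <- as.numeric(F$labels)
  vapply(seq_len(ncol(F$values)),
         function(j) compute_mic(F$values[, j], y, config)$value,
         numeric(1), USE.NAMES = FALSE) -> scores
  names(scores) <- F$names
  scores
}
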