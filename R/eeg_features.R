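#' Standard 19-channel montage labels (international 10-20 system)
#'
#' Channel labels used by default for 19-channel epoch sets.
#' @export
eeg_channels_1020 <- c("Fp1", "F3", "C3", "P3", "O1", "F7", "T3", "T5", "Fz",
                       "Fp2", "F4", "C4", "P4", "O2", "F8", "T4", "T6", "Cz",
                       "Pz")

.eeg_bands <- c("delta", "theta", "alpha", "beta", "gamma")

#' Construct a set of multichannel EEG epochs
#'
#' An `epoch_set` holds segmented multichannel recordings: a 3-d numeric
#' array of epochs x channels x samples, the sampling rate, one integer class
#' label per epoch, and channel names.
#'
#' @param data numeric array, `n_epochs x n_channels x n_samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param labels integer class label per epoch (`length(labels) == dim(data)[1]`).
#' @param channel_names character vector, one name per channel. Defaults to
#'   the 10-20 montage for 19 channels, `Ch1..ChK` otherwise.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, labels, channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (epochs x channels x samples)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar (Hz)")
  }
  if (length(labels) != dim(data)[1L]) {
    stop("`labels` must have one entry per epoch")
  }
  n_ch <- dim(data)[2L]
  if (is.null(channel_names)) {
    channel_names <- if (n_ch == 19L) eeg_channels_1020 else paste0("Ch", seq_len(n_ch))
  }
  if (length(channel_names) != n_ch) {
    stop("`channel_names` must have one entry per channel")
  }
  structure(
    list(data = data, fs = fs, labels = as.integer(labels),
         channel_names = as.character(channel_names)),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  classes:", paste(sprintf("%s (n=%d)", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Decompose an epoch into the five clinical EEG bands
#'
#' Applies a six-level discrete wavelet transform (default `db4`) and
#' reconstructs one time series per band from masked coefficient sets. At the
#' standard 256 Hz sampling rate the dyadic detail levels line up with the
#' clinical bands: gamma = D2 (32-64 Hz), beta = D3 (16-32 Hz),
#' alpha = D4 (8-16 Hz), theta = D5 (4-8 Hz), delta = D6 + A6 (0-4 Hz).
#' The five reconstructions are an exact additive decomposition of the input:
#' their sum equals `x` to machine precision.
#'
#' Signals whose length is not a multiple of `2^6` are zero-padded to the next
#' multiple for the transform and the reconstructions are truncated back, so
#' the additive property is preserved at any length `>= 64`.
#'
#' @param x numeric vector, one single-channel epoch (length >= 64).
#' @param fs sampling rate in Hz. The band labels assume 256 Hz; a different
#'   rate is accepted (the dyadic split still applies) but shifts the
#'   physical band edges proportionally.
#' @param wavelet mother wavelet, one of `"db2"`, `"db4"`, `"db8"` (default).
#'   The longer `db8` filter keeps at least 90% of a band-centred sinusoid's
#'   energy inside its own band; shorter filters leak noticeably more into
#'   neighbouring bands.
#' @return named list of five numeric vectors (`delta`, `theta`, `alpha`,
#'   `beta`, `gamma`), each of `length(x)`.
#' @export
decompose_bands <- function(x, fs = 256, wavelet = "db8") {
  levels <- 6L
  min_len <- 2L^levels
  if (length(x) < min_len) {
    stop("epoch too short for a ", levels, "-level decomposition: need at least ",
         min_len, " samples, got ", length(x))
  }
  if (!all(is.finite(x))) stop("epoch contains non-finite values")
  n <- length(x)
  pad <- (min_len - n %% min_len) %% min_len
  xp <- if (pad > 0L) c(x, numeric(pad)) else x
  dec <- .dwt_decompose(xp, levels, wavelet)
  keep_sets <- list(
    delta = c("d6", "a"),
    theta = "d5",
    alpha = "d4",
    beta  = "d3",
    gamma = "d2"
  )
  # D1 (64-128 Hz at fs = 256) lies above the gamma band of interest; it is
  # folded into gamma so the five bands remain an exact partition of the
  # signal.
  keep_sets$gamma <- c("d1", "d2")
  lapply(keep_sets, function(keep) .dwt_band_reconstruct(dec, keep)[seq_len(n)])
}

#' Approximate entropy of a time series
#'
#' Regularity statistic from template matching: embed the series at dimension
#' `m`, count template pairs whose Chebyshev distance is within tolerance `r`
#' (self-matches included), and return `Phi^m(r) - Phi^(m+1)(r)` with the
#' standard `N - m + 1` template-count normalisation and natural logarithms.
#'
#' @param x numeric vector, length > `m + 1`.
#' @param m embedding dimension (default 2).
#' @param r tolerance; if `NULL` (default) it is set to `0.2 * sd(x)`.
#' @return a single finite number (0 for perfectly regular series).
#' @export
approximate_entropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  m <- as.integer(m)
  if (n < m + 2L) stop("series too short: need length > m + 1")
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (!is.finite(r) || r <= 0) {
    # a constant series yields sd 0; all template distances are 0 <= any r,
    # so the entropy is exactly 0 for every positive tolerance
    if (isTRUE(stats::sd(x) == 0)) return(0)
    stop("tolerance `r` must be positive")
  }
  phis <- apen_phis_cpp(as.numeric(x), m, r)
  phis[1L] - phis[2L]
}

#' Mean power spectral density of a series
#'
#' Periodogram-style summary: `(1/N) * sum(|DFT(x)|^2)` with the
#' unnormalised DFT, which by Parseval's theorem equals `sum(x^2)`.
#'
#' @param x nonempty numeric vector.
#' @return nonnegative scalar.
#' @export
psd_mean <- function(x) {
  if (length(x) == 0L) stop("empty series")
  X <- stats::fft(x)
  sum(Mod(X)^2) / length(x)
}

#' Hjorth parameters of a series
#'
#' Activity is the population variance of the signal. Mobility and complexity
#' are computed from the spectral moments, i.e. the mean squares of the first
#' and second difference signals: `mobility = sqrt(mean(dx^2) / activity)` and
#' `complexity = mobility(dx) / mobility(x)` with
#' `mobility(dx) = sqrt(mean(ddx^2) / mean(dx^2))`.
#'
#' @param x numeric vector, length >= 3.
#' @param which which parameters to return (default all three).
#' @return named numeric vector with the requested parameters. For a constant
#'   series the activity is 0; requesting mobility or complexity on a constant
#'   series raises a degenerate-signal error.
#' @export
hjorth <- function(x, which = c("activity", "mobility", "complexity")) {
  if (length(x) < 3L) stop("series too short: need length >= 3")
  which <- match.arg(which, several.ok = TRUE)
  n <- length(x)
  activity <- sum((x - mean(x))^2) / n
  out <- c(activity = activity)
  if (any(c("mobility", "complexity") %in% which)) {
    if (activity == 0) {
      stop("degenerate signal: constant series has zero activity, ",
           "mobility and complexity are undefined")
    }
    dx <- diff(x)
    ddx <- diff(dx)
    m2 <- mean(dx^2)
    m4 <- mean(ddx^2)
    mobility <- sqrt(m2 / activity)
    out <- c(out, mobility = mobility,
             complexity = (sqrt(m4 / m2) / mobility))
  }
  out[which]
}

#' C0 complexity of a series
#'
#' Fraction of signal energy not carried by the dominant spectral components.
#' Spectrum bins whose power is at or below the mean bin power are zeroed; the
#' kept spectrum is inverted to give the "regular" part `y`, and the statistic
#' is `sum(|x - y|^2) / sum(|x|^2)`, a value in `[0, 1]`.
#'
#' @param x nonempty numeric vector, not identically zero.
#' @return scalar in `[0, 1]`.
#' @export
c0_complexity <- function(x) {
  if (length(x) == 0L) stop("empty series")
  denom <- sum(x^2)
  if (denom == 0) stop("all-zero series: C0 complexity undefined (zero energy)")
  X <- stats::fft(x)
  pw <- Mod(X)^2
  M <- mean(pw)
  Y <- ifelse(pw > M, X, 0 + 0i)
  y <- Re(stats::fft(Y, inverse = TRUE)) / length(x)
  val <- sum((x - y)^2) / denom
  min(max(val, 0), 1)
}

#' Higuchi fractal dimension of a series
#'
#' Standard Higuchi curve-length method: for each scale `T = 1..kmax` and
#' offset `tau = 1..T`, the normalised curve length is
#' `L_tau(T) = (sum |x(tau + iT) - x(tau + (i-1)T)|) * (N - 1) / (M * T^2)`
#' with `M = floor((N - tau)/T)`; `L(T)` averages over offsets, and the
#' fractal dimension is the least-squares slope of `ln L(T)` against
#' `ln(1/T)`.
#'
#' @param x numeric vector, `length(x) >= 10 * kmax`.
#' @param kmax largest scale (default 8).
#' @return scalar, about 1 for smooth curves up to 2 for white noise.
#' @export
higuchi_fd <- function(x, kmax = 8L) {
  n <- length(x)
  kmax <- as.integer(kmax)
  if (kmax < 2L) stop("`kmax` must be >= 2")
  if (n < 10L * kmax) {
    stop("series too short for kmax = ", kmax, ": need length >= ", 10L * kmax)
  }
  LT <- numeric(kmax)
  for (T in seq_len(kmax)) {
    Ltau <- numeric(T)
    for (tau in seq_len(T)) {
      M <- (n - tau) %/% T
      if (M < 1L) { Ltau[tau] <- NA_real_; next }
      idx <- tau + (0:M) * T
      Ltau[tau] <- sum(abs(diff(x[idx]))) * (n - 1) / (M * T^2)
    }
    LT[T] <- mean(Ltau, na.rm = TRUE)
  }
  ok <- is.finite(log(LT))
  if (sum(ok) < 2L) stop("degenerate signal: curve lengths are zero")
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[ok])),
                       log(LT[ok]))
  unname(fit$coefficients[2L])
}

.feature_families <- c("CO", "ApEn", "FD", "Hjorth", "PSD")

.family_colnames <- function(family) {
  switch(family,
    CO = "c0",
    ApEn = "apen",
    FD = "fd",
    Hjorth = c("hjorth_activity", "hjorth_mobility", "hjorth_complexity"),
    PSD = "psd"
  )
}

.family_values <- function(family, band_x, params) {
  switch(family,
    CO = c0_complexity(band_x),
    ApEn = approximate_entropy(band_x, m = params$apen_m, r = params$apen_r),
    FD = higuchi_fd(band_x, kmax = params$fd_kmax),
    Hjorth = unname(hjorth(band_x)),
    PSD = psd_mean(band_x)
  )
}

#' Construct a labelled feature matrix
#'
#' @param values numeric matrix, samples x features, with unique column names.
#' @param labels integer class label per row.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop("`values` must have unique column names")
  }
  if (!all(is.finite(values))) stop("feature values must be finite")
  if (length(labels) != nrow(values)) {
    stop("`labels` must have one entry per row of `values`")
  }
  structure(list(values = values, names = colnames(values),
                 labels = as.integer(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tb <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  df <- as.data.frame(x$values)
  df$label <- x$labels
  df
}

#' Extract the band-by-family EEG feature matrix from an epoch set
#'
#' Each channel of each epoch is decomposed into the five clinical bands
#' (see [decompose_bands()]) and each band series is summarised by the
#' requested feature families. Scalar families (CO, ApEn, FD, PSD) contribute
#' one column per channel x band; Hjorth contributes three. For a 19-channel
#' montage that gives 95 columns per scalar family, 285 for Hjorth and 665
#' for the full five-family fusion.
#'
#' @param epochs an [epoch_set()].
#' @param families character subset of `c("CO","ApEn","FD","Hjorth","PSD")`
#'   (case-insensitive); default all five.
#' @param wavelet mother wavelet for the band decomposition.
#' @param apen_m,apen_r approximate-entropy embedding dimension and tolerance
#'   (`NULL` tolerance means `0.2 * sd` per band series).
#' @param fd_kmax largest Higuchi scale.
#' @param on_degenerate what to do when a band series is degenerate (constant)
#'   so a feature is undefined: `"error"` (default) or `"zero"` (fill 0 with a
#'   warning).
#' @return a [feature_matrix()] with deterministic column names
#'   `channel.band.family` and the epoch labels.
#' @export
extract_feature_matrix <- function(epochs,
                                   families = .feature_families,
                                   wavelet = "db8",
                                   apen_m = 2L, apen_r = NULL,
                                   fd_kmax = 8L,
                                   on_degenerate = c("error", "zero")) {
  stopifnot(inherits(epochs, "epoch_set"))
  on_degenerate <- match.arg(on_degenerate)
  idx <- match(toupper(families), toupper(.feature_families))
  if (anyNA(idx) || length(idx) == 0L) {
    stop("`families` must be a nonempty subset of: ",
         paste(.feature_families, collapse = ", "))
  }
  families <- .feature_families[idx]
  params <- list(apen_m = apen_m, apen_r = apen_r, fd_kmax = fd_kmax)

  n_ep <- dim(epochs$data)[1L]
  n_ch <- dim(epochs$data)[2L]
  col_names <- unlist(lapply(families, function(fam) {
    unlist(lapply(epochs$channel_names, function(ch) {
      paste(ch, .eeg_bands, rep(.family_colnames(fam),
                                each = length(.eeg_bands)), sep = ".")
    }))
  }))
  values <- matrix(NA_real_, n_ep, length(col_names),
                   dimnames = list(NULL, col_names))

  fam_width <- vapply(families, function(f) length(.family_colnames(f)), 1L)
  fam_offset <- c(0L, cumsum(fam_width * n_ch * length(.eeg_bands)))[seq_along(families)]

  for (e in seq_len(n_ep)) {
    for (ch in seq_len(n_ch)) {
      bands <- decompose_bands(epochs$data[e, ch, ], fs = epochs$fs,
                               wavelet = wavelet)
      for (fi in seq_along(families)) {
        fam <- families[fi]
        w <- fam_width[fi]
        for (bi in seq_along(.eeg_bands)) {
          vals <- tryCatch(
            .family_values(fam, bands[[bi]], params),
            error = function(err) {
              if (on_degenerate == "zero") {
                warning("degenerate band series (epoch ", e, ", channel ",
                        epochs$channel_names[ch], ", ", .eeg_bands[bi],
                        "): filling ", fam, " with 0", call. = FALSE)
                rep(0, w)
              } else {
                stop(err)
              }
            }
          )
          cols <- fam_offset[fi] + (ch - 1L) * length(.eeg_bands) * w +
            (seq_len(w) - 1L) * length(.eeg_bands) + bi
          values[e, cols] <- vals
        }
      }
    }
  }
  feature_matrix(values, epochs$labels)
}
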