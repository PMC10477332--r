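#' Generate a feature table with planted relevant / redundant / irrelevant structure
#'
#' Relevant columns are class-conditional Gaussians whose class means differ by
#' `class_gap` standard deviations. Redundant columns are strictly monotone
#' transforms (alternating cube and scaled-exponential) of a relevant parent
#' plus a small amount of noise; parents are assigned round-robin so clones
#' spread over distinct parents. Irrelevant columns are independent standard
#' normals. Planted guarantees are verified at generation with bounded
#' redraws: each redundant column has pairwise MIC with its parent above 0.8,
#' each irrelevant column has MIC with the label below 0.2, and each relevant
#' column has MIC with the label of at least 0.25 (a margin above the 0.2
#' irrelevance threshold, so planted-relevant features are guaranteed to
#' survive the default filter).
#'
#' @param n_samples number of rows (labels are balanced 0/1).
#' @param n_relevant number of planted relevant columns (>= 1).
#' @param n_redundant number of monotone-transformed clones.
#' @param n_irrelevant number of independent noise columns.
#' @param class_gap between-class mean shift in SD units (> 0).
#' @param seed integer seed; the table is a pure function of the spec + seed.
#' @param max_retries bounded redraw/recalibration attempts per column.
#' @return list with `features` (a [feature_matrix()]), `roles` (character
#'   per column: relevant/redundant/irrelevant), and `parents` (for redundant
#'   columns, the parent column index; NA otherwise).
#' @export
gen_feature_table <- function(n_samples = 300L, n_relevant = 5L,
                              n_redundant = 3L, n_irrelevant = 12L,
                              class_gap = 2.0, seed = 1L,
                              max_retries = 10L) {
  if (n_relevant < 1L) stop("`n_relevant` must be >= 1")
  if (n_redundant < 0L || n_irrelevant < 0L) stop("counts must be >= 0")
  if (class_gap <= 0) stop("`class_gap` must be positive")
  set.seed(seed)
  n0 <- n_samples %/% 2L
  y <- c(rep(0L, n0), rep(1L, n_samples - n0))
  yn <- as.numeric(y)
  cfg <- mic_config()

  rel <- matrix(NA_real_, n_samples, n_relevant)
  for (j in seq_len(n_relevant)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      col <- stats::rnorm(n_samples) + class_gap * yn
      score <- compute_mic(col, yn, cfg)$value
      if (score >= 0.25) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not plant relevant column ", j, ": achieved MIC with label ",
           signif(score, 3), " after ", max_retries, " draws")
    }
    rel[, j] <- col
  }

  red <- matrix(NA_real_, n_samples, n_redundant)
  parents <- rep(NA_integer_, n_redundant)
  transforms <- list(function(u) u^3,
                     function(u) exp(u / 2),
                     function(u) asinh(2 * u))
  for (j in seq_len(n_redundant)) {
    parent <- ((j - 1L) %% n_relevant) + 1L
    parents[j] <- parent
    tf <- transforms[[((j - 1L) %% length(transforms)) + 1L]]
    base <- tf(rel[, parent])
    noise_sd <- 0.05 * stats::sd(base)
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      col <- base + noise_sd * stats::rnorm(n_samples)
      score <- compute_mic(col, rel[, parent], cfg)$value
      if (score > 0.8) { ok <- TRUE; break }
      noise_sd <- noise_sd / 2
    }
    if (!ok) {
      stop("could not plant redundant column ", j, ": achieved pairwise MIC ",
           signif(score, 3), " after ", max_retries, " calibration attempts")
    }
    red[, j] <- col
  }

  irr <- matrix(NA_real_, n_samples, n_irrelevant)
  for (j in seq_len(n_irrelevant)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      col <- stats::rnorm(n_samples)
      score <- compute_mic(col, yn, cfg)$value
      if (score < 0.2) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not plant irrelevant column ", j, ": achieved MIC with label ",
           signif(score, 3), " after ", max_retries, " draws")
    }
    irr[, j] <- col
  }

  values <- cbind(rel, red, irr)
  colnames(values) <- c(
    paste0("rel", seq_len(n_relevant)),
    if (n_redundant > 0L) paste0("red", seq_len(n_redundant), "_of_rel", parents),
    if (n_irrelevant > 0L) paste0("irr", seq_len(n_irrelevant))
  )
  roles <- c(rep("relevant", n_relevant), rep("redundant", n_redundant),
             rep("irrelevant", n_irrelevant))
  list(features = feature_matrix(values, y),
       roles = roles,
       parents = c(rep(NA_integer_, n_relevant), parents,
                   rep(NA_integer_, n_irrelevant)))
}

#' Generate a synthetic two-class multichannel EEG epoch set
#'
#' Emulates a resting-state acquisition design: `n_subjects` subjects (split
#' into two balanced classes), `duration_s` seconds per subject at `fs` Hz on
#' `n_channels` channels, segmented into non-overlapping `epoch_s`-second
#' epochs (any remainder truncated). Each channel is a sum of five
#' band-limited oscillations centred at 2/6/10/20/40 Hz (delta, theta, alpha,
#' beta, gamma) with per-epoch random phases and 10% amplitude jitter, plus
#' white Gaussian noise. Class 1 multiplies each band's base amplitude by
#' `class_effect`; the default boosts alpha power by 1.5x, mimicking a
#' band-power group difference.
#'
#' With the defaults (58 subjects x 240 s in 10-s epochs) the set contains
#' 58 x 24 = 1392 epochs.
#'
#' @param n_subjects number of subjects (default 58).
#' @param duration_s recording length per subject in seconds (default 240).
#' @param fs sampling rate in Hz (default 256).
#' @param n_channels channels (default 19).
#' @param epoch_s epoch length in seconds (default 10; must not exceed
#'   `duration_s`).
#' @param class_effect named per-band amplitude multipliers for class 1.
#' @param noise_sd white-noise standard deviation (signal units; default 1).
#' @param seed integer seed.
#' @return an [epoch_set()] with one integer label per epoch (subject-level
#'   class, alternating over subjects for balance).
#' @export
gen_eeg_dataset <- function(n_subjects = 58L, duration_s = 240,
                            fs = 256, n_channels = 19L, epoch_s = 10,
                            class_effect = c(delta = 1, theta = 1,
                                             alpha = 1.5, beta = 1, gamma = 1),
                            noise_sd = 1.0, seed = 1L) {
  if (epoch_s > duration_s) stop("`epoch_s` must not exceed `duration_s`")
  if (fs <= 0 || n_channels < 1L) stop("`fs` and `n_channels` must be positive")
  if (!all(.eeg_bands %in% names(class_effect))) {
    stop("`class_effect` must name all five bands: ",
         paste(.eeg_bands, collapse = ", "))
  }
  set.seed(seed)
  epochs_per_subject <- floor(duration_s / epoch_s)
  n_epochs <- n_subjects * epochs_per_subject
  n_samp <- round(epoch_s * fs)
  band_freq <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 40)
  base_amp <- c(delta = 2.0, theta = 1.5, alpha = 2.0, beta = 1.0, gamma = 0.5)
  subj_class <- rep_len(c(0L, 1L), n_subjects)
  tt <- (seq_len(n_samp) - 1L) / fs

  data <- array(NA_real_, c(n_epochs, n_channels, n_samp))
  labels <- integer(n_epochs)
  e <- 0L
  for (s in seq_len(n_subjects)) {
    cls <- subj_class[s]
    mult <- if (cls == 1L) class_effect[.eeg_bands] else
      stats::setNames(rep(1, 5), .eeg_bands)
    for (ep in seq_len(epochs_per_subject)) {
      e <- e + 1L
      labels[e] <- cls
      for (ch in seq_len(n_channels)) {
        sig <- stats::rnorm(n_samp, sd = noise_sd)
        for (b in .eeg_bands) {
          amp <- base_amp[b] * mult[b] * (1 + 0.1 * stats::rnorm(1))
          phase <- stats::runif(1, 0, 2 * pi)
          sig <- sig + amp * sin(2 * pi * band_freq[b] * tt + phase)
        }
        data[e, ch, ] <- sig
      }
    }
  }
  epoch_set(data, fs = fs, labels = labels,
            channel_names = if (n_channels == 19L) eeg_channels_1020 else NULL)
}
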