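# CSV / JSON interchange for feature tables and epoch bundles.

#' Write a feature matrix to CSV
#'
#' Header row of feature names plus a trailing integer `label` column.
#'
#' @param F a [feature_matrix()].
#' @param path output file.
#' @export
write_feature_csv <- function(F, path) {
  stopifnot(inherits(F, "feature_matrix"))
  utils::write.csv(as.data.frame(F), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Expects a header row and a trailing (or named) integer `label` column.
#'
#' @param path CSV file written by [write_feature_csv()] or any feature table
#'   in the same layout.
#' @return a [feature_matrix()].
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("label" %in% names(df))) {
    stop("feature CSV must contain a `label` column")
  }
  labels <- as.integer(df$label)
  df$label <- NULL
  feature_matrix(as.matrix(df), labels)
}

#' Write an epoch set as a plain-text matrix bundle
#'
#' The signal goes to `<path>.csv` as a long numeric matrix of
#' `(epochs * samples)` rows by `channels` columns (one epoch per row-block);
#' the metadata (sampling rate, samples per epoch, labels, channel names) goes
#' to `<path>.json`.
#'
#' @param epochs an [epoch_set()].
#' @param path output path prefix (no extension).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  long <- matrix(aperm(epochs$data, c(3L, 1L, 2L)), d[1] * d[3], d[2])
  colnames(long) <- epochs$channel_names
  utils::write.csv(long, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(fs = epochs$fs, n_epochs = d[1], n_channels = d[2],
               samples_per_epoch = d[3], labels = epochs$labels,
               channel_names = epochs$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set written by [write_epochs()]
#'
#' @param path path prefix (no extension).
#' @return an [epoch_set()].
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  long <- as.matrix(utils::read.csv(paste0(path, ".csv"), check.names = FALSE))
  arr <- aperm(array(long, c(meta$samples_per_epoch, meta$n_epochs,
                             meta$n_channels)),
               c(2L, 3L, 1L))
  epoch_set(arr, fs = meta$fs, labels = meta$labels,
            channel_names = meta$channel_names)
}
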