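# Small fixtures built in code and shared across test files.

# A tiny 19-channel epoch set (1-second epochs at 256 Hz) -- enough for
# column-layout and feature-finiteness checks without the cost of full-length
# epochs.
tiny_eeg <- function(seed = 2) {
  gen_eeg_dataset(n_subjects = 2, duration_s = 2, epoch_s = 1, seed = seed)
}

# Two well-separated Gaussian classes as a feature matrix.
separable_gaussians <- function(n = 200, p = 2, gap = 4, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + gap * y
  colnames(X) <- paste0("f", seq_len(p))
  feature_matrix(X, y)
}
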