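# Periodized orthogonal discrete wavelet transform.
#
# No wavelet package is part of this package's dependency set, so the small
# piece of machinery needed here -- a decimated, circularly-extended DWT with
# per-level coefficient masking and inverse transform -- is implemented
# directly. Analysis and synthesis are exact matrix transposes of one
# another, so perfect reconstruction holds to machine precision for any
# orthonormal filter pair.

# Daubechies filter taps (analysis lowpass); highpass derived by the
# alternating-flip quadrature mirror construction.
.dwt_filters <- local({
  lo <- list(
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    db8 = c(-0.00011747678400228192, 0.0006754494059985568,
            -0.0003917403729959771, -0.00487035299301066,
            0.008746094047015655, 0.013981027917015516,
            -0.04408825393106472, -0.01736930100202211,
            0.128747426620186, 0.00047248457399797254,
            -0.2840155429624281, -0.015829105256023893,
            0.5853546836548691, 0.6756307362980128,
            0.3128715909144659, 0.05441584224308161)
  )
  lapply(lo, function(h) {
    L <- length(h)
    g <- rev(h) * rep_len(c(1, -1), L)
    list(lo = h, hi = g)
  })
})

.dwt_get_filter <- function(wavelet) {
  f <- .dwt_filters[[wavelet]]
  if (is.null(f)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.dwt_filters), collapse = ", "))
  }
  f
}

# One analysis level: s (even length n) -> list(a, d) each of length n/2.
.dwt_analysis_step <- function(s, filt) {
  n <- length(s)
  m <- n %/% 2L
  L <- length(filt$lo)
  a <- numeric(m)
  d <- numeric(m)
  base <- 2L * (seq_len(m) - 1L)
  for (l in seq_len(L)) {
    idx <- (base + (l - 1L)) %% n + 1L
    sv <- s[idx]
    a <- a + filt$lo[l] * sv
    d <- d + filt$hi[l] * sv
  }
  list(a = a, d = d)
}

# Transpose of the analysis step: coefficients -> signal of length 2*length(a).
.dwt_synthesis_step <- function(a, d, filt) {
  m <- length(a)
  n <- 2L * m
  L <- length(filt$lo)
  s <- numeric(n)
  base <- 2L * (seq_len(m) - 1L)
  for (l in seq_len(L)) {
    idx <- (base + (l - 1L)) %% n + 1L
    s[idx] <- s[idx] + filt$lo[l] * a + filt$hi[l] * d
  }
  s
}

# Full decomposition: returns list(d = list(d1..dJ), a = aJ, n = length used).
.dwt_decompose <- function(x, levels, wavelet = "db4") {
  filt <- .dwt_get_filter(wavelet)
  n <- length(x)
  details <- vector("list", levels)
  s <- x
  for (j in seq_len(levels)) {
    step <- .dwt_analysis_step(s, filt)
    details[[j]] <- step$d
    s <- step$a
  }
  list(d = details, a = s, levels = levels, wavelet = wavelet, n = n)
}

# Inverse transform of a (possibly masked) coefficient set.
.dwt_reconstruct <- function(dec) {
  filt <- .dwt_get_filter(dec$wavelet)
  s <- dec$a
  for (j in rev(seq_len(dec$levels))) {
    s <- .dwt_synthesis_step(s, dec$d[[j]], filt)
  }
  s
}

# Reconstruct keeping only the named coefficient sets; `keep` is a character
# vector drawn from c("d1".."dJ", "a").
.dwt_band_reconstruct <- function(dec, keep) {
  masked <- dec
  if (!("a" %in% keep)) masked$a <- numeric(length(dec$a))
  for (j in seq_len(dec$levels)) {
    if (!(paste0("d", j) %in% keep)) {
      masked$d[[j]] <- numeric(length(dec$d[[j]]))
    }
  }
  .dwt_reconstruct(masked)
}
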