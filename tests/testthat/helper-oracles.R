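# Naive, loop-based reimplementations of every scalar feature operation.
# These are deliberately slow and literal (explicit double loops, textbook
# DFT) so they are independent of the package's vectorized/compiled paths.

apen_naive <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nv <- n - mm + 1
    logs <- numeric(nv)
    for (i in seq_len(nv)) {
      cnt <- 0
      for (j in seq_len(nv)) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1
      }
      logs[i] <- log(cnt / nv)
    }
    mean(logs)
  }
  phi(m) - phi(m + 1)
}

dft_naive <- function(x) {
  n <- length(x)
  X <- complex(n)
  for (k in 0:(n - 1)) {
    acc <- 0 + 0i
    for (t in 0:(n - 1)) acc <- acc + x[t + 1] * exp(-2i * pi * k * t / n)
    X[k + 1] <- acc
  }
  X
}

idft_naive <- function(X) {
  n <- length(X)
  x <- complex(n)
  for (t in 0:(n - 1)) {
    acc <- 0 + 0i
    for (k in 0:(n - 1)) acc <- acc + X[k + 1] * exp(2i * pi * k * t / n)
    x[t + 1] <- acc / n
  }
  x
}

psd_naive <- function(x) {
  X <- dft_naive(x)
  s <- 0
  for (k in seq_along(X)) s <- s + Mod(X[k])^2
  s / length(x)
}

hjorth_naive <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  act <- sum((x - mu)^2) / n
  dx <- x[-1] - x[-n]
  ddx <- dx[-1] - dx[-(n - 1)]
  m2 <- sum(dx^2) / (n - 1)
  m4 <- sum(ddx^2) / (n - 2)
  mob <- sqrt(m2 / act)
  c(activity = act, mobility = mob, complexity = sqrt(m4 / m2) / mob)
}

c0_naive <- function(x) {
  n <- length(x)
  X <- dft_naive(x)
  pw <- Mod(X)^2
  M <- sum(pw) / n
  Y <- X
  for (k in seq_len(n)) if (pw[k] <= M) Y[k] <- 0
  y <- Re(idft_naive(Y))
  sum((x - y)^2) / sum(x^2)
}

higuchi_naive <- function(x, kmax) {
  n <- length(x)
  LT <- numeric(kmax)
  for (T in 1:kmax) {
    ls <- numeric(T)
    for (tau in 1:T) {
      M <- floor((n - tau) / T)
      s <- 0
      for (i in 1:M) s <- s + abs(x[tau + i * T] - x[tau + (i - 1) * T])
      ls[tau] <- s * (n - 1) / (M * T^2)
    }
    LT[T] <- mean(ls)
  }
  lx <- log(1 / (1:kmax))
  ly <- log(LT)
  # closed-form simple regression slope
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# Mutual information (bits) of two discretized vectors -- independent of the
# package's internal entropy bookkeeping.
mi_naive <- function(bx, by) {
  tab <- table(bx, by)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        mi <- mi + pij * log2(pij / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  mi
}
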