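# small shared numerical helpers

# periodic-symmetric Hanning taper of length n (endpoints zero)
hanning_taper <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
}

# analytic signal via frequency-domain construction on the full trace
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# phase unwrapping with tolerance pi
unwrap_phase <- function(p) {
  dp <- diff(p)
  jump <- round(dp / (2 * pi))
  p - c(0, cumsum(jump)) * 2 * pi
}

# row-wise median of a small-column matrix via vectorized odd-even
# transposition sort (avoids one median() call per row)
row_median_small <- function(M) {
  k <- ncol(M)
  if (k == 1L) return(M[, 1L])
  for (pass in seq_len(k)) {
    start <- if (pass %% 2L) 1L else 2L
    for (j in seq(start, k - 1L, by = 2L)) {
      a <- M[, j]; b <- M[, j + 1L]
      swap <- a > b
      if (any(swap)) {
        M[swap, j] <- b[swap]
        M[swap, j + 1L] <- a[swap]
      }
    }
  }
  if (k %% 2L) M[, (k + 1L) %/% 2L] else (M[, k %/% 2L] + M[, k %/% 2L + 1L]) / 2
}

# mirror-pad a vector by np samples on each side
mirror_pad <- function(x, np) {
  n <- length(x)
  np <- min(np, n - 1L)
  c(x[(np + 1L):2L], x, x[(n - 1L):(n - np)])
}
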