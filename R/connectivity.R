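#' Pairwise phase consistency
#'
#' Bias-free phase-synchronization estimator: the mean over all trial
#' pairs of the cosine of their phase-difference difference, computed via
#' the closed form `(|sum_j exp(i*theta_j)|^2 - N) / (N*(N-1))`.
#'
#' @param theta numeric vector (one frequency) or trials x frequencies
#'   matrix of per-trial phase differences (radians).
#' @return PPC per frequency (scalar or vector).
#' @export
ppc <- function(theta) {
  theta <- as.matrix(theta)
  N <- nrow(theta)
  if (N < 2L) stop("invalid argument: PPC needs at least 2 trials")
  z <- exp(1i * theta)
  s <- Mod(colSums(z))^2
  drop((s - N) / (N * (N - 1)))
}

#' PPC spectrum between two channels of a spectrum_set
#'
#' Uses the trial-wise Fourier coefficients' phase difference
#' `Arg(X1) - Arg(X2)` at each frequency.
#'
#' @param spec a `spectrum_set` (see [fourier_spectra()]).
#' @param ch1,ch2 channel names or indices.
#' @return numeric vector of PPC values on `spec$freqs`.
#' @export
ppc_spectrum <- function(spec, ch1 = 1L, ch2 = 2L) {
  stopifnot(inherits(spec, "spectrum_set"))
  i1 <- if (is.character(ch1)) match(ch1, spec$channels) else ch1
  i2 <- if (is.character(ch2)) match(ch2, spec$channels) else ch2
  theta <- Arg(spec$coef[, i1, ] * Conj(spec$coef[, i2, ]))
  ppc(theta)
}

#' Trial-averaged cross-spectral density matrix
#'
#' Averages the rank-one trial cross-spectra of two channels on the full
#' padded frequency grid (0..Nyquist) and optionally smooths across
#' frequency with a running mean of `2*smooth + 1` bins, which
#' conditions the matrix for spectral factorization.
#'
#' @param spec a `spectrum_set` computed with `fmax = NULL`.
#' @param ch1,ch2 channel names or indices.
#' @param smooth half-width of the frequency smoothing kernel in bins.
#' @return a `cross_spectra`: list with `S` (2 x 2 x n_freq complex,
#'   Hermitian with real non-negative diagonal), `freqs`, `channels`.
#' @export
cross_spectra <- function(spec, ch1 = 1L, ch2 = 2L, smooth = 1L) {
  stopifnot(inherits(spec, "spectrum_set"))
  i1 <- if (is.character(ch1)) match(ch1, spec$channels) else ch1
  i2 <- if (is.character(ch2)) match(ch2, spec$channels) else ch2
  x1 <- spec$coef[, i1, ]
  x2 <- spec$coef[, i2, ]
  nf <- ncol(x1)
  S <- array(0i, dim = c(2L, 2L, nf))
  S[1L, 1L, ] <- colMeans(Mod(x1)^2)
  S[2L, 2L, ] <- colMeans(Mod(x2)^2)
  S[1L, 2L, ] <- colMeans(x1 * Conj(x2))
  S[2L, 1L, ] <- Conj(S[1L, 2L, ])
  if (smooth > 0L) {
    k <- 2L * smooth + 1L
    run <- function(v) {
      cs <- cumsum(c(0i, v))
      lo <- pmax(seq_len(nf) - smooth, 1L)
      hi <- pmin(seq_len(nf) + smooth, nf)
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    for (i in 1:2) for (j in 1:2) S[i, j, ] <- run(S[i, j, ])
  }
  structure(list(S = S, freqs = spec$freqs,
                 channels = spec$channels[c(i1, i2)]),
            class = "cross_spectra")
}

# 2x2-over-frequency complex matrix helpers (arrays 2 x 2 x nf)
m2_mul <- function(A, B) {
  C <- array(0i, dim = dim(A))
  C[1, 1, ] <- A[1, 1, ] * B[1, 1, ] + A[1, 2, ] * B[2, 1, ]
  C[1, 2, ] <- A[1, 1, ] * B[1, 2, ] + A[1, 2, ] * B[2, 2, ]
  C[2, 1, ] <- A[2, 1, ] * B[1, 1, ] + A[2, 2, ] * B[2, 1, ]
  C[2, 2, ] <- A[2, 1, ] * B[1, 2, ] + A[2, 2, ] * B[2, 2, ]
  C
}

m2_inv <- function(A) {
  det <- A[1, 1, ] * A[2, 2, ] - A[1, 2, ] * A[2, 1, ]
  B <- array(0i, dim = dim(A))
  B[1, 1, ] <- A[2, 2, ] / det
  B[2, 2, ] <- A[1, 1, ] / det
  B[1, 2, ] <- -A[1, 2, ] / det
  B[2, 1, ] <- -A[2, 1, ] / det
  B
}

m2_ctrans <- function(A) {
  B <- array(0i, dim = dim(A))
  B[1, 1, ] <- Conj(A[1, 1, ])
  B[2, 2, ] <- Conj(A[2, 2, ])
  B[1, 2, ] <- Conj(A[2, 1, ])
  B[2, 1, ] <- Conj(A[1, 2, ])
  B
}

# causal part of a matrix Laurent series given on the full circle:
# ifft along frequency, zero the negative lags, and split the zero-lag
# matrix as T with T + T^H = g0 and T lower-triangular (strict lower kept
# in full, diagonal halved) -- the lower-triangular H(0) convention
plus_operator <- function(G) {
  nfft <- dim(G)[3L]
  nkeep <- nfft %/% 2L
  Gp <- array(0i, dim = dim(G))
  for (i in 1:2) for (j in 1:2) {
    g <- stats::fft(G[i, j, ], inverse = TRUE) / nfft
    g[(nkeep + 2L):nfft] <- 0
    if (i == j) g[1L] <- 0.5 * g[1L] else if (i < j) g[1L] <- 0
    Gp[i, j, ] <- stats::fft(g)
  }
  Gp
}

#' Wilson's spectral matrix factorization
#'
#' Factorizes a Hermitian positive semi-definite cross-spectral density
#' on a uniform grid from 0 to Nyquist into `S(f) = H(f) Sigma H(f)*`
#' with a minimum-phase transfer function H (H(0) lower-triangular) and a
#' real noise covariance Sigma, by Wilson's iteration. Iterates until the
#' maximum relative change falls below `tol` or `max_iter` iterations.
#'
#' @param S complex array 2 x 2 x n_freq on the half grid including 0 and
#'   Nyquist, or a `cross_spectra` object.
#' @param tol convergence tolerance on the relative update.
#' @param max_iter maximum iterations.
#' @return a `wilson_factorization`: list with `H` (2 x 2 x n_freq),
#'   `Sigma` (2 x 2 real), `converged`, `iterations`, `residual`
#'   (relative reconstruction error `||S - H Sigma H*|| / ||S||`), and
#'   the input `S` and `freqs` (when available).
#' @export
spectral_factorization <- function(S, tol = 1e-9, max_iter = 100L) {
  freqs <- NULL
  if (inherits(S, "cross_spectra")) {
    freqs <- S$freqs
    S <- S$S
  }
  nf <- dim(S)[3L]
  if (any(Re(S[1, 1, ]) < -1e-12) || any(Re(S[2, 2, ]) < -1e-12))
    stop("invalid argument: non-PSD cross-spectrum (negative diagonal)")
  detS <- Re(S[1, 1, ] * S[2, 2, ]) - Mod(S[1, 2, ])^2
  if (any(detS < -1e-8 * max(Mod(S))^2))
    stop("invalid argument: non-PSD cross-spectrum (negative determinant)")
  nfft <- 2L * (nf - 1L)
  # full circle: S(-f) = conj(S(f))
  Sf <- array(0i, dim = c(2L, 2L, nfft))
  Sf[, , 1:nf] <- S
  Sf[, , (nf + 1L):nfft] <- Conj(S[, , (nf - 1L):2L])
  # init: lower Cholesky of the zero-lag covariance
  g0 <- matrix(0i, 2L, 2L)
  for (i in 1:2) for (j in 1:2)
    g0[i, j] <- mean(Sf[i, j, ])
  g0 <- Re(g0 + t(g0)) / 2
  L <- t(chol(g0 + diag(1e-12 * max(abs(g0)) + 1e-300, 2L)))
  psi <- array(0i, dim = c(2L, 2L, nfft))
  psi[1, 1, ] <- L[1, 1]; psi[2, 1, ] <- L[2, 1]; psi[2, 2, ] <- L[2, 2]
  I2 <- array(0i, dim = c(2L, 2L, nfft))
  I2[1, 1, ] <- 1; I2[2, 2, ] <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ipsi <- m2_inv(psi)
    G <- m2_mul(m2_mul(ipsi, Sf), m2_ctrans(ipsi)) + I2
    Gp <- plus_operator(G)
    psi_new <- m2_mul(psi, Gp)
    delta <- max(Mod(psi_new - psi)) / max(Mod(psi_new))
    psi <- psi_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # zero-lag coefficient -> noise covariance and transfer function
  A0 <- matrix(0i, 2L, 2L)
  for (i in 1:2) for (j in 1:2)
    A0[i, j] <- mean(psi[i, j, ])
  A0 <- Re(A0)
  Sigma <- A0 %*% t(A0)
  A0i <- solve(A0)
  H <- array(0i, dim = c(2L, 2L, nf))
  ph <- psi[, , 1:nf, drop = FALSE]
  H[1, 1, ] <- ph[1, 1, ] * A0i[1, 1] + ph[1, 2, ] * A0i[2, 1]
  H[1, 2, ] <- ph[1, 1, ] * A0i[1, 2] + ph[1, 2, ] * A0i[2, 2]
  H[2, 1, ] <- ph[2, 1, ] * A0i[1, 1] + ph[2, 2, ] * A0i[2, 1]
  H[2, 2, ] <- ph[2, 1, ] * A0i[1, 2] + ph[2, 2, ] * A0i[2, 2]
  # reconstruction residual on the half grid
  rec <- array(0i, dim = c(2L, 2L, nf))
  HS <- H
  HS[1, 1, ] <- H[1, 1, ] * Sigma[1, 1] + H[1, 2, ] * Sigma[2, 1]
  HS[1, 2, ] <- H[1, 1, ] * Sigma[1, 2] + H[1, 2, ] * Sigma[2, 2]
  HS[2, 1, ] <- H[2, 1, ] * Sigma[1, 1] + H[2, 2, ] * Sigma[2, 1]
  HS[2, 2, ] <- H[2, 1, ] * Sigma[1, 2] + H[2, 2, ] * Sigma[2, 2]
  rec <- m2_mul(HS, m2_ctrans(H))
  residual <- sqrt(sum(Mod(rec - S)^2)) / sqrt(sum(Mod(S)^2))
  if (!converged)
    warning(sprintf("Wilson factorization did not converge in %d iterations (residual %.2e)",
                    max_iter, residual))
  structure(list(H = H, Sigma = Sigma, converged = converged,
                 iterations = it, residual = residual, S = S, freqs = freqs),
            class = "wilson_factorization")
}

#' Frequency-resolved Granger causality from a factorization
#'
#' For channels x (1) and y (2):
#' `G_x->y(f) = ln[ S_yy / (S_yy - (Sigma_xx - Sigma_xy^2/Sigma_yy) |H_yx|^2 ) ]`
#' and symmetrically for the reverse direction. Small numerical negatives
#' are clipped to zero.
#'
#' @param fac a `wilson_factorization`.
#' @return list with `freqs`, `gc_xy` (influence of channel 1 on channel
#'   2), `gc_yx`.
#' @export
granger_spectrum <- function(fac) {
  stopifnot(inherits(fac, "wilson_factorization"))
  S <- fac$S; H <- fac$H; Sg <- fac$Sigma
  Syy <- Re(S[2, 2, ]); Sxx <- Re(S[1, 1, ])
  if (any(Syy == 0) || any(Sxx == 0))
    stop("invalid argument: zero spectral power on the diagonal")
  sig_x_given_y <- Sg[1, 1] - Sg[1, 2]^2 / Sg[2, 2]
  sig_y_given_x <- Sg[2, 2] - Sg[1, 2]^2 / Sg[1, 1]
  gxy <- log(Syy / (Syy - sig_x_given_y * Mod(H[2, 1, ])^2))
  gyx <- log(Sxx / (Sxx - sig_y_given_x * Mod(H[1, 2, ])^2))
  gxy[!is.finite(gxy) | gxy < 0] <- 0
  gyx[!is.finite(gyx) | gyx < 0] <- 0
  list(freqs = fac$freqs, gc_xy = gxy, gc_yx = gyx)
}

#' Beta-band connectivity after a median split on reaction time
#'
#' Splits the trials into fast and slow halves ([median_split()]),
#' computes full-grid Fourier coefficients per half, and returns the PPC
#' and both directed Granger spectra read out on the beta grid.
#'
#' @param epochs two-channel `epoch_set` with reaction times attached.
#' @param window analysis window, seconds.
#' @param pad_to padded duration, seconds.
#' @param band read-out band, Hz.
#' @param smooth cross-spectral frequency smoothing half-width, bins.
#' @return data.frame with columns `freq`, `ppc_slow`, `ppc_fast`,
#'   `gc_m2a_slow`, `gc_m2a_fast`, `gc_a2m_slow`, `gc_a2m_fast`
#'   (channel 1 is "motor"/source, channel 2 "auditory"/target).
#' @export
split_connectivity <- function(epochs, window = c(-0.7, 0), pad_to = 2,
                               band = c(13, 30), smooth = 1L) {
  validate_epoch_set(epochs)
  if (is.null(epochs$rts)) stop("invalid argument: reaction times required")
  sp <- median_split(epochs$rts)
  if (length(sp$fast) < 2L || length(sp$slow) < 2L)
    stop("invalid argument: need >= 2 trials per half")
  one_half <- function(idx) {
    sub <- epochs
    sub$data <- epochs$data[idx, , , drop = FALSE]
    sub$rts <- epochs$rts[idx]
    spec <- fourier_spectra(sub, window = window, pad_to = pad_to,
                            fmax = NULL)
    keep <- which(spec$freqs >= band[1L] - 1e-9 &
                    spec$freqs <= band[2L] + 1e-9)
    cs <- cross_spectra(spec, 1L, 2L, smooth = smooth)
    fac <- spectral_factorization(cs)
    g <- granger_spectrum(fac)
    list(freqs = spec$freqs[keep],
         ppc = ppc_spectrum(spec, 1L, 2L)[keep],
         gc_m2a = g$gc_xy[keep], gc_a2m = g$gc_yx[keep])
  }
  fast <- one_half(sp$fast)
  slow <- one_half(sp$slow)
  data.frame(freq = fast$freqs,
             ppc_slow = slow$ppc, ppc_fast = fast$ppc,
             gc_m2a_slow = slow$gc_m2a, gc_m2a_fast = fast$gc_m2a,
             gc_a2m_slow = slow$gc_a2m, gc_a2m_fast = fast$gc_a2m)
}
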