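# shared fixture builders (everything generated in code)

fs_default <- 300
time_default <- seq(-1, 0.4, by = 1 / fs_default)

# single-channel epoch_set around a given trials x samples matrix
epochs_from_matrix <- function(m, fs = fs_default, time = time_default,
                               channel = "motor", rts = NULL) {
  epoch_set(array(m, dim = c(nrow(m), 1L, ncol(m))), fs = fs, time = time,
            channels = channel, rts = rts)
}

# pure tone epochs
tone_epochs <- function(freq, n_trials = 1, amp = 1, fs = fs_default,
                        time = time_default) {
  m <- matrix(rep(amp * sin(2 * pi * freq * time), n_trials),
              nrow = n_trials, byrow = TRUE)
  epochs_from_matrix(m, fs = fs, time = time)
}

# log-log spectral slope oracle: Welch-style averaged periodogram + OLS
spectral_slope <- function(m, fs, fmin = 2, fmax = 100) {
  sp <- apply(m, 1L, function(x)
    stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                      taper = 0.1)$spec)
  f <- stats::spec.pgram(stats::ts(m[1L, ], frequency = fs), plot = FALSE,
                         taper = 0.1)$freq
  keep <- f >= fmin & f <= fmax
  unname(stats::coef(stats::lm(log(rowMeans(sp)[keep]) ~ log(f[keep])))[2L])
}

# amplitude of a sinusoidal component by complex projection over an
# interior segment (robust to edge transients)
tone_amplitude <- function(x, freq, fs, skip = 60L) {
  seg <- x[(skip + 1L):(length(x) - skip)]
  tt <- seq_along(seg) / fs
  2 * Mod(mean(seg * exp(-2i * pi * freq * tt)))
}

# independent connected-components oracle: recursive flood fill with
# explicit 4-neighbourhood, intentionally distinct from cluster_events()
flood_fill_labels <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  fill <- function(i, j) {
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- p[1L]; j <- p[2L]
      if (i < 1L || j < 1L || i > nrow(mask) || j > ncol(mask)) next
      if (!mask[i, j] || lab[i, j] != 0L) next
      lab[i, j] <<- cur
      stack <- c(stack, list(c(i - 1L, j), c(i + 1L, j),
                             c(i, j - 1L), c(i, j + 1L)))
    }
  }
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      fill(i, j)
    }
  lab
}

# stable random bivariate VAR(2) with analytic spectrum on a half grid;
# spectral radius kept below 0.85 so the lag sequence decays well inside
# the grid (no wraparound aliasing on nf >= 257 grids)
random_var2_spectrum <- function(nf, seed) {
  set.seed(seed)
  repeat {
    A1 <- matrix(stats::rnorm(4, 0, 0.4), 2L)
    A2 <- matrix(stats::rnorm(4, 0, 0.3), 2L)
    comp <- rbind(cbind(A1, A2), cbind(diag(2), matrix(0, 2L, 2L)))
    if (max(Mod(eigen(comp, only.values = TRUE)$values)) < 0.85) break
  }
  L <- matrix(c(1, 0.3, 0, 0.8), 2L)
  Sig <- L %*% t(L)
  fgrid <- seq(0, 0.5, length.out = nf)
  S <- array(0i, dim = c(2L, 2L, nf))
  for (k in seq_len(nf)) {
    z1 <- exp(-2i * pi * fgrid[k])
    H <- solve(diag(2) - A1 * z1 - A2 * z1^2)
    S[, , k] <- H %*% Sig %*% Conj(t(H))
  }
  list(S = S, A1 = A1, A2 = A2, Sigma = Sig, fgrid = fgrid)
}

# simulate a bivariate VAR(2) as trial epochs
simulate_var2_epochs <- function(A1, A2, Sigma, n_trials, n_samples,
                                 fs = 300, seed = 1L, burn = 200L) {
  set.seed(seed)
  R <- chol(Sigma)
  dat <- array(0, dim = c(n_trials, 2L, n_samples))
  for (tr in seq_len(n_trials)) {
    n <- n_samples + burn
    e <- t(matrix(stats::rnorm(2L * n), ncol = 2L) %*% R)
    x <- matrix(0, 2L, n)
    for (t in 3:n)
      x[, t] <- A1 %*% x[, t - 1L] + A2 %*% x[, t - 2L] + e[, t]
    dat[tr, , ] <- x[, (burn + 1L):n]
  }
  epoch_set(dat, fs = fs, time = seq(0, n_samples - 1L) / fs,
            channels = c("x", "y"))
}
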