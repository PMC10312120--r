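test_that("PPC takes its exact degenerate values and is unbiased under the null", {
  expect_equal(ppc(matrix(rep(1.3, 10), 10, 1)), 1)
  expect_equal(ppc(matrix(c(0, pi), 2, 1)), -1)
  expect_error(ppc(matrix(0, 1, 1)), "2 trials")

  set.seed(14)
  sims <- replicate(1000, ppc(matrix(runif(100, 0, 2 * pi), 100, 1)))
  se <- sd(sims) / sqrt(1000)
  expect_lt(abs(mean(sims)), 3 * se)
})

test_that("PPC expectation does not depend on the trial count", {
  set.seed(15)
  mean_ppc <- function(N, sims = 400) {
    mean(replicate(sims, ppc(matrix(rnorm(N, 0, 0.8) %% (2 * pi), N, 1))))
  }
  m10 <- mean_ppc(10); m50 <- mean_ppc(50); m200 <- mean_ppc(200)
  expect_lt(abs(m10 - m200), 0.03)
  expect_lt(abs(m50 - m200), 0.03)
})

test_that("cross-spectra are Hermitian with non-negative diagonals", {
  set.seed(16)
  ep <- epoch_set(array(rnorm(40 * 2 * 210), c(40, 2, 210)), 300,
                  seq(0, 209) / 300, c("x", "y"))
  spec <- fourier_spectra(ep, c(0, 0.7), 2, fmax = NULL)
  cs <- cross_spectra(spec)
  expect_true(all(Re(cs$S[1, 1, ]) >= 0))
  expect_true(all(Re(cs$S[2, 2, ]) >= 0))
  expect_equal(cs$S[2, 1, ], Conj(cs$S[1, 2, ]))
})

test_that("Wilson factorization is exact for white noise", {
  S0 <- matrix(c(2, 0.5, 0.5, 1), 2)
  S <- array(0i, c(2, 2, 64))
  for (k in 1:64) S[, , k] <- S0
  fac <- spectral_factorization(S)
  expect_true(fac$converged)
  expect_lt(max(abs(fac$Sigma - S0)), 1e-6)
  expect_lt(max(Mod(sweep(fac$H, 1:2, diag(2)))), 1e-6)
  expect_lt(fac$residual, 1e-10)
})

test_that("factorization reconstructs analytic AR(2) and random PSD spectra", {
  # known AR(2)
  ref <- random_var2_spectrum(257, seed = 100)
  fac <- spectral_factorization(ref$S)
  expect_true(fac$converged)
  expect_lt(fac$residual, 1e-6)

  # property sweep over random stable spectra
  resid <- vapply(1:100, function(s)
    spectral_factorization(random_var2_spectrum(257, seed = 200 + s)$S)$residual,
    numeric(1))
  expect_lt(max(resid), 1e-6)

  bad <- ref$S; bad[1, 1, 3] <- -1
  expect_error(spectral_factorization(bad), "non-PSD")
})

test_that("independent white channels show no Granger influence", {
  set.seed(17)
  ep <- epoch_set(array(rnorm(500 * 2 * 210), c(500, 2, 210)), 300,
                  seq(0, 209) / 300, c("x", "y"))
  spec <- fourier_spectra(ep, c(0, 0.7), 2, fmax = NULL)
  fac <- spectral_factorization(cross_spectra(spec))
  g <- granger_spectrum(fac)
  expect_true(all(g$gc_xy < 0.01))
  expect_true(all(g$gc_yx < 0.01))
  expect_true(all(g$gc_xy >= 0) && all(g$gc_yx >= 0))
})

test_that("nonparametric Granger matches a parametric AR oracle and finds direction", {
  A1 <- matrix(c(0.55, 0, 0.25, 0.35), 2, byrow = TRUE)   # x drives y
  A2 <- matrix(c(-0.6, 0, -0.1, -0.4), 2, byrow = TRUE)
  Sig <- diag(c(1, 0.7))
  ep <- simulate_var2_epochs(A1, A2, Sig, n_trials = 600, n_samples = 600,
                             seed = 18)
  spec <- fourier_spectra(ep, c(0, 2), 2, fmax = NULL)
  fac <- suppressWarnings(spectral_factorization(cross_spectra(spec)))
  expect_lt(fac$residual, 1e-3)   # empirical spectra: flagged if not converged
  g <- granger_spectrum(fac)

  # least-squares VAR fit oracle (pooled trials), parametric spectrum
  X <- matrix(aperm(ep$data, c(3, 1, 2)), ncol = 2)
  fit <- ar(X, order.max = 2, aic = FALSE, method = "ols", demean = TRUE)
  A1h <- fit$ar[1, , ]; A2h <- fit$ar[2, , ]; Sigh <- fit$var.pred
  sigxy <- Sigh[1, 1] - Sigh[1, 2]^2 / Sigh[2, 2]
  gpar <- vapply(fac$freqs / 300, function(fr) {
    z1 <- exp(-2i * pi * fr)
    H <- solve(diag(2) - A1h * z1 - A2h * z1^2)
    S <- H %*% Sigh %*% Conj(t(H))
    log(Re(S[2, 2]) / (Re(S[2, 2]) - sigxy * Mod(H[2, 1])^2))
  }, numeric(1))
  # compare over the peak region (+/- 2 bins) to damp single-bin jitter
  pk <- which.max(gpar)
  sel <- max(1, pk - 2):min(length(gpar), pk + 2)
  expect_lt(abs(mean(g$gc_xy[sel]) - mean(gpar[sel])) / mean(gpar[sel]), 0.1)
  expect_gt(g$gc_xy[pk], g$gc_yx[pk])
})

test_that("Granger is invariant to rescaling one channel", {
  ref <- random_var2_spectrum(257, seed = 300)
  g1 <- granger_spectrum(spectral_factorization(ref$S))
  scaled <- ref$S
  scaled[1, 1, ] <- scaled[1, 1, ] * 100
  scaled[1, 2, ] <- scaled[1, 2, ] * 10
  scaled[2, 1, ] <- scaled[2, 1, ] * 10
  g2 <- granger_spectrum(spectral_factorization(scaled))
  expect_lt(max(abs(g1$gc_xy - g2$gc_xy)), 1e-6)
  expect_lt(max(abs(g1$gc_yx - g2$gc_yx)), 1e-6)
})

test_that("lag-coupled synthetic channels order the directed estimates correctly", {
  m <- generate_noise(120, 421, 300, 1, seed = 41, t0 = -1, channel = "motor")
  a <- generate_noise(120, 421, 300, 1, seed = 42, t0 = -1, channel = "auditory")
  a2 <- couple_channels(m, a, gain = 0.8, lag = 0.02)
  dat <- array(0, c(120, 2, 421))
  dat[, 1, ] <- m$data[, 1, ]; dat[, 2, ] <- a2$data[, 1, ]
  ep <- epoch_set(dat, 300, m$time, c("motor", "auditory"))
  spec <- fourier_spectra(differentiate(ep), c(-0.7, 0), 2, fmax = NULL)
  fac <- suppressWarnings(spectral_factorization(cross_spectra(spec)))
  g <- granger_spectrum(fac)
  beta <- which(fac$freqs >= 13 & fac$freqs <= 30)
  pk <- beta[which.max(g$gc_xy[beta])]
  expect_gt(g$gc_xy[pk], g$gc_yx[pk])
})

test_that("split_connectivity is symmetric for duplicated halves and needs RTs", {
  set.seed(19)
  half <- array(rnorm(10 * 2 * 421), c(10, 2, 421))
  dat <- array(0, c(20, 2, 421))
  dat[1:10, , ] <- half; dat[11:20, , ] <- half
  rts <- c(rep(300, 10), rep(600, 10))
  ep <- epoch_set(dat, 300, time_default, c("motor", "auditory"), rts = rts)
  out <- suppressWarnings(split_connectivity(ep))
  expect_equal(out$ppc_slow, out$ppc_fast, tolerance = 1e-9)
  expect_equal(out$gc_m2a_slow, out$gc_m2a_fast, tolerance = 1e-6)
  expect_equal(out$freq, seq(13, 30, by = 0.5))

  ep$rts <- NULL
  expect_error(split_connectivity(ep), "reaction times")
})

test_that("RT-dependent coupling raises slow-half directed connectivity", {
  cfg <- sim_config(n_trials = 120, rt_coefs = c(500, 0, 0, 40),
                    rt_noise_sd = 20, coupling_gain = 0.6, seed = 77)
  ds <- make_dataset(cfg)
  out <- suppressWarnings(split_connectivity(differentiate(ds$pretarget)))
  pk <- which.max(out$gc_m2a_slow + out$gc_m2a_fast)
  expect_gt(out$gc_m2a_slow[pk], out$gc_m2a_fast[pk])
})
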