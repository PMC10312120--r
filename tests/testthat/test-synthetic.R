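test_that("generated noise has the requested aperiodic slope", {
  e1 <- generate_noise(200, 391, 300, exponent = 1, seed = 42)
  s1 <- spectral_slope(channel_matrix(e1, 1L), 300)
  expect_lt(abs(s1 - (-1)), 0.15)

  e0 <- generate_noise(200, 391, 300, exponent = 0, seed = 42)
  s0 <- spectral_slope(channel_matrix(e0, 1L), 300)
  expect_lt(abs(s0), 0.1)

  # zero-mean, unit-SD traces
  expect_lt(max(abs(apply(channel_matrix(e1, 1L), 1L, mean))), 1e-10)
  expect_equal(apply(channel_matrix(e1, 1L), 1L, sd), rep(1, 200))
})

test_that("noise generation is deterministic and validates arguments", {
  a <- generate_noise(5, 128, 300, 1, seed = 7)
  b <- generate_noise(5, 128, 300, 1, seed = 7)
  expect_identical(a$data, b$data)
  expect_error(generate_noise(0, 128, 300, 1), "positive")
  expect_error(generate_noise(5, 32, 300, 1), "64")
  expect_error(generate_noise(5, 128, -1, 1), "positive")
})

test_that("burst injection records every burst and respects rate 0", {
  base <- generate_noise(10, 421, 300, 1, seed = 3, t0 = -1)
  out <- inject_bursts(base, rate = 0, seed = 5)
  expect_identical(out$epochs$data, base$data)
  expect_equal(nrow(out$records), 0L)

  out <- inject_bursts(base, rate = 2, seed = 5)
  expect_true(all(out$records$freq >= 13 & out$records$freq <= 30))
  expect_true(all(out$records$duration <= 6 / out$records$freq + 1e-9))
  # conservation: modified trials are exactly those with records
  changed <- which(apply(out$epochs$data != base$data, 1L, any))
  expect_setequal(changed, unique(out$records$trial))
})

test_that("injected burst count follows the Poisson rate", {
  base <- generate_noise(1000, 128, 300, 0, seed = 11)
  out <- inject_bursts(base, rate = 2, cycles = c(2, 3),
                       freq_range = c(20, 30), seed = 12)
  m <- nrow(out$records) / 1000
  expect_lt(abs(m - 2), 3 * sqrt(2 / 1000))
})

test_that("a single injected burst raises TFR power at its locus", {
  sil <- epochs_from_matrix(matrix(0, 1, length(time_default)))
  noise <- generate_noise(1, 421, 300, 1, seed = 2, t0 = -1)
  with_burst <- noise
  tc <- -0.4; f0 <- 20; dur <- 4 / f0
  idx <- which(time_default >= tc - dur / 2 & time_default <= tc + dur / 2)
  tt <- time_default[idx]
  with_burst$data[1, 1, idx] <- with_burst$data[1, 1, idx] +
    5 * 0.5 * (1 + cos(2 * pi * (tt - tc) / dur)) * sin(2 * pi * f0 * (tt - tc))
  t_plain <- tfr(noise); t_burst <- tfr(with_burst)
  fi <- which.min(abs(t_plain$freqs - f0))
  ti <- which.min(abs(t_plain$times - tc))
  expect_gt(t_burst$power[1, 1, fi, ti], t_plain$power[1, 1, fi, ti])
})

test_that("coupling adds a lagged band-limited copy and gain 0 is a no-op", {
  m <- generate_noise(20, 421, 300, 1, seed = 21, t0 = -1, channel = "motor")
  a <- generate_noise(20, 421, 300, 1, seed = 22, t0 = -1, channel = "auditory")
  expect_identical(couple_channels(m, a, gain = 0)$data, a$data)

  a2 <- couple_channels(m, a, gain = 0.8, lag = 0.02)
  # cross-correlation between bandpassed motor and the added component
  # peaks at +20 ms (positive lag = motor leads)
  added <- a2$data[1, 1, ] - a$data[1, 1, ]
  bp <- bandpass(m)$data[1, 1, ]
  cc <- stats::ccf(added, bp, lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], round(0.02 * 300))

  short <- generate_noise(5, 421, 300, 1, seed = 1, t0 = -1)
  expect_error(couple_channels(short, a, gain = 1), "mismatched")
})

test_that("coupling raises beta-band phase consistency", {
  m <- generate_noise(80, 421, 300, 1, seed = 31, t0 = -1, channel = "motor")
  a <- generate_noise(80, 421, 300, 1, seed = 32, t0 = -1, channel = "auditory")
  two_ch <- function(mm, aa) {
    dat <- array(0, c(80, 2, 421))
    dat[, 1, ] <- mm$data[, 1, ]; dat[, 2, ] <- aa$data[, 1, ]
    epoch_set(dat, 300, mm$time, c("motor", "auditory"))
  }
  beta_ppc <- function(ep) {
    spec <- fourier_spectra(ep, c(-0.7, 0), 2)
    mean(ppc_spectrum(spec)[spec$freqs >= 13 & spec$freqs <= 30])
  }
  p0 <- beta_ppc(two_ch(m, a))
  p1 <- beta_ppc(two_ch(m, couple_channels(m, a, gain = 0.8, lag = 0.02)))
  expect_gt(p1, p0)
})

test_that("reaction-time model matches its definition", {
  set.seed(1)
  feats <- data.frame(P = rnorm(1000), F = rnorm(1000), C = rnorm(1000))
  rt <- generate_rts(feats, c(500, 0, 0, 0), rt_noise_sd = 50, seed = 2)
  expect_lt(abs(mean(rt) - 500), 3 * 50 / sqrt(1000))

  rt <- generate_rts(feats, c(500, 30, 0, 0), rt_noise_sd = 0, seed = 2)
  expect_equal(cor(feats$P, rt), 1)

  # positive correlation recovered in >= 99/100 seeded draws
  hits <- sum(vapply(1:100, function(s) {
    set.seed(s + 1000)
    f <- data.frame(P = rnorm(500), F = rnorm(500), C = rnorm(500))
    cor(f$P, generate_rts(f, c(500, 30, 0, 0), 50, seed = s)) > 0
  }, logical(1)))
  expect_gte(hits, 99)

  expect_error(generate_rts(data.frame(P = rep(1, 5), F = 1:5, C = 1:5),
                            c(500, 30, 0, 0), 50), "degenerate")
  # zero-variance feature is fine when its coefficient is 0
  expect_silent(generate_rts(data.frame(P = rep(1, 5), F = 1:5, C = 1:5),
                             c(500, 0, 10, 0), 50))
})

test_that("make_dataset is reproducible and self-consistent", {
  cfg <- sim_config(n_trials = 25, seed = 99)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1$pretarget$data, d2$pretarget$data)
  expect_identical(d1$ground_truth, d2$ground_truth)
  expect_silent(validate_epoch_set(d1$pretarget))
  expect_silent(validate_epoch_set(d1$precue))
  expect_equal(length(d1$pretarget$rts), 25L)
  expect_true(all(d1$pretarget$rts >= 100))
  expect_equal(nrow(d1$ground_truth$rt_features), 25L)
  expect_true(all(is.finite(as.matrix(d1$ground_truth$rt_features))))
  expect_equal(d1$pretarget$channels, c("motor", "auditory"))
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(n_trials = 0), "n_trials")
  expect_error(sim_config(fs = 50), "twice")
  expect_error(sim_config(rt_noise_sd = -1), "rt_noise_sd")
  expect_error(sim_config(burst_freq_range = c(0, 30)), "fs/2")
})
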