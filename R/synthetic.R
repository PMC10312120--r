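#' Simulation configuration for synthetic two-channel epochs
#'
#' Bundles the generative parameters for synthetic "motor" and "auditory"
#' virtual-channel epochs: 1/f background noise, transient beta bursts,
#' a lagged directed motor-to-auditory coupling, and reaction times drawn
#' as a noisy linear function of single-trial beta power, beta frequency,
#' and coupling strength.
#'
#' @param n_trials number of trials (>= 1).
#' @param fs sampling rate, Hz.
#' @param epoch_span epoch extent in seconds relative to target onset.
#'   The default covers the full time-frequency grid (-750..+250 ms with a
#'   250 ms analysis window) with margin to spare.
#' @param precue_span epoch extent in seconds relative to cue onset for
#'   the baseline (precue) epochs.
#' @param noise_exponent alpha of the 1/f^alpha background power spectrum.
#' @param burst_rate mean bursts per trial and channel (Poisson lambda).
#' @param burst_freq_range burst frequency range, Hz.
#' @param burst_cycles range of burst duration in cycles.
#' @param burst_amp burst peak amplitude as a multiple of the noise SD.
#' @param burst_time_range range of burst center times, seconds; defaults
#'   to the region covered by the analysis grid.
#' @param coupling_gain motor-to-auditory coupling gain (unitless). When
#'   `rt_coefs[4]` is nonzero the per-trial gain is drawn
#'   Uniform(0, 2 * coupling_gain) so coupling strength varies across
#'   trials and can drive reaction times.
#' @param coupling_lag coupling lag, seconds.
#' @param rt_coefs numeric length 4: intercept (ms) and slopes (ms per
#'   z-unit) for motor beta power, auditory beta frequency, and coupling
#'   strength.
#' @param rt_noise_sd SD of the additive reaction-time noise, ms.
#' @param seed integer RNG seed; the full dataset is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_trials = 150, fs = 300,
                       epoch_span = c(-1.0, 0.4),
                       precue_span = c(-1.0, 0.4),
                       noise_exponent = 1.0,
                       burst_rate = 2,
                       burst_freq_range = c(13, 30),
                       burst_cycles = c(2, 6),
                       burst_amp = 5,
                       burst_time_range = c(-0.7, 0.1),
                       coupling_gain = 0.4,
                       coupling_lag = 0.02,
                       rt_coefs = c(500, 30, 30, 30),
                       rt_noise_sd = 50,
                       seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials), fs = fs,
              epoch_span = epoch_span, precue_span = precue_span,
              noise_exponent = noise_exponent, burst_rate = burst_rate,
              burst_freq_range = burst_freq_range,
              burst_cycles = burst_cycles, burst_amp = burst_amp,
              burst_time_range = burst_time_range,
              coupling_gain = coupling_gain, coupling_lag = coupling_lag,
              rt_coefs = rt_coefs, rt_noise_sd = rt_noise_sd,
              seed = as.integer(seed))
  if (cfg$n_trials < 1L) stop("n_trials must be >= 1")
  if (cfg$fs <= 2 * max(cfg$burst_freq_range))
    stop("fs must exceed twice the upper burst frequency")
  if (min(cfg$burst_freq_range) <= 0 || max(cfg$burst_freq_range) >= cfg$fs / 2)
    stop("burst_freq_range must lie within (0, fs/2)")
  if (cfg$rt_noise_sd < 0) stop("rt_noise_sd must be >= 0")
  if (diff(cfg$epoch_span) <= 0) stop("epoch_span must be increasing")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate 1/f^alpha background noise epochs
#'
#' Frequency-domain synthesis: Gaussian-amplitude spectral coefficients
#' with uniform random phases are shaped by f^(-alpha/2) (DC bin zeroed)
#' and inverse-transformed, giving zero-mean traces whose expected power
#' spectrum is proportional to 1/f^alpha. Each trace is rescaled to unit
#' standard deviation so burst amplitudes can be specified in noise-SD
#' units.
#'
#' @param n_trials number of trials.
#' @param n_samples samples per trial (>= 64).
#' @param fs sampling rate, Hz.
#' @param exponent spectral exponent alpha (>= 0).
#' @param seed integer RNG seed.
#' @param t0 time of the first sample, seconds.
#' @param channel channel name for the returned single-channel epoch_set.
#' @param window window label.
#' @return an `epoch_set` with one channel.
#' @export
generate_noise <- function(n_trials, n_samples, fs, exponent = 1, seed = 1L,
                           t0 = 0, channel = "ch1", window = "pretarget") {
  if (n_trials < 1 || fs <= 0) stop("invalid argument: n_trials and fs must be positive")
  if (n_samples < 64) stop("invalid argument: n_samples must be >= 64")
  if (exponent < 0) stop("invalid argument: exponent must be >= 0")
  set.seed(seed)
  dat <- array(0, dim = c(n_trials, 1L, n_samples))
  freqs <- seq(0, n_samples - 1) * fs / n_samples
  nyq <- floor(n_samples / 2)
  shape <- c(0, freqs[2:(nyq + 1)]^(-exponent / 2))  # bins 0..nyq
  for (tr in seq_len(n_trials)) {
    mag <- shape * abs(stats::rnorm(nyq + 1))
    ph <- stats::runif(nyq + 1, 0, 2 * pi)
    half <- mag * exp(1i * ph)
    spec <- complex(length.out = n_samples)
    spec[1:(nyq + 1)] <- half
    # Hermitian symmetry for a real signal; real DC/Nyquist bins
    spec[1] <- 0
    if (n_samples %% 2 == 0) spec[nyq + 1] <- Re(spec[nyq + 1])
    spec[seq(n_samples, nyq + 2)] <- Conj(spec[2:(n_samples - nyq)])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x <- x / s
    dat[tr, 1L, ] <- x
  }
  epoch_set(dat, fs = fs, time = t0 + seq(0, n_samples - 1) / fs,
            channels = channel, window = window)
}

#' Inject transient beta bursts into epochs
#'
#' Each burst is a Hanning-windowed sinusoid
#' `A * w(t) * sin(2*pi*f*(t - t0) + phi)` added in place, with uniform
#' random phase. Burst counts per trial and channel are Poisson
#' distributed; frequencies, durations (in cycles), and center times are
#' drawn uniformly from the configured ranges. All injections are
#' recorded.
#'
#' @param epochs an `epoch_set`.
#' @param rate Poisson mean bursts per trial and channel.
#' @param freq_range burst frequency range, Hz.
#' @param cycles range of burst duration in cycles.
#' @param amp peak amplitude (same units as the data; with unit-SD noise,
#'   a multiple of the noise SD).
#' @param time_range range of admissible burst center times, seconds.
#'   Clipped so every burst fits inside the epoch.
#' @param seed integer RNG seed.
#' @return list with elements `epochs` (modified copy) and `records`
#'   (data.frame: trial, channel, time, freq, duration, amplitude).
#' @export
inject_bursts <- function(epochs, rate, freq_range = c(13, 30),
                          cycles = c(2, 6), amp = 5,
                          time_range = NULL, seed = 1L) {
  validate_epoch_set(epochs)
  if (max(freq_range) >= epochs$fs / 2)
    stop("invalid argument: burst frequencies must be below Nyquist")
  max_dur <- max(cycles) / min(freq_range)
  tspan <- range(epochs$time)
  if (max_dur > diff(tspan))
    stop("invalid argument: burst duration exceeds epoch length")
  if (is.null(time_range)) time_range <- tspan
  set.seed(seed)
  d <- dim(epochs$data)
  recs <- list()
  k <- 0L
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      nb <- stats::rpois(1L, rate)
      if (nb == 0L) next
      for (b in seq_len(nb)) {
        f <- stats::runif(1L, freq_range[1L], freq_range[2L])
        ncyc <- stats::runif(1L, cycles[1L], cycles[2L])
        dur <- ncyc / f
        lo <- max(time_range[1L], tspan[1L] + dur / 2)
        hi <- min(time_range[2L], tspan[2L] - dur / 2)
        tc <- if (hi > lo) stats::runif(1L, lo, hi) else (lo + hi) / 2
        phi <- stats::runif(1L, 0, 2 * pi)
        idx <- which(epochs$time >= tc - dur / 2 & epochs$time <= tc + dur / 2)
        tt <- epochs$time[idx]
        w <- 0.5 * (1 + cos(2 * pi * (tt - tc) / dur))
        epochs$data[tr, ch, idx] <- epochs$data[tr, ch, idx] +
          amp * w * sin(2 * pi * f * (tt - tc) + phi)
        k <- k + 1L
        recs[[k]] <- data.frame(trial = tr, channel = epochs$channels[ch],
                                time = tc, freq = f, duration = dur,
                                amplitude = amp)
      }
    }
  }
  records <- if (k > 0L) do.call(rbind, recs) else
    data.frame(trial = integer(), channel = character(), time = numeric(),
               freq = numeric(), duration = numeric(), amplitude = numeric())
  list(epochs = epochs, records = records)
}

#' Add lagged band-limited coupling from one channel set to another
#'
#' Adds `gain * bandpass(motor)(t - lag)` to the auditory traces,
#' simulating a directed motor-to-auditory beta influence. The gain may
#' be a scalar or one value per trial.
#'
#' @param motor single-channel `epoch_set` (source).
#' @param auditory single-channel `epoch_set` (target, modified copy).
#' @param gain scalar or per-trial coupling gain.
#' @param lag coupling lag in seconds (>= 0, < epoch length).
#' @param band frequency band of the coupled component, Hz.
#' @return the modified auditory `epoch_set`.
#' @export
couple_channels <- function(motor, auditory, gain, lag = 0.02,
                            band = c(13, 30)) {
  validate_epoch_set(motor); validate_epoch_set(auditory)
  nt <- n_trials(motor)
  if (nt != n_trials(auditory))
    stop("invalid argument: mismatched trial counts")
  if (lag < 0 || lag >= diff(range(motor$time)))
    stop("invalid argument: lag must be within the epoch length")
  if (min(band) <= 0 || max(band) >= motor$fs / 2)
    stop("invalid argument: band must lie within (0, fs/2)")
  gain <- rep_len(gain, nt)
  if (all(gain == 0)) return(auditory)
  src <- channel_matrix(motor, 1L)
  bp <- t(apply(src, 1L, fir_bandpass_filter, fs = motor$fs, band = band))
  shift <- as.integer(round(lag * motor$fs))
  ns <- ncol(bp)
  lagged <- matrix(0, nrow = nt, ncol = ns)
  if (shift < ns)
    lagged[, (shift + 1L):ns] <- bp[, 1L:(ns - shift), drop = FALSE]
  auditory$data[, 1L, ] <- auditory$data[, 1L, ] + gain * lagged
  auditory
}

#' Generate reaction times from single-trial beta features
#'
#' Draws `RT_i = b0 + bP*z(P_i) + bF*z(F_i) + bC*z(C_i) + eps_i` with
#' Gaussian noise, clipping at a 100 ms physiological floor. Features
#' with a zero coefficient are ignored; a zero-variance feature with a
#' nonzero coefficient is a degenerate input.
#'
#' @param features data.frame or list with per-trial columns `P` (motor
#'   beta power), `F` (auditory beta frequency), `C` (coupling strength).
#' @param rt_coefs numeric length 4 (intercept, bP, bF, bC), ms per z-unit.
#' @param rt_noise_sd noise SD, ms.
#' @param seed integer RNG seed.
#' @return numeric vector of reaction times, ms.
#' @export
generate_rts <- function(features, rt_coefs, rt_noise_sd = 50, seed = 1L) {
  if (rt_noise_sd < 0) stop("invalid argument: rt_noise_sd must be >= 0")
  n <- length(features$P)
  zsafe <- function(x, coef, name) {
    if (coef == 0) return(numeric(n))
    if (any(!is.finite(x))) stop("degenerate input: non-finite feature ", name)
    s <- stats::sd(x)
    if (s == 0) stop("degenerate input: zero-variance feature ", name,
                     " with nonzero coefficient")
    (x - mean(x)) / s
  }
  zP <- zsafe(features$P, rt_coefs[2L], "P")
  zF <- zsafe(features$F, rt_coefs[3L], "F")
  zC <- zsafe(features$C, rt_coefs[4L], "C")
  set.seed(seed)
  eps <- if (rt_noise_sd > 0) stats::rnorm(n, 0, rt_noise_sd) else numeric(n)
  rt <- rt_coefs[1L] + rt_coefs[2L] * zP + rt_coefs[3L] * zF +
    rt_coefs[4L] * zC + eps
  pmax(rt, 100)
}

# Internal single-trial feature estimators used by the generator to tie
# reaction times to measurable signal properties (deliberately simpler
# than the analysis pipeline's estimators).
sim_beta_power_feature <- function(x, fs, time, band, win) {
  idx <- which(time >= win[1L] & time <= win[2L])
  bp <- fir_bandpass_filter(x, fs, band)
  mean(bp[idx]^2)
}

sim_beta_freq_feature <- function(x, fs, time, band, win) {
  bp <- fir_bandpass_filter(x, fs, band)
  a <- analytic_signal(bp)
  ph <- unwrap_phase(Arg(a))
  inst <- diff(ph) * fs / (2 * pi)
  tm <- (time[-1L] + time[-length(time)]) / 2
  idx <- which(tm >= win[1L] & tm <= win[2L])
  stats::median(inst[idx])
}

#' Generate a complete synthetic two-channel dataset
#'
#' Composes noise generation, burst injection, directed coupling, and the
#' reaction-time model into pretarget and precue epoch sets for "motor"
#' and "auditory" channels, with a full ground-truth record: all injected
#' bursts, per-trial coupling strengths, the reaction-time features and
#' coefficients, and the seed. Identical configurations reproduce the
#' dataset exactly.
#'
#' @param config a `sim_config`.
#' @return list with `pretarget` and `precue` two-channel `epoch_set`s
#'   (reaction times attached to both), and `ground_truth` (list:
#'   `burst_records`, `precue_burst_records`, `rt_features`, `rt_coefs`,
#'   `coupling_gain`, `coupling_lag`, `seed`).
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 12L)
  ns <- as.integer(round(diff(config$epoch_span) * config$fs)) + 1L
  build_window <- function(span, window, s_idx) {
    motor <- generate_noise(config$n_trials, ns, config$fs,
                            config$noise_exponent, seed = seeds[s_idx],
                            t0 = span[1L], channel = "motor", window = window)
    auditory <- generate_noise(config$n_trials, ns, config$fs,
                               config$noise_exponent, seed = seeds[s_idx + 1L],
                               t0 = span[1L], channel = "auditory",
                               window = window)
    bm <- inject_bursts(motor, config$burst_rate, config$burst_freq_range,
                        config$burst_cycles, config$burst_amp,
                        config$burst_time_range, seed = seeds[s_idx + 2L])
    ba <- inject_bursts(auditory, config$burst_rate, config$burst_freq_range,
                        config$burst_cycles, config$burst_amp,
                        config$burst_time_range, seed = seeds[s_idx + 3L])
    list(motor = bm$epochs, auditory = ba$epochs,
         records = rbind(bm$records, ba$records))
  }
  pre <- build_window(config$epoch_span, "pretarget", 1L)
  base <- build_window(config$precue_span, "precue", 5L)

  # per-trial coupling strength
  set.seed(seeds[9L])
  gains <- if (config$rt_coefs[4L] != 0 && config$coupling_gain > 0)
    stats::runif(config$n_trials, 0, 2 * config$coupling_gain)
  else rep(config$coupling_gain, config$n_trials)
  pre$auditory <- couple_channels(pre$motor, pre$auditory, gains,
                                  config$coupling_lag,
                                  config$burst_freq_range)
  base$auditory <- couple_channels(base$motor, base$auditory,
                                   rep(config$coupling_gain, config$n_trials),
                                   config$coupling_lag,
                                   config$burst_freq_range)

  win <- c(-0.7, 0)
  band <- config$burst_freq_range
  P <- vapply(seq_len(config$n_trials), function(tr)
    sim_beta_power_feature(pre$motor$data[tr, 1L, ], config$fs,
                           pre$motor$time, band, win), numeric(1L))
  Fq <- vapply(seq_len(config$n_trials), function(tr)
    sim_beta_freq_feature(pre$auditory$data[tr, 1L, ], config$fs,
                          pre$auditory$time, band, win), numeric(1L))
  features <- data.frame(P = P, F = Fq, C = gains)
  rts <- generate_rts(features, config$rt_coefs, config$rt_noise_sd,
                      seed = seeds[10L])

  combine <- function(w) {
    dat <- array(0, dim = c(config$n_trials, 2L, ns))
    dat[, 1L, ] <- w$motor$data[, 1L, ]
    dat[, 2L, ] <- w$auditory$data[, 1L, ]
    epoch_set(dat, fs = config$fs, time = w$motor$time,
              channels = c("motor", "auditory"), window = w$motor$window,
              rts = rts)
  }
  list(pretarget = combine(pre), precue = combine(base),
       ground_truth = list(burst_records = pre$records,
                           precue_burst_records = base$records,
                           rt_features = features,
                           rt_coefs = config$rt_coefs,
                           coupling_gain = gains,
                           coupling_lag = config$coupling_lag,
                           seed = config$seed))
}
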