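#' Temporal differentiation (1/f flattening)
#'
#' First difference scaled by the sampling rate. Differentiation
#' multiplies the power spectrum by approximately `(2*pi*f)^2`, turning a
#' `1/f^2` background into a flat one and making narrow-band beta
#' activity more salient; it removes additive constants exactly. The
#' output is one sample shorter and its time axis sits at the interval
#' midpoints.
#'
#' @param epochs an `epoch_set` with at least 2 samples.
#' @return a differentiated `epoch_set` (units/s).
#' @export
differentiate <- function(epochs) {
  validate_epoch_set(epochs)
  d <- dim(epochs$data)
  if (d[3L] < 2L) stop("invalid argument: need at least 2 samples")
  out <- (epochs$data[, , -1L, drop = FALSE] -
            epochs$data[, , -d[3L], drop = FALSE]) * epochs$fs
  tm <- (epochs$time[-1L] + epochs$time[-d[3L]]) / 2
  epoch_set(out, fs = epochs$fs, time = tm, channels = epochs$channels,
            window = epochs$window, rts = epochs$rts)
}

#' Single-trial Hanning-tapered Fourier spectra
#'
#' Extracts the analysis window from each trial, applies a Hanning taper,
#' zero-pads to `pad_to` seconds, and returns complex Fourier
#' coefficients together with natural-log power on a frequency axis with
#' spacing exactly `1/pad_to` Hz. With the defaults (700 ms window padded
#' to 2 s) the resolution is 0.5 Hz.
#'
#' @param epochs an `epoch_set`.
#' @param window analysis window `c(t0, t1)` in seconds (half-open on the
#'   right so a 700 ms window at 300 Hz holds exactly 210 samples).
#' @param pad_to padded duration in seconds (>= window length).
#' @param fmax keep frequencies up to this limit, Hz; `NULL` keeps the
#'   full grid to Nyquist (needed for spectral factorization).
#' @param taper `"hanning"` or `"none"`.
#' @return a `spectrum_set`: list with `coef` (complex array trials x
#'   channels x frequencies), `logpow`, `freqs`, `df`, `channels`,
#'   `n_window` (samples in the window), `floored` (TRUE if any zero
#'   power bin was floored before the log).
#' @export
fourier_spectra <- function(epochs, window = c(-0.7, 0), pad_to = 2,
                            fmax = 30, taper = c("hanning", "none")) {
  validate_epoch_set(epochs)
  taper <- match.arg(taper)
  idx <- which(epochs$time >= window[1L] - 1e-9 &
                 epochs$time < window[2L] - 1e-9)
  n <- length(idx)
  if (n == 0L) stop("invalid argument: empty analysis window")
  if (pad_to < n / epochs$fs)
    stop("invalid argument: pad_to shorter than the window")
  nfft <- as.integer(round(pad_to * epochs$fs))
  tap <- if (taper == "hanning") hanning_taper(n) else rep(1, n)
  d <- dim(epochs$data)
  freqs <- seq(0, floor(nfft / 2)) / pad_to
  keep <- if (is.null(fmax)) seq_along(freqs) else which(freqs <= fmax + 1e-9)
  coef <- array(0i, dim = c(d[1L], d[2L], length(keep)))
  for (ch in seq_len(d[2L])) {
    seg <- epochs$data[, ch, idx, drop = FALSE]
    dim(seg) <- c(d[1L], n)
    seg <- sweep(seg, 2L, tap, `*`)
    padded <- cbind(seg, matrix(0, d[1L], nfft - n))
    X <- t(stats::mvfft(t(padded)))
    coef[, ch, ] <- X[, keep, drop = FALSE]
  }
  pow <- Mod(coef)^2
  floored <- any(pow == 0)
  if (floored) {
    warning("zero-power bins floored before log transform")
    pow[pow == 0] <- .Machine$double.xmin
  }
  structure(list(coef = coef, logpow = log(pow), freqs = freqs[keep],
                 df = 1 / pad_to, channels = epochs$channels,
                 n_window = n, floored = floored),
            class = "spectrum_set")
}

#' Sliding-window time-frequency representation
#'
#' Hanning-tapered short-time Fourier power on an exact frequency-by-time
#' grid (defaults: 13-30 Hz in 0.5 Hz steps, -750..+250 ms in 20 ms
#' steps, 250 ms window), computed as multiplication with complex
#' exponential kernels (equivalently a windowed FFT). Epochs must extend
#' half a window beyond the extreme time points.
#'
#' @param epochs an `epoch_set`.
#' @param foi frequencies of interest, Hz.
#' @param toi time points of interest, seconds.
#' @param window sliding window length, seconds.
#' @return a `tfr_set`: list with `power` (array trials x channels x
#'   frequencies x times), `freqs`, `times`, `channels`, `fs`, `norm`
#'   (per-channel normalization factor, NA until [normalize_tfr()]).
#' @export
tfr <- function(epochs, foi = seq(13, 30, by = 0.5),
                toi = seq(-0.75, 0.25, by = 0.02), window = 0.25) {
  validate_epoch_set(epochs)
  nwin <- as.integer(round(window * epochs$fs))
  if (nwin %% 2L == 0L) nwin <- nwin + 1L
  half <- (nwin - 1L) %/% 2L
  centers <- vapply(toi, function(t0) which.min(abs(epochs$time - t0)),
                    integer(1L))
  ns <- length(epochs$time)
  if (any(centers - half < 1L) || any(centers + half > ns))
    stop("invalid argument: toi window exceeds epoch edges; supply epochs ",
         "extending at least half a window beyond the toi extremes")
  tap <- hanning_taper(nwin)
  tseg <- (seq_len(nwin) - 1L - half) / epochs$fs
  kern <- exp(-2i * pi * outer(foi, tseg)) *
    matrix(tap, nrow = length(foi), ncol = nwin, byrow = TRUE)
  d <- dim(epochs$data)
  pow <- array(0, dim = c(d[1L], d[2L], length(foi), length(toi)))
  segidx <- outer(seq(-half, half), centers, `+`)  # nwin x ntoi
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      x <- epochs$data[tr, ch, ]
      segs <- matrix(x[segidx], nrow = nwin)
      pow[tr, ch, , ] <- Mod(kern %*% segs)^2
    }
  }
  structure(list(power = pow, freqs = foi, times = toi,
                 channels = epochs$channels, fs = epochs$fs,
                 norm = rep(NA_real_, d[2L])),
            class = "tfr_set")
}

#' Normalize a TFR by its per-channel grand mean
#'
#' One scalar factor per channel, the mean over all trials, frequencies,
#' and time points; every point is divided by it, so the normalized grand
#' mean is 1 per channel.
#'
#' @param x a `tfr_set`.
#' @return the normalized `tfr_set` with `norm` filled in.
#' @export
normalize_tfr <- function(x) {
  stopifnot(inherits(x, "tfr_set"))
  for (ch in seq_along(x$channels)) {
    m <- mean(x$power[, ch, , ])
    if (!is.finite(m) || m <= 0)
      stop("degenerate input: non-positive mean power in channel ",
           x$channels[ch])
    x$power[, ch, , ] <- x$power[, ch, , ] / m
    x$norm[ch] <- m
  }
  x
}

#' Band-averaged single-trial power time courses
#'
#' Arithmetic mean over the frequency rows inside `band`, per trial and
#' time point, for one channel.
#'
#' @param x a `tfr_set`.
#' @param band frequency band `c(lo, hi)`, Hz (inclusive).
#' @param channel channel name or index.
#' @return numeric matrix, trials x times.
#' @export
band_power_timecourse <- function(x, band = c(13, 30), channel = 1L) {
  stopifnot(inherits(x, "tfr_set"))
  ci <- if (is.character(channel)) match(channel, x$channels) else channel
  rows <- which(x$freqs >= band[1L] - 1e-9 & x$freqs <= band[2L] + 1e-9)
  if (length(rows) == 0L) stop("invalid argument: empty frequency band")
  p <- x$power[, ci, rows, , drop = FALSE]
  out <- apply(p, c(1L, 4L), mean)
  dim(out) <- c(dim(x$power)[1L], length(x$times))
  out
}
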