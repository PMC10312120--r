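# windowed-sinc FIR bandpass, Hamming design; order = `cycles` periods of
# the low cutoff at fs (even, so the kernel is odd-length and symmetric)
fir_bandpass_coefs <- function(fs, band, cycles = 3) {
  ord <- as.integer(round(cycles * fs / band[1L]))
  if (ord %% 2L == 1L) ord <- ord + 1L
  signal::fir1(ord, band / (fs / 2), type = "pass")
}

# zero-phase single-channel filtering: centered convolution of the
# symmetric kernel with a mirror-padded trace
fir_bandpass_filter <- function(x, fs, band, cycles = 3, h = NULL) {
  if (is.null(h)) h <- fir_bandpass_coefs(fs, band, cycles)
  L <- length(h)
  half <- (L - 1L) %/% 2L
  if (length(x) < 3L * L)
    stop("invalid argument: epoch too short for the bandpass filter (need >= 3 filter lengths)")
  xp <- mirror_pad(x, half)
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  as.numeric(y[(half + 1L):(half + length(x))])
}

#' Zero-phase beta bandpass filter
#'
#' Windowed-sinc FIR (Hamming design) of order three cycles of the low
#' cutoff, applied as a centered convolution of the symmetric kernel on
#' mirror-padded traces; being linear-phase and applied centered, the
#' filter has exactly zero group delay, and the passband gain at the band
#' center is within 1% of unity.
#'
#' @param epochs an `epoch_set`.
#' @param band passband `c(lo, hi)`, Hz.
#' @param cycles filter order in cycles of the low cutoff.
#' @return the filtered `epoch_set`.
#' @export
bandpass <- function(epochs, band = c(13, 30), cycles = 3) {
  validate_epoch_set(epochs)
  h <- fir_bandpass_coefs(epochs$fs, band, cycles)
  d <- dim(epochs$data)
  if (d[3L] < 3L * length(h))
    stop("invalid argument: epoch too short for the bandpass filter")
  for (tr in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      epochs$data[tr, ch, ] <- fir_bandpass_filter(epochs$data[tr, ch, ],
                                                   epochs$fs, band, h = h)
  epochs
}

#' Single-trial instantaneous frequency
#'
#' Per trial: analytic signal (frequency-domain construction on the
#' mirror-padded trace), unwrapped phase, first difference scaled to Hz,
#' then a bank of `n_filters` median filters with kernel durations
#' linearly spaced over `kernel_range`; the pointwise median across the
#' filtered versions is returned. Edge samples within the largest kernel
#' half-width are invalidated, as are samples where the analytic
#' amplitude vanishes.
#'
#' @param epochs a band-limited `epoch_set` (see [bandpass()]).
#' @param channel channel name or index.
#' @param n_filters number of median filters.
#' @param kernel_range range of kernel durations, seconds.
#' @return an `instfreq_series`: list with `freq` (trials x times matrix,
#'   Hz; invalid samples NA), `times` (first-difference midpoints), and
#'   `valid` (logical vector marking samples away from the edges).
#' @export
instantaneous_frequency <- function(epochs, channel = 1L, n_filters = 10,
                                    kernel_range = c(0.01, 0.4)) {
  validate_epoch_set(epochs)
  x <- channel_matrix(epochs, channel)
  fs <- epochs$fs
  ns <- ncol(x)
  durs <- seq(kernel_range[1L], kernel_range[2L], length.out = n_filters)
  ks <- pmin(as.integer(round(durs * fs)) %/% 2L * 2L + 1L, ns - 2L)
  ks <- ifelse(ks %% 2L == 0L, ks - 1L, ks)
  tm <- (epochs$time[-1L] + epochs$time[-ns]) / 2
  out <- matrix(NA_real_, nrow(x), ns - 1L)
  zero_amp <- FALSE
  for (tr in seq_len(nrow(x))) {
    a <- analytic_signal(mirror_pad(x[tr, ], ns - 1L))
    a <- a[ns:(2L * ns - 1L)]
    bad <- Mod(a) == 0
    raw <- diff(unwrap_phase(Arg(a))) * fs / (2 * pi)
    # endrule "keep": the invalidated edge region already covers the
    # largest kernel half-width, so end smoothing is never consumed
    filtered <- vapply(ks, function(k)
      as.numeric(stats::runmed(raw, k, endrule = "keep")),
      numeric(ns - 1L))
    est <- row_median_small(filtered)
    if (any(bad)) {
      zero_amp <- TRUE
      est[bad[-ns] | bad[-1L]] <- NA_real_
    }
    out[tr, ] <- est
  }
  if (zero_amp)
    warning("zero-amplitude analytic signal; affected samples invalidated")
  halfmax <- (max(ks) - 1L) %/% 2L
  valid <- rep(TRUE, ns - 1L)
  valid[seq_len(min(halfmax, ns - 1L))] <- FALSE
  valid[seq.int(ns - 1L, by = -1L, length.out = min(halfmax, ns - 1L))] <- FALSE
  out[, !valid] <- NA_real_
  structure(list(freq = out, times = tm, valid = valid),
            class = "instfreq_series")
}

#' Detect the beta peak frequency of a mean spectrum
#'
#' Returns the frequency of the largest local maximum strictly inside the
#' band (a point exceeding both neighbors); `NA` when the spectrum has no
#' local maximum across the band (monotone). Equal-power local maxima
#' resolve to the lower frequency.
#'
#' @param power numeric vector, mean (1/f-flattened) power spectrum.
#' @param freqs frequency axis, Hz.
#' @param band search band `c(lo, hi)`, Hz.
#' @return peak frequency in Hz, or `NA_real_` for no-peak.
#' @export
detect_beta_peak <- function(power, freqs, band = c(13, 30)) {
  idx <- which(freqs >= band[1L] - 1e-9 & freqs <= band[2L] + 1e-9)
  if (length(idx) < 3L)
    stop("invalid argument: band outside (or too narrow for) the spectrum axis")
  p <- power[idx]
  interior <- 2:(length(p) - 1L)
  is_max <- p[interior] > p[interior - 1L] & p[interior] > p[interior + 1L]
  cand <- interior[is_max]
  if (length(cand) == 0L) return(NA_real_)
  best <- cand[order(-p[cand], freqs[idx][cand])][1L]
  freqs[idx][best]
}
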