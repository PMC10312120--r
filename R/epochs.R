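#' Trial-epoched multi-channel time series
#'
#' An `epoch_set` holds trial-epoched virtual-channel data as a numeric
#' array of dimension trials x channels x samples, together with the
#' sampling rate, a time axis relative to the locking event (target onset
#' for pretarget epochs, cue onset for precue epochs), channel names, a
#' window label, and optionally per-trial reaction times in milliseconds.
#'
#' @param data numeric array, trials x channels x samples.
#' @param fs sampling rate in Hz.
#' @param time numeric vector of sample times in seconds relative to the
#'   locking event; strictly increasing with spacing `1/fs`.
#' @param channels character vector of channel names.
#' @param window window label, `"pretarget"` or `"precue"`.
#' @param rts optional numeric vector of reaction times (ms), one per
#'   trial, all positive.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, time, channels = NULL, window = "pretarget",
                      rts = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  if (is.null(channels))
    channels <- paste0("ch", seq_len(dim(data)[2L]))
  x <- structure(
    list(data = data, fs = fs, time = as.numeric(time),
         channels = as.character(channels), window = window, rts = rts),
    class = "epoch_set")
  validate_epoch_set(x)
  x
}

#' Validate an epoch_set against its invariants
#'
#' Checks the container schema: array dimensionality, time-axis length,
#' monotonicity and spacing (`1/fs` within numerical tolerance), channel
#' name count, and (when present) reaction-time length and positivity.
#' Errors name the offending field.
#'
#' @param x an `epoch_set`.
#' @return `x`, invisibly, if valid.
#' @export
validate_epoch_set <- function(x) {
  for (f in c("data", "fs", "time", "channels", "window"))
    if (is.null(x[[f]])) stop(sprintf("epoch_set schema error: missing field '%s'", f))
  d <- dim(x$data)
  if (length(d) != 3L)
    stop("epoch_set schema error: 'data' must be trials x channels x samples")
  if (length(x$time) != d[3L])
    stop("epoch_set schema error: 'time' length does not match sample count")
  dt <- diff(x$time)
  if (any(dt <= 0))
    stop("epoch_set schema error: 'time' must be strictly increasing")
  if (max(abs(dt - 1 / x$fs)) > 1e-6 / x$fs)
    stop("epoch_set schema error: 'time' spacing must equal 1/fs")
  if (length(x$channels) != d[2L])
    stop("epoch_set schema error: 'channels' length does not match data")
  if (!is.null(x$rts)) {
    if (length(x$rts) != d[1L])
      stop("epoch_set schema error: 'rts' length does not match trial count")
    if (any(!is.finite(x$rts)) || any(x$rts <= 0))
      stop("epoch_set schema error: 'rts' must be positive and finite")
  }
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  window: %s, time %.3f..%.3f s, channels: %s%s\n",
              x$window, x$time[1L], x$time[length(x$time)],
              paste(x$channels, collapse = ", "),
              if (is.null(x$rts)) "" else ", RTs attached"))
  invisible(x)
}

#' Number of trials in an epoch_set
#' @param x an `epoch_set`.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Extract one channel's trials x samples matrix
#' @param x an `epoch_set`.
#' @param channel channel name or index.
#' @return numeric matrix, trials x samples.
#' @export
channel_matrix <- function(x, channel) {
  ci <- if (is.character(channel)) match(channel, x$channels) else as.integer(channel)
  if (is.na(ci) || ci < 1L || ci > dim(x$data)[2L])
    stop("unknown channel: ", channel)
  m <- x$data[, ci, , drop = FALSE]
  dim(m) <- dim(x$data)[c(1L, 3L)]
  m
}
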