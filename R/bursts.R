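#' Mark supra-threshold time-frequency points in one trial
#'
#' Per frequency row, the threshold is the within-trial mean plus two
#' (sample, n-1) standard deviations of that row's power over the full
#' trial time axis; points strictly above it are marked. Contiguous
#' supra-threshold runs shorter than one oscillatory cycle (1/frequency)
#' are then cleared, where a run of k bins at time step dt lasts k*dt
#' seconds. A constant row (zero SD) yields no marks.
#'
#' @param power_ft numeric matrix, frequencies x times, of (normalized)
#'   power for one trial and channel.
#' @param freqs frequency axis, Hz.
#' @param times time axis, seconds (uniform spacing).
#' @param n_sd threshold in SD units (default 2).
#' @return logical matrix of the same shape.
#' @export
burst_mask <- function(power_ft, freqs, times, n_sd = 2) {
  if (ncol(power_ft) < 2L)
    stop("invalid argument: need at least 2 time points per row")
  dt <- times[2L] - times[1L]
  mask <- matrix(FALSE, nrow(power_ft), ncol(power_ft))
  for (fi in seq_len(nrow(power_ft))) {
    row <- power_ft[fi, ]
    thr <- mean(row) + n_sd * stats::sd(row)
    m <- row > thr
    if (any(m)) {
      r <- rle(m)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      min_bins <- (1 / freqs[fi]) / dt
      for (j in which(r$values)) {
        if (r$lengths[j] < min_bins - 1e-9)
          m[starts[j]:ends[j]] <- FALSE
      }
    }
    mask[fi, ] <- m
  }
  mask
}

#' Cluster marked points into burst events
#'
#' Connected components of the mask under 4-connectivity (adjacent in
#' time or in frequency, not diagonally); one event per component.
#'
#' @param mask logical matrix, frequencies x times.
#' @return list of events, each a two-column integer matrix of member
#'   points (frequency bin, time bin).
#' @export
cluster_events <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  events <- list()
  nev <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    nev <- nev + 1L
    queue <- p
    lab[p] <- nev
    members <- integer(0)
    while (length(queue)) {
      q <- queue[[1L]]; queue <- queue[-1L]
      members <- c(members, q)
      fi <- ((q - 1L) %% nr) + 1L
      ti <- ((q - 1L) %/% nr) + 1L
      nb <- c(if (fi > 1L) q - 1L, if (fi < nr) q + 1L,
              if (ti > 1L) q - nr, if (ti < nc) q + nr)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- nev
      queue <- c(queue, nb)
    }
    fi <- ((members - 1L) %% nr) + 1L
    ti <- ((members - 1L) %/% nr) + 1L
    events[[nev]] <- cbind(freq_bin = fi, time_bin = ti)
  }
  events
}

# peak (highest-power member) of one event; ties broken by earliest
# time, then lowest frequency
event_peak <- function(members, power_ft) {
  p <- power_ft[members]
  best <- which(p == max(p))
  if (length(best) > 1L) {
    cand <- members[best, , drop = FALSE]
    ord <- order(cand[, 2L], cand[, 1L])
    best <- best[ord[1L]]
  }
  list(freq_bin = unname(members[best, 1L]),
       time_bin = unname(members[best, 2L]),
       power = unname(power_ft[members[best, , drop = FALSE]]))
}

#' Extract the six burst parameters for one trial and window
#'
#' Counts the events whose peak point falls inside the analysis window
#' and, focusing on the event containing the highest-power marked point
#' among those, extracts its peak power, peak time (ms), peak frequency
#' (Hz), frequency range (Hz), and time range (ms). With no events the
#' five parameters are NA.
#'
#' @param events list of member matrices from [cluster_events()].
#' @param power_ft frequencies x times power matrix for the trial.
#' @param freqs frequency axis, Hz.
#' @param times time axis, seconds.
#' @param window analysis window `c(t0, t1)` in seconds (inclusive).
#' @return one-row data.frame: `n_events`, `peak_power`, `peak_time_ms`,
#'   `peak_freq_hz`, `freq_range_hz`, `time_range_ms`.
#' @export
burst_parameters <- function(events, power_ft, freqs, times,
                             window = c(-0.7, 0)) {
  peaks <- lapply(events, event_peak, power_ft = power_ft)
  inwin <- vapply(peaks, function(p) {
    tt <- times[p$time_bin]
    tt >= window[1L] - 1e-9 && tt <= window[2L] + 1e-9
  }, logical(1L))
  nev <- sum(inwin)
  if (nev == 0L)
    return(data.frame(n_events = 0L, peak_power = NA_real_,
                      peak_time_ms = NA_real_, peak_freq_hz = NA_real_,
                      freq_range_hz = NA_real_, time_range_ms = NA_real_))
  sel <- which(inwin)
  pk <- vapply(peaks[sel], `[[`, numeric(1L), "power")
  top <- sel[order(-pk, vapply(peaks[sel], function(p) times[p$time_bin],
                               numeric(1L)),
                   vapply(peaks[sel], function(p) freqs[p$freq_bin],
                          numeric(1L)))[1L]]
  m <- events[[top]]
  p <- peaks[[top]]
  data.frame(n_events = nev,
             peak_power = p$power,
             peak_time_ms = times[p$time_bin] * 1000,
             peak_freq_hz = freqs[p$freq_bin],
             freq_range_hz = diff(range(freqs[m[, 1L]])),
             time_range_ms = diff(range(times[m[, 2L]])) * 1000)
}

#' Detect bursts in every trial of a TFR
#'
#' Runs [burst_mask()] and [cluster_events()] per trial on one channel,
#' returning per-trial burst parameters for a window and a table of all
#' event peaks (for recovery scoring).
#'
#' @param x a (normalized) `tfr_set`.
#' @param channel channel name or index.
#' @param window analysis window, seconds.
#' @param n_sd threshold in SD units.
#' @return list with `params` (data.frame, one row per trial, with
#'   `trial` column) and `events` (data.frame: trial, peak_time,
#'   peak_freq, peak_power for every detected event on the full grid).
#' @export
detect_bursts <- function(x, channel = 1L, window = c(-0.7, 0), n_sd = 2) {
  stopifnot(inherits(x, "tfr_set"))
  ci <- if (is.character(channel)) match(channel, x$channels) else channel
  nt <- dim(x$power)[1L]
  params <- vector("list", nt)
  evrows <- vector("list", nt)
  for (tr in seq_len(nt)) {
    p <- x$power[tr, ci, , ]
    mask <- burst_mask(p, x$freqs, x$times, n_sd = n_sd)
    ev <- cluster_events(mask)
    params[[tr]] <- cbind(trial = tr,
                          burst_parameters(ev, p, x$freqs, x$times, window))
    if (length(ev)) {
      pks <- lapply(ev, event_peak, power_ft = p)
      evrows[[tr]] <- data.frame(
        trial = tr,
        peak_time = x$times[vapply(pks, `[[`, integer(1L), "time_bin")],
        peak_freq = x$freqs[vapply(pks, `[[`, integer(1L), "freq_bin")],
        peak_power = vapply(pks, `[[`, numeric(1L), "power"))
    }
  }
  list(params = do.call(rbind, params),
       events = if (length(ev <- Filter(Negate(is.null), evrows)))
         do.call(rbind, ev)
       else data.frame(trial = integer(), peak_time = numeric(),
                       peak_freq = numeric(), peak_power = numeric()))
}

#' Score detected events against injected ground truth
#'
#' An injected burst counts as recovered when some detected event's peak
#' in the same trial lies within the tolerance of the burst center;
#' precision is the fraction of detected events matching some injection.
#'
#' @param events data.frame of detected events (`trial`, `peak_time`,
#'   `peak_freq`), e.g. from [detect_bursts()].
#' @param records injected burst records (`trial`, `time`, `freq`), e.g.
#'   from [inject_bursts()]; filter to one channel first.
#' @param tol_freq frequency tolerance, Hz.
#' @param tol_time time tolerance, seconds.
#' @return list with `recall` (NA when no injections), `precision`,
#'   `n_injected`, `n_events`.
#' @export
recover_injected <- function(events, records, tol_freq = 2, tol_time = 0.1) {
  n_inj <- nrow(records)
  n_ev <- nrow(events)
  if (n_inj == 0L)
    return(list(recall = NA_real_,
                precision = if (n_ev) 0 else NA_real_,
                n_injected = 0L, n_events = n_ev))
  if (n_ev == 0L)
    return(list(recall = 0, precision = NA_real_,
                n_injected = n_inj, n_events = 0L))
  hit_inj <- logical(n_inj)
  hit_ev <- logical(n_ev)
  for (i in seq_len(n_inj)) {
    same <- which(events$trial == records$trial[i] &
                    abs(events$peak_freq - records$freq[i]) <= tol_freq &
                    abs(events$peak_time - records$time[i]) <= tol_time)
    if (length(same)) {
      hit_inj[i] <- TRUE
      hit_ev[same] <- TRUE
    }
  }
  list(recall = mean(hit_inj), precision = mean(hit_ev),
       n_injected = n_inj, n_events = n_ev)
}
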