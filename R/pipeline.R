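#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: the simulation (or
#' input directories), the beta band, grids, analysis windows, and the
#' statistical parameters. Defaults mirror the analysis design: 700 ms
#' windows, 13-30 Hz at 0.5 Hz, TFR time grid -750..+250 ms at 20 ms with
#' a 250 ms window, 2 SD burst threshold, 1000 permutations, 100
#' shuffles, cluster-forming alpha 0.05.
#'
#' @param sim a `sim_config` used as the per-subject generative model
#'   (subject seeds are derived from `seed`), or `NULL` when
#'   `input_dirs` is given.
#' @param input_dirs optional character vector of per-subject dataset
#'   directories (see [write_dataset()]).
#' @param n_subjects number of simulated subjects.
#' @param band beta band, Hz.
#' @param foi TFR frequency grid, Hz.
#' @param toi TFR time grid, seconds.
#' @param tfr_window TFR sliding window, seconds.
#' @param window analysis (pretarget/precue) window, seconds.
#' @param pad_to spectral padding, seconds.
#' @param n_perm cluster permutations.
#' @param n_shuffles RT-correspondence shuffles.
#' @param alpha_cluster cluster-forming alpha.
#' @param burst_sd burst threshold, SD units.
#' @param smooth cross-spectral smoothing half-width, bins.
#' @param flatten apply temporal differentiation first (default TRUE).
#' @param out_dir optional directory for CSV tables and the run log.
#' @param seed master seed; all per-subject and statistical seeds derive
#'   from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dirs = NULL,
                            n_subjects = 10, band = c(13, 30),
                            foi = seq(13, 30, by = 0.5),
                            toi = seq(-0.75, 0.25, by = 0.02),
                            tfr_window = 0.25, window = c(-0.7, 0),
                            pad_to = 2, n_perm = 1000, n_shuffles = 100,
                            alpha_cluster = 0.05, burst_sd = 2,
                            smooth = 1L, flatten = TRUE, out_dir = NULL,
                            seed = 1L) {
  structure(list(sim = sim, input_dirs = input_dirs,
                 n_subjects = as.integer(n_subjects), band = band,
                 foi = foi, toi = toi, tfr_window = tfr_window,
                 window = window, pad_to = pad_to, n_perm = n_perm,
                 n_shuffles = n_shuffles, alpha_cluster = alpha_cluster,
                 burst_sd = burst_sd, smooth = smooth, flatten = flatten,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

burst_param_names <- c("n_events", "peak_power", "peak_time_ms",
                       "peak_freq_hz", "freq_range_hz", "time_range_ms")

#' Run all single-subject analyses on one dataset
#'
#' Executes differentiation, single-trial spectra, TFR (normalized per
#' region), burst detection, instantaneous frequency, RT regressions with
#' shuffled nulls, median splits, and median-split connectivity for one
#' subject's pretarget and precue epochs.
#'
#' @param dataset list with `pretarget` and `precue` `epoch_set`s (RTs
#'   attached to the pretarget set).
#' @param config a `pipeline_config`.
#' @param seed per-subject seed for the shuffled nulls.
#' @return a list of per-subject summaries consumed by [run_pipeline()].
#' @export
analyze_subject <- function(dataset, config, seed = 1L) {
  pre <- dataset$pretarget
  base <- dataset$precue
  rts <- pre$rts
  if (config$flatten) {
    pre <- differentiate(pre)
    base <- differentiate(base)
  }
  sp <- median_split(rts)
  out <- list()

  # single-trial spectra (beta grid) per window
  spec_pre <- fourier_spectra(pre, config$window, config$pad_to,
                              fmax = config$band[2L])
  spec_base <- fourier_spectra(base, config$window, config$pad_to,
                               fmax = config$band[2L])
  bidx <- which(spec_pre$freqs >= config$band[1L] - 1e-9)
  out$spec_freqs <- spec_pre$freqs[bidx]
  for (ch in seq_along(pre$channels)) {
    nm <- pre$channels[ch]
    out$logpow_pre[[nm]] <- colMeans(spec_pre$logpow[, ch, bidx])
    out$logpow_base[[nm]] <- colMeans(spec_base$logpow[, ch, bidx])
    out$logpow_slow[[nm]] <- colMeans(spec_pre$logpow[sp$slow, ch, bidx])
    out$logpow_fast[[nm]] <- colMeans(spec_pre$logpow[sp$fast, ch, bidx])
    out$peak_slow[[nm]] <- detect_beta_peak(
      colMeans(exp(spec_pre$logpow[sp$slow, ch, , drop = FALSE])[, 1L, ]),
      spec_pre$freqs, config$band)
    out$peak_fast[[nm]] <- detect_beta_peak(
      colMeans(exp(spec_pre$logpow[sp$fast, ch, , drop = FALSE])[, 1L, ]),
      spec_pre$freqs, config$band)
  }

  # TFR, band-limited power time courses, RT regression, bursts
  tfr_pre <- normalize_tfr(tfr(pre, config$foi, config$toi, config$tfr_window))
  tfr_base <- normalize_tfr(tfr(base, config$foi, config$toi, config$tfr_window))
  tsel <- which(tfr_pre$times >= config$window[1L] - 1e-9 &
                  tfr_pre$times <= config$window[2L] + 1e-9)
  out$power_times <- tfr_pre$times[tsel]
  for (ch in seq_along(pre$channels)) {
    nm <- pre$channels[ch]
    tc <- band_power_timecourse(tfr_pre, config$band, ch)[, tsel, drop = FALSE]
    out$power_tc_slow[[nm]] <- colMeans(tc[sp$slow, , drop = FALSE])
    out$power_tc_fast[[nm]] <- colMeans(tc[sp$fast, , drop = FALSE])
    reg <- regress_timecourse(tc, rts)
    out$power_slope[[nm]] <- reg$slope
    out$power_r2max[[nm]] <- reg$max_r2
    # shuffle seed kept distinct from the generator's stream seed
    out$power_null[[nm]] <- shuffled_null(tc, rts, config$n_shuffles,
                                          seed = (seed + 7919L * ch) %%
                                            .Machine$integer.max)
    bp <- detect_bursts(tfr_pre, ch, config$window, config$burst_sd)$params
    bb <- detect_bursts(tfr_base, ch, config$window, config$burst_sd)$params
    out$burst_pre[[nm]] <- colMeans(bp[burst_param_names], na.rm = TRUE)
    out$burst_base[[nm]] <- colMeans(bb[burst_param_names], na.rm = TRUE)
  }

  # instantaneous frequency
  bp_pre <- bandpass(pre, config$band)
  bp_base <- bandpass(base, config$band)
  for (ch in seq_along(pre$channels)) {
    nm <- pre$channels[ch]
    if_pre <- instantaneous_frequency(bp_pre, ch)
    if_base <- instantaneous_frequency(bp_base, ch)
    isel <- which(if_pre$valid & if_pre$times >= config$window[1L] &
                    if_pre$times <= config$window[2L])
    # common decimated grid keeps the group-level matrices small
    isel <- isel[seq(1L, length(isel), by = 6L)]
    out$if_times <- if_pre$times[isel]
    out$if_pre[[nm]] <- colMeans(if_pre$freq[, isel, drop = FALSE])
    out$if_base[[nm]] <- colMeans(if_base$freq[, isel, drop = FALSE])
    out$if_slow[[nm]] <- colMeans(if_pre$freq[sp$slow, isel, drop = FALSE])
    out$if_fast[[nm]] <- colMeans(if_pre$freq[sp$fast, isel, drop = FALSE])
    reg <- regress_timecourse(if_pre$freq[, isel, drop = FALSE], rts)
    out$if_slope[[nm]] <- reg$slope
    out$if_r2max[[nm]] <- reg$max_r2
    out$if_null[[nm]] <- shuffled_null(if_pre$freq[, isel, drop = FALSE],
                                       rts, config$n_shuffles,
                                       seed = (seed + 104729L * ch) %%
                                         .Machine$integer.max)
  }

  # median-split connectivity (motor = channel 1, auditory = channel 2)
  out$conn <- split_connectivity(pre, config$window, config$pad_to,
                                 config$band, config$smooth)
  out
}

# rbind data.frames with unequal columns, filling with NA
rbind_fill <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  do.call(rbind, lapply(lst, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[cols]
  }))
}

subject_matrix <- function(subjects, field, channel) {
  do.call(rbind, lapply(subjects, function(s) s[[field]][[channel]]))
}

cluster_rows <- function(contrast, region, axis, axis_values, test) {
  if (length(test$clusters) == 0L)
    return(data.frame(contrast = contrast, region = region, axis = axis,
                      cluster = 0L, extent = "", n_bins = 0L, stat = 0,
                      p = 1, d = 0))
  do.call(rbind, lapply(seq_along(test$clusters), function(k) {
    idx <- test$clusters[[k]]
    data.frame(contrast = contrast, region = region, axis = axis,
               cluster = k,
               extent = sprintf("%g..%g", axis_values[min(idx)],
                                axis_values[max(idx)]),
               n_bins = length(idx), stat = test$stats[k], p = test$p[k],
               d = test$d[k])
  }))
}

#' Run the full pipeline and assemble the results bundle
#'
#' Simulates (or loads) per-subject two-channel datasets and reproduces
#' the study's contrasts end to end: pretarget-vs-precue power spectra,
#' instantaneous frequency, and burst parameters; reaction-time contrasts
#' (median-split power spectra and time courses, regression slopes
#' against shuffled nulls, spectral peak frequencies); and median-split
#' beta connectivity (PPC and both directed Granger spectra). All
#' group-level tests are cluster-based permutation tests or paired
#' contrasts; every table row carries the contrast name, cluster extent,
#' statistic, p, and Cohen's d. Fully deterministic given the config
#' seed.
#'
#' @param config a `pipeline_config`.
#' @return a `results_bundle`: list of data.frames `power_tables`,
#'   `burst_table`, `rt_tables`, `connectivity_table`, per-subject
#'   summaries in `subjects`, and a `log` with seeds and timing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  set.seed(config$seed)
  n_sub <- if (!is.null(config$input_dirs)) length(config$input_dirs)
  else config$n_subjects
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_sub + 1L)
  stat_seed <- sub_seeds[n_sub + 1L]
  subjects <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    dataset <- if (!is.null(config$input_dirs))
      read_dataset(config$input_dirs[s])
    else {
      cfg_s <- config$sim
      cfg_s$seed <- sub_seeds[s]
      make_dataset(cfg_s)
    }
    subjects[[s]] <- analyze_subject(dataset, config, seed = sub_seeds[s])
  }
  regions <- names(subjects[[1L]]$logpow_pre)
  freqs <- subjects[[1L]]$spec_freqs
  ptimes <- subjects[[1L]]$power_times * 1000
  itimes <- subjects[[1L]]$if_times * 1000

  power_tables <- list(); rt_tables <- list(); burst_rows <- list()
  k <- 0L
  for (rg in regions) {
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "logpow_pre", rg),
                                   subject_matrix(subjects, "logpow_base", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    power_tables[[length(power_tables) + 1L]] <-
      cluster_rows("power_pretarget_vs_precue", rg, "frequency_hz", freqs, ct)
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "logpow_slow", rg),
                                   subject_matrix(subjects, "logpow_fast", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    power_tables[[length(power_tables) + 1L]] <-
      cluster_rows("power_slow_vs_fast", rg, "frequency_hz", freqs, ct)
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "power_tc_slow", rg),
                                   subject_matrix(subjects, "power_tc_fast", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    rt_tables[[length(rt_tables) + 1L]] <-
      cluster_rows("power_timecourse_slow_vs_fast", rg, "time_ms", ptimes, ct)
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "power_slope", rg),
                                   subject_matrix(subjects, "power_null", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    rows <- cluster_rows("power_rt_slope_vs_shuffled", rg, "time_ms", ptimes, ct)
    rows$mean_slope <- mean(subject_matrix(subjects, "power_slope", rg))
    rows$mean_max_r2 <- mean(unlist(lapply(subjects, function(s)
      s$power_r2max[[rg]])))
    rt_tables[[length(rt_tables) + 1L]] <- rows
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "if_pre", rg),
                                   subject_matrix(subjects, "if_base", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    power_tables[[length(power_tables) + 1L]] <-
      cluster_rows("instfreq_pretarget_vs_precue", rg, "time_ms", itimes, ct)
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "if_slow", rg),
                                   subject_matrix(subjects, "if_fast", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    rt_tables[[length(rt_tables) + 1L]] <-
      cluster_rows("instfreq_slow_vs_fast", rg, "time_ms", itimes, ct)
    k <- k + 1L
    ct <- cluster_permutation_test(subject_matrix(subjects, "if_slope", rg),
                                   subject_matrix(subjects, "if_null", rg),
                                   config$n_perm, config$alpha_cluster,
                                   seed = stat_seed + k)
    rows <- cluster_rows("instfreq_rt_slope_vs_shuffled", rg, "time_ms",
                         itimes, ct)
    rows$mean_slope <- mean(subject_matrix(subjects, "if_slope", rg))
    rows$mean_max_r2 <- mean(unlist(lapply(subjects, function(s)
      s$if_r2max[[rg]])))
    rt_tables[[length(rt_tables) + 1L]] <- rows

    # spectral peak frequency, slow vs fast (subjects lacking a peak in
    # either half are excluded from the contrast)
    pk_s <- unlist(lapply(subjects, function(s) s$peak_slow[[rg]]))
    pk_f <- unlist(lapply(subjects, function(s) s$peak_fast[[rg]]))
    ok <- is.finite(pk_s) & is.finite(pk_f)
    if (sum(ok) >= 3L) {
      pc <- paired_contrast(pk_s[ok], pk_f[ok])
      rt_tables[[length(rt_tables) + 1L]] <- data.frame(
        contrast = "beta_peak_slow_vs_fast", region = rg,
        axis = "subjects", cluster = NA_integer_,
        extent = sprintf("n=%d", sum(ok)), n_bins = sum(ok),
        stat = pc$statistic, p = pc$p, d = pc$d)
    }

    for (bp in burst_param_names) {
      a <- unlist(lapply(subjects, function(s) s$burst_pre[[rg]][[bp]]))
      b <- unlist(lapply(subjects, function(s) s$burst_base[[rg]][[bp]]))
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < 3L) next
      pc <- paired_contrast(a[ok], b[ok])
      burst_rows[[length(burst_rows) + 1L]] <- data.frame(
        contrast = paste0("burst_", bp, "_pretarget_vs_precue"),
        region = rg, statistic = pc$statistic, df = pc$df, p = pc$p,
        d = pc$d)
    }
  }

  conn_freqs <- subjects[[1L]]$conn$freq
  conn_tables <- list()
  specs <- list(ppc = c("ppc_slow", "ppc_fast"),
                gc_m2a = c("gc_m2a_slow", "gc_m2a_fast"),
                gc_a2m = c("gc_a2m_slow", "gc_a2m_fast"))
  for (nm in names(specs)) {
    k <- k + 1L
    A <- do.call(rbind, lapply(subjects, function(s) s$conn[[specs[[nm]][1L]]]))
    B <- do.call(rbind, lapply(subjects, function(s) s$conn[[specs[[nm]][2L]]]))
    ct <- cluster_permutation_test(A, B, config$n_perm,
                                   config$alpha_cluster,
                                   seed = stat_seed + k)
    conn_tables[[length(conn_tables) + 1L]] <-
      cluster_rows(paste0(nm, "_slow_vs_fast"), "auditory-motor",
                   "frequency_hz", conn_freqs, ct)
  }

  bundle <- structure(list(
    power_tables = rbind_fill(power_tables),
    burst_table = rbind_fill(burst_rows),
    rt_tables = rbind_fill(rt_tables),
    connectivity_table = rbind_fill(conn_tables),
    subjects = subjects,
    log = list(seed = config$seed, subject_seeds = sub_seeds[seq_len(n_sub)],
               n_subjects = n_sub, n_perm = config$n_perm,
               n_shuffles = config$n_shuffles,
               flatten = config$flatten,
               elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                               units = "secs")))),
    class = "results_bundle")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("power_tables", "burst_table", "rt_tables",
                 "connectivity_table"))
      utils::write.csv(bundle[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    writeLines(jsonlite::toJSON(bundle$log, auto_unbox = TRUE, digits = NA),
               file.path(config$out_dir, "run_log.json"))
  }
  bundle
}

#' Simulate a dataset from a YAML configuration and write it to disk
#'
#' Reads a `sim_config` from YAML (any subset of its fields), generates
#' the dataset, and writes the epoch containers and ground-truth JSON.
#'
#' @param config_path YAML file with `sim_config` fields.
#' @param out_dir output directory.
#' @param seed optional seed override.
#' @return the output directory, invisibly.
#' @export
simulate_command <- function(config_path, out_dir, seed = NULL) {
  fields <- tryCatch(yaml::read_yaml(config_path),
                     error = function(e) stop("config error: ",
                                              conditionMessage(e)))
  if (!is.list(fields)) stop("config error: YAML must map sim_config fields")
  known <- names(formals(sim_config))
  bad <- setdiff(names(fields), known)
  if (length(bad)) stop("config error: unknown field(s) ",
                        paste(bad, collapse = ", "))
  if (!is.null(seed)) fields$seed <- seed
  cfg <- do.call(sim_config, fields)
  write_dataset(make_dataset(cfg), out_dir)
  invisible(out_dir)
}
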