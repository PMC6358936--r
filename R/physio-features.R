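#' Detect R peaks in an ECG trace
#'
#' A dependency-free time-domain detector: the signal is detrended by
#' subtracting a centred moving average (window `detrend_s`, default
#' 0.6 s), an adaptive threshold is set at `threshold_frac` (default 0.5)
#' of the local signal maximum computed over a rolling context of about
#' `context_s` seconds (the current and previous 3-s block), and local
#' maxima above the threshold are kept subject to a refractory period
#' (default 0.2 s, i.e. a 300 bpm ceiling); within the refractory span the
#' larger candidate wins. The result is deterministic for fixed input.
#'
#' @param ecg A [channel_trace()] with channel `"ECG"`; rates of 50 Hz and
#'   above are recommended for usable R-R resolution.
#' @param refractory_s Minimum peak separation in seconds.
#' @param detrend_s Moving-average detrend window in seconds.
#' @param context_s Span of the adaptive-threshold context in seconds.
#' @param threshold_frac Fraction of the local maximum used as threshold.
#' @return An object of class `r_peak_series` with `peak_times` (strictly
#'   increasing, seconds), `indices` (1-based sample indices) and `fs`.
#' @export
detect_r_peaks <- function(ecg, refractory_s = 0.2, detrend_s = 0.6,
                           context_s = 3, threshold_frac = 0.5) {
  stopifnot(inherits(ecg, "channel_trace"))
  if (ecg$channel != "ECG") {
    stop(sprintf("expected an ECG trace, got %s", ecg$channel), call. = FALSE)
  }
  x <- ecg$values
  n <- length(x)
  if (n == 0L) stop("trace is empty", call. = FALSE)
  fs <- ecg$fs

  w <- max(3L, as.integer(round(detrend_s * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  if (n >= w) {
    baseline <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    # fill the half-window edges with the nearest interior baseline value
    h <- (w - 1L) %/% 2L
    baseline[seq_len(h)] <- baseline[h + 1L]
    baseline[(n - h + 1L):n] <- baseline[n - h]
  } else {
    baseline <- rep(mean(x), n)
  }
  d <- x - baseline

  # adaptive threshold: fraction of the max over the current + previous block
  block <- max(1L, as.integer(round(context_s * fs)))
  bid <- ((seq_len(n) - 1L) %/% block) + 1L
  bmax <- vapply(split(d, bid), max, 1)
  ctx <- pmax(bmax, c(bmax[1L], bmax[-length(bmax)]))
  thr <- threshold_frac * ctx[bid]

  is_peak <- d > 0 & d >= thr &
    d >= c(-Inf, d[-n]) & d > c(d[-1L], -Inf)
  cand <- which(is_peak)

  refr <- refractory_s * fs
  keep <- integer()
  for (i in cand) {
    if (length(keep) && (i - keep[length(keep)]) < refr) {
      if (d[i] > d[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep[[length(keep) + 1L]] <- i
    }
  }
  structure(
    list(peak_times = ecg$t0 + (keep - 1L) / fs, indices = keep, fs = fs),
    class = "r_peak_series"
  )
}

#' @export
print.r_peak_series <- function(x, ...) {
  cat(sprintf("<r_peak_series> %d peaks @ %g Hz\n", length(x$peak_times), x$fs))
  invisible(x)
}

#' Heart-rate-variability summary from an R-peak series
#'
#' Beat-to-beat (R-R) intervals are the successive differences of the peak
#' times. The summary reports the R-R sequence, its mean and sample
#' standard deviation, and the mean heart rate `60 / mean_rr` in beats per
#' minute. The statistics are invariant under a constant time shift of all
#' peaks.
#'
#' @param peaks An `r_peak_series` from [detect_r_peaks()] (or a numeric
#'   vector of peak times) with at least two peaks.
#' @return An object of class `hrv_summary` with `rr_intervals` (s),
#'   `mean_rr`, `sd_rr`, `mean_hr`, `n_beats`.
#' @export
compute_hrv <- function(peaks) {
  times <- if (inherits(peaks, "r_peak_series")) peaks$peak_times else as.numeric(peaks)
  if (length(times) < 2L) stop("need at least 2 peaks to form an R-R interval", call. = FALSE)
  if (any(diff(times) <= 0)) stop("peak times must be strictly increasing", call. = FALSE)
  rr <- diff(times)
  structure(
    list(rr_intervals = rr, mean_rr = mean(rr), sd_rr = sd0(rr),
         mean_hr = 60 / mean(rr), n_beats = length(times)),
    class = "hrv_summary"
  )
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf("<hrv_summary> %d beats: mean RR %.4f s (sd %.4f), mean HR %.1f bpm\n",
              x$n_beats, x$mean_rr, x$sd_rr, x$mean_hr))
  invisible(x)
}

#' Windowed summary of an EMG or GSR channel
#'
#' Groups the samples in sets of 20 (by default) and reports the mean and
#' sample standard deviation of each set together with the total mean and
#' standard deviation, in the channel's units. Amplitude summaries operate
#' on the raw signed samples; set `rectify = TRUE` to summarise absolute
#' values instead.
#'
#' @param trace A [channel_trace()] with channel `"EMG"` or `"GSR"`.
#' @param window Samples per set (default 20).
#' @param rectify Summarise absolute values (default `FALSE`).
#' @return An object of class `channel_summary`: `channel`, `units`,
#'   `window_stats`, `total_mean`, `total_sd`, `n`.
#' @export
summarize_channel <- function(trace, window = 20, rectify = FALSE) {
  stopifnot(inherits(trace, "channel_trace"))
  if (!trace$channel %in% c("EMG", "GSR")) {
    stop(sprintf("expected an EMG or GSR trace, got %s", trace$channel), call. = FALSE)
  }
  if (!length(trace$values)) stop("trace is empty", call. = FALSE)
  v <- if (rectify) abs(trace$values) else trace$values
  ws <- windowed_stats(v, window = window)
  structure(
    list(channel = trace$channel, units = trace$units,
         window_stats = ws$windows, total_mean = ws$total_mean,
         total_sd = ws$total_sd, n = ws$n),
    class = "channel_summary"
  )
}

#' @export
print.channel_summary <- function(x, ...) {
  cat(sprintf("<channel_summary> %s: %d samples, mean %.4g %s (sd %.4g), %d windows\n",
              x$channel, x$n, x$total_mean, x$units, x$total_sd,
              nrow(x$window_stats)))
  invisible(x)
}

#' Per-driver physiological means by state and scenario class
#'
#' For a set of sessions carrying physiological traces, computes per
#' driver, physiological state (rested/tired) and scenario class the mean
#' R-R interval recovered from the ECG, the mean EMG (mV) and the mean GSR
#' (kOhm). Sessions are combined within a group by duration-weighted
#' averaging. Purely descriptive: no hypothesis test is performed.
#'
#' @param sessions List of [driving_session()] objects whose `traces`
#'   include `ecg`, `emg` and `gsr` entries (missing channels yield `NA`
#'   in the corresponding column).
#' @param states Physiological states to compare (default rested/tired);
#'   every driver must contribute at least one session per compared state.
#' @param rectify_emg Use rectified EMG amplitudes (default `FALSE`).
#' @return Data frame with one row per (driver, state, scenario class).
#' @export
compare_states <- function(sessions, states = c("rested", "tired"),
                           rectify_emg = FALSE) {
  stopifnot(length(sessions) >= 1L)
  info <- data.frame(
    driver_id = vapply(sessions, function(s) s$driver_id, ""),
    physio_state = vapply(sessions, function(s) s$physio_state, ""),
    scenario_class = vapply(sessions, function(s) s$scenario_class, "")
  )
  for (d in unique(info$driver_id)) {
    have <- unique(info$physio_state[info$driver_id == d])
    miss <- setdiff(states, have)
    if (length(miss)) {
      stop(sprintf("driver %s has no session in state(s): %s",
                   d, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  keep <- info$physio_state %in% states
  groups <- split(which(keep), interaction(info$driver_id[keep],
                                           info$physio_state[keep],
                                           info$scenario_class[keep],
                                           drop = TRUE))
  rows <- lapply(groups, function(ix) {
    ss <- sessions[ix]
    dur <- vapply(ss, function(s) s$duration, 1)
    wmean <- function(vals) {
      ok <- !is.na(vals)
      if (!any(ok)) NA_real_ else sum(vals[ok] * dur[ok]) / sum(dur[ok])
    }
    rr <- vapply(ss, function(s) {
      if (is.null(s$traces$ecg)) return(NA_real_)
      pk <- detect_r_peaks(s$traces$ecg)
      if (length(pk$peak_times) < 2L) return(NA_real_)
      compute_hrv(pk)$mean_rr
    }, 1)
    emg <- vapply(ss, function(s) {
      if (is.null(s$traces$emg)) return(NA_real_)
      v <- s$traces$emg$values
      mean(if (rectify_emg) abs(v) else v)
    }, 1)
    gsr <- vapply(ss, function(s) {
      if (is.null(s$traces$gsr)) return(NA_real_)
      mean(s$traces$gsr$values)
    }, 1)
    data.frame(driver_id = ss[[1L]]$driver_id,
               physio_state = ss[[1L]]$physio_state,
               scenario_class = ss[[1L]]$scenario_class,
               mean_rr = wmean(rr), mean_emg = wmean(emg), mean_gsr = wmean(gsr),
               n_sessions = length(ss))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$driver_id, out$physio_state, out$scenario_class), , drop = FALSE]
}
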