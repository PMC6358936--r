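# Gyroscope-derived steering-wheel features. All event indices are 1-based
# (R convention); a zero-crossing event is indexed at the LATER sample of
# the sign-changing pair.

#' Integrate angular speed into steering-wheel position
#'
#' The wheel angle is accumulated one sample at a time:
#' `position[i] = position[i - 1] + values[i] / fs`, starting from
#' `initial`. At the gyroscope rate this is plain rectangular integration
#' of the angular speed.
#'
#' @param trace An [angular_speed_trace()].
#' @param initial Starting angle in degrees.
#' @return An object of class `position_trace` with fields `positions`
#'   (degrees, same length as the input), `fs` and `initial`.
#' @export
#' @examples
#' tr <- angular_speed_trace(rep(10.2, 10), fs = 10.2)
#' integrate_position(tr)$positions  # 1, 2, ..., 10 degrees
integrate_position <- function(trace, initial = 0) {
  stopifnot(inherits(trace, "angular_speed_trace"))
  stopifnot(is.numeric(initial), length(initial) == 1L, is.finite(initial))
  structure(
    list(positions = initial + cumsum(trace$values) / trace$fs,
         fs = trace$fs, initial = as.numeric(initial)),
    class = "position_trace"
  )
}

#' Count complete steering-wheel turns
#'
#' Walks the position stream; whenever the running (rebased) position
#' exceeds 360 degrees in absolute value, the complete-turn counter is
#' incremented and the position is rebased by subtracting a signed 360 so
#' that continuing rotation can register further turns. The per-sample
#' counter values are additionally summarised in consecutive windows of
#' `window` samples (mean and sample standard deviation) — at the 10.2 Hz
#' gyroscope rate a 20-sample window yields a summary roughly every 2 s.
#'
#' @param positions A `position_trace` from [integrate_position()], or an
#'   [angular_speed_trace()] (integrated from `initial`).
#' @param window Window length for the turn-count summaries (default 20).
#' @param initial Starting angle when `positions` is an angular-speed trace.
#' @return An object of class `turn_counter`: `complete_turns` (final
#'   count), `per_sample_turns` (counter value at each sample),
#'   `rebased_positions` (position after rebasing, degrees), and
#'   `window_stats` (see [windowed_stats()]).
#' @export
count_complete_turns <- function(positions, window = 20, initial = 0) {
  if (inherits(positions, "angular_speed_trace")) {
    positions <- integrate_position(positions, initial = initial)
  }
  stopifnot(inherits(positions, "position_trace"))
  p <- positions$positions
  n <- length(p)
  increments <- diff(c(positions$initial, p))
  pos <- positions$initial
  turns <- 0L
  rebased <- numeric(n)
  counts <- integer(n)
  for (i in seq_len(n)) {
    pos <- pos + increments[i]
    while (abs(pos) > 360) {
      turns <- turns + 1L
      pos <- pos - sign(pos) * 360
    }
    rebased[i] <- pos
    counts[i] <- turns
  }
  structure(
    list(complete_turns = turns, per_sample_turns = counts,
         rebased_positions = rebased,
         window_stats = windowed_stats(counts, window = window)),
    class = "turn_counter"
  )
}

#' Windowed mean and standard deviation of a sample stream
#'
#' Groups consecutive values into non-overlapping sets of `window` samples
#' and reports the mean and sample standard deviation of each complete set,
#' together with the cumulative mean and standard deviation over all
#' samples. An incomplete tail window is excluded from the windowed series
#' but still contributes to the cumulative statistics. This is the 20-sample
#' summary applied to EMG/GSR streams and to the turn counter.
#'
#' @param values Numeric vector.
#' @param window Samples per window, at least 2 (default 20).
#' @return A list: `windows` (data frame with columns `window`, `mean`,
#'   `sd`), `total_mean`, `total_sd`, `n`.
#' @export
windowed_stats <- function(values, window = 20) {
  if (!is.numeric(window) || length(window) != 1L || window < 2) {
    stop("`window` must be a single number >= 2", call. = FALSE)
  }
  window <- as.integer(window)
  values <- as.numeric(values)
  n <- length(values)
  k <- n %/% window
  if (k > 0L) {
    m <- matrix(values[seq_len(k * window)], nrow = window)
    win <- data.frame(window = seq_len(k),
                      mean = colMeans(m),
                      sd = apply(m, 2L, stats::sd))
  } else {
    win <- data.frame(window = integer(), mean = numeric(), sd = numeric())
  }
  list(windows = win,
       total_mean = if (n) mean(values) else NA_real_,
       total_sd = if (n) sd0(values) else NA_real_,
       n = n)
}

.bin_breaks <- c(0, 2.5, 5, 7.5, 10, Inf)

#' Five-interval histogram of absolute angular speed
#'
#' Each sample's absolute angular speed is assigned to exactly one of five
#' intervals (degrees/second): at least 10, 7.5-10, 5-7.5, 2.5-5, and below
#' 2.5. Boundaries are half-open, closed at the lower edge. Per interval the
#' count, the percentage of all samples, and the mean and sample standard
#' deviation of the absolute angular speed are reported (0 by convention for
#' empty or single-sample bins). Rows are ordered from the fastest interval
#' down.
#'
#' @param trace A non-empty [angular_speed_trace()].
#' @return Data frame of class `interval_histogram` with columns
#'   `interval`, `lower`, `upper`, `count`, `percentage`, `mean`, `sd`.
#' @export
bin_angular_speeds <- function(trace) {
  stopifnot(inherits(trace, "angular_speed_trace"))
  a <- abs(trace$values)
  n <- length(a)
  if (n == 0L) stop("trace is empty", call. = FALSE)
  idx <- findInterval(a, .bin_breaks)  # 1..5, [10, Inf) -> 5
  out <- data.frame(
    interval = c("[10,Inf)", "[7.5,10)", "[5,7.5)", "[2.5,5)", "[0,2.5)"),
    lower = rev(.bin_breaks[1:5]),
    upper = rev(.bin_breaks[2:6])
  )
  ord <- 5:1  # bin id (ascending speed) for each output row
  out$count <- vapply(ord, function(b) sum(idx == b), 1L)
  out$percentage <- 100 * out$count / n
  out$mean <- vapply(ord, function(b) if (any(idx == b)) mean(a[idx == b]) else 0, 1)
  out$sd <- vapply(ord, function(b) sd0(a[idx == b]), 1)
  class(out) <- c("interval_histogram", "data.frame")
  out
}

# Effective sign of each sample: zeros inherit the most recent nonzero
# sign; a leading run of zeros has effective sign 0 and cannot take part
# in a crossing.
effective_signs <- function(values) {
  s <- sign(values)
  nz <- s != 0
  last_nz <- cummax(ifelse(nz, seq_along(s), 0L))
  ifelse(last_nz > 0L, s[pmax(last_nz, 1L)], 0)
}

#' Count zero-crossing points of the angular speed
#'
#' Each sample is compared with the next; a crossing is an adjacent pair
#' whose effective signs are opposite. Zero-valued samples inherit the most
#' recent nonzero sign, so touching zero without changing direction does
#' not count. Frequent crossings are the signature of an alert driver
#' continuously correcting the wheel. The event index is the index of the
#' later sample of the pair (1-based).
#'
#' @param trace An [angular_speed_trace()] (or plain numeric vector).
#' @return List with `count` and `indices`.
#' @export
#' @examples
#' count_zero_crossings(angular_speed_trace(c(1, -1, 2, 3, -4), fs = 10.2))
count_zero_crossings <- function(trace) {
  values <- if (inherits(trace, "sensor_trace")) trace$values else as.numeric(trace)
  n <- length(values)
  if (n < 2L) return(list(count = 0L, indices = integer()))
  eff <- effective_signs(values)
  a <- eff[-n]
  b <- eff[-1L]
  idx <- which(a != 0 & b != 0 & a != b) + 1L
  list(count = length(idx), indices = idx)
}

#' Track the running maximum of the absolute angular speed
#'
#' The maximum absolute angular speed is tracked from the first sample
#' onward; an update event occurs at every sample whose absolute value
#' strictly exceeds the running maximum so far (the first sample is always
#' an update). Late, isolated maximum updates combined with an absence of
#' zero crossings are the signature of a drowsy driver making sudden hard
#' corrections.
#'
#' @param trace An [angular_speed_trace()] (or plain numeric vector) with
#'   at least one sample.
#' @return List with `max_abs` and `indices` (update events, 1-based).
#' @export
track_max_abs_speed <- function(trace) {
  values <- if (inherits(trace, "sensor_trace")) trace$values else as.numeric(trace)
  n <- length(values)
  if (n == 0L) stop("trace is empty", call. = FALSE)
  a <- abs(values)
  run_before <- c(-Inf, cummax(a)[-n])
  idx <- which(a > run_before)
  list(max_abs = max(a), indices = idx)
}

#' Classify five-second periods as possible low-attention driving
#'
#' The trace is partitioned into consecutive periods of
#' `floor(period_s * fs)` samples (an incomplete final period is dropped;
#' at 10.2 Hz and 5-s periods each full period holds exactly 51 samples).
#' A period is flagged as possible low attention when, over the period and
#' its predecessor taken together, there was no zero-crossing point AND at
#' least one update of the running maximum absolute angular speed. The
#' first period is evaluated over itself alone. Crossings are indexed at
#' the later sample of the pair, so a sign change across a period boundary
#' belongs to the later period.
#'
#' @param trace An [angular_speed_trace()].
#' @param period_s Period length in seconds (default 5).
#' @return Data frame of class `attention_periods`: `period` (1-based),
#'   `t_start`, `t_end`, `n_samples`, `has_zero_crossing`,
#'   `has_max_update`, `low_attention`.
#' @export
classify_low_attention <- function(trace, period_s = 5) {
  stopifnot(inherits(trace, "angular_speed_trace"))
  if (!is.numeric(period_s) || length(period_s) != 1L || period_s <= 0) {
    stop("`period_s` must be a single positive number", call. = FALSE)
  }
  np <- samples_in(period_s, trace$fs)
  if (np < 2L) stop("period must contain at least 2 samples", call. = FALSE)
  k <- length(trace$values) %/% np
  zc <- count_zero_crossings(trace)$indices
  mx <- track_max_abs_speed(trace)$indices
  in_period <- function(idx) {
    p <- ((idx - 1L) %/% np) + 1L
    tabulate(p[p <= k], nbins = k) > 0L
  }
  has_zc <- in_period(zc)
  has_mx <- in_period(mx)
  with_prev <- function(f) if (k == 0L) logical() else f | c(f[1L], f[-k])
  low <- !with_prev(has_zc) & with_prev(has_mx)
  structure(
    data.frame(period = seq_len(k),
               t_start = trace$t0 + (seq_len(k) - 1L) * np / trace$fs,
               t_end = trace$t0 + seq_len(k) * np / trace$fs,
               n_samples = rep(np, k),
               has_zero_crossing = has_zc,
               has_max_update = has_mx,
               low_attention = low),
    class = c("attention_periods", "data.frame")
  )
}

#' Full steering-feature report for an angular-speed trace
#'
#' Aggregates every gyroscope-derived feature into one deterministic
#' report: mean and standard deviation of the angular speed, zero-crossing
#' count and events, running maximum of the absolute angular speed and its
#' update events, the five-interval histogram, the complete-turn counter
#' with its 20-value summaries, and 20-sample windowed statistics of the
#' angular speed itself.
#'
#' @param trace A non-empty [angular_speed_trace()].
#' @param window Window length for the 20-sample summaries.
#' @param initial Initial wheel angle in degrees for position integration.
#' @return An object of class `steering_report`.
#' @export
steering_report <- function(trace, window = 20, initial = 0) {
  stopifnot(inherits(trace, "angular_speed_trace"))
  if (!length(trace$values)) stop("trace is empty", call. = FALSE)
  duration <- length(trace$values) / trace$fs
  zc <- count_zero_crossings(trace)
  mx <- track_max_abs_speed(trace)
  structure(
    list(n = length(trace$values), fs = trace$fs, duration = duration,
         mean_w = mean(trace$values), sd_w = sd0(trace$values),
         zero_crossings = zc, max_abs = mx,
         histogram = bin_angular_speeds(trace),
         turns = count_complete_turns(trace, window = window, initial = initial),
         window_stats = windowed_stats(trace$values, window = window)),
    class = "steering_report"
  )
}

#' @export
print.steering_report <- function(x, digits = 4, ...) {
  cat(sprintf("<steering_report> %d samples @ %g Hz (%.1f s)\n", x$n, x$fs, x$duration))
  cat(sprintf("  angular speed: mean %.*g, sd %.*g deg/s\n",
              digits, x$mean_w, digits, x$sd_w))
  cat(sprintf("  zero crossings: %d (%.3g per s)\n",
              x$zero_crossings$count, x$zero_crossings$count / x$duration))
  cat(sprintf("  max |angular speed|: %.*g deg/s (%d updates)\n",
              digits, x$max_abs$max_abs, length(x$max_abs$indices)))
  cat(sprintf("  complete turns: %d\n", x$turns$complete_turns))
  cat("  interval histogram (%):",
      paste(sprintf("%s %.1f", x$histogram$interval, x$histogram$percentage),
            collapse = ", "), "\n")
  invisible(x)
}
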