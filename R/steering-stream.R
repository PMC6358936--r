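#' Streaming steering-feature tracker
#'
#' Sample-at-a-time evaluation of every steering feature, as an on-line
#' monitor would run it: feed samples with `$update()`, read the current
#' state with `$report()`. On identical input, `$report()` is identical to
#' the batch [steering_report()] (up to floating-point accumulation on the
#' order of 1e-12).
#'
#' Internally the tracker keeps Welford accumulators for the global and
#' per-bin moments, the running position/turn counter, the effective-sign
#' state for crossing detection, the running maximum, and one partial
#' window buffer each for the angular-speed and turn-count summaries.
#'
#' @param fs Sampling rate in Hz.
#' @param window Window length for the 20-sample summaries.
#' @param initial Initial wheel angle in degrees.
#' @param t0 Session-relative start time (s) of the first sample.
#' @return An object of class `steering_tracker`: a list of closures
#'   `update(values)` (accepts one sample or a chunk), `report()`, and
#'   `attention(period_s)` (current [classify_low_attention()] table).
#' @export
#' @examples
#' trk <- steering_tracker(fs = 10.2)
#' for (v in c(1, -1, 2, 3, -4)) trk$update(v)
#' trk$report()$zero_crossings$count
steering_tracker <- function(fs, window = 20, initial = 0, t0 = 0) {
  fs <- assert_fs(fs)
  window <- as.integer(window)
  if (window < 2L) stop("`window` must be >= 2", call. = FALSE)

  n <- 0L
  # Welford state: global signed speed, per-bin absolute speed
  g_mean <- 0; g_m2 <- 0
  b_n <- integer(5); b_mean <- numeric(5); b_m2 <- numeric(5)
  # crossings / running max
  last_sign <- 0; zc_idx <- integer()
  run_max <- -Inf; mx_idx <- integer()
  # position / turns
  pos <- initial; turns <- 0L
  # window buffers (angular speed, turn counts) and emitted window rows
  wbuf <- numeric(0); w_rows <- list()
  tbuf <- numeric(0); t_rows <- list()
  # cumulative turn-count moments
  t_mean <- 0; t_m2 <- 0

  welford <- function(mean, m2, k, x) {
    d <- x - mean
    mean <- mean + d / k
    list(mean = mean, m2 = m2 + d * (x - mean))
  }

  update_one <- function(v) {
    if (!is.finite(v)) {
      stop(sprintf("non-finite angular-speed sample at index %d", n + 1L), call. = FALSE)
    }
    n <<- n + 1L
    w <- welford(g_mean, g_m2, n, v); g_mean <<- w$mean; g_m2 <<- w$m2
    a <- abs(v)
    b <- findInterval(a, .bin_breaks)
    b_n[b] <<- b_n[b] + 1L
    w <- welford(b_mean[b], b_m2[b], b_n[b], a)
    b_mean[b] <<- w$mean; b_m2[b] <<- w$m2
    s <- sign(v)
    if (s != 0) {
      if (last_sign != 0 && s != last_sign) zc_idx[[length(zc_idx) + 1L]] <<- n
      last_sign <<- s
    }
    if (a > run_max) {
      run_max <<- a
      mx_idx[[length(mx_idx) + 1L]] <<- n
    }
    pos <<- pos + v / fs
    while (abs(pos) > 360) {
      turns <<- turns + 1L
      pos <<- pos - sign(pos) * 360
    }
    w <- welford(t_mean, t_m2, n, turns); t_mean <<- w$mean; t_m2 <<- w$m2
    wbuf[[length(wbuf) + 1L]] <<- v
    if (length(wbuf) == window) {
      w_rows[[length(w_rows) + 1L]] <<- c(mean(wbuf), stats::sd(wbuf))
      wbuf <<- numeric(0)
    }
    tbuf[[length(tbuf) + 1L]] <<- turns
    if (length(tbuf) == window) {
      t_rows[[length(t_rows) + 1L]] <<- c(mean(tbuf), stats::sd(tbuf))
      tbuf <<- numeric(0)
    }
    invisible(NULL)
  }

  win_df <- function(rows) {
    if (!length(rows)) {
      return(data.frame(window = integer(), mean = numeric(), sd = numeric()))
    }
    m <- do.call(rbind, rows)
    data.frame(window = seq_along(rows), mean = m[, 1L], sd = m[, 2L])
  }
  wsd <- function(m2, k) if (k <= 1L) 0 else sqrt(m2 / (k - 1L))

  report <- function() {
    if (n == 0L) stop("no samples seen yet", call. = FALSE)
    hist <- data.frame(
      interval = c("[10,Inf)", "[7.5,10)", "[5,7.5)", "[2.5,5)", "[0,2.5)"),
      lower = rev(.bin_breaks[1:5]), upper = rev(.bin_breaks[2:6]),
      count = b_n[5:1], percentage = 100 * b_n[5:1] / n,
      mean = ifelse(b_n[5:1] > 0L, b_mean[5:1], 0),
      sd = vapply(5:1, function(b) wsd(b_m2[b], b_n[b]), 1))
    class(hist) <- c("interval_histogram", "data.frame")
    structure(
      list(n = n, fs = fs, duration = n / fs,
           mean_w = g_mean, sd_w = wsd(g_m2, n),
           zero_crossings = list(count = length(zc_idx), indices = zc_idx),
           max_abs = list(max_abs = run_max, indices = mx_idx),
           histogram = hist,
           turns = structure(list(complete_turns = turns,
                                  window_stats = list(windows = win_df(t_rows),
                                                      total_mean = t_mean,
                                                      total_sd = wsd(t_m2, n),
                                                      n = n)),
                             class = "turn_counter"),
           window_stats = list(windows = win_df(w_rows),
                               total_mean = g_mean, total_sd = wsd(g_m2, n),
                               n = n)),
      class = "steering_report")
  }

  attention <- function(period_s = 5) {
    np <- samples_in(period_s, fs)
    if (np < 2L) stop("period must contain at least 2 samples", call. = FALSE)
    k <- n %/% np
    in_period <- function(idx) {
      p <- ((idx - 1L) %/% np) + 1L
      tabulate(p[p <= k], nbins = k) > 0L
    }
    has_zc <- in_period(zc_idx)
    has_mx <- in_period(mx_idx)
    with_prev <- function(f) if (k == 0L) logical() else f | c(f[1L], f[-k])
    structure(
      data.frame(period = seq_len(k),
                 t_start = t0 + (seq_len(k) - 1L) * np / fs,
                 t_end = t0 + seq_len(k) * np / fs,
                 n_samples = rep(np, k),
                 has_zero_crossing = has_zc, has_max_update = has_mx,
                 low_attention = !with_prev(has_zc) & with_prev(has_mx)),
      class = c("attention_periods", "data.frame"))
  }

  structure(
    list(update = function(values) {
           for (v in as.numeric(values)) update_one(v)
           invisible(NULL)
         },
         report = report,
         attention = attention,
         n_seen = function() n),
    class = "steering_tracker"
  )
}

#' @export
print.steering_tracker <- function(x, ...) {
  cat(sprintf("<steering_tracker> %d samples seen\n", x$n_seen()))
  invisible(x)
}
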