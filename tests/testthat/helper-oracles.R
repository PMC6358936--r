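# Independent brute-force oracles, deliberately written as plain per-sample
# loops so they share no code path with the package implementation.

oracle_position <- function(values, fs, initial = 0) {
  out <- numeric(length(values))
  prev <- initial
  for (i in seq_along(values)) {
    prev <- prev + values[i] / fs
    out[i] <- prev
  }
  out
}

oracle_turns <- function(values, fs, initial = 0) {
  pos <- initial
  turns <- 0L
  for (v in values) {
    pos <- pos + v / fs
    while (abs(pos) > 360) {
      turns <- turns + 1L
      pos <- pos - sign(pos) * 360
    }
  }
  list(turns = turns, final_pos = pos)
}

oracle_mean_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- if (n <= 1) 0 else sqrt(sum((x - m)^2) / (n - 1))
  c(mean = m, sd = s)
}

oracle_zero_crossings <- function(values) {
  last <- 0
  idx <- integer()
  for (i in seq_along(values)) {
    s <- sign(values[i])
    if (s != 0) {
      if (last != 0 && s != last) idx <- c(idx, i)
      last <- s
    }
  }
  list(count = length(idx), indices = idx)
}

oracle_max_updates <- function(values) {
  best <- -Inf
  idx <- integer()
  for (i in seq_along(values)) {
    if (abs(values[i]) > best) {
      best <- abs(values[i])
      idx <- c(idx, i)
    }
  }
  list(max_abs = best, indices = idx)
}

oracle_bins <- function(values) {
  counts <- integer(5)  # ascending: [0,2.5) [2.5,5) [5,7.5) [7.5,10) [10,Inf)
  for (v in abs(values)) {
    b <- if (v < 2.5) 1 else if (v < 5) 2 else if (v < 7.5) 3 else if (v < 10) 4 else 5
    counts[b] <- counts[b] + 1L
  }
  counts
}

# Independent period-by-period re-evaluation of the low-attention rule.
oracle_low_attention <- function(values, fs, period_s = 5) {
  np <- floor(period_s * fs + 1e-9)
  k <- length(values) %/% np
  zc <- oracle_zero_crossings(values)$indices
  mx <- oracle_max_updates(values)$indices
  flags <- logical(k)
  for (p in seq_len(k)) {
    span <- if (p == 1) c(1, np) else c((p - 2) * np + 1, p * np)
    any_zc <- any(zc >= span[1] & zc <= span[2])
    any_mx <- any(mx >= span[1] & mx <= span[2])
    flags[p] <- !any_zc && any_mx
  }
  flags
}

# Random test traces, including exact zeros and zero runs.
random_trace <- function(n, fs = 10.2, zero_frac = 0.2) {
  v <- runif(n, -20, 20)
  v[runif(n) < zero_frac] <- 0
  angular_speed_trace(v, fs = fs)
}

make_test_session <- function(seed = 1, duration = 30, physio = FALSE) {
  simulate_session(driver_profile(sprintf("d%02d", seed), seed = seed),
                   duration = duration, include_physio = physio)
}
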