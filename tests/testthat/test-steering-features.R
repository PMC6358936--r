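test_that("position integration accumulates angular speed over the sampling rate", {
  # constant 10.2 deg/s at 10.2 Hz adds exactly 1 degree per sample
  p <- integrate_position(angular_speed_trace(rep(10.2, 10), 10.2))
  expect_equal(p$positions, 1:10)
  expect_equal(tail(p$positions, 1), 10)

  p2 <- integrate_position(angular_speed_trace(rep(0, 25), 50.2), initial = 37)
  expect_true(all(p2$positions == 37))

  withr::with_seed(42, {
    for (rep in 1:5) {
      v <- runif(200, -20, 20)
      tr <- angular_speed_trace(v, fs = 10.2)
      expect_equal(integrate_position(tr, initial = 5)$positions,
                   oracle_position(v, 10.2, 5), tolerance = 1e-9)
    }
  })
})

test_that("complete turns count threshold crossings of the rebased position", {
  fs <- 10.2
  # 11 samples of 36 deg each -> position 396 -> one turn, rebased to 36
  tc <- count_complete_turns(angular_speed_trace(rep(36 * fs, 11), fs))
  expect_equal(tc$complete_turns, 1L)
  expect_equal(tail(tc$rebased_positions, 1), 36, tolerance = 1e-9)
  expect_equal(tc$per_sample_turns, c(rep(0L, 10), 1L))

  # oscillation between +350 and -350 never exceeds the threshold
  osc <- c(350, rep(c(-700, 700), 10)) * fs
  expect_equal(count_complete_turns(angular_speed_trace(osc, fs))$complete_turns, 0L)

  # drifting sawtooth that repeatedly exceeds the turn threshold
  saw <- rep(c(rep(120, 4), rep(-120, 2)), 10) * fs  # net +240 deg per cycle
  got <- count_complete_turns(angular_speed_trace(saw, fs))
  orc <- oracle_turns(saw, fs)
  expect_equal(got$complete_turns, orc$turns)
  expect_gte(got$complete_turns, 5L)
  expect_equal(tail(got$rebased_positions, 1), orc$final_pos, tolerance = 1e-9)

  # counter is non-decreasing and random traces agree with the oracle
  withr::with_seed(7, {
    for (rep in 1:5) {
      v <- runif(300, -900, 900)
      got <- count_complete_turns(angular_speed_trace(v, fs))
      expect_true(all(diff(got$per_sample_turns) >= 0L))
      expect_equal(got$complete_turns, oracle_turns(v, fs)$turns)
    }
  })
})

test_that("windowed statistics follow the 20-sample grouping contract", {
  ws <- windowed_stats(rep(7, 40), window = 20)
  expect_equal(nrow(ws$windows), 2L)
  expect_equal(ws$windows$mean, c(7, 7))
  expect_equal(ws$windows$sd, c(0, 0))
  expect_equal(ws$total_mean, 7)
  expect_equal(ws$total_sd, 0)

  ws2 <- windowed_stats(1:20, window = 20)
  orc <- oracle_mean_sd(1:20)
  expect_equal(ws2$windows$mean, unname(orc["mean"]))
  expect_equal(ws2$windows$sd, unname(orc["sd"]))

  # 19 values: no complete window, but cumulative stats exist
  ws3 <- windowed_stats(1:19, window = 20)
  expect_equal(nrow(ws3$windows), 0L)
  expect_equal(ws3$total_mean, 10)
  expect_error(windowed_stats(1:10, window = 1), ">= 2")
})

test_that("angular-speed histogram classifies each sample into one of five intervals", {
  h <- bin_angular_speeds(angular_speed_trace(c(11, 8, 6, 3, 1), 10.2))
  expect_equal(h$count, rep(1L, 5))
  expect_equal(h$percentage, rep(20, 5))
  expect_equal(h$interval[1], "[10,Inf)")

  h0 <- bin_angular_speeds(angular_speed_trace(rep(0, 30), 10.2))
  expect_equal(h0$percentage, c(0, 0, 0, 0, 100))
  expect_equal(h0$mean, rep(0, 5))

  expect_error(bin_angular_speeds(angular_speed_trace(numeric(), 10.2)), "empty")

  withr::with_seed(11, {
    for (rep in 1:5) {
      v <- runif(500, -15, 15)
      h <- bin_angular_speeds(angular_speed_trace(v, 10.2))
      expect_equal(rev(h$count), oracle_bins(v))
      expect_equal(sum(h$count), 500L)
      expect_equal(sum(h$percentage), 100, tolerance = 1e-9)
      # per-bin means lie inside the bin hull
      nz <- h$count > 0
      expect_true(all(h$mean[nz] >= h$lower[nz] - 1e-12))
      expect_true(all(h$mean[nz] <= h$upper[nz] + 1e-12))
    }
  })
})

test_that("zero crossings use sign inheritance through exact zeros", {
  got <- count_zero_crossings(angular_speed_trace(c(1, -1, 2, 3, -4), 10.2))
  expect_equal(got$count, 3L)
  expect_equal(got$indices, c(2L, 3L, 5L))

  expect_equal(count_zero_crossings(angular_speed_trace(abs(rnorm(50)) + 1, 10.2))$count, 0L)

  # zeros inherit the last nonzero sign; leading zeros are signless
  expect_equal(count_zero_crossings(c(0, 0, 1, 0, 0, -1))$indices, 6L)
  expect_equal(count_zero_crossings(c(0, 0, 0))$count, 0L)
  expect_equal(count_zero_crossings(c(1, 0, 1, 0, -1))$indices, 5L)

  withr::with_seed(13, {
    for (rep in 1:10) {
      tr <- random_trace(300)
      got <- count_zero_crossings(tr)
      orc <- oracle_zero_crossings(tr$values)
      expect_equal(got$count, orc$count)
      expect_equal(got$indices, orc$indices)
      # sign symmetry
      flipped <- count_zero_crossings(angular_speed_trace(-tr$values, tr$fs))
      expect_equal(flipped$count, got$count)
    }
  })
})

test_that("running maximum updates are tracked from the first sample", {
  got <- track_max_abs_speed(angular_speed_trace(c(1, -5, 3), 10.2))
  expect_equal(got$max_abs, 5)
  expect_equal(got$indices, c(1L, 2L))

  const <- track_max_abs_speed(angular_speed_trace(rep(2.5, 40), 10.2))
  expect_equal(const$indices, 1L)

  withr::with_seed(17, {
    for (rep in 1:10) {
      tr <- random_trace(300)
      got <- track_max_abs_speed(tr)
      orc <- oracle_max_updates(tr$values)
      expect_equal(got$max_abs, orc$max_abs)
      expect_equal(got$indices, orc$indices)
      expect_true(all(got$max_abs >= abs(tr$values)))
      # invariant under sign flip
      expect_equal(track_max_abs_speed(-tr$values)$max_abs, got$max_abs)
    }
  })
})

test_that("low-attention periods follow the 5-second window rule", {
  # 10.2 Hz, 5 s periods: every full period holds exactly 51 samples
  tr <- simulate_steering(driver_profile(seed = 1), 30)
  la <- classify_low_attention(tr, period_s = 5)
  expect_true(all(la$n_samples == 51L))
  expect_equal(nrow(la), 6L)

  # a sign change in every period -> no low-attention period anywhere
  alt <- angular_speed_trace(rep(c(1, -1), 200), fs = 10.2)
  expect_false(any(classify_low_attention(alt)$low_attention))

  # quiescent 12 s then a single large spike: flags match the period oracle
  quiet <- c(rep(0.1, 123), 40, rep(0.1, 80))
  tr2 <- angular_speed_trace(quiet, fs = 10.2)
  la2 <- classify_low_attention(tr2)
  expect_equal(la2$low_attention, oracle_low_attention(quiet, 10.2))
  expect_true(any(la2$low_attention))

  withr::with_seed(19, {
    for (rep in 1:8) {
      tr3 <- simulate_steering(driver_profile(attention = "drowsy", seed = rep), 40)
      la3 <- classify_low_attention(tr3)
      expect_equal(la3$low_attention, oracle_low_attention(tr3$values, 10.2))
      # low attention implies no crossing in the period or its predecessor
      prev <- c(la3$has_zero_crossing[1],
                la3$has_zero_crossing[-nrow(la3)])
      expect_true(all(!la3$has_zero_crossing[la3$low_attention]))
      expect_true(all(!prev[la3$low_attention]))
    }
  })

  expect_error(classify_low_attention(tr, period_s = 0.05), "at least 2")
})

test_that("the steering report composes all features consistently", {
  zero <- angular_speed_trace(rep(0, 612), fs = 10.2)  # one quiet minute
  rep0 <- steering_report(zero)
  expect_equal(rep0$mean_w, 0)
  expect_equal(rep0$sd_w, 0)
  expect_equal(rep0$zero_crossings$count, 0L)
  expect_equal(rep0$max_abs$max_abs, 0)
  expect_equal(rep0$histogram$percentage, c(0, 0, 0, 0, 100))
  expect_equal(rep0$turns$complete_turns, 0L)

  tr <- simulate_steering(driver_profile(seed = 23), 60)
  rp <- steering_report(tr)
  expect_equal(rp$mean_w, mean(tr$values))
  expect_equal(rp$sd_w, sd(tr$values))
  expect_equal(rp$zero_crossings, count_zero_crossings(tr))
  expect_equal(rp$max_abs, track_max_abs_speed(tr))
  expect_equal(rp$histogram, bin_angular_speeds(tr))
  expect_equal(rp$turns$complete_turns,
               count_complete_turns(tr)$complete_turns)
})

test_that("streaming and batch evaluation agree sample for sample", {
  withr::with_seed(29, {
    for (rep in 1:3) {
      v <- runif(500, -50, 50) * sample(c(0, 1), 500, replace = TRUE, prob = c(0.1, 0.9))
      tr <- angular_speed_trace(v, fs = 10.2)
      batch <- steering_report(tr)
      trk <- steering_tracker(fs = 10.2)
      for (x in v) trk$update(x)
      stream <- trk$report()
      expect_equal(stream$mean_w, batch$mean_w)
      expect_equal(stream$sd_w, batch$sd_w)
      expect_equal(as.integer(stream$zero_crossings$indices),
                   batch$zero_crossings$indices)
      expect_equal(as.integer(stream$max_abs$indices), batch$max_abs$indices)
      expect_equal(stream$max_abs$max_abs, batch$max_abs$max_abs)
      expect_equal(stream$histogram$count, batch$histogram$count)
      expect_equal(stream$histogram$mean, batch$histogram$mean)
      expect_equal(stream$histogram$sd, batch$histogram$sd)
      expect_equal(stream$turns$complete_turns, batch$turns$complete_turns)
      expect_equal(stream$turns$window_stats$windows$mean,
                   batch$turns$window_stats$windows$mean)
      expect_equal(stream$turns$window_stats$windows$sd,
                   batch$turns$window_stats$windows$sd)
      expect_equal(stream$window_stats$windows$mean, batch$window_stats$windows$mean)
      expect_equal(stream$window_stats$windows$sd, batch$window_stats$windows$sd)
      expect_equal(trk$attention(5)$low_attention,
                   classify_low_attention(tr, 5)$low_attention)
    }
  })
})
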