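#' Synthetic driver profile
#'
#' Parameters of one simulated driver. The two steering regimes encode the
#' accepted behavioural contrast: an alert driver continuously corrects the
#' wheel (many zero crossings, modest angular speeds), while a drowsy
#' driver lets the wheel sit near-still and then makes rare, large
#' corrective spikes (few zero crossings, larger maximum absolute angular
#' speed). The tired physiological state raises EMG amplitude
#' multiplicatively and shifts GSR upward.
#'
#' @param driver_id Driver identifier.
#' @param attention `"alert"` or `"drowsy"` steering regime.
#' @param physio_state `"rested"` or `"tired"`.
#' @param correction_rate Mean steering-correction events per second
#'   (default 2.0 when alert, 0.3 when drowsy).
#' @param spike_amplitude Scale of drowsy corrective spikes, deg/s.
#' @param steering_scale Multiplier on the alert-regime correction
#'   amplitudes (models between-driver steering vigour; default 1).
#' @param emg_gain_tired Multiplicative EMG amplitude factor in tired state.
#' @param gsr_shift_tired Additive GSR offset in tired state, kOhm.
#' @param base_hr Baseline heart rate, beats/min.
#' @param offence_rate Mean traffic offences per second.
#' @param seed Integer seed; the same profile and seed reproduce every
#'   simulated output bit for bit.
#' @return An object of class `driver_profile`.
#' @export
driver_profile <- function(driver_id = "d001",
                           attention = c("alert", "drowsy"),
                           physio_state = c("rested", "tired"),
                           correction_rate = NULL,
                           spike_amplitude = 30,
                           steering_scale = 1,
                           emg_gain_tired = 1.8,
                           gsr_shift_tired = 50,
                           base_hr = 70,
                           offence_rate = 0.05,
                           seed = 1L) {
  attention <- match.arg(attention)
  physio_state <- match.arg(physio_state)
  correction_rate <- correction_rate %||% if (attention == "alert") 2.0 else 0.3
  stopifnot(correction_rate >= 0, spike_amplitude >= 0, steering_scale > 0,
            emg_gain_tired > 0, gsr_shift_tired >= 0, base_hr > 0,
            offence_rate >= 0)
  structure(
    list(driver_id = as.character(driver_id), attention = attention,
         physio_state = physio_state, correction_rate = correction_rate,
         spike_amplitude = spike_amplitude, steering_scale = steering_scale,
         emg_gain_tired = emg_gain_tired, gsr_shift_tired = gsr_shift_tired,
         base_hr = base_hr, offence_rate = offence_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "driver_profile"
  )
}

#' @export
print.driver_profile <- function(x, ...) {
  cat(sprintf("<driver_profile> %s: %s / %s, corrections %.2g/s, offences %.3g/s, seed %s\n",
              x$driver_id, x$attention, x$physio_state, x$correction_rate,
              x$offence_rate, x$seed %||% "none"))
  invisible(x)
}

# Add half-sine pulses of the given width to x at sample positions `at`.
add_pulses <- function(x, at, amps, width_s, fs) {
  L <- max(1L, as.integer(round(width_s * fs)))
  shape <- sin(pi * seq_len(L) / (L + 1L))
  n <- length(x)
  for (j in seq_along(at)) {
    ix <- at[j]:min(n, at[j] + L - 1L)
    x[ix] <- x[ix] + amps[j] * shape[seq_along(ix)]
  }
  x
}

#' Simulate a steering angular-speed trace
#'
#' Alert regime: zero-mean Gaussian micro-corrections (sd 2 deg/s, scaled
#' by `steering_scale`) plus Poisson-timed correction pulses, giving many
#' zero crossings. Drowsy regime: near-still wheel — a slowly wandering
#' drift of piecewise-constant sign with small smooth noise (sd 0.2 deg/s)
#' — interrupted by rare large corrective spikes of amplitude about
#' `spike_amplitude`, giving few zero crossings and a larger maximum
#' absolute angular speed.
#'
#' @param profile A [driver_profile()].
#' @param duration Trace length in seconds.
#' @param fs Sampling rate in Hz (default 10.2, the gyroscope rate).
#' @return An [angular_speed_trace()] with `floor(duration * fs)` samples.
#' @export
#' @examples
#' tr <- simulate_steering(driver_profile("a", "alert", seed = 7), 60)
#' length(tr$values)  # 612 samples at 10.2 Hz
simulate_steering <- function(profile, duration, fs = 10.2) {
  stopifnot(inherits(profile, "driver_profile"))
  fs <- assert_fs(fs)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a single positive number", call. = FALSE)
  }
  n <- samples_in(duration, fs)
  if (n < 1L) stop("duration * fs must be at least 1 sample", call. = FALSE)
  with_seed(profile$seed, {
    if (profile$attention == "alert") {
      x <- stats::rnorm(n, 0, 2 * profile$steering_scale)
      n_ev <- stats::rpois(1L, profile$correction_rate * duration)
      if (n_ev > 0L) {
        at <- sort(sample.int(n, n_ev, replace = TRUE))
        amps <- sample(c(-1, 1), n_ev, replace = TRUE) *
          stats::runif(n_ev, 3, 8) * profile$steering_scale
        x <- add_pulses(x, at, amps, width_s = 0.3, fs = fs)
      }
    } else {
      # piecewise-constant drift: the un-corrected wheel creeps one way,
      # then the other, for stretches of ~10 s
      drift <- numeric(n)
      i <- 1L
      while (i <= n) {
        len <- max(1L, as.integer(round(stats::rexp(1L, 1 / 10) * fs)))
        drift[i:min(n, i + len - 1L)] <-
          sample(c(-1, 1), 1L) * stats::runif(1L, 0.4, 1.0)
        i <- i + len
      }
      ar <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.2 * sqrt(1 - 0.9^2)),
                                     0.9, method = "recursive"))
      x <- drift + ar
      n_sp <- stats::rpois(1L, profile$correction_rate * duration)
      if (n_sp > 0L) {
        at <- sort(sample.int(n, n_sp, replace = TRUE))
        # the corrective jerk continues the wheel's current creep direction
        # (a hard turn from near-zero speed, without a sign change)
        amps <- sign(drift[at]) *
          profile$spike_amplitude * stats::runif(n_sp, 0.8, 1.2)
        x <- add_pulses(x, at, amps, width_s = 0.5, fs = fs)
      }
    }
    angular_speed_trace(x, fs = fs)
  })
}

# Raised-cosine ECG beat template: dominant R spike plus a small T bump.
ecg_template_at <- function(n, fs, peak_times, r_amp = 1) {
  x <- numeric(n)
  bump <- function(x, centre_i, width_s, amp) {
    half <- max(1L, as.integer(round(width_s * fs / 2)))
    ix <- max(1L, centre_i - half):min(n, centre_i + half)
    x[ix] <- x[ix] + amp * 0.5 * (1 + cos(pi * (ix - centre_i) / half))
    x
  }
  for (tp in peak_times) {
    ci <- as.integer(round(tp * fs)) + 1L
    if (ci < 1L || ci > n) next
    x <- bump(x, ci, 0.05, r_amp)                               # R wave
    ti <- ci + as.integer(round(0.25 * fs))
    if (ti <= n) x <- bump(x, ti, 0.12, 0.15 * r_amp)           # T wave
  }
  x
}

#' Simulate physiological channels for one session
#'
#' ECG: a periodic beat template at the profile's base heart rate with
#' Gaussian R-R jitter (sd 50 ms rested, 25 ms tired) and optional additive
#' Gaussian noise. EMG: zero-mean noise whose amplitude is multiplied by
#' `emg_gain_tired` in the tired state. GSR: a slow random walk around a
#' 200 kOhm baseline, shifted up by `gsr_shift_tired` in the tired state.
#' Channel streams are seeded independently from the profile seed, so the
#' rested and tired variants of the same profile share underlying noise
#' draws and differ only by the programmed state effects.
#'
#' @param profile A [driver_profile()].
#' @param duration Seconds.
#' @param fs_ecg,fs_emg,fs_gsr Sampling rates (defaults 128, 128, 10.2 Hz).
#' @param rr_jitter_sd R-R jitter sd in seconds; `NULL` uses the state
#'   default (0.05 rested, 0.025 tired). Set 0 for a perfectly regular beat.
#' @param ecg_noise_sd Additive ECG noise sd in mV (0 = noise-free; the R
#'   spike has amplitude 1 mV, so e.g. 0.1 corresponds to an amplitude SNR
#'   of 10).
#' @param emg_base_sd Rested EMG amplitude sd in mV.
#' @return List with [channel_trace()] entries `ecg`, `emg`, `gsr`, and
#'   `true_r_times` (the programmed R-peak times, for closed-loop checks).
#' @export
simulate_physio <- function(profile, duration, fs_ecg = 128, fs_emg = 128,
                            fs_gsr = 10.2, rr_jitter_sd = NULL,
                            ecg_noise_sd = 0, emg_base_sd = 0.15) {
  stopifnot(inherits(profile, "driver_profile"))
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("duration must be a single positive number", call. = FALSE)
  }
  tired <- profile$physio_state == "tired"
  jit <- rr_jitter_sd %||% if (tired) 0.025 else 0.05
  seeds <- derive_seeds(profile$seed, 3L)

  ecg_parts <- with_seed(seeds[[1L]], {
    ibi <- 60 / profile$base_hr
    n_beat_max <- as.integer(ceiling(duration / max(ibi - 4 * max(jit, 0.01), 0.3))) + 2L
    gaps <- pmax(0.3, ibi + stats::rnorm(n_beat_max, 0, jit))
    tp <- 0.4 + cumsum(gaps)
    tp <- tp[tp < duration - 0.1]
    n <- samples_in(duration, fs_ecg)
    x <- ecg_template_at(n, fs_ecg, tp)
    if (ecg_noise_sd > 0) x <- x + stats::rnorm(n, 0, ecg_noise_sd)
    list(values = x, true_r_times = (round(tp * fs_ecg)) / fs_ecg)
  })

  emg_values <- with_seed(seeds[[2L]], {
    n <- samples_in(duration, fs_emg)
    stats::rnorm(n, 0, emg_base_sd) * if (tired) profile$emg_gain_tired else 1
  })

  gsr_values <- with_seed(seeds[[3L]], {
    n <- samples_in(duration, fs_gsr)
    200 + cumsum(stats::rnorm(n, 0, 0.2)) + if (tired) profile$gsr_shift_tired else 0
  })

  list(ecg = channel_trace("ECG", ecg_parts$values, fs = fs_ecg),
       emg = channel_trace("EMG", emg_values, fs = fs_emg),
       gsr = channel_trace("GSR", gsr_values, fs = fs_gsr),
       true_r_times = ecg_parts$true_r_times)
}

#' Simulate a complete driving session
#'
#' Generates the steering trace, optionally the physiological channels,
#' one-hertz vehicle telemetry (an AR(1) speed process around the scenario
#' regime mean — 40 km/h urban, 90 km/h interurban — with rpm and fuel as
#' smooth noisy functions of speed, and an integrated 2-D position), and
#' Poisson-timed traffic-offence events with kinds drawn from the 18-label
#' vocabulary. Everything is deterministic given the profile seed. The
#' vehicle model is deliberately crude; the package tests analytics, not
#' vehicle physics.
#'
#' @param profile A [driver_profile()].
#' @param scenario_class `"urban"` or `"interurban"`.
#' @param gear `"automatic"` or `"manual"`.
#' @param duration Session length in seconds (at least 10).
#' @param fs_gyro Gyroscope sampling rate (default 10.2 Hz).
#' @param include_physio Attach ECG/EMG/GSR traces (default `TRUE`; cohort
#'   simulation switches them off for speed unless asked).
#' @param kind_rates Optional named per-kind offence rates (events/s)
#'   overriding the uniform split of `profile$offence_rate`.
#' @param speed_bias Additive shift of the regime mean speed in km/h (used
#'   e.g. to give automatic-gear urban driving a configurable bias).
#' @return A [driving_session()].
#' @export
simulate_session <- function(profile, scenario_class = c("urban", "interurban"),
                             gear = c("automatic", "manual"), duration = 600,
                             fs_gyro = 10.2, include_physio = TRUE,
                             kind_rates = NULL, speed_bias = 0) {
  stopifnot(inherits(profile, "driver_profile"))
  scenario_class <- match.arg(scenario_class)
  gear <- match.arg(gear)
  if (!is.numeric(duration) || length(duration) != 1L || duration < 10) {
    stop("duration must be at least 10 s", call. = FALSE)
  }
  seeds <- derive_seeds(profile$seed, 4L)
  sub <- function(s) { p <- profile; p$seed <- s; p }

  gyro <- simulate_steering(sub(seeds[[1L]]), duration, fs = fs_gyro)

  nT <- as.integer(floor(duration))
  vehicle <- with_seed(seeds[[2L]], {
    m <- (if (scenario_class == "urban") 40 else 90) + speed_bias
    dev <- as.numeric(stats::filter(stats::rnorm(nT, 0, 5 * sqrt(1 - 0.9^2)),
                                    0.9, method = "recursive"))
    speed <- pmax(0, m + dev)
    rpm <- pmax(0, 800 + 35 * speed + stats::rnorm(nT, 0, 60))
    fuel <- pmax(0, 2 + 0.06 * speed + stats::rnorm(nT, 0, 0.3))
    heading <- cumsum(stats::rnorm(nT, 0, if (scenario_class == "urban") 0.15 else 0.03))
    step <- speed / 3.6
    vehicle_records(t = seq_len(nT), speed = speed, rpm = rpm, fuel = fuel,
                    pos_x = cumsum(step * cos(heading)),
                    pos_y = cumsum(step * sin(heading)))
  })

  rates <- kind_rates %||% stats::setNames(
    rep(profile$offence_rate / 18, 18), offence_kinds())
  stopifnot(all(names(rates) %in% offence_kinds()), all(rates >= 0))
  offences <- with_seed(seeds[[3L]], {
    counts <- stats::rpois(length(rates), rates * duration)
    kinds <- rep(names(rates), counts)
    tt <- sort(stats::runif(sum(counts), 0, duration))
    kinds <- sample(kinds)  # shuffle so kinds are not blocked in time
    px <- stats::approx(vehicle$t, vehicle$pos_x, xout = tt, rule = 2)$y %||% numeric()
    py <- stats::approx(vehicle$t, vehicle$pos_y, xout = tt, rule = 2)$y %||% numeric()
    if (sum(counts) == 0L) offence_events() else
      offence_events(t = tt, kind = kinds, pos_x = px, pos_y = py)
  })

  traces <- list(gyro = gyro)
  if (include_physio) {
    ph <- simulate_physio(sub(seeds[[4L]]), duration)
    traces$ecg <- ph$ecg
    traces$emg <- ph$emg
    traces$gsr <- ph$gsr
  }
  driving_session(
    driver_id = profile$driver_id, scenario_class = scenario_class,
    gear = gear, duration = duration, traces = traces,
    vehicle = vehicle, offences = offences,
    physio_state = if (include_physio) profile$physio_state else "unspecified",
    validate = FALSE
  )
}

#' Cohort design for simulated studies
#'
#' Fixes the study conditions of a simulated cohort: session length and
#' scenario layout, the base offence rate, and which cross-driver
#' correlation (if any) is planted and how strongly. Two plantable targets
#' are supported: `"sdw_leaving_road"` couples per-driver steering vigour
#' (hence the standard deviation of the angular speed) with the
#' leaving-the-road offence rate, keeping every driver in the alert regime
#' so the planted signal is not confounded by regime switching;
#' `"sss_offences"` couples the Stanford sleepiness score with the total
#' offence rate and ties the drowsy-steering probability to the same latent
#' sleepiness.
#'
#' @param plant `"none"`, `"sdw_leaving_road"` or `"sss_offences"`.
#' @param rho_plant Planted correlation, in (-1, 1).
#' @param duration Session length in seconds (default 600, a typical
#'   simulator route).
#' @param base_offence_rate Mean offences/s across all kinds.
#' @param leaving_road_rate Mean leaving-the-road rate for the
#'   `"sdw_leaving_road"` plant.
#' @param scale_load,rate_load Relative between-driver spreads of steering
#'   vigour and offence propensity.
#' @param scenario_classes,gears Session grid per driver.
#' @param include_physio Attach physiological channels (default `FALSE`:
#'   cohorts are steering/offence studies unless physiology is requested).
#' @param fs_gyro Gyroscope rate.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(plant = c("none", "sdw_leaving_road", "sss_offences"),
                          rho_plant = 0, duration = 600,
                          base_offence_rate = 0.05, leaving_road_rate = 0.05,
                          scale_load = 0.3, rate_load = 0.5,
                          scenario_classes = "urban", gears = "automatic",
                          include_physio = FALSE, fs_gyro = 10.2) {
  plant <- match.arg(plant)
  if (!is.numeric(rho_plant) || length(rho_plant) != 1L ||
      rho_plant <= -1 || rho_plant >= 1) {
    stop("rho_plant must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    list(plant = plant, rho_plant = rho_plant, duration = duration,
         base_offence_rate = base_offence_rate,
         leaving_road_rate = leaving_road_rate,
         scale_load = scale_load, rate_load = rate_load,
         scenario_classes = scenario_classes, gears = gears,
         include_physio = include_physio, fs_gyro = fs_gyro),
    class = "cohort_design"
  )
}

#' Simulate a cohort of drivers with plantable correlations
#'
#' Draws per-driver latent sleepiness and two further latent factors
#' correlated at the design's `rho_plant`, generates one session per
#' (driver, scenario, gear) cell plus a sleepiness questionnaire per
#' driver, and returns the generating truth so parameter-recovery tests
#' can close the loop. Deterministic from `seed`.
#'
#' @param n_drivers Number of drivers (at least 3).
#' @param design A [cohort_design()].
#' @param seed Integer master seed.
#' @return List of class `driving_cohort`: `sessions` (list of
#'   [driving_session()]), `questionnaires` (data frame), `truth` (data
#'   frame of latent values per driver), `design`.
#' @export
simulate_cohort <- function(n_drivers, design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (!is.numeric(n_drivers) || n_drivers < 3) {
    stop("n_drivers must be at least 3", call. = FALSE)
  }
  n_drivers <- as.integer(n_drivers)
  rho <- design$rho_plant
  a <- sqrt(abs(rho))
  b <- sqrt(1 - abs(rho))

  lat <- with_seed(seed, {
    z <- stats::rnorm(n_drivers)   # latent sleepiness
    e1 <- stats::rnorm(n_drivers)
    e2 <- stats::rnorm(n_drivers)
    e3 <- stats::rnorm(n_drivers)
    e4 <- stats::rnorm(n_drivers)
    u <- stats::runif(n_drivers)
    list(z = z, lat_x = a * z + b * e1, lat_y = sign(rho + (rho == 0)) * a * z + b * e2,
         e3 = e3, e4 = e4, u = u,
         age = pmin(60, pmax(18, round(stats::rnorm(n_drivers, 27, 7)))),
         game_exp = sample(1:10, n_drivers, replace = TRUE),
         racing_exp = sample(1:10, n_drivers, replace = TRUE),
         seeds = sample.int(.Machine$integer.max - 1L, n_drivers))
  })

  uniform_rates <- stats::setNames(rep(design$base_offence_rate / 18, 18),
                                   offence_kinds())
  ids <- sprintf("d%03d", seq_len(n_drivers))

  sessions <- list()
  truth <- data.frame(driver_id = ids, sleepiness = lat$z,
                      lat_x = lat$lat_x, lat_y = lat$lat_y,
                      steering_scale = 1, attention = "alert",
                      stringsAsFactors = FALSE)

  for (i in seq_len(n_drivers)) {
    scale_i <- 1
    attention_i <- "alert"
    rates_i <- uniform_rates
    if (design$plant == "sdw_leaving_road") {
      scale_i <- pmax(0.2, 1 + design$scale_load * lat$lat_x[i])
      rates_i["leaving_road"] <-
        design$leaving_road_rate * pmax(0.02, 1 + design$rate_load * lat$lat_y[i])
    } else if (design$plant == "sss_offences") {
      rates_i <- uniform_rates *
        pmax(0.02, 1 + design$rate_load * lat$lat_y[i])
      # drowsy probability rises steeply with latent sleepiness (38% at the
      # median), so sleepiness visibly drives the steering regime
      attention_i <- if (lat$u[i] < stats::plogis(-0.5 + 4 * lat$z[i])) "drowsy" else "alert"
    }
    truth$steering_scale[i] <- scale_i
    truth$attention[i] <- attention_i
    prof <- driver_profile(
      driver_id = ids[i], attention = attention_i,
      physio_state = if (lat$z[i] > 0) "tired" else "rested",
      steering_scale = scale_i, seed = lat$seeds[i]
    )
    for (sc in design$scenario_classes) {
      for (g in design$gears) {
        p2 <- prof
        p2$seed <- (prof$seed + 7919L * (match(sc, c("urban", "interurban")) +
                                           2L * match(g, c("automatic", "manual")))) %%
          (.Machine$integer.max - 1L)
        sessions[[length(sessions) + 1L]] <-
          simulate_session(p2, scenario_class = sc, gear = g,
                           duration = design$duration, fs_gyro = design$fs_gyro,
                           include_physio = design$include_physio,
                           kind_rates = rates_i)
      }
    }
  }

  clamp_round <- function(x, lo, hi) as.integer(pmin(hi, pmax(lo, round(x))))
  sss_src <- if (design$plant == "sss_offences") lat$lat_x else
    0.6 * lat$z + 0.8 * lat$e3
  questionnaires <- data.frame(
    driver_id = ids,
    kss = clamp_round(5 + 2 * (0.7 * lat$z + 0.71 * lat$e4), 1, 9),
    sss = clamp_round(4 + 1.5 * sss_src, 1, 7),
    ess = clamp_round(8 + 4 * (0.5 * lat$z + 0.87 * lat$e3), 0, 24),
    age = lat$age,
    license_years = pmax(0, lat$age - 18 - clamp_round(abs(lat$e4) * 3, 0, 10)),
    game_exp = lat$game_exp,
    racing_exp = lat$racing_exp,
    stringsAsFactors = FALSE
  )

  structure(list(sessions = sessions, questionnaires = questionnaires,
                 truth = truth, design = design),
            class = "driving_cohort")
}

#' @export
print.driving_cohort <- function(x, ...) {
  cat(sprintf("<driving_cohort> %d drivers, %d sessions (plant: %s, rho = %g)\n",
              nrow(x$truth), length(x$sessions), x$design$plant,
              x$design$rho_plant))
  invisible(x)
}
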