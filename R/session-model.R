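#' The closed vocabulary of traffic-offence kinds
#'
#' The simulator logs eighteen kinds of traffic offence: five collision
#' types, leaving the road, speeding either way, three junction/roundabout
#' errors, three signal violations, tailgating, crossing a solid line, and
#' two turn-light omissions. Offence events are validated against this
#' vocabulary at construction.
#'
#' @return Character vector of the 18 offence labels.
#' @export
#' @examples
#' offence_kinds()
offence_kinds <- function() {
  c(
    "collision_pedestrian",
    "collision_vehicle",
    "collision_motorcycle",
    "collision_cyclist",
    "collision_still_object",
    "leaving_road",
    "over_speed",
    "under_speed",
    "leaving_roundabout_incorrectly",
    "driving_roundabout_incorrectly",
    "leaving_junction_incorrectly",
    "stop_sign",
    "yield_sign",
    "traffic_light",
    "safety_distance",
    "crossing_solid_line",
    "no_turn_light_turn",
    "no_turn_light_overtaking"
  )
}

.channel_units <- c(
  ECG = "mV", EMG = "mV", GSR = "kOhm",
  ACCEL_X = "g", ACCEL_Y = "g", ACCEL_Z = "g",
  GYRO_Z = "deg/s"
)

#' Construct a steering angular-speed trace
#'
#' A uniformly sampled signed angular-speed signal from a gyroscope mounted
#' on the steering-wheel rotation axis. Positive values denote
#' counter-clockwise wheel rotation as seen by the driver (any fixed
#' convention is self-consistent; this one is the package's). Sample `i`
#' (1-based) is taken at time `t0 + (i - 1) / fs` seconds from session start.
#'
#' @param values Numeric vector of angular speeds in degrees/second; must be
#'   finite.
#' @param fs Sampling rate in Hz (e.g. 10.2 for the steering gyroscope).
#' @param t0 Session-relative start time of the first sample, seconds.
#' @return An object of class `angular_speed_trace`.
#' @export
#' @examples
#' tr <- angular_speed_trace(c(1, -2, 0.5), fs = 10.2)
#' trace_times(tr)
angular_speed_trace <- function(values, fs, t0 = 0) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite angular-speed sample at index %d", bad), call. = FALSE)
  }
  fs <- assert_fs(fs)
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  structure(
    list(values = values, fs = fs, t0 = as.numeric(t0),
         channel = "GYRO_Z", units = "deg/s"),
    class = c("angular_speed_trace", "sensor_trace")
  )
}

#' Construct a physiological channel trace
#'
#' Uniformly sampled ECG/EMG (millivolts), GSR (kiloohms) or accelerometer
#' (g) signal. Units are fixed by channel and never implicit.
#'
#' @param channel One of `"ECG"`, `"EMG"`, `"GSR"`, `"ACCEL_X"`,
#'   `"ACCEL_Y"`, `"ACCEL_Z"`.
#' @param values Numeric samples in the channel's units.
#' @param fs Sampling rate in Hz.
#' @param t0 Session-relative start time of the first sample, seconds.
#' @return An object of class `channel_trace`.
#' @export
channel_trace <- function(channel, values, fs, t0 = 0) {
  channel <- match.arg(channel, setdiff(names(.channel_units), "GYRO_Z"))
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite %s sample at index %d", channel, bad), call. = FALSE)
  }
  fs <- assert_fs(fs)
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  structure(
    list(values = values, fs = fs, t0 = as.numeric(t0),
         channel = channel, units = unname(.channel_units[channel])),
    class = c("channel_trace", "sensor_trace")
  )
}

#' Sample times of a sensor trace
#'
#' @param trace An `angular_speed_trace` or `channel_trace`.
#' @return Numeric vector of session-relative times (s), one per sample.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "sensor_trace"))
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<%s> channel %s: %d samples @ %g Hz, t0 = %g s, units %s\n",
              class(x)[1L], x$channel, length(x$values), x$fs, x$t0, x$units))
  invisible(x)
}

#' Construct the one-hertz vehicle telemetry table
#'
#' The simulator stores one record per second: instantaneous fuel
#' consumption, speed, engine rpm and the 2-D scenario position.
#'
#' @param t Integer-valued times (s), strictly increasing by 1.
#' @param speed Speed in km/h, non-negative.
#' @param rpm Engine revolutions per minute, non-negative.
#' @param fuel Instantaneous fuel consumption, non-negative.
#' @param pos_x,pos_y Scenario coordinates (may be negative).
#' @return A `data.frame` with one row per second.
#' @export
vehicle_records <- function(t, speed, rpm, fuel, pos_x, pos_y) {
  t <- as.numeric(t)
  if (length(t) && (any(abs(t - round(t)) > 1e-9) ||
                    (length(t) > 1L && any(abs(diff(t) - 1) > 1e-9)))) {
    stop("vehicle record times must be integers increasing by exactly 1 s", call. = FALSE)
  }
  df <- data.frame(t = t, speed = as.numeric(speed), rpm = as.numeric(rpm),
                   fuel = as.numeric(fuel),
                   pos_x = as.numeric(pos_x), pos_y = as.numeric(pos_y))
  if (nrow(df) && any(df$speed < 0 | df$rpm < 0 | df$fuel < 0, na.rm = TRUE)) {
    stop("speed, rpm and fuel must be non-negative", call. = FALSE)
  }
  df
}

#' Construct a traffic-offence event table
#'
#' @param t Event times (s).
#' @param kind Offence labels drawn from [offence_kinds()].
#' @param pos_x,pos_y Scenario coordinates of the event.
#' @return A `data.frame` with one row per offence.
#' @export
offence_events <- function(t = numeric(), kind = character(),
                           pos_x = numeric(length(t)), pos_y = numeric(length(t))) {
  kind <- as.character(kind)
  unknown <- setdiff(unique(kind), offence_kinds())
  if (length(unknown)) {
    stop("unknown offence kind(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  data.frame(t = as.numeric(t), kind = kind,
             pos_x = as.numeric(pos_x), pos_y = as.numeric(pos_y))
}

#' Construct a driving session
#'
#' One simulator run by one driver: sensor traces, one-hertz vehicle
#' telemetry, traffic-offence events and session metadata.
#'
#' @param driver_id Driver identifier (coerced to character).
#' @param scenario_class `"urban"` or `"interurban"`.
#' @param gear `"automatic"` or `"manual"`.
#' @param duration Session length in seconds, positive.
#' @param traces Named list of [angular_speed_trace()] / [channel_trace()]
#'   objects; all samples must lie within `[0, duration]`.
#' @param vehicle Vehicle telemetry from [vehicle_records()] (optional).
#' @param offences Offence events from [offence_events()] (optional).
#' @param physio_state `"rested"`, `"tired"` or `"unspecified"`.
#' @param validate Set `FALSE` to skip invariant checks (used internally
#'   when the components are constructed by the package itself).
#' @return An object of class `driving_session`.
#' @export
driving_session <- function(driver_id, scenario_class, gear, duration,
                            traces = list(), vehicle = NULL, offences = NULL,
                            physio_state = "unspecified", validate = TRUE) {
  scenario_class <- match.arg(scenario_class, c("urban", "interurban"))
  gear <- match.arg(gear, c("automatic", "manual"))
  physio_state <- match.arg(physio_state, c("rested", "tired", "unspecified"))
  stopifnot(is.numeric(duration), length(duration) == 1L, is.finite(duration))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (length(traces) && is.null(names(traces))) {
    stop("`traces` must be a named list", call. = FALSE)
  }
  if (is.null(vehicle)) vehicle <- vehicle_records(numeric(), numeric(), numeric(), numeric(), numeric(), numeric())
  if (is.null(offences)) offences <- offence_events()
  if (validate) {
    for (nm in names(traces)) {
      tr <- traces[[nm]]
      if (!inherits(tr, "sensor_trace")) {
        stop(sprintf("trace '%s' is not a sensor trace", nm), call. = FALSE)
      }
      tt <- range(tr$t0, tr$t0 + (length(tr$values) - 1) / tr$fs)
      if (length(tr$values) && (tt[1L] < -1e-9 || tt[2L] > duration + 1e-9)) {
        stop(sprintf("trace '%s' extends outside [0, duration]", nm), call. = FALSE)
      }
    }
    unknown <- setdiff(unique(offences$kind), offence_kinds())
    if (length(unknown)) {
      stop("unknown offence kind(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (nrow(offences) && any(offences$t < -1e-9 | offences$t > duration + 1e-9)) {
      stop("offence events outside [0, duration]", call. = FALSE)
    }
    if (nrow(vehicle) && any(vehicle$t < -1e-9 | vehicle$t > duration + 1e-9)) {
      stop("vehicle records outside [0, duration]", call. = FALSE)
    }
  }
  structure(
    list(driver_id = as.character(driver_id), scenario_class = scenario_class,
         gear = gear, physio_state = physio_state, duration = as.numeric(duration),
         traces = traces, vehicle = vehicle, offences = offences),
    class = "driving_session"
  )
}

#' @export
print.driving_session <- function(x, ...) {
  cat(sprintf("<driving_session> driver %s | %s | %s gear | %s | %g s\n",
              x$driver_id, x$scenario_class, x$gear, x$physio_state, x$duration))
  cat(sprintf("  traces: %s\n",
              if (length(x$traces)) paste(names(x$traces), collapse = ", ") else "(none)"))
  cat(sprintf("  vehicle records: %d | offences: %d\n", nrow(x$vehicle), nrow(x$offences)))
  invisible(x)
}

#' Construct a sleepiness questionnaire record
#'
#' Subjective sleepiness scores and driver covariates: Karolinska (KSS,
#' 1-9), Stanford (SSS, 1-7) and Epworth (ESS, 0-24) sleepiness scales,
#' plus age, years holding a driving licence, and self-rated computer-game
#' and racing-game experience (1-10).
#'
#' @param driver_id Driver identifier.
#' @param kss,sss,ess Integer questionnaire scores.
#' @param age Age in years.
#' @param license_years Years holding a driving licence.
#' @param game_exp,racing_exp Self-rated experience, 1-10.
#' @return One-row `data.frame`.
#' @export
questionnaire <- function(driver_id, kss, sss, ess, age, license_years,
                          game_exp, racing_exp) {
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(sprintf("%s must be a single value in [%g, %g]", nm, lo, hi), call. = FALSE)
    }
  }
  chk(kss, 1, 9, "kss"); chk(sss, 1, 7, "sss"); chk(ess, 0, 24, "ess")
  chk(game_exp, 1, 10, "game_exp"); chk(racing_exp, 1, 10, "racing_exp")
  stopifnot(age >= 0, license_years >= 0)
  data.frame(driver_id = as.character(driver_id),
             kss = as.integer(kss), sss = as.integer(sss), ess = as.integer(ess),
             age = as.numeric(age), license_years = as.numeric(license_years),
             game_exp = as.integer(game_exp), racing_exp = as.integer(racing_exp))
}
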