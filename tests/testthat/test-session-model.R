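test_that("trace constructors enforce units, finiteness and timing", {
  tr <- angular_speed_trace(c(1, -2, 0.5), fs = 10.2, t0 = 1)
  expect_equal(tr$units, "deg/s")
  expect_equal(trace_times(tr), 1 + (0:2) / 10.2)
  expect_error(angular_speed_trace(c(1, NA), 10.2), "index 2")
  expect_error(angular_speed_trace(c(1, Inf), 10.2), "index 2")
  expect_error(angular_speed_trace(1:3, fs = 0), "positive")

  expect_equal(channel_trace("ECG", 1:5, 128)$units, "mV")
  expect_equal(channel_trace("GSR", 1:5, 10.2)$units, "kOhm")
  expect_error(channel_trace("FOO", 1:5, 10.2))
})

test_that("offence vocabulary is closed and enforced", {
  expect_length(offence_kinds(), 18L)
  expect_silent(offence_events(t = 1, kind = "leaving_road"))
  expect_error(offence_events(t = 1, kind = "jaywalking"), "unknown offence")
  expect_error(
    driving_session("d1", "urban", "automatic", duration = 10,
                    offences = data.frame(t = 1, kind = "jaywalking",
                                          pos_x = 0, pos_y = 0)),
    "unknown offence")
})

test_that("session invariants: traces and events must lie within the session", {
  tr <- angular_speed_trace(rep(0, 51), fs = 10.2)
  expect_s3_class(driving_session("d1", "urban", "manual", duration = 10,
                                  traces = list(gyro = tr)),
                  "driving_session")
  expect_error(driving_session("d1", "urban", "manual", duration = 3,
                               traces = list(gyro = tr)),
               "outside")
  expect_error(driving_session("d1", "urban", "manual", duration = 0), "positive")
  expect_error(vehicle_records(t = c(1, 3), speed = c(1, 1), rpm = c(1, 1),
                               fuel = c(1, 1), pos_x = c(0, 0), pos_y = c(0, 0)),
               "increasing by exactly 1")
})

test_that("questionnaire scores are range-checked", {
  q <- questionnaire("d1", kss = 5, sss = 3, ess = 10, age = 30,
                     license_years = 10, game_exp = 5, racing_exp = 2)
  expect_equal(q$sss, 3L)
  expect_error(questionnaire("d1", 10, 3, 10, 30, 10, 5, 2), "kss")
  expect_error(questionnaire("d1", 5, 8, 10, 30, 10, 5, 2), "sss")
  expect_error(questionnaire("d1", 5, 3, 25, 30, 10, 5, 2), "ess")
})

test_that("write/read round-trips a simulated session to value identity", {
  s <- make_test_session(seed = 4, duration = 30, physio = TRUE)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$driver_id, s$driver_id)
  expect_equal(s2$duration, s$duration)
  expect_setequal(names(s2$traces), names(s$traces))
  for (nm in names(s$traces)) {
    expect_equal(s2$traces[[nm]]$values, s$traces[[nm]]$values, tolerance = 1e-9)
    expect_equal(s2$traces[[nm]]$fs, s$traces[[nm]]$fs)
    expect_equal(s2$traces[[nm]]$channel, s$traces[[nm]]$channel)
  }
  expect_equal(s2$vehicle, s$vehicle, tolerance = 1e-9)
  expect_equal(s2$offences$kind, s$offences$kind)
  expect_equal(s2$offences$t, s$offences$t, tolerance = 1e-9)

  # byte-deterministic output
  dir2 <- withr::local_tempdir()
  write_session(s, dir2)
  for (f in list.files(dir, full.names = FALSE)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = f)
  }
})

test_that("degenerate and hand-written session files parse as documented", {
  # empty session: metadata plus empty vehicle/offence tables
  s <- driving_session("dx", "urban", "automatic", duration = 10)
  dir <- withr::local_tempdir()
  files <- write_session(s, dir)
  expect_true(all(c("metadata.txt", "vehicle.csv", "offences.csv") %in%
                    basename(files)))
  s2 <- read_session(dir)
  expect_equal(nrow(s2$vehicle), 0L)
  expect_length(s2$traces, 0L)

  # one 3-sample gyro trace -> 3 data rows
  s3 <- driving_session("dy", "urban", "automatic", duration = 10,
                        traces = list(gyro = angular_speed_trace(1:3, 10.2)))
  dir3 <- withr::local_tempdir()
  write_session(s3, dir3)
  lines <- readLines(file.path(dir3, "trace_gyro.csv"))
  expect_length(grep("^[^#]", lines), 3L)

  # hand-written fixture: fs = 10.2 and 51 rows -> trace of length 51
  dir4 <- withr::local_tempdir()
  writeLines(c("driver_id: z", "scenario_class: urban", "gear: manual",
               "physio_state: unspecified", "duration: 6", "traces: gyro"),
             file.path(dir4, "metadata.txt"))
  writeLines(c("# channel: GYRO_Z", "# units: deg/s", "# fs: 10.2", "# t0: 0",
               sprintf("%.3f", sin(1:51))),
             file.path(dir4, "trace_gyro.csv"))
  writeLines("# t,speed,rpm,fuel,pos_x,pos_y", file.path(dir4, "vehicle.csv"))
  writeLines("# t,kind,pos_x,pos_y", file.path(dir4, "offences.csv"))
  s4 <- read_session(dir4)
  expect_length(s4$traces$gyro$values, 51L)
  expect_equal(s4$traces$gyro$fs, 10.2)
})

test_that("malformed rows raise errors naming file and line", {
  s <- make_test_session(seed = 5, duration = 20)
  dir <- withr::local_tempdir()
  write_session(s, dir)
  path <- file.path(dir, "trace_gyro.csv")
  lines <- readLines(path)
  lines[10] <- "not-a-number"
  writeLines(lines, path)
  expect_error(read_session(dir), "trace_gyro.csv: line 10")

  expect_error(read_session(withr::local_tempdir()), "metadata")
})

test_that("questionnaire tables round-trip through CSV", {
  q <- rbind(questionnaire("d1", 5, 3, 10, 30, 10, 5, 2),
             questionnaire("d2", 2, 6, 4, 45, 20.5, 9, 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_questionnaires(q, path)
  q2 <- read_questionnaires(path)
  expect_equal(q2, q)
})
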