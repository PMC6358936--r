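# Session directory layout (one directory per session):
#   metadata.txt        key: value lines (driver, scenario, gear, state, duration)
#   trace_<name>.csv    '#'-prefixed header (channel, units, fs, t0), then one
#                       sample per line
#   vehicle.csv         '# t,speed,rpm,fuel,pos_x,pos_y' then comma rows
#   offences.csv        '# t,kind,pos_x,pos_y' then comma rows
# Comma-separated, UTF-8, '.' decimal separator. Numbers are written with
# %.15g so a write/read cycle preserves values far below the 1e-9 contract.

fmt_num <- function(x) sprintf("%.15g", x)

#' Write a driving session to a directory of CSV files
#'
#' Persists one CSV per sensor trace (self-describing `#` header carrying
#' channel, units, sampling rate and start time), one vehicle-telemetry CSV,
#' one offence CSV and a `metadata.txt` manifest. Output bytes are
#' deterministic for a fixed session: trace files are written in sorted name
#' order with fixed numeric formatting.
#'
#' @param session A [driving_session()].
#' @param directory Target directory; created if missing.
#' @return Invisibly, the character vector of files written.
#' @seealso [read_session()], the inverse up to floating-point text round-trip.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "driving_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory, call. = FALSE)

  written <- character()
  put <- function(lines, file) {
    path <- file.path(directory, file)
    con <- file(path, open = "wb")  # binary: byte-deterministic, LF endings
    on.exit(close(con), add = TRUE)
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    written <<- c(written, path)
  }

  put(c(sprintf("driver_id: %s", session$driver_id),
        sprintf("scenario_class: %s", session$scenario_class),
        sprintf("gear: %s", session$gear),
        sprintf("physio_state: %s", session$physio_state),
        sprintf("duration: %s", fmt_num(session$duration)),
        sprintf("traces: %s", paste(sort(names(session$traces)), collapse = ","))),
      "metadata.txt")

  for (nm in sort(names(session$traces))) {
    tr <- session$traces[[nm]]
    if (is.null(tr$units) || !nzchar(tr$units)) {
      stop(sprintf("trace '%s' has undefined units", nm), call. = FALSE)
    }
    put(c(sprintf("# channel: %s", tr$channel),
          sprintf("# units: %s", tr$units),
          sprintf("# fs: %s", fmt_num(tr$fs)),
          sprintf("# t0: %s", fmt_num(tr$t0)),
          fmt_num(tr$values)),
        sprintf("trace_%s.csv", nm))
  }

  v <- session$vehicle
  put(c("# t,speed,rpm,fuel,pos_x,pos_y",
        if (nrow(v)) sprintf("%s,%s,%s,%s,%s,%s", fmt_num(v$t), fmt_num(v$speed),
                             fmt_num(v$rpm), fmt_num(v$fuel),
                             fmt_num(v$pos_x), fmt_num(v$pos_y))),
      "vehicle.csv")

  o <- session$offences
  put(c("# t,kind,pos_x,pos_y",
        if (nrow(o)) sprintf("%s,%s,%s,%s", fmt_num(o$t), o$kind,
                             fmt_num(o$pos_x), fmt_num(o$pos_y))),
      "offences.csv")

  invisible(written)
}

read_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([a-z_]+):[ ]?(.*)$", lines))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad)) {
    stop(sprintf("%s: line %d: malformed 'key: value' line", path, bad[1L]), call. = FALSE)
  }
  stats::setNames(vapply(m, `[[`, "", 3L), vapply(m, `[[`, "", 2L))
}

parse_num <- function(txt, path, line_no) {
  x <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(x) & !is.na(txt))
  if (length(bad)) {
    stop(sprintf("%s: line %d: malformed numeric value '%s'",
                 path, line_no[bad[1L]], txt[bad[1L]]), call. = FALSE)
  }
  x
}

read_trace_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  if (!length(hdr_idx) || any(diff(hdr_idx) != 1L) || hdr_idx[1L] != 1L) {
    stop(sprintf("%s: malformed header (expected leading '#' lines)", path), call. = FALSE)
  }
  hdr <- sub("^#[ ]?", "", lines[hdr_idx])
  kv <- stats::setNames(sub("^[a-z0-9_]+:[ ]?", "", hdr),
                        sub(":.*$", "", hdr))
  need <- c("channel", "units", "fs", "t0")
  if (!all(need %in% names(kv))) {
    stop(sprintf("%s: header missing %s", path,
                 paste(setdiff(need, names(kv)), collapse = ", ")), call. = FALSE)
  }
  body_idx <- setdiff(seq_along(lines), hdr_idx)
  body_idx <- body_idx[nzchar(lines[body_idx])]
  values <- parse_num(lines[body_idx], path, body_idx)
  fs <- parse_num(kv[["fs"]], path, 0L)
  t0 <- parse_num(kv[["t0"]], path, 0L)
  if (kv[["channel"]] == "GYRO_Z") {
    angular_speed_trace(values, fs = fs, t0 = t0)
  } else {
    channel_trace(kv[["channel"]], values, fs = fs, t0 = t0)
  }
}

read_table_file <- function(path, columns) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "#")) {
    stop(sprintf("%s: missing '#' column header", path), call. = FALSE)
  }
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  parts <- strsplit(lines[body_idx], ",", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf != length(columns))) {
    bad <- which(nf != length(columns))[1L]
    stop(sprintf("%s: line %d: expected %d fields, found %d",
                 path, body_idx[bad], length(columns), nf[bad]), call. = FALSE)
  }
  out <- lapply(seq_along(columns), function(j) {
    vals <- vapply(parts, `[[`, "", j)
    if (columns[j] %in% c("kind", "driver_id", "scenario_class")) vals
    else parse_num(vals, path, body_idx)
  })
  names(out) <- columns
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a driving session written by [write_session()]
#'
#' Parses the session directory dialect back into a [driving_session()].
#' Malformed rows raise an error naming the file and line.
#'
#' @param directory Directory produced by [write_session()] (or conforming
#'   to the documented dialect).
#' @return A [driving_session()].
#' @export
read_session <- function(directory) {
  meta_path <- file.path(directory, "metadata.txt")
  if (!file.exists(meta_path)) {
    stop("missing metadata.txt in ", directory, call. = FALSE)
  }
  meta <- read_kv(meta_path)
  need <- c("driver_id", "scenario_class", "gear", "physio_state", "duration", "traces")
  if (!all(need %in% names(meta))) {
    stop(sprintf("%s: missing key(s): %s", meta_path,
                 paste(setdiff(need, names(meta)), collapse = ", ")), call. = FALSE)
  }
  trace_names <- setdiff(strsplit(meta[["traces"]], ",", fixed = TRUE)[[1L]], "")
  traces <- stats::setNames(lapply(trace_names, function(nm) {
    path <- file.path(directory, sprintf("trace_%s.csv", nm))
    if (!file.exists(path)) stop("missing trace file: ", path, call. = FALSE)
    read_trace_file(path)
  }), trace_names)

  vehicle <- read_table_file(file.path(directory, "vehicle.csv"),
                             c("t", "speed", "rpm", "fuel", "pos_x", "pos_y"))
  off <- read_table_file(file.path(directory, "offences.csv"),
                         c("t", "kind", "pos_x", "pos_y"))
  driving_session(
    driver_id = meta[["driver_id"]],
    scenario_class = meta[["scenario_class"]],
    gear = meta[["gear"]],
    physio_state = meta[["physio_state"]],
    duration = parse_num(meta[["duration"]], meta_path, 0L),
    traces = traces,
    vehicle = do.call(vehicle_records, vehicle),
    offences = do.call(offence_events, off)
  )
}

#' Write or read a questionnaire table
#'
#' Plain CSV (with a `#`-prefixed column header, matching the session
#' dialect) holding one [questionnaire()] row per driver.
#'
#' @param questionnaires Data frame of questionnaire rows.
#' @param path File path.
#' @return `write_questionnaires()` returns the path invisibly;
#'   `read_questionnaires()` returns the data frame.
#' @export
write_questionnaires <- function(questionnaires, path) {
  cols <- c("driver_id", "kss", "sss", "ess", "age", "license_years",
            "game_exp", "racing_exp")
  stopifnot(all(cols %in% names(questionnaires)))
  q <- questionnaires[cols]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("# ", paste(cols, collapse = ",")),
               do.call(sprintf, c(list("%s,%d,%d,%d,%s,%s,%d,%d"),
                                  list(q$driver_id, as.integer(q$kss), as.integer(q$sss),
                                       as.integer(q$ess), fmt_num(q$age),
                                       fmt_num(q$license_years), as.integer(q$game_exp),
                                       as.integer(q$racing_exp))))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_questionnaires
#' @export
read_questionnaires <- function(path) {
  df <- read_table_file(path, c("driver_id", "kss", "sss", "ess", "age",
                                "license_years", "game_exp", "racing_exp"))
  df$driver_id <- as.character(df$driver_id)
  for (nm in c("kss", "sss", "ess", "game_exp", "racing_exp")) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  df
}
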