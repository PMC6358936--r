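# Session synchronisation protocol between a simulator client and a sensor
# node server, on TCP (default port 8080). Wire format:
#   commands   newline-terminated ASCII tokens:
#              "connect <peer>", "start", "pause", "resume", "stopall",
#              "sendfiles"  ("stopall" is the fixed stop token)
#   replies    "ok ...", "error <reason>", "refused"
#   transfer   after stopall: "duration <seconds>", "files <k>", then per
#              file "file <name> <bytes> <md5>" followed by the raw bytes,
#              and finally "done". Length-prefix framing keeps arbitrary
#              binary content intact; the md5 checksum closes the loop.

SYNC_VERBS <- c("connect", "start", "pause", "resume", "stopall", "sendfiles")

# Read one LF-terminated ASCII line from a binary-mode socket, polling
# until `timeout` seconds have elapsed.
sock_read_line <- function(con, timeout = 30) {
  deadline <- Sys.time() + timeout
  buf <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b)) {
      if (b == as.raw(10L)) return(rawToChar(buf))
      buf <- c(buf, b)
    } else {
      if (Sys.time() > deadline) stop("protocol timeout waiting for a line", call. = FALSE)
      Sys.sleep(0.005)
    }
  }
}

sock_write_line <- function(con, line) {
  writeBin(c(charToRaw(line), as.raw(10L)), con)
  flush(con)
}

sock_read_bytes <- function(con, size, timeout = 60, chunk = 65536L) {
  deadline <- Sys.time() + timeout
  out <- vector("list", 0L)
  got <- 0
  while (got < size) {
    b <- readBin(con, "raw", n = min(chunk, size - got))
    if (length(b)) {
      out[[length(out) + 1L]] <- b
      got <- got + length(b)
    } else {
      if (Sys.time() > deadline) stop("protocol timeout during file transfer", call. = FALSE)
      Sys.sleep(0.005)
    }
  }
  do.call(c, out)
}

#' Serve one synchronised recording session over TCP
#'
#' Clean-room server side of the session synchronisation protocol: listens
#' on `port`, accepts a connection whose `connect` handshake names the
#' allowed peer (base R sockets expose no peer address, so identity rides
#' on the handshake token), then drives a recording state machine —
#' `start` begins recording, `pause`/`resume` toggle it (paused time is
#' excluded from the recorded duration), and the literal token `stopall`
#' closes recording, materialises the session files through the pluggable
#' `data_source`, and transmits them with length-prefix framing and md5
#' checksums before closing the connection. Commands arriving in the wrong
#' state get an `error` reply and change nothing. Ports below 1024 are
#' rejected (mobile socket APIs reserve them).
#'
#' @param port TCP port (default 8080).
#' @param allowed_peer Token the client must present in its `connect` line.
#' @param data_source Function `(active_seconds)` returning the character
#'   vector of file paths to transmit after `stopall`. The default records
#'   a simulated driving session of that duration and writes it with
#'   [write_session()] to a temporary directory.
#' @param timeout Seconds to wait for a connection and for each command.
#' @return Invisibly, a list: `peer_ok`, `active_seconds`, `files` sent,
#'   and the command `log`.
#' @export
serve_session <- function(port = 8080, allowed_peer = "simulator",
                          data_source = NULL, timeout = 30) {
  if (port < 1024) stop("ports below 1024 are rejected", call. = FALSE)
  if (is.null(data_source)) {
    data_source <- function(active_seconds) {
      prof <- driver_profile(seed = 1L)
      s <- simulate_session(prof, duration = max(10, active_seconds),
                            include_physio = FALSE)
      write_session(s, file.path(tempdir(), sprintf("served_%d", port)))
    }
  }
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  if (!socketSelect(list(srv), timeout = timeout)) {
    stop("timeout waiting for a connection", call. = FALSE)
  }
  con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = timeout)
  on.exit(try(close(con), silent = TRUE), add = TRUE)

  log <- character()
  state <- "idle"
  active <- 0
  seg_start <- NA_real_
  now <- function() as.numeric(Sys.time())

  hello <- strsplit(sock_read_line(con, timeout), " ", fixed = TRUE)[[1L]]
  if (length(hello) != 2L || hello[1L] != "connect" || hello[2L] != allowed_peer) {
    sock_write_line(con, "refused")
    return(invisible(list(peer_ok = FALSE, active_seconds = 0,
                          files = character(), log = "refused")))
  }
  sock_write_line(con, "ok connected")

  files <- character()
  repeat {
    cmd <- sock_read_line(con, timeout)
    log <- c(log, cmd)
    if (cmd == "start") {
      if (state != "idle") { sock_write_line(con, "error already-started"); next }
      state <- "recording"; seg_start <- now()
      sock_write_line(con, "ok recording")
    } else if (cmd == "pause") {
      if (state != "recording") { sock_write_line(con, "error not-recording"); next }
      active <- active + (now() - seg_start); state <- "paused"
      sock_write_line(con, "ok paused")
    } else if (cmd == "resume") {
      if (state != "paused") { sock_write_line(con, "error not-paused"); next }
      state <- "recording"; seg_start <- now()
      sock_write_line(con, "ok recording")
    } else if (cmd == "stopall") {
      if (state == "idle") { sock_write_line(con, "error not-started"); next }
      if (state == "recording") active <- active + (now() - seg_start)
      state <- "stopped"
      files <- data_source(active)
      sock_write_line(con, sprintf("duration %.6f", active))
      sock_write_line(con, sprintf("files %d", length(files)))
      for (f in files) {
        size <- file.size(f)
        md5 <- unname(tools::md5sum(f))
        sock_write_line(con, sprintf("file %s %d %s", basename(f), size, md5))
        fcon <- file(f, open = "rb")
        repeat {
          chunk <- readBin(fcon, "raw", n = 65536L)
          if (!length(chunk)) break
          writeBin(chunk, con)
        }
        close(fcon)
        flush(con)
      }
      sock_write_line(con, "done")
      break
    } else if (cmd == "sendfiles") {
      sock_write_line(con, if (state == "stopped") "error already-sent"
                      else "error not-stopped")
    } else {
      sock_write_line(con, "error unknown-command")
    }
  }
  invisible(list(peer_ok = TRUE, active_seconds = active, files = files,
                 log = log))
}

connect_retry <- function(host, port, timeout) {
  deadline <- Sys.time() + timeout
  repeat {
    con <- tryCatch(
      suppressWarnings(socketConnection(host, port, blocking = TRUE,
                                        open = "r+b", timeout = timeout)),
      error = function(e) NULL)
    if (!is.null(con)) return(con)
    if (Sys.time() > deadline) {
      stop(sprintf("timeout: no server at %s:%d", host, port), call. = FALSE)
    }
    Sys.sleep(0.1)
  }
}

#' Run a scripted client against a session server
#'
#' Connects to [serve_session()], presents the peer token, executes the
#' scripted command sequence (elements are protocol verbs, or `"wait:x"`
#' to sleep x seconds between commands), and — after `stopall` — receives
#' the transmitted files into `out_dir`, verifying each one's byte length
#' and md5 checksum against the manifest (a mismatch is an error).
#'
#' @param script Character vector of commands, e.g.
#'   `c("start", "wait:1", "stopall")`.
#' @param host Server host (default loopback).
#' @param port Server port.
#' @param peer Peer token to present (must match the server's
#'   `allowed_peer`).
#' @param out_dir Directory for received files (created if needed).
#' @param timeout Seconds before a connection or read attempt fails.
#' @return List: `files` (data frame with `name`, `size`, `md5`, `path`),
#'   `recorded_seconds` as reported by the server, and the reply `log`.
#' @export
client_run <- function(script, host = "127.0.0.1", port = 8080,
                       peer = "simulator", out_dir = tempfile("received_"),
                       timeout = 30) {
  con <- connect_retry(host, port, timeout)
  on.exit(try(close(con), silent = TRUE), add = TRUE)
  sock_write_line(con, paste("connect", peer))
  reply <- sock_read_line(con, timeout)
  if (reply != "ok connected") {
    stop("server refused connection: ", reply, call. = FALSE)
  }
  log <- character()
  recorded <- NA_real_
  files <- data.frame(name = character(), size = numeric(), md5 = character(),
                      path = character(), stringsAsFactors = FALSE)
  for (cmd in script) {
    if (startsWith(cmd, "wait:")) {
      Sys.sleep(as.numeric(sub("^wait:", "", cmd)))
      next
    }
    sock_write_line(con, cmd)
    reply <- sock_read_line(con, timeout)
    log <- c(log, paste(cmd, "->", reply))
    if (cmd == "stopall" && startsWith(reply, "duration ")) {
      recorded <- as.numeric(sub("^duration ", "", reply))
      k <- as.integer(sub("^files ", "", sock_read_line(con, timeout)))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (j in seq_len(k)) {
        hdr <- strsplit(sock_read_line(con, timeout), " ", fixed = TRUE)[[1L]]
        if (length(hdr) != 4L || hdr[1L] != "file") {
          stop("malformed file header: ", paste(hdr, collapse = " "), call. = FALSE)
        }
        name <- hdr[2L]; size <- as.numeric(hdr[3L]); md5 <- hdr[4L]
        bytes <- sock_read_bytes(con, size, timeout = timeout)
        path <- file.path(out_dir, name)
        writeBin(bytes, path)
        got_md5 <- unname(tools::md5sum(path))
        if (!identical(got_md5, md5)) {
          stop(sprintf("checksum mismatch for %s: expected %s, got %s",
                       name, md5, got_md5), call. = FALSE)
        }
        files[nrow(files) + 1L, ] <- list(name, size, md5, path)
      }
      final <- sock_read_line(con, timeout)
      if (final != "done") stop("missing transfer terminator", call. = FALSE)
    }
  }
  list(files = files, recorded_seconds = recorded, log = log)
}

#' Launch a session server in a background R process
#'
#' Convenience wrapper for loopback testing: starts an `Rscript` child
#' that calls [serve_session()] with a `data_source` serving the given
#' files, and returns immediately. The child exits after one served
#' session or on timeout.
#'
#' @param port TCP port.
#' @param files Character vector of file paths the server will transmit.
#' @param allowed_peer Peer token required at handshake.
#' @param timeout Child server timeout in seconds.
#' @return The child's log-file path (server output), invisibly.
#' @export
serve_in_background <- function(port, files, allowed_peer = "simulator",
                                timeout = 30) {
  rscript <- file.path(R.home("bin"), "Rscript")
  code <- sprintf(
    paste0(".libPaths(c(%s, .libPaths())); ",
           "fls <- c(%s); ",
           "drivesense::serve_session(port = %d, allowed_peer = '%s', ",
           "data_source = function(active) fls, timeout = %d)"),
    paste(sprintf("'%s'", .libPaths()), collapse = ", "),
    paste(sprintf("'%s'", files), collapse = ", "),
    as.integer(port), allowed_peer, as.integer(timeout))
  logf <- tempfile("server_log_", fileext = ".txt")
  system2(rscript, c("-e", shQuote(code)), wait = FALSE,
          stdout = logf, stderr = logf)
  invisible(logf)
}
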