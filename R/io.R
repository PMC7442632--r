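# Event-log serialization: JSON Lines with a schema-versioned header record
# carrying the config fingerprint and master seed, plus a flat CSV dialect
# for spreadsheet users and externally archived session data.

LOG_SCHEMA <- "apeworld-log/1"
EVENT_COLS <- c("day", "t", "type", "actor", "target", "x", "y",
                "detail", "value")

#' Write a session log to a JSON Lines file
#'
#' One JSON record per line: a header (schema version, master seed, config
#' and its fingerprint) followed by one record per event. Writing and
#' re-reading reproduces the log exactly.
#'
#' @param log a `session_log`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  header <- jsonlite::toJSON(
    list(schema = LOG_SCHEMA, seed = log$seed,
         fingerprint = log$fingerprint,
         final_points = log$final_points,
         config = unclass_deep(log$config)),
    auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(log$events)) {
    jsonlite::stream_out(log$events, con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

#' Read a session log from a JSON Lines file
#'
#' Validates the schema version, reconstructs the configuration (refusing a
#' header whose fingerprint does not match its own config), and checks that
#' event timestamps are non-decreasing and actors exist. Corrupt lines are
#' reported with their line number.
#'
#' @param path path to a file written by [write_log()].
#' @return A `session_log`.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty log file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1L]),
                     error = function(e) {
                       stop("corrupt header (line 1): ",
                            conditionMessage(e), call. = FALSE)
                     })
  if (!identical(header$schema, LOG_SCHEMA)) {
    stop("unsupported log schema '", header$schema, "' (expected '",
         LOG_SCHEMA, "')", call. = FALSE)
  }
  raw <- header$config
  raw$treatment <- do.call(treatment_params, raw$treatment)
  config <- do.call(world_config, raw)
  if (!identical(config_fingerprint(config), header$fingerprint)) {
    stop("config fingerprint mismatch: log header is internally ",
         "inconsistent", call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  events <- if (length(body)) {
    parsed <- tryCatch(
      jsonlite::stream_in(textConnection(body), verbose = FALSE),
      error = function(e) e)
    if (inherits(parsed, "error")) {
      for (k in seq_along(body)) {
        ok <- tryCatch({jsonlite::fromJSON(body[k]); TRUE},
                       error = function(e) FALSE)
        if (!ok) stop("corrupt log record at line ", k + 1L,
                      call. = FALSE)
      }
      stop("corrupt log body: ", conditionMessage(parsed), call. = FALSE)
    }
    for (cl in setdiff(EVENT_COLS, names(parsed))) parsed[[cl]] <- NA
    parsed <- parsed[EVENT_COLS]
    parsed$day <- as.integer(parsed$day)
    parsed$actor <- as.integer(parsed$actor)
    parsed$target <- as.integer(parsed$target)
    parsed$type <- as.character(parsed$type)
    parsed$detail <- as.character(parsed$detail)
    for (cl in c("t", "x", "y", "value")) {
      parsed[[cl]] <- as.numeric(parsed[[cl]])
    }
    parsed
  } else {
    empty_events()
  }
  log <- structure(
    list(config = config,
         fingerprint = header$fingerprint,
         seed = as.integer(header$seed),
         events = events,
         final_points = as.numeric(header$final_points)),
    class = "session_log")
  validate_session_log(log)
  log
}

empty_events <- function() {
  data.frame(day = integer(0), t = numeric(0), type = character(0),
             actor = integer(0), target = integer(0),
             x = numeric(0), y = numeric(0),
             detail = character(0), value = numeric(0),
             stringsAsFactors = FALSE)
}

validate_session_log <- function(log) {
  ev <- log$events
  if (nrow(ev)) {
    stamp <- ev$day * (log$config$day_length + 1) + ev$t
    if (any(diff(stamp) < -1e-9)) {
      stop("invalid log: event timestamps are not non-decreasing",
           call. = FALSE)
    }
    act <- ev$actor[!is.na(ev$actor)]
    if (length(act) && (any(act < 1) || any(act > log$config$n_avatars))) {
      stop("invalid log: event actor outside 1..", log$config$n_avatars,
           call. = FALSE)
    }
  }
  invisible(log)
}

#' Export / import session events as flat CSV
#'
#' The tabular dialect: the event columns (`day`, `t`, `type`, `actor`,
#' `target`, `x`, `y`, `detail`, `value`) as a plain CSV with a header row,
#' for spreadsheet use and for ingesting externally archived session data.
#' Because CSV carries no configuration, reading requires the
#' `world_config` the events were recorded under.
#'
#' @param log a `session_log`.
#' @param path CSV file path.
#' @return `write_events_csv()`: `path` invisibly; `read_session_csv()`:
#'   a `session_log`.
#' @export
write_events_csv <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  utils::write.csv(log$events, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @param config the `world_config` the events were recorded under.
#' @param seed the session seed, if known.
#' @export
read_session_csv <- function(path, config, seed = NA_integer_) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(day = "integer", t = "numeric",
                                       type = "character",
                                       actor = "integer",
                                       target = "integer",
                                       x = "numeric", y = "numeric",
                                       detail = "character",
                                       value = "numeric"))
  missing_cols <- setdiff(EVENT_COLS, names(ev))
  if (length(missing_cols)) {
    stop("CSV lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in c("type", "detail")) {
    ev[[cl]][!nzchar(ev[[cl]]) | is.na(ev[[cl]])] <- NA_character_
  }
  snap <- ev[ev$type == "points_snapshot", , drop = FALSE]
  fp <- rep(NA_real_, config$n_avatars)
  if (nrow(snap)) {
    last <- snap[snap$day == max(snap$day), , drop = FALSE]
    fp[last$actor] <- last$value
  }
  log <- structure(
    list(config = config,
         fingerprint = config_fingerprint(config),
         seed = as.integer(seed),
         events = ev[EVENT_COLS],
         final_points = fp),
    class = "session_log")
  validate_session_log(log)
  log
}

#' Write an analysis report as JSON
#'
#' @param report a `session_report` from [analyze_log()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null",
                       na = "null")
  invisible(path)
}
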