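#' Write / read a trial schedule
#'
#' Schedules serialize to a tidy CSV (one row per trial) with the session
#' kind, seed and generating config stored in `#`-prefixed header lines, so
#' a round trip preserves the object exactly. [read_schedule()] re-runs
#' [validate_schedule()] on load.
#'
#' @param schedule A [trial_schedule].
#' @param path File path.
#' @return `path` (write) or the schedule (read).
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# session_kind: %s", attr(schedule, "session_kind")),
    sprintf("# seed: %d", attr(schedule, "seed")),
    sprintf("# config: %s",
            jsonlite::toJSON(attr(schedule, "config"), auto_unbox = TRUE,
                             digits = NA))), con)
  write.csv(as.data.frame(schedule), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 3)
  grab <- function(key) sub(sprintf("^# %s: ", key), "",
                            hdr[grepl(sprintf("^# %s:", key), hdr)])
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  sched <- new_trial_schedule(
    df, grab("session_kind"),
    jsonlite::fromJSON(grab("config"), simplifyVector = TRUE),
    as.integer(grab("seed")))
  validate_schedule(sched)
  sched
}

#' Write / read an event log
#'
#' Plain CSV with columns `timestamp`, `code`, `trial`. Validated with
#' [validate_event_log()] on read.
#'
#' @param events Event-log tibble.
#' @param path File path.
#' @export
write_event_log <- function(events, path) {
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  log <- tibble::as_tibble(df)
  log$trial <- as.integer(log$trial)
  validate_event_log(log)
  log
}

#' Write / read a raw photometry stream
#'
#' CSV with columns `time`, `sig465`, `iso405`, `disconnect`; the sampling
#' rate is stored in a header line.
#'
#' @param raw A [raw_photometry()].
#' @param path File path.
#' @export
write_photometry <- function(raw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate: %.10g", raw$rate), con)
  write.csv(data.frame(time = raw$time, sig465 = raw$sig,
                       iso405 = raw$iso,
                       disconnect = as.integer(raw$disconnect_mask)),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photometry
#' @export
read_photometry <- function(path) {
  hdr <- readLines(path, n = 1)
  rate <- as.numeric(sub("^# rate: ", "", hdr))
  df <- read.csv(path, comment.char = "#")
  raw_photometry(df$time, df$sig465, df$iso405, rate,
                 disconnect_mask = df$disconnect == 1L)
}

#' Write / read an epoch matrix
#'
#' Long-format CSV (`trial`, `trial_type`, `rel_time`, `z`) with alignment
#' metadata in header lines; round-trips an `epoch_matrix` losslessly up to
#' numeric printing precision.
#'
#' @param epoch An `epoch_matrix`.
#' @param path File path.
#' @export
write_epochs <- function(epoch, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# align_event: %s", epoch$align_event),
    sprintf("# baseline_window: %.10g %.10g", epoch$baseline_window[1],
            epoch$baseline_window[2])), con)
  long <- data.frame(
    trial = rep(epoch$trial, each = length(epoch$rel_time)),
    trial_type = rep(epoch$trial_type, each = length(epoch$rel_time)),
    rel_time = rep(epoch$rel_time, times = nrow(epoch$z)),
    z = as.vector(t(epoch$z)))
  write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  hdr <- readLines(path, n = 2)
  align <- sub("^# align_event: ", "", hdr[1])
  bw <- as.numeric(strsplit(sub("^# baseline_window: ", "", hdr[2]),
                            " ")[[1]])
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  trials <- unique(df$trial)
  rel <- unique(df$rel_time)
  z <- matrix(df$z, nrow = length(trials), byrow = TRUE)
  structure(list(
    z = z, rel_time = rel, trial = as.integer(trials),
    trial_type = df$trial_type[match(trials, df$trial)],
    align_event = align, baseline_window = bw,
    excluded = tibble::tibble(trial = integer(), reason = character())),
    class = "epoch_matrix")
}

#' Read a flat key-value configuration file
#'
#' Parses a YAML-style flat `key: value` file and checks every key against
#' the formals of [sim_config()] plus the schedule parameters, erroring on
#' unknown keys.
#'
#' @param path File path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$",
                                  lines))
  if (any(lengths(kv) != 3))
    stop_config("malformed config line: %s",
                lines[which(lengths(kv) != 3)[1]])
  keys <- vapply(kv, `[[`, character(1), 2)
  vals <- lapply(kv, function(m) {
    v <- trimws(m[[3]])
    num <- suppressWarnings(as.numeric(strsplit(v, ",\\s*")[[1]]))
    if (!anyNA(num)) num else v
  })
  names(vals) <- keys
  known <- unique(c(names(formals(sim_config)), names(formals(pla_schedule)),
                    names(formals(rpe_schedule)),
                    names(formals(magazine_schedules)),
                    "n_rats", "session_kind", "rate"))
  bad <- setdiff(keys, known)
  if (length(bad))
    stop_config("unknown config key(s): %s", paste(bad, collapse = ", "))
  vals
}
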