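# Raw trial-log I/O.
#
# The exoskeleton's own raw file layout is proprietary and undocumented, so
# the package defines a plain-text stand-in dialect: one UTF-8 CSV per trial,
# a metadata block of '#' comment lines, then rows of type SAMPLE (t, x, y)
# and EVENT (t, target_index, kind) merged by timestamp. Timestamps are
# trial-relative seconds printed with 6 decimals; positions are cm with 4
# decimals; x points rightward, y away from the subject, origin at the
# lower-left corner of the workspace.

EVENT_KINDS <- c("appeared", "caught", "timed_out")

#' Construct a trial recording
#'
#' A trial recording is the unit of parsing: one trial's raw 64 Hz hand
#' position samples in the horizontal plane together with the timestamped
#' target event log (each target appears once and is then either caught or
#' times out after at most 10 s).
#'
#' @param subject_id Character subject identifier (used in file names, so it
#'   must not contain `_s` or path separators).
#' @param session_index Session number, 1-3.
#' @param trial_index Trial number within the session, 1-10.
#' @param samples `data.frame` with columns `t` (s, strictly increasing,
#'   starting at or after 0), `x`, `y` (cm).
#' @param events `data.frame` with columns `t` (s), `target_index` (1-12)
#'   and `kind` (`"appeared"`, `"caught"` or `"timed_out"`).
#' @param workspace Numeric length-2, workspace width and height in cm.
#' @param rate_hz Nominal sampling rate, Hz.
#' @param validate Run [validate_trial_recording()] on the result?
#'
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, session_index, trial_index,
                            samples, events,
                            workspace = c(40, 30), rate_hz = 64,
                            validate = TRUE) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         session_index = as.integer(session_index),
         trial_index = as.integer(trial_index),
         samples = as.data.frame(samples),
         events = as.data.frame(events),
         workspace = as.numeric(workspace),
         rate_hz = as.numeric(rate_hz)),
    class = "trial_recording")
  rec$events$kind <- as.character(rec$events$kind)
  if (validate) validate_trial_recording(rec)
  rec
}

#' Validate a trial recording against the domain invariants
#'
#' Checks sample monotonicity, the per-target event grammar
#' (`appeared` followed by exactly one of `caught`/`timed_out`), the 10 s
#' per-target limit, the 120 s trial cap and the 12-target maximum. Gaps
#' larger than 1.5 nominal sampling intervals are tolerated but reported as
#' messages (interpolation, if any, is a kinematics-layer decision).
#'
#' @param rec A `trial_recording`.
#' @param gap_tolerance Multiple of the nominal sampling interval above which
#'   a gap between consecutive samples is reported.
#' @return `rec`, invisibly; errors of class `armkin_validation_error`
#'   otherwise.
#' @export
validate_trial_recording <- function(rec, gap_tolerance = 1.5) {
  s <- rec$samples
  e <- rec$events
  if (!all(c("t", "x", "y") %in% names(s)))
    stop_validation("samples must have columns t, x, y")
  if (!all(c("t", "target_index", "kind") %in% names(e)))
    stop_validation("events must have columns t, target_index, kind")
  if (nrow(s) > 0) {
    if (any(!is.finite(s$t)) || s$t[1] < 0)
      stop_validation("sample timestamps must be finite and non-negative")
    if (nrow(s) > 1 && any(diff(s$t) <= 0))
      stop_validation("sample timestamps must be strictly increasing")
    dt <- 1 / rec$rate_hz
    gaps <- which(diff(s$t) > gap_tolerance * dt)
    if (length(gaps))
      message(sprintf("trial %s/s%d/t%d: %d sampling gap(s) > %.2g s tolerated",
                      rec$subject_id, rec$session_index, rec$trial_index,
                      length(gaps), gap_tolerance * dt))
  }
  if (!(rec$session_index %in% 1:3))
    stop_validation("session_index must be in 1..3")
  if (!(rec$trial_index %in% 1:10))
    stop_validation("trial_index must be in 1..10")
  if (nrow(e) > 0) {
    if (any(!e$kind %in% EVENT_KINDS))
      stop_validation("unknown event kind(s): %s",
                      paste(setdiff(e$kind, EVENT_KINDS), collapse = ", "))
    if (any(e$target_index < 1 | e$target_index > 12))
      stop_validation("target_index must be in 1..12 (at most 12 targets)")
    if (is.unsorted(e$t)) stop_validation("event timestamps must be ordered")
    for (tg in unique(e$target_index)) {
      ev <- e[e$target_index == tg, , drop = FALSE]
      if (sum(ev$kind == "appeared") != 1L)
        stop_validation("target %d must have exactly one 'appeared' event", tg)
      res <- ev[ev$kind != "appeared", , drop = FALSE]
      if (nrow(res) != 1L)
        stop_validation(
          "target %d must have exactly one 'caught' or 'timed_out' event", tg)
      if (res$t < ev$t[ev$kind == "appeared"])
        stop_validation("target %d resolved before it appeared", tg)
      if (res$t - ev$t[ev$kind == "appeared"] > 10 + 1 / rec$rate_hz)
        stop_validation("target %d resolved more than 10 s after appearing", tg)
    }
    dur <- max(e$t, if (nrow(s)) max(s$t) else -Inf) -
      min(e$t, if (nrow(s)) min(s$t) else Inf)
    if (dur > 120 + 1 / rec$rate_hz)
      stop_validation("trial duration %.2f s exceeds the 120 s maximum", dur)
  }
  invisible(rec)
}

#' @export
print.trial_recording <- function(x, ...) {
  caught <- sum(x$events$kind == "caught")
  appeared <- sum(x$events$kind == "appeared")
  cat(sprintf("<trial_recording> %s session %d trial %d: %d samples @ %g Hz, %d/%d targets caught\n",
              x$subject_id, x$session_index, x$trial_index,
              nrow(x$samples), x$rate_hz, caught, appeared))
  invisible(x)
}

fmt_t <- function(t) sprintf("%.6f", t)
fmt_xy <- function(p) sprintf("%.4f", p)

#' Write a trial recording to a CSV trial log
#'
#' Serializes a [trial_recording()] into the package's plain-text log
#' dialect. The file round-trips through [parse_trial_log()] to an equal
#' recording (timestamps at 6 decimals, positions at 4).
#'
#' @param rec A valid `trial_recording` with at least one sample.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(rec, path) {
  validate_trial_recording(rec)
  if (nrow(rec$samples) == 0)
    stop_armkin("refusing to serialize a trial recording with no samples")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop_armkin("cannot open '%s' for writing", path))
  on.exit(close(con))
  meta <- c(
    sprintf("# subject=%s", rec$subject_id),
    sprintf("# session=%d", rec$session_index),
    sprintf("# trial=%d", rec$trial_index),
    sprintf("# workspace_cm=%gx%g", rec$workspace[1], rec$workspace[2]),
    sprintf("# rate_hz=%g", rec$rate_hz),
    "type,t,a,b")
  srow <- data.frame(t = rec$samples$t,
                     line = sprintf("SAMPLE,%s,%s,%s", fmt_t(rec$samples$t),
                                    fmt_xy(rec$samples$x), fmt_xy(rec$samples$y)),
                     prio = 1L)
  erow <- data.frame(t = rec$events$t,
                     line = sprintf("EVENT,%s,%d,%s", fmt_t(rec$events$t),
                                    rec$events$target_index, rec$events$kind),
                     prio = 0L)
  merged <- rbind(erow, srow)
  # merge by timestamp; events sort before samples at equal times
  merged <- merged[order(merged$t, merged$prio), ]
  writeLines(c(meta, merged$line), con)
  invisible(path)
}

parse_meta_line <- function(line, lineno) {
  m <- regmatches(line, regexec("^# *([a-z_]+) *= *(.+) *$", line))[[1]]
  if (length(m) != 3)
    stop_parse("line %d: malformed metadata line '%s'", lineno, line)
  setNames(list(m[3]), m[2])
}

#' Parse a CSV trial log
#'
#' Reads a file written in the trial-log dialect (see [write_trial_log()])
#' back into a validated [trial_recording()]. Sample and event streams are
#' separated from the merged rows and validated against the event grammar.
#'
#' @param path Path to a trial log file.
#' @return A `trial_recording`.
#' @export
parse_trial_log <- function(path) {
  if (!file.exists(path)) stop_armkin("file '%s' does not exist", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    meta <- c(meta, parse_meta_line(lines[i], i))
    i <- i + 1L
  }
  required <- c("subject", "session", "trial")
  if (!all(required %in% names(meta)))
    stop_parse("missing metadata line(s): %s",
               paste(setdiff(required, names(meta)), collapse = ", "))
  if (i > length(lines) || lines[i] != "type,t,a,b")
    stop_parse("line %d: expected header 'type,t,a,b'", i)
  body <- lines[-seq_len(i)]
  lineno <- i + seq_along(body)
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop_parse("line %d: expected 4 comma-separated fields", lineno[bad[1]])
  type <- vapply(parts, `[[`, "", 1L)
  tval <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tval))
    stop_parse("line %d: non-numeric timestamp", lineno[which(is.na(tval))[1]])
  is_s <- type == "SAMPLE"
  is_e <- type == "EVENT"
  if (any(!is_s & !is_e))
    stop_parse("line %d: unknown row type '%s'",
               lineno[which(!is_s & !is_e)[1]], type[which(!is_s & !is_e)[1]])
  xs <- suppressWarnings(as.numeric(vapply(parts[is_s], `[[`, "", 3L)))
  ys <- suppressWarnings(as.numeric(vapply(parts[is_s], `[[`, "", 4L)))
  if (anyNA(xs) || anyNA(ys))
    stop_parse("line %d: non-numeric position",
               lineno[is_s][which(is.na(xs) | is.na(ys))[1]])
  ti <- suppressWarnings(as.integer(vapply(parts[is_e], `[[`, "", 3L)))
  if (anyNA(ti) && any(is_e))
    stop_parse("line %d: non-integer target index",
               lineno[is_e][which(is.na(ti))[1]])
  ws <- c(40, 30)
  if (!is.null(meta$workspace_cm)) {
    ws <- suppressWarnings(as.numeric(strsplit(meta$workspace_cm, "x")[[1]]))
    if (length(ws) != 2 || anyNA(ws))
      stop_parse("malformed workspace_cm metadata '%s'", meta$workspace_cm)
  }
  trial_recording(
    subject_id = meta$subject,
    session_index = as.integer(meta$session),
    trial_index = as.integer(meta$trial),
    samples = data.frame(t = tval[is_s], x = xs, y = ys),
    events = data.frame(t = tval[is_e], target_index = ti,
                        kind = vapply(parts[is_e], `[[`, "", 4L)),
    workspace = ws,
    rate_hz = as.numeric(meta$rate_hz %||% 64))
}

#' Load a directory of trial logs into session recordings
#'
#' Files must follow the naming convention `<subject>_s<session>_t<trial>.csv`.
#' Recordings are grouped by subject and session with trials ordered;
#' partial sessions (fewer than 10 trials) are allowed and reported with a
#' warning, duplicated (subject, session, trial) triples are an error.
#'
#' @param directory Directory containing trial logs.
#' @return A list of `session_recording` objects, each a list with
#'   `subject_id`, `session_index` and `trials` (a list of
#'   `trial_recording`s).
#' @export
load_cohort <- function(directory) {
  if (!dir.exists(directory)) stop_armkin("'%s' is not a directory", directory)
  files <- list.files(directory, pattern = "^.+_s[0-9]+_t[0-9]+\\.csv$",
                      full.names = TRUE)
  if (!length(files)) stop_armkin("no trial logs found in '%s'", directory)
  recs <- lapply(files, parse_trial_log)
  key <- vapply(recs, function(r)
    sprintf("%s|%d|%d", r$subject_id, r$session_index, r$trial_index), "")
  if (anyDuplicated(key))
    stop_armkin("duplicate trial log for %s", key[duplicated(key)][1])
  skey <- vapply(recs, function(r)
    sprintf("%s|%d", r$subject_id, r$session_index), "")
  out <- lapply(split(recs, skey), function(trials) {
    trials <- trials[order(vapply(trials, `[[`, 0L, "trial_index"))]
    structure(list(subject_id = trials[[1]]$subject_id,
                   session_index = trials[[1]]$session_index,
                   trials = trials),
              class = "session_recording")
  })
  out <- unname(out[order(names(out))])
  # report subjects with missing sessions or short sessions
  subj <- vapply(out, `[[`, "", "subject_id")
  for (s in unique(subj)) {
    have <- sort(vapply(out[subj == s], `[[`, 0L, "session_index"))
    if (!identical(have, 1:3))
      warning(sprintf("subject %s: sessions present: %s",
                      s, paste(have, collapse = ",")), call. = FALSE)
    nt <- vapply(out[subj == s], function(x) length(x$trials), 0L)
    if (any(nt < 10))
      message(sprintf("subject %s: partial session(s) with %s trials",
                      s, paste(nt[nt < 10], collapse = ",")))
  }
  out
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s session %d: %d trial(s)\n",
              x$subject_id, x$session_index, length(x$trials)))
  invisible(x)
}
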