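# Unitary-movement segmentation and kinematic parameters.
#
# A unitary movement is the hand trajectory between two consecutively caught
# targets; movements whose start or end target timed out are discarded, and
# the movement into target 1 never exists (there is no preceding catch), so
# a complete 12-target trial yields at most 11 movements. This mirrors the
# exclusion of the first trajectory: subjects often start with the hand
# already over the first ball, so that movement does not reflect a real
# reach.

#' Kinematics configuration
#'
#' @param cutoff_hz Low-pass cutoff (Hz) applied to the speed signal before
#'   peak analysis. A 2nd-order zero-phase Butterworth filter is used; raw
#'   64 Hz differentiation is noise-dominated, so peak counting without a
#'   documented filter would not be reproducible. Set `smoothing = FALSE`
#'   to disable.
#' @param smoothing Apply the low-pass filter?
#' @param min_displacement_cm Movements whose straight-line displacement is
#'   below this are degenerate (HPR undefined) and are dropped from
#'   movement-level averages.
#' @param rate_hz Nominal sampling rate (Hz), used for filter design.
#' @return A list of class `kin_config`.
#' @export
kin_config <- function(cutoff_hz = 6, smoothing = TRUE,
                       min_displacement_cm = 0.5, rate_hz = 64) {
  assert_scalar_number(cutoff_hz, "cutoff_hz")
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2)
    stop_armkin("cutoff_hz must lie in (0, rate_hz/2)")
  structure(list(cutoff_hz = cutoff_hz, smoothing = isTRUE(smoothing),
                 min_displacement_cm = min_displacement_cm,
                 rate_hz = rate_hz),
            class = "kin_config")
}

# Cache Butterworth designs: filter design is pure and depends only on
# (cutoff, rate), and trial processing calls it once per movement.
.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(cutoff_hz, rate_hz) {
  key <- sprintf("%g|%g", cutoff_hz, rate_hz)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
    .butter_cache[[key]] <- bf
  }
  bf
}

#' Segment a trial into unitary movements
#'
#' Produces one movement per pair of consecutively indexed targets that were
#' both caught, anchored to the two catch events; trajectory samples are
#' taken in the closed time interval between them. Movements with fewer
#' than 2 samples are skipped.
#'
#' @param rec A `trial_recording`.
#' @return A list of `unitary_movement` objects (possibly empty), each with
#'   fields `from_target`, `to_target`, `t_start`, `t_end`, `duration` and
#'   `samples`.
#' @export
segment_movements <- function(rec) {
  ev <- rec$events
  caught <- ev[ev$kind == "caught", , drop = FALSE]
  if (nrow(caught) < 2) return(list())
  catch_time <- setNames(caught$t, caught$target_index)
  idx <- sort(as.integer(names(catch_time)))
  out <- list()
  for (k in idx[(idx + 1L) %in% idx]) {
    t0 <- catch_time[[as.character(k)]]
    t1 <- catch_time[[as.character(k + 1L)]]
    keep <- rec$samples$t >= t0 & rec$samples$t <= t1
    if (sum(keep) < 2) next
    out[[length(out) + 1L]] <- structure(
      list(from_target = k, to_target = k + 1L,
           t_start = t0, t_end = t1, duration = t1 - t0,
           samples = rec$samples[keep, , drop = FALSE]),
      class = "unitary_movement")
  }
  out
}

central_diff <- function(p, t) {
  n <- length(p)
  v <- numeric(n)
  if (n >= 3)
    v[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  v[1] <- (p[2] - p[1]) / (t[2] - t[1])
  v[n] <- (p[n] - p[n - 1]) / (t[n] - t[n - 1])
  v
}

#' Planar speed profile of a movement
#'
#' Differentiates the x and y positions by central finite differences and,
#' by default, low-pass filters the resulting planar speed magnitude with a
#' zero-phase Butterworth filter (see [kin_config()]). Very short segments
#' (< 15 samples) are left unfiltered because zero-phase filtering needs
#' padding; the descriptor records what was applied.
#'
#' @param m A `unitary_movement` or a `data.frame` with columns `t`, `x`, `y`.
#' @param cfg A [kin_config()].
#' @return A `velocity_profile`: list with `t`, `speed` (cm/s, >= 0) and
#'   `smoothing` descriptor.
#' @export
compute_speed <- function(m, cfg = kin_config()) {
  s <- if (inherits(m, "unitary_movement")) m$samples else as.data.frame(m)
  if (nrow(s) < 2) stop_armkin("need at least 2 samples to differentiate")
  if (anyDuplicated(s$t)) stop_armkin("duplicated timestamps in movement")
  vx <- central_diff(s$x, s$t)
  vy <- central_diff(s$y, s$t)
  speed <- sqrt(vx^2 + vy^2)
  desc <- "none"
  if (cfg$smoothing && length(speed) >= 15) {
    bf <- butter_coefs(cfg$cutoff_hz, cfg$rate_hz)
    speed <- pmax(signal::filtfilt(bf, speed), 0)
    desc <- sprintf("butterworth2-zerophase-%gHz", cfg$cutoff_hz)
  } else if (cfg$smoothing) {
    desc <- "none (segment too short to filter)"
  }
  structure(list(t = s$t, speed = speed, smoothing = desc),
            class = "velocity_profile")
}

#' Peak velocity of a movement
#'
#' Maximum of the (smoothed) planar speed profile, cm/s.
#'
#' @param v A `velocity_profile`.
#' @return Peak speed in cm/s.
#' @export
peak_velocity <- function(v) {
  if (!length(v$speed)) stop_armkin("empty velocity profile")
  max(v$speed)
}

#' Number of velocity peaks (movement smoothness)
#'
#' Counts strict positive-to-negative sign changes of the discrete speed
#' derivative. Runs of zero derivative are compressed first, so a
#' flat-topped maximum counts once. Fewer peaks indicate a smoother
#' movement; a single minimum-jerk reach has exactly one.
#'
#' @param v A `velocity_profile`.
#' @return Integer peak count (>= 0).
#' @export
n_velocity_peaks <- function(v) {
  if (!length(v$speed)) stop_armkin("empty velocity profile")
  s <- sign(diff(v$speed))
  s <- s[s != 0]                      # plateau compression
  if (length(s) < 2) return(0L)
  sum(s[-length(s)] == 1 & s[-1] == -1)
}

#' Hand path ratio (spatial efficiency)
#'
#' Ratio of the traveled path length (sum of successive Euclidean steps) to
#' the straight-line distance between the positions at the two catch events;
#' 1 for a perfectly straight reach, larger for curved or corrective paths.
#'
#' @param m A `unitary_movement`.
#' @param min_displacement_cm Displacements below this are degenerate and
#'   return `NA` (the movement should be dropped by the caller).
#' @return Dimensionless ratio >= 1, or `NA` for degenerate movements.
#' @export
hand_path_ratio <- function(m, min_displacement_cm = 0.5) {
  s <- m$samples
  n <- nrow(s)
  chord <- sqrt((s$x[n] - s$x[1])^2 + (s$y[n] - s$y[1])^2)
  if (chord < min_displacement_cm) return(NA_real_)
  path <- sum(sqrt(diff(s$x)^2 + diff(s$y)^2))
  path / chord
}

#' Movement time
#'
#' Event-based duration of a unitary movement: catch time of the target
#' reached minus catch time of the previous target (at most 10 s).
#'
#' @param m A `unitary_movement`.
#' @return Duration in seconds.
#' @export
movement_time <- function(m) m$duration

#' Task time
#'
#' Time from the first target appearance to the last target resolution
#' (caught or timed out), capped at the 120 s exercise maximum.
#'
#' @param rec A `trial_recording`.
#' @return Duration in seconds.
#' @export
task_time <- function(rec) {
  ev <- rec$events
  if (!nrow(ev)) stop_armkin("trial has no target events")
  t0 <- min(ev$t[ev$kind == "appeared"])
  t1 <- max(ev$t[ev$kind != "appeared"])
  min(t1 - t0, 120)
}

#' Game score
#'
#' Percentage of presented targets that were caught. If the trial was
#' truncated, targets that never appeared do not enter the denominator.
#'
#' @param rec A `trial_recording`.
#' @return Score in percent, 0-100.
#' @export
score <- function(rec) {
  ev <- rec$events
  appeared <- sum(ev$kind == "appeared")
  if (appeared < 1) stop_armkin("trial has no appeared targets")
  100 * sum(ev$kind == "caught") / appeared
}

#' Relative timing of the velocity peak
#'
#' Time of the global speed maximum expressed as a percentage of the
#' movement duration (0 = at the start, 100 = at the end); ties are broken
#' by the earliest sample. A right shift indicates a longer corrective
#' phase after the ballistic launch.
#'
#' @param v A `velocity_profile`.
#' @return Percentage in \[0, 100\].
#' @export
perc_peak_vel <- function(v) {
  if (!length(v$speed)) stop_armkin("empty velocity profile")
  n <- length(v$t)
  dur <- v$t[n] - v$t[1]
  if (dur <= 0) return(0)
  100 * (v$t[which.max(v$speed)] - v$t[1]) / dur
}

#' Per-trial kinematic parameters
#'
#' Segments the trial, computes the per-movement parameters (MovementTime,
#' PeakVel, HPR, nPeak, PercPeakVel), drops degenerate movements
#' (displacement below `cfg$min_displacement_cm`), and averages over the
#' remaining valid movements. TaskTime and Score are computed at trial
#' level. With zero valid movements the movement-level fields are `NA` and
#' the trial-level fields are still returned.
#'
#' @param rec A `trial_recording`.
#' @param cfg A [kin_config()].
#' @return A one-row `data.frame` with columns `subject`, `session`,
#'   `trial`, `TaskTime`, `MovementTime`, `PeakVel`, `HPR`, `nPeak`,
#'   `Score`, `PercPeakVel` and `n_valid_movements`.
#' @export
trial_kinematics <- function(rec, cfg = kin_config()) {
  moves <- segment_movements(rec)
  mt <- pv <- hpr <- np <- ppv <- numeric(0)
  for (m in moves) {
    h <- hand_path_ratio(m, cfg$min_displacement_cm)
    if (is.na(h)) next                # degenerate: displacement too small
    v <- compute_speed(m, cfg)
    mt <- c(mt, movement_time(m))
    pv <- c(pv, peak_velocity(v))
    np <- c(np, n_velocity_peaks(v))
    ppv <- c(ppv, perc_peak_vel(v))
    hpr <- c(hpr, h)
  }
  nv <- length(mt)
  avg <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(subject = rec$subject_id,
             session = rec$session_index,
             trial = rec$trial_index,
             TaskTime = task_time(rec),
             MovementTime = avg(mt),
             PeakVel = avg(pv),
             HPR = avg(hpr),
             nPeak = avg(np),
             Score = score(rec),
             PercPeakVel = avg(ppv),
             n_valid_movements = nv,
             stringsAsFactors = FALSE)
}

#' Kinematic parameter table for a whole cohort
#'
#' Applies [trial_kinematics()] to every trial of every session recording
#' and returns the long-format parameter table used by the aggregation,
#' learning and reliability modules.
#'
#' @param sessions A list of `session_recording`s (see [load_cohort()] or
#'   [synth_cohort()]).
#' @param cfg A [kin_config()].
#' @return A `data.frame` with columns `subject`, `session`, `trial`,
#'   `parameter`, `value` (one row per parameter per trial).
#' @export
cohort_kinematics <- function(sessions, cfg = kin_config()) {
  rows <- lapply(sessions, function(sr)
    do.call(rbind, lapply(sr$trials, trial_kinematics, cfg = cfg)))
  wide <- do.call(rbind, rows)
  long <- do.call(rbind, lapply(KIN_PARAMETERS, function(p)
    data.frame(subject = wide$subject, session = wide$session,
               trial = wide$trial, parameter = p, value = wide[[p]],
               stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  long[order(long$subject, long$session, long$trial, long$parameter), ]
}
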