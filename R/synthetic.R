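# Synthetic cohort generation.
#
# Raw trial logs are not publicly deposited for this assessment task, so the
# package ships a generator that emulates their statistical structure from
# the ground up: minimum-jerk submovement trajectories along curved paths,
# per-subject ability (mapping to speed, pauses, curvature, submovement
# count and catch probability), exponential learning over cumulative trials
# with a between-session retention multiplier, per-(subject, session) day
# effects (the "session bias" variance component) and additive sensor
# noise. Every emitted movement is recorded in a ground-truth table so that
# downstream estimates can be checked against what was generated.

# minimum-jerk displacement fraction at normalized time tau in [0,1]
min_jerk_sigma <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# Solve theta / sin(theta) = ratio for the circular-arc half-angle.
arc_half_angle <- function(ratio) {
  if (ratio <= 1 + 1e-9) return(0)
  if (ratio >= pi / 2 / sin(pi / 2 - 1e-6)) {
    # cap just below a semicircle-and-beyond regime we never need
    ratio <- min(ratio, 10)
  }
  stats::uniroot(function(th) th / sin(th) - ratio,
                 lower = 1e-8, upper = pi - 1e-6, tol = 1e-10)$root
}

# Point(s) on the arc at displacement fraction u in [0,1], local frame:
# chord from (0,0) to (D,0), arc bulging toward +y.
arc_point <- function(u, D, theta) {
  if (theta == 0) return(cbind(x = u * D, y = 0 * u))
  R <- D / (2 * sin(theta))
  cy <- -R * cos(theta)
  beta <- pi / 2 + theta - 2 * theta * u
  cbind(x = D / 2 + R * cos(beta), y = cy + R * sin(beta))
}

#' Generate one reaching movement
#'
#' Builds a planar trajectory whose displacement along a circular-arc path
#' is a superposition of `n_submovements` equal minimum-jerk lobes. The
#' chord length is `D` and the arc/chord ratio equals `curvature`, so the
#' noiseless hand path ratio of the movement equals `curvature`. Lobes are
#' tiled over the duration with `sub_gap` seconds of rest between them;
#' the total duration `T` must accommodate all lobes.
#'
#' @param D Chord length, cm (> 0).
#' @param T Total movement duration, s (<= 10).
#' @param n_submovements Number of minimum-jerk lobes (>= 1); with rests
#'   between them, each contributes one velocity peak.
#' @param curvature Arc length / chord length (>= 1; 1 = straight).
#' @param noise_sd Additive Gaussian position noise, cm, per axis.
#' @param rate_hz Sampling rate.
#' @param sub_gap Rest between consecutive lobes, s.
#' @return `data.frame` with columns `t`, `x`, `y`; local frame from
#'   (0,0) to (D,0), arc bulging toward +y.
#' @export
synth_movement <- function(D, T, n_submovements = 1, curvature = 1,
                           noise_sd = 0, rate_hz = 64, sub_gap = 0) {
  if (T > 10) stop_armkin("movement duration exceeds the 10 s target limit")
  synth_movement_impl(D, T, n_submovements, curvature, noise_sd, rate_hz,
                      sub_gap)
}

# Trajectory builder without the 10 s guard: trial simulation generates
# attempts slower than the target limit and truncates them at timeout.
# Returns a plain xy matrix (hot path).
synth_movement_xy <- function(D, T, n_submovements = 1, curvature = 1,
                              noise_sd = 0, rate_hz = 64, sub_gap = 0) {
  assert_scalar_number(D, "D"); assert_scalar_number(T, "T")
  if (D <= 0) stop_armkin("D must be positive")
  n <- as.integer(n_submovements)
  if (n < 1) stop_armkin("n_submovements must be >= 1")
  t_sub <- (T - (n - 1) * sub_gap) / n
  if (t_sub <= 0)
    stop_armkin("infeasible submovement layout: %d lobes with %.2g s gaps do not fit in %.2g s",
                n, sub_gap, T)
  t <- seq(0, T, by = 1 / rate_hz)
  g <- numeric(length(t))
  for (i in seq_len(n)) {
    onset <- (i - 1) * (t_sub + sub_gap)
    g <- g + min_jerk_sigma((t - onset) / t_sub) / n
  }
  theta <- arc_half_angle(curvature)
  p <- arc_point(g, D, theta)
  if (noise_sd > 0)
    p <- p + matrix(rnorm(2 * length(t), 0, noise_sd), ncol = 2)
  p
}

synth_movement_impl <- function(D, T, n_submovements = 1, curvature = 1,
                                noise_sd = 0, rate_hz = 64, sub_gap = 0) {
  p <- synth_movement_xy(D, T, n_submovements, curvature, noise_sd, rate_hz,
                         sub_gap)
  data.frame(t = seq(0, by = 1 / rate_hz, length.out = nrow(p)),
             x = p[, 1], y = p[, 2])
}

#' Cohort specification for the synthetic generator
#'
#' Bundles the study conditions (cohort size, 3 sessions of 10 trials of a
#' 12-target catch in a 40 x 30 cm workspace at 64 Hz) with the learning
#' model and the generator's calibration constants. The default constants
#' were calibrated once so that sessions 2-3 of a default cohort land near
#' the published scale of the task (MovementTime ~3 s, PeakVel ~28 cm/s,
#' Score ~70%, TaskTime ~55 s, HPR ~1.85, nPeak ~6).
#'
#' @param n_subjects Number of subjects.
#' @param n_sessions,n_trials,n_targets Design dimensions.
#' @param workspace Width and height, cm.
#' @param rate_hz Sampling rate.
#' @param seed Cohort-level seed; per-subject streams are derived from it
#'   deterministically, so enlarging the cohort does not replay existing
#'   subjects.
#' @param learning_rate Exponential approach rate to asymptote, per trial.
#' @param retention Fraction of accumulated learning gain retained across a
#'   session boundary (1 = perfect retention).
#' @param ability_range Uniform range of the latent ability scalar.
#' @param noise_sd White sensor position noise, cm. Defaults to 0: because
#'   the number of ripple maxima of low-pass-filtered white noise does not
#'   shrink with its amplitude, any white floor would dominate the peak
#'   count during pauses, which real recordings do not show. Small smooth
#'   postural wobble (see `wobble_amp`) models hand unsteadiness instead.
#' @param constants Named list of calibration constants; see the vignette.
#'   Any entry supplied here overrides the default.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 30, n_sessions = 3, n_trials = 10,
                        n_targets = 12, workspace = c(40, 30), rate_hz = 64,
                        seed = 1, learning_rate = 0.35, retention = 1,
                        ability_range = c(0.08, 1), noise_sd = 0,
                        constants = list()) {
  if (retention < 0 || retention > 1)
    stop_armkin("retention must be in [0, 1]")
  if (learning_rate < 0) stop_armkin("learning_rate must be >= 0")
  defaults <- list(
    v_base = 4, v_gain = 55, v_pow = 1.35, v_subj_sd = 0.10, v_move_sd = 0.12,
    day_v_shift = 2.2,
    dwell_asym_base = 0.3, dwell_asym_gain = 0.9,
    dwell_amp_base = 0.9, dwell_amp_gain = 0.9, dwell_move_sd = 0.35,
    lambda_base = 0.5, lambda_gain = 2.0,
    lambda_learn_floor = 0.55, lambda_learn_amp = 0.8,
    miss_base = 0.97, miss_pow = 2.2, miss_offset = 1.5,
    curv_base = 0.35, curv_gain = 1.3,
    curv_learn_floor = 0.7, curv_learn_amp = 0.55, curv_move_sd = 0.25,
    sub_gap = 0.18,
    day_dwell_sd = 0.12, day_curv_sd = 0.08,
    day_lambda_sd = 0.10, day_cor = 0.9,
    wobble_amp = 0.06, wobble_freq = c(0.5, 2),
    start_offset = 1.5, min_target_sep = 6)
  unknown <- setdiff(names(constants), names(defaults))
  if (length(unknown))
    stop_armkin("unknown constant(s): %s", paste(unknown, collapse = ", "))
  defaults[names(constants)] <- constants
  structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                 n_trials = n_trials, n_targets = n_targets,
                 workspace = workspace, rate_hz = rate_hz, seed = seed,
                 learning_rate = learning_rate, retention = retention,
                 ability_range = ability_range, noise_sd = noise_sd,
                 constants = defaults),
            class = "cohort_spec")
}

# Accumulated learning gain in [0,1) before a given trial: within a session
# the gain approaches 1 exponentially per completed trial; at each session
# boundary the accumulated gain is multiplied by the retention fraction.
learning_gain <- function(session, trial, rate, retention, n_trials = 10) {
  g <- 0
  for (s in seq_len(session)) {
    if (s > 1) g <- retention * g
    done <- if (s < session) n_trials else trial - 1
    if (done > 0) g <- 1 - (1 - g) * exp(-rate * done)
  }
  g
}

#' Draw a subject profile
#'
#' Maps a latent ability scalar in \[0, 1\] to the subject-level generative
#' parameters (peak speed, pause duration, submovement tendency, path
#' curvature) plus multiplicative random offsets, and draws the
#' per-session day effects. Uses the current RNG state.
#'
#' @param ability Latent ability in \[0, 1\] (1 = least impaired).
#' @param spec A [cohort_spec()].
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(ability, spec) {
  cst <- spec$constants
  inv <- 1 - ability
  ns <- spec$n_sessions
  # day-to-day form is shared across channels: fatigue, motivation and
  # spasticity move speed, pauses, smoothness and path quality together.
  # day_cor sets how much of each channel's day effect is the common factor.
  core <- rnorm(ns)
  rho <- cst$day_cor
  mix <- function(sign = 1) sign * (rho * core + sqrt(1 - rho^2) * rnorm(ns))
  day <- function(sd, sign = 1) exp(sd * mix(sign))
  structure(list(
    ability = ability,
    v = (cst$v_base + cst$v_gain * ability^cst$v_pow) *
      exp(rnorm(1, 0, cst$v_subj_sd)),
    dwell_asym = cst$dwell_asym_base + cst$dwell_asym_gain * inv,
    dwell_amp = cst$dwell_amp_base + cst$dwell_amp_gain * inv,
    lambda = cst$lambda_base + cst$lambda_gain * inv,
    curv = cst$curv_base + cst$curv_gain * inv,
    # peak speed moves by a similar absolute amount on a good vs bad day
    # regardless of baseline (additive, cm/s), so day-to-day speed
    # variability is homoscedastic across the ability range
    day_v = cst$day_v_shift * mix(1),             # good day: faster
    day_dwell = day(cst$day_dwell_sd, sign = -1), # ... shorter pauses
    day_curv = day(cst$day_curv_sd, sign = -1),   # ... straighter paths
    day_lambda = day(cst$day_lambda_sd, sign = -1)),
    class = "subject_profile")
}

# Rotate local movement samples (xy matrix) into the workspace frame:
# chord from p0 to p1, arc side flipped by 'flip'.
place_movement <- function(xy, p0, p1, flip) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  d <- sqrt(dx^2 + dy^2)
  cs <- dx / d; sn <- dy / d
  yy <- xy[, 2] * flip
  cbind(p0[1] + cs * xy[, 1] - sn * yy,
        p0[2] + sn * xy[, 1] + cs * yy)
}

#' Simulate one trial
#'
#' Presents the targets sequentially: before each reach the hand dwells at
#' its current position (reaction plus planning pause), then moves along a
#' curved minimum-jerk submovement trajectory. A target fails in one of
#' two ways: the reach is too slow (total required time exceeds the 10 s
#' limit; the hand is caught mid-reach) or it misses spatially (the hand
#' arrives near but not on the ball and hovers until the 10 s timeout) -
#' the latter dominates in impaired subjects and keeps the duration of
#' *successful* movements decoupled from the failure rate, as observed in
#' real cohorts where Score varies far more than MovementTime. The trial
#' is at most 12 x 10 s = 120 s by construction. All durations are
#' quantized to the sampling grid. Uses the current RNG state.
#'
#' @param profile A [subject_profile()].
#' @param subject_id,session,trial Identifiers.
#' @param spec A [cohort_spec()].
#' @param targets `n_targets x 2` matrix of target positions, cm.
#' @return List with `recording` (a [trial_recording()]) and `truth`
#'   (per-target `data.frame` of the generative parameters).
#' @export
synth_trial <- function(profile, subject_id, session, trial, spec, targets) {
  cst <- spec$constants
  rate <- spec$rate_hz
  g <- learning_gain(session, trial, spec$learning_rate, spec$retention,
                     spec$n_trials)
  inv_g <- 1 - g
  dwell_mean <- (profile$dwell_asym + profile$dwell_amp * inv_g) *
    profile$day_dwell[session]
  lambda <- profile$lambda * (cst$lambda_learn_floor +
                                cst$lambda_learn_amp * inv_g) *
    profile$day_lambda[session]
  curv_level <- profile$curv * (cst$curv_learn_floor +
                                  cst$curv_learn_amp * inv_g) *
    profile$day_curv[session]
  v_day <- max(profile$v + profile$day_v[session], 2)

  ang <- runif(1, 0, 2 * pi)
  hand <- targets[1, ] + cst$start_offset * c(cos(ang), sin(ang))
  nt <- spec$n_targets
  pos_blocks <- vector("list", nt)
  ev_t <- ev_tgt <- numeric(2 * nt)
  ev_kind <- character(2 * nt)
  tr_caught <- logical(nt)
  tr_D <- tr_L <- tr_curv <- tr_v <- tr_tmove <- tr_dwell <- tr_req <-
    numeric(nt)
  tr_nsub <- integer(nt)
  n_total <- 0L                       # samples emitted so far
  p_miss_subj <- cst$miss_base * (1 - profile$ability)^cst$miss_pow
  for (j in seq_len(nt)) {
    tgt <- targets[j, ]
    # spatial miss: the reach aims slightly off the ball and hovers there
    p_miss <- if (j == 1) 0.2 * p_miss_subj else p_miss_subj
    miss <- runif(1) < p_miss
    aim <- tgt
    if (miss) {
      ma <- runif(1, 0, 2 * pi)
      aim <- tgt + cst$miss_offset * exp(rnorm(1, 0, 0.3)) * c(cos(ma), sin(ma))
    }
    D <- max(sqrt(sum((aim - hand)^2)), 0.05)
    curv <- 1 + curv_level * exp(rnorm(1, 0, cst$curv_move_sd))
    L <- curv * D
    v <- v_day * exp(rnorm(1, 0, cst$v_move_sd))
    t_move <- min(max(1.875 * L / v, 3 / rate), 15)
    n_sub <- 1L + rpois(1, lambda)
    move_total <- t_move + (n_sub - 1L) * cst$sub_gap
    dwell <- dwell_mean * exp(rnorm(1, 0, cst$dwell_move_sd))
    if (j == 1) dwell <- 0.4 * dwell  # hand starts almost over ball 1
    n_dwell <- max(round(dwell * rate), 1L)
    n_move <- max(round(move_total * rate), 2L)
    required <- (n_dwell + n_move) / rate
    caught <- !miss && required <= 10
    t_app <- n_total / rate

    dwell_xy <- cbind(rep(hand[1], n_dwell), rep(hand[2], n_dwell)) +
      matrix(rnorm(2 * n_dwell, 0, spec$noise_sd), n_dwell, 2)
    mv <- synth_movement_xy(D, n_move / rate, n_submovements = n_sub,
                            curvature = curv, noise_sd = spec$noise_sd,
                            rate_hz = rate, sub_gap = cst$sub_gap)
    mv_xy <- place_movement(mv, hand, aim,
                            sample(c(-1, 1), 1))[-1, , drop = FALSE]

    if (caught) {
      block <- rbind(dwell_xy, mv_xy)
      hand <- tgt
      t_res <- t_app + nrow(block) / rate
      kind <- "caught"
    } else {
      n_max <- 10 * rate
      reach <- rbind(dwell_xy, mv_xy)
      if (nrow(reach) >= n_max) {
        block <- reach[seq_len(n_max), , drop = FALSE]  # too slow: truncated
      } else {
        # arrived off-target: hover at the aim point until the timeout
        n_hover <- n_max - nrow(reach)
        hover <- cbind(rep(aim[1], n_hover), rep(aim[2], n_hover)) +
          matrix(rnorm(2 * n_hover, 0, spec$noise_sd), n_hover, 2)
        block <- rbind(reach, hover)
      }
      hand <- block[nrow(block), ]
      t_res <- t_app + 10
      kind <- "timed_out"
    }
    pos_blocks[[j]] <- block
    n_total <- n_total + nrow(block)
    ii <- c(2 * j - 1, 2 * j)
    ev_t[ii] <- c(t_app, t_res)
    ev_tgt[ii] <- j
    ev_kind[ii] <- c("appeared", kind)
    tr_caught[j] <- caught; tr_D[j] <- D; tr_L[j] <- L; tr_curv[j] <- curv
    tr_v[j] <- v; tr_tmove[j] <- n_move / rate; tr_dwell[j] <- n_dwell / rate
    tr_nsub[j] <- n_sub; tr_req[j] <- required
  }
  pos <- do.call(rbind, pos_blocks)
  # smooth postural wobble, continuous across the whole trial (two random
  # sinusoids per axis) so block boundaries introduce no velocity spikes
  if (cst$wobble_amp > 0) {
    tt <- (seq_len(nrow(pos)) - 1L) / rate
    for (ax in 1:2) {
      f <- runif(2, cst$wobble_freq[1], cst$wobble_freq[2])
      ph <- runif(2, 0, 2 * pi)
      amp <- cst$wobble_amp * exp(rnorm(2, 0, 0.4))
      pos[, ax] <- pos[, ax] + amp[1] * sin(2 * pi * f[1] * tt + ph[1]) +
        amp[2] * sin(2 * pi * f[2] * tt + ph[2])
    }
  }
  samples <- data.frame(t = (seq_len(nrow(pos)) - 1L) / rate,
                        x = pos[, 1], y = pos[, 2])
  events <- data.frame(t = ev_t, target_index = as.integer(ev_tgt),
                       kind = ev_kind, stringsAsFactors = FALSE)
  truth <- data.frame(
    subject = subject_id, session = session, trial = trial,
    target = seq_len(nt), caught = tr_caught, D = tr_D, arc_length = tr_L,
    curvature = tr_curv, v_nominal = tr_v, t_move = tr_tmove,
    dwell = tr_dwell, n_submovements = tr_nsub, required = tr_req,
    gain = g, stringsAsFactors = FALSE)
  # events are stamped at block boundaries; first sample is at t = 0
  rec <- trial_recording(subject_id, session, trial, samples, events,
                         workspace = spec$workspace, rate_hz = rate,
                         validate = FALSE)
  list(recording = rec, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject ability and profiles, simulates every trial of every
#' session and returns the recordings grouped per session together with
#' the exhaustive ground-truth table. Reproducible: the same spec and seed
#' give an identical cohort, and each subject has its own derived RNG
#' stream.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional directory; when given, every trial is also written
#'   as a CSV log via [write_trial_log()].
#' @return List with `sessions` (list of `session_recording`s), `truth`
#'   (`data.frame`, one row per simulated target) and `subjects`
#'   (`data.frame` of ability and latent speed per subject).
#' @export
synth_cohort <- function(spec = cohort_spec(), dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, 0L))
  targets <- draw_target_layout(spec)
  sessions <- list()
  truth <- list()
  subjects <- list()
  for (i in seq_len(spec$n_subjects)) {
    set.seed(derive_seed(spec$seed, i))
    sid <- sprintf("SYN%02d", i)
    ability <- runif(1, spec$ability_range[1], spec$ability_range[2])
    prof <- subject_profile(ability, spec)
    subjects[[i]] <- data.frame(subject = sid, ability = ability,
                                v = prof$v, stringsAsFactors = FALSE)
    for (s in seq_len(spec$n_sessions)) {
      trials <- vector("list", spec$n_trials)
      for (tr in seq_len(spec$n_trials)) {
        sim <- synth_trial(prof, sid, s, tr, spec, targets)
        trials[[tr]] <- sim$recording
        truth[[length(truth) + 1L]] <- sim$truth
        if (!is.null(dir)) {
          if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
          write_trial_log(sim$recording,
                          file.path(dir, sprintf("%s_s%d_t%d.csv", sid, s, tr)))
        }
      }
      sessions[[length(sessions) + 1L]] <- structure(
        list(subject_id = sid, session_index = s, trials = trials),
        class = "session_recording")
    }
  }
  list(sessions = sessions,
       truth = do.call(rbind, truth),
       subjects = do.call(rbind, subjects),
       targets = targets)
}

# Fixed target layout per cohort: uniform positions with a minimum
# consecutive-target separation, drawn once from the layout stream.
draw_target_layout <- function(spec) {
  w <- spec$workspace
  margin <- 2
  pts <- matrix(NA_real_, spec$n_targets, 2)
  pts[1, ] <- c(runif(1, margin, w[1] - margin), runif(1, margin, w[2] - margin))
  for (j in 2:spec$n_targets) {
    repeat {
      p <- c(runif(1, margin, w[1] - margin), runif(1, margin, w[2] - margin))
      if (sqrt(sum((p - pts[j - 1, ])^2)) >= spec$constants$min_target_sep) break
    }
    pts[j, ] <- p
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Simulate parameter-level test-retest pairs with known components
#'
#' Draws `value = mean + subject_effect + session_bias_indicator +
#' within_noise` for `n` subjects and two sessions. Used to verify that
#' the reliability estimators recover known variance components; the
#' population ICC(2,k) implied by the inputs is
#' `sigma_b^2 / (sigma_b^2 + (sigma_bias^2/2 + sigma_w^2)/2)` under the
#' two-session decomposition (the bias contributes `bias^2/2` to the
#' session variance component).
#'
#' @param n Number of subjects.
#' @param mean Grand mean.
#' @param between_sd Between-subject SD.
#' @param within_sd Within-subject (residual) SD.
#' @param session_bias Fixed systematic test-to-retest shift.
#' @return `n x 2` matrix of (test, retest) values.
#' @export
synth_test_retest <- function(n, mean = 0, between_sd = 1, within_sd = 1,
                              session_bias = 0) {
  subj <- rnorm(n, 0, between_sd)
  cbind(test = mean + subj + rnorm(n, 0, within_sd),
        retest = mean + session_bias + subj + rnorm(n, 0, within_sd))
}
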