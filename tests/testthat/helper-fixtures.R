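# Fixture builders shared across test files. Everything is generated in
# code; no binary data.

# A hand-built trial: `pattern` gives per-target resolution ("c" caught,
# "t" timed out), each target taking `per_target` seconds. Samples are a
# straight sweep across the workspace at 64 Hz.
make_trial <- function(pattern = rep("c", 12), per_target = 5,
                       subject = "T01", session = 1, trial = 1,
                       rate = 64) {
  nt <- length(pattern)
  ev <- do.call(rbind, lapply(seq_len(nt), function(j) {
    t_app <- (j - 1) * per_target
    data.frame(t = c(t_app, t_app + per_target), target_index = j,
               kind = c("appeared", ifelse(pattern[j] == "c",
                                           "caught", "timed_out")))
  }))
  dur <- nt * per_target
  tt <- seq(0, dur, by = 1 / rate)
  samples <- data.frame(t = tt, x = 1 + 30 * tt / dur, y = 1 + 20 * tt / dur)
  trial_recording(subject, session, trial, samples, ev)
}

# Sampled minimum-jerk reach along x, returned as movement-like samples.
min_jerk_samples <- function(D = 20, T = 1, rate = 64) {
  t <- seq(0, T, by = 1 / rate)
  tau <- t / T
  data.frame(t = t, x = D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5), y = 0)
}

as_movement <- function(samples) {
  structure(list(from_target = 1L, to_target = 2L,
                 t_start = samples$t[1], t_end = samples$t[nrow(samples)],
                 duration = samples$t[nrow(samples)] - samples$t[1],
                 samples = samples),
            class = "unitary_movement")
}

# Independent brute-force peak counter used as the oracle for
# n_velocity_peaks: walks the array and counts local maxima after
# collapsing ties.
brute_force_peaks <- function(speed) {
  r <- rle(speed)$values
  n <- 0L
  for (i in seq_along(r)) {
    if (i > 1 && i < length(r) && r[i] > r[i - 1] && r[i] > r[i + 1])
      n <- n + 1L
  }
  n
}

# Long parameter table from a subjects x sessions x trials array of one
# parameter (plus optional extras), for statistics-level tests.
param_table <- function(arr, parameter = "TaskTime") {
  dn <- dimnames(arr)
  subj <- dn[[1]] %||% paste0("P", seq_len(dim(arr)[1]))
  g <- expand.grid(i = seq_len(dim(arr)[1]), s = seq_len(dim(arr)[2]),
                   t = seq_len(dim(arr)[3]))
  data.frame(subject = subj[g$i], session = g$s, trial = g$t,
             parameter = parameter, value = arr[cbind(g$i, g$s, g$t)],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
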