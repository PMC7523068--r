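# Test-retest reliability: ICC(2,k), SEM, MDC95 / MDC%, mean-difference CI.
#
# Reliability is computed on subject-level session means (by design the
# last four trials of sessions 2 and 3, i.e. after the learning effect has
# plateaued). All statistics derive from the two-way subjects x sessions
# ANOVA mean squares: MSR (between subjects), MSC (between sessions) and
# MSE (residual). The session variance component enters the SEM, so
# systematic test-retest bias (residual learning) inflates the minimal
# detectable change - deliberately, since in practice an observed change
# competes against that bias too.

two_way_ms <- function(X) {
  # X: n subjects x k sessions, complete
  n <- nrow(X); k <- ncol(X)
  gm <- mean(X)
  rm_ <- rowMeans(X); cm <- colMeans(X)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((X - outer(rm_, cm, "+") + gm)^2)
  list(n = n, k = k, grand_mean = gm,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)),
       ssr = ssr, ssc = ssc, sse = sse)
}

as_pair_matrix <- function(test, retest) {
  if (is.matrix(test) || is.data.frame(test)) X <- as.matrix(test)
  else X <- cbind(test, retest)
  if (anyNA(X)) stop_armkin("test-retest pairs must be complete")
  if (ncol(X) < 2) stop_armkin("need at least 2 measurement columns")
  X
}

#' ICC(2,k): two-way random effects, absolute agreement, average measures
#'
#' The intraclass correlation of the k-session average, from the two-way
#' ANOVA mean squares: `ICC = (MSR - MSE) / (MSR + (MSC - MSE)/n)`.
#' Session is a random effect and agreement is absolute, so systematic
#' session differences lower the coefficient. The 95% confidence bounds
#' use the F-based interval for the single-measure ICC(A,1) (McGraw-Wong
#' with the Satterthwaite denominator df) stepped up to average measures
#' with the Spearman-Brown relation.
#'
#' @param test Either an `n x k` matrix of per-session values or the test
#'   vector when `retest` is given.
#' @param retest Optional retest vector (then `k = 2`).
#' @param conf_level Confidence level for the bounds.
#' @return A list with `icc`, `ci_low`, `ci_high`, `n`, `k` and the mean
#'   squares. `icc` is `NA` with a warning when the between-subject
#'   variance is zero (agreement is then undefined).
#' @export
icc_2k <- function(test, retest = NULL, conf_level = 0.95) {
  X <- as_pair_matrix(test, retest)
  if (nrow(X) < 3) stop_armkin("need at least 3 subjects for the ICC")
  ms <- two_way_ms(X)
  n <- ms$n; k <- ms$k
  if (ms$msr <= ms$mse && ms$ssr <= .Machine$double.eps * sum(X^2)) {
    warning("zero between-subject variance: ICC undefined")
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n = n, k = k, msr = ms$msr, msc = ms$msc, mse = ms$mse))
  }
  icc_k <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  # single-measure estimate and its F-based bounds
  r1 <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf_level
  aa <- (k * r1) / (n * (1 - r1))
  bb <- 1 + (k * r1 * (n - 1)) / (n * (1 - r1))
  v <- (aa * ms$msc + bb * ms$mse)^2 /
    ((aa * ms$msc)^2 / (k - 1) + (bb * ms$mse)^2 / ((n - 1) * (k - 1)))
  f1 <- qf(1 - alpha / 2, n - 1, v)
  f2 <- qf(1 - alpha / 2, v, n - 1)
  low1 <- n * (ms$msr - f1 * ms$mse) /
    (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  up1 <- n * (f2 * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown step-up
  list(icc = icc_k, ci_low = sb(low1), ci_high = sb(up1),
       n = n, k = k, msr = ms$msr, msc = ms$msc, mse = ms$mse)
}

#' Standard error of measurement including systematic session differences
#'
#' `SEM = sqrt(sigma2_session + sigma2_residual)` where `sigma2_session =
#' (MSC - MSE)/n` is the ANOVA estimate of the test-retest (session)
#' variance component - the systematic part, e.g. residual learning - and
#' `sigma2_residual = MSE`. A negative session component estimate is
#' truncated at zero (and noted), so the SEM is never below
#' `sqrt(MSE)`. The within-subject mean-square reading
#' `sqrt((SSC + SSE)/(n(k-1)))` is returned alongside as `sem_wms` for
#' comparison.
#'
#' @inheritParams icc_2k
#' @return List with `sem`, `sem_wms`, `var_session`, `var_residual`.
#' @export
sem_from_anova <- function(test, retest = NULL) {
  X <- as_pair_matrix(test, retest)
  if (nrow(X) < 3) stop_armkin("need at least 3 subjects for the SEM")
  ms <- two_way_ms(X)
  var_sess <- (ms$msc - ms$mse) / ms$n
  if (var_sess < 0) {
    message("negative session variance component truncated at 0")
    var_sess <- 0
  }
  list(sem = sqrt(var_sess + ms$mse),
       sem_wms = sqrt((ms$ssc + ms$sse) / (ms$n * (ms$k - 1))),
       var_session = var_sess, var_residual = ms$mse)
}

#' Minimal detectable change
#'
#' `MDC95 = 1.96 * SEM * sqrt(2)`: the smallest change between two repeated
#' measures that exceeds measurement error with 95% confidence. `MDC%`
#' expresses it as a percentage of the grand mean so parameters with
#' different units can be compared.
#'
#' @param sem Standard error of measurement (>= 0).
#' @param grand_mean Mean of all observations across both sessions.
#' @return Named list `mdc95`, `mdc_pct` (`NA` when the grand mean is 0).
#' @export
mdc <- function(sem, grand_mean) {
  assert_scalar_number(sem, "sem")
  if (sem < 0) stop_armkin("sem must be non-negative")
  mdc95 <- 1.96 * sem * sqrt(2)
  mdc_pct <- if (is.finite(grand_mean) && grand_mean != 0)
    100 * mdc95 / grand_mean else NA_real_
  list(mdc95 = mdc95, mdc_pct = mdc_pct)
}

#' Mean test-retest difference with confidence interval
#'
#' `mdiff = mean(retest - test)` with
#' `CI = mdiff +/- multiplier * SD(diff)/sqrt(n)`. A CI excluding zero
#' indicates residual systematic bias (e.g. continued learning between the
#' sessions). The default multiplier is the normal 1.96; `"t"` uses the
#' t(n-1) quantile.
#'
#' @inheritParams icc_2k
#' @param multiplier `"normal"` or `"t"`.
#' @param conf_level Confidence level.
#' @return List with `mdiff`, `ci_low`, `ci_high`, `sd_diff`, `n`.
#' @export
mean_diff_ci <- function(test, retest = NULL,
                         multiplier = c("normal", "t"), conf_level = 0.95) {
  multiplier <- match.arg(multiplier)
  X <- as_pair_matrix(test, retest)
  if (nrow(X) < 3) stop_armkin("need at least 3 pairs")
  d <- X[, 2] - X[, 1]
  n <- length(d)
  mult <- if (multiplier == "normal") qnorm(1 - (1 - conf_level) / 2)
          else qt(1 - (1 - conf_level) / 2, n - 1)
  half <- mult * sd(d) / sqrt(n)
  list(mdiff = mean(d), ci_low = mean(d) - half, ci_high = mean(d) + half,
       sd_diff = sd(d), n = n)
}

classify_icc <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc >= 0.75) "excellent" else if (icc >= 0.40) "moderate" else "weak"
}

#' Test-retest reliability report per parameter
#'
#' Computes session means over the selected trials (via [session_means()]),
#' forms complete test-retest pairs per subject, and reports per parameter:
#' session means and SDs, ICC(2,k) with CI and its classification
#' (excellent >= 0.75, moderate 0.40-0.75, weak < 0.40), SEM (and the
#' `sem_wms` diagnostic), MDC95, MDC% of the grand mean, and the mean
#' difference with CI. Subjects lacking either session are dropped
#' pairwise with a message.
#'
#' @param tbl A long parameter table.
#' @param sessions Length-2 test/retest sessions (default 2 and 3).
#' @param trials Trial subset for the session means (default 7-10, the last
#'   four trials, chosen because learning has plateaued by then).
#' @param parameters Parameters to report on.
#' @param multiplier Passed to [mean_diff_ci()].
#' @return A `data.frame` of class `reliability_report`, one row per
#'   parameter.
#' @export
reliability_report <- function(tbl, sessions = c(2, 3), trials = 7:10,
                               parameters = setdiff(KIN_PARAMETERS, "PercPeakVel"),
                               multiplier = "normal") {
  if (length(sessions) != 2) stop_armkin("exactly two sessions required")
  sm <- session_means(tbl, sessions = sessions, trials = trials)
  rows <- list()
  for (p in parameters) {
    d <- sm[sm$parameter == p & sm$n_trials > 0, , drop = FALSE]
    wide <- merge(d[d$session == sessions[1], c("subject", "mean")],
                  d[d$session == sessions[2], c("subject", "mean")],
                  by = "subject", suffixes = c("_test", "_retest"))
    n_dropped <- length(unique(d$subject)) - nrow(wide)
    if (n_dropped > 0)
      message(sprintf("%s: %d subject(s) without both sessions dropped", p,
                      n_dropped))
    if (nrow(wide) < 3) {
      warning(sprintf("%s: fewer than 3 complete test-retest pairs; skipped",
                      p), call. = FALSE)
      next
    }
    X <- as.matrix(wide[, c("mean_test", "mean_retest")])
    icc <- icc_2k(X)
    semr <- sem_from_anova(X)
    md <- mdc(semr$sem, mean(X))
    dif <- mean_diff_ci(X, multiplier = multiplier)
    rows[[p]] <- data.frame(
      parameter = p, n = nrow(X),
      mean_test = mean(X[, 1]), sd_test = sd(X[, 1]),
      mean_retest = mean(X[, 2]), sd_retest = sd(X[, 2]),
      icc = icc$icc, icc_ci_low = icc$ci_low, icc_ci_high = icc$ci_high,
      classification = classify_icc(icc$icc),
      sem = semr$sem, sem_wms = semr$sem_wms,
      mdc95 = md$mdc95, mdc_pct = md$mdc_pct,
      mdiff = dif$mdiff, mdiff_ci_low = dif$ci_low,
      mdiff_ci_high = dif$ci_high,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop_armkin("fewer than 3 complete test-retest pairs for every parameter")
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  structure(out, class = c("reliability_report", "data.frame"),
            sessions = sessions, trials = trials)
}

#' Reliability as a function of trials retained
#'
#' For `k = 1..max_k`, averages the last `k` trials of each session and
#' recomputes ICC(2,k) and MDC per parameter, tracing how much averaging
#' is needed before reliability stabilizes. The `k = 4` row matches
#' [reliability_report()] with the default trial subset, and `k = max_k`
#' uses all trials.
#'
#' @param tbl A long parameter table (full 10-trial sessions expected for
#'   the swept subjects).
#' @param sessions Test/retest session pair.
#' @param max_k Largest number of retained trials.
#' @param parameters Parameters to sweep.
#' @return Tidy `data.frame` with columns `parameter`,
#'   `trials_retained`, `icc`, `icc_ci_low`, `icc_ci_high`, `sem`,
#'   `mdc95`, `mdc_pct`, `n`.
#' @export
reliability_vs_trials_sweep <- function(tbl, sessions = c(2, 3), max_k = 10,
                                        parameters = setdiff(KIN_PARAMETERS,
                                                             "PercPeakVel")) {
  trials_all <- sort(unique(tbl$trial))
  rows <- list()
  for (k in seq_len(max_k)) {
    keep <- tail(trials_all, k)
    rep_k <- reliability_report(tbl, sessions = sessions, trials = keep,
                                parameters = parameters)
    rows[[k]] <- data.frame(parameter = rep_k$parameter, trials_retained = k,
                            icc = rep_k$icc, icc_ci_low = rep_k$icc_ci_low,
                            icc_ci_high = rep_k$icc_ci_high, sem = rep_k$sem,
                            mdc95 = rep_k$mdc95, mdc_pct = rep_k$mdc_pct,
                            n = rep_k$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
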