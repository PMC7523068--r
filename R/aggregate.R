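# Parameter-table aggregation and Tukey-fence outlier screening.

check_parameter_table <- function(tbl) {
  need <- c("subject", "session", "trial", "parameter", "value")
  if (!all(need %in% names(tbl)))
    stop_armkin("parameter table needs columns %s", paste(need, collapse = ", "))
  key <- paste(tbl$subject, tbl$session, tbl$trial, tbl$parameter)
  if (anyDuplicated(key))
    stop_armkin("duplicate (subject, session, trial, parameter) rows")
  invisible(tbl)
}

#' Tukey fences for outlier detection
#'
#' Computes the classical fences Q1 - 1.5 IQR and Q3 + 1.5 IQR. The default
#' quartile estimator is Tukey's hinges (median-of-halves, as returned by
#' [stats::fivenum()]), the rule used in the original boxplot method;
#' `rule = "quartile"` uses the type-7 sample quantiles instead. Quantile
#' conventions shift the fences, so the rule is explicit and recorded.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param rule `"hinges"` (default) or `"quartile"`.
#' @return Named numeric vector `c(low, high)`.
#' @export
tukey_fences <- function(values, rule = c("hinges", "quartile")) {
  rule <- match.arg(rule)
  v <- values[is.finite(values)]
  if (length(v) < 4) stop_armkin("need at least 4 finite values for fences")
  if (rule == "hinges") {
    f <- fivenum(v)
    q1 <- f[2]; q3 <- f[4]
  } else {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q1 <- q[1]; q3 <- q[2]
  }
  iqr <- q3 - q1
  c(low = q1 - 1.5 * iqr, high = q3 + 1.5 * iqr)
}

#' Remove Tukey outliers from a parameter table
#'
#' Values strictly outside the Tukey fences are set to `NA` (rows are kept,
#' so the table shape is preserved and missingness stays explicit). Fences
#' are computed per parameter, either over all values (`scope = "global"`,
#' the default) or separately within each session
#' (`scope = "per_session"`). Applying the function a second time at the
#' reported fences removes nothing further.
#'
#' @param tbl A long parameter table (see [cohort_kinematics()]).
#' @param scope `"global"` or `"per_session"`.
#' @param rule Quartile rule passed to [tukey_fences()].
#' @return A list with `table` (the screened table) and `report` (a
#'   `data.frame` of fences and flag counts per parameter/scope plus the
#'   flagged cells in `attr(report, "flagged")`).
#' @export
remove_outliers <- function(tbl, scope = c("global", "per_session"),
                            rule = c("hinges", "quartile")) {
  scope <- match.arg(scope)
  rule <- match.arg(rule)
  check_parameter_table(tbl)
  out <- tbl
  rep_rows <- list()
  flagged <- list()
  groups <- if (scope == "global") {
    split(seq_len(nrow(tbl)), tbl$parameter)
  } else {
    split(seq_len(nrow(tbl)), list(tbl$parameter, tbl$session), drop = TRUE)
  }
  for (g in names(groups)) {
    idx <- groups[[g]]
    v <- tbl$value[idx]
    if (sum(is.finite(v)) < 4) next
    fences <- tukey_fences(v, rule)
    bad <- idx[is.finite(v) & (v < fences["low"] | v > fences["high"])]
    out$value[bad] <- NA_real_
    rep_rows[[g]] <- data.frame(
      parameter = tbl$parameter[idx[1]],
      session = if (scope == "global") NA_integer_ else tbl$session[idx[1]],
      low = fences[["low"]], high = fences[["high"]],
      n_values = sum(is.finite(v)), n_flagged = length(bad),
      stringsAsFactors = FALSE)
    if (length(bad))
      flagged[[g]] <- tbl[bad, c("subject", "session", "trial",
                                 "parameter", "value")]
  }
  report <- do.call(rbind, unname(rep_rows))
  rownames(report) <- NULL
  attr(report, "flagged") <- if (length(flagged))
    do.call(rbind, unname(flagged)) else NULL
  nflag <- sum(report$n_flagged)
  if (nflag) message(sprintf("outlier screening (%s, %s): %d value(s) removed",
                             scope, rule, nflag))
  list(table = out, report = report)
}

#' Session means over a trial subset
#'
#' Averages the per-trial parameter values over the selected trials within
#' each subject x session x parameter cell, skipping missing trials. Cells
#' with no available trial are returned as `NA` with a message. The number
#' of contributing trials is attached as `n_trials`.
#'
#' @param tbl A long parameter table.
#' @param sessions Sessions to keep (default: all present).
#' @param trials Trial subset to average over (default: all present).
#' @return A `data.frame` with columns `subject`, `session`, `parameter`,
#'   `mean`, `n_trials`.
#' @export
session_means <- function(tbl, sessions = NULL, trials = NULL) {
  check_parameter_table(tbl)
  if (is.null(sessions)) sessions <- sort(unique(tbl$session))
  if (is.null(trials)) trials <- sort(unique(tbl$trial))
  if (!length(trials)) stop_armkin("trial subset must be nonempty")
  base <- tbl[tbl$session %in% sessions, , drop = FALSE]
  sub <- base[base$trial %in% trials, , drop = FALSE]
  g <- interaction(sub$subject, sub$session, sub$parameter, drop = TRUE)
  agg <- lapply(split(sub, g), function(d)
    data.frame(subject = d$subject[1], session = d$session[1],
               parameter = d$parameter[1],
               mean = if (any(is.finite(d$value)))
                 mean(d$value[is.finite(d$value)]) else NA_real_,
               n_trials = sum(is.finite(d$value)),
               stringsAsFactors = FALSE))
  res <- do.call(rbind, unname(agg))
  # cells that exist in the selected sessions but have no trial in the
  # subset (e.g. a subject who stopped early) stay as explicit missings
  cells <- unique(base[, c("subject", "session", "parameter")])
  res <- merge(cells, res, all.x = TRUE)
  res$n_trials[is.na(res$n_trials)] <- 0L
  rownames(res) <- NULL
  miss <- res[res$n_trials == 0, , drop = FALSE]
  if (nrow(miss))
    message(sprintf("session_means: %d subject-session cell(s) with no data",
                    nrow(miss)))
  res[order(res$parameter, res$subject, res$session), ]
}
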