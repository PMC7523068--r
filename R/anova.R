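# Two-way fully-within repeated-measures ANOVA for the trial x session
# learning design, with sphericity diagnostics and Tukey HSD post-hocs.
#
# The design is subjects x sessions (a = 3) x trials (b = 10), both factors
# within-subject. Each effect is tested against its own subject-by-effect
# interaction mean square. Sphericity is assessed per effect with Mauchly's
# test on the orthonormal-contrast covariance; when rejected (or always,
# per policy) the Greenhouse-Geisser epsilon multiplies both degrees of
# freedom of the F test.

#' Build a complete-case design array from a parameter table
#'
#' Extracts one parameter, pivots to a subjects x sessions x trials array
#' and drops subjects with any missing cell (complete-case analysis;
#' unbalanced designs are out of scope). The number of excluded subjects is
#' reported.
#'
#' @param tbl A long parameter table.
#' @param parameter Parameter name to extract.
#' @param sessions,trials Factor levels expected in the design.
#' @return A numeric array `n x a x b` with dimnames, or an error if fewer
#'   than 3 complete subjects remain.
#' @export
build_design <- function(tbl, parameter, sessions = 1:3, trials = 1:10) {
  check_parameter_table(tbl)
  d <- tbl[tbl$parameter == parameter & tbl$session %in% sessions &
             tbl$trial %in% trials, , drop = FALSE]
  subjects <- sort(unique(d$subject))
  a <- length(sessions); b <- length(trials)
  arr <- array(NA_real_, c(length(subjects), a, b),
               dimnames = list(subjects, paste0("S", sessions),
                               paste0("T", trials)))
  arr[cbind(match(d$subject, subjects), match(d$session, sessions),
            match(d$trial, trials))] <- d$value
  complete <- apply(arr, 1, function(x) all(is.finite(x)))
  if (sum(!complete))
    message(sprintf("%s: %d incomplete subject(s) excluded from the ANOVA",
                    parameter, sum(!complete)))
  arr <- arr[complete, , , drop = FALSE]
  if (dim(arr)[1] < 3)
    stop_armkin("%s: fewer than 3 complete subjects", parameter)
  arr
}

orthonormal_contrasts <- function(k) {
  m <- stats::contr.helmert(k)
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

#' Greenhouse-Geisser epsilon
#'
#' Computed from the eigenvalues of the effect's orthonormal-contrast
#' covariance `S`: `eps = (sum lambda)^2 / (d * sum lambda^2)`, equivalently
#' `tr(S)^2 / (d * tr(S^2))`, clipped to `[1/d, 1]` where `d` is the
#' contrast dimension. Equal eigenvalues (sphericity) give 1; a rank-one
#' covariance gives the lower bound.
#'
#' @param S Covariance matrix of orthonormal within-effect contrasts.
#' @return Epsilon in `[1/d, 1]`.
#' @export
gg_epsilon <- function(S) {
  S <- as.matrix(S)
  d <- ncol(S)
  if (d == 1) return(1)
  tr <- sum(diag(S))
  tr2 <- sum(S * S)                   # tr(S %*% S) for symmetric S
  if (tr2 <= 0 || !is.finite(tr2)) {
    warning("degenerate contrast covariance; returning the lower bound")
    return(1 / d)
  }
  min(max(tr^2 / (d * tr2), 1 / d), 1)
}

#' Mauchly's sphericity test
#'
#' `W = det(S) / (tr(S)/d)^d` on the orthonormal-contrast covariance `S`
#' estimated with `nu = n - 1` degrees of freedom, with the usual
#' chi-square approximation. With a single contrast (two factor levels)
#' sphericity holds trivially and `W = 1, p = 1`.
#'
#' @param S Contrast covariance matrix.
#' @param n Number of subjects; must exceed the contrast dimension, i.e.
#'   `n > d`, otherwise `S` is singular and the test is unavailable.
#' @param p_orig Dimension of the untransformed response the contrasts were
#'   built from (the number of within-subject cells). Only enters the
#'   second-order term of the chi-square approximation, following the
#'   convention of the standard R implementations; defaults to `d + 1`.
#' @return List with `W`, `chisq`, `df`, `p`.
#' @export
mauchly_sphericity <- function(S, n, p_orig = ncol(S) + 1) {
  S <- as.matrix(S)
  d <- ncol(S)
  if (d == 1) return(list(W = 1, chisq = 0, df = 0, p = 1))
  if (n - 1 < d)
    stop_armkin(paste("too few subjects (%d) for Mauchly's test on %d",
                      "contrasts; use gg_policy = 'always'"), n, d)
  detS <- det(S)
  W <- detS / (sum(diag(S)) / d)^d
  if (!is.finite(W) || W <= 0)
    return(list(W = 0, chisq = Inf, df = d * (d + 1) / 2 - 1, p = 0))
  nu <- n - 1
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * nu)
  w2 <- (d + 2) * (d - 1) * (d - 2) * (2 * d^3 + 6 * d^2 + 3 * p_orig + 2) /
    (288 * d^2 * nu^2 * rho^2)
  chisq <- -nu * rho * log(W)
  df <- d * (d + 1) / 2 - 1
  # chi-square approximation with the second-order Box correction
  p1 <- pchisq(chisq, df, lower.tail = FALSE)
  p2 <- pchisq(chisq, df + 4, lower.tail = FALSE)
  list(W = W, chisq = chisq, df = df, p = p1 + w2 * (p2 - p1))
}

# Effect-specific orthonormal contrast matrix over the a*b cells.
# Cells are ordered with the session index varying slowest, matching
# matrix(Y, n, a*b) of an n x a x b array.
effect_contrasts <- function(a, b, effect) {
  Ma <- orthonormal_contrasts(a)
  Mb <- orthonormal_contrasts(b)
  ua <- matrix(1 / sqrt(a), a, 1)
  ub <- matrix(1 / sqrt(b), b, 1)
  switch(effect,
         session = kronecker(Ma, ub),
         trial = kronecker(ua, Mb),
         interaction = kronecker(Ma, Mb),
         stop_armkin("unknown effect '%s'", effect))
}

#' Two-way fully-within repeated-measures ANOVA
#'
#' Partitions the total sum of squares of an `n x a x b` design (subjects x
#' sessions x trials) into subject, session, trial and session:trial
#' effects plus their subject-interaction error terms, and tests each
#' within effect against its own error term. Mauchly's test and the
#' Greenhouse-Geisser epsilon are computed per effect; the reported
#' p-value (`p_reported`) is GG-corrected according to `gg_policy`.
#'
#' @param design Numeric array `n x a x b` with no missing values (see
#'   [build_design()]).
#' @param gg_policy `"mauchly"` (correct only when Mauchly's p < alpha, the
#'   default), `"always"`, or `"never"`.
#' @param alpha Significance level used for the Mauchly gate.
#' @return An object of class `rm_anova`: a `data.frame` with one row per
#'   effect (`session`, `trial`, `session:trial`) and columns `ss`, `df`,
#'   `ms`, `err_ss`, `err_df`, `err_ms`, `F`, `p`, `epsilon_gg`,
#'   `p_gg`, `mauchly_w`, `mauchly_p`, `gg_applied`, `p_reported`,
#'   `pes` (partial eta squared); attributes `ss_total`, `ss_subjects`,
#'   `n`, `a`, `b`, `cell_means`, `design`.
#' @export
rm_anova_2way <- function(design, gg_policy = c("mauchly", "always", "never"),
                          alpha = 0.05) {
  gg_policy <- match.arg(gg_policy)
  stopifnot(is.array(design), length(dim(design)) == 3)
  if (anyNA(design)) stop_armkin("design must be complete (no missing cells)")
  n <- dim(design)[1]; a <- dim(design)[2]; b <- dim(design)[3]
  if (n < 3) stop_armkin("need at least 3 subjects")
  if (sd(design) == 0)
    warning("constant response: F statistics are undefined")

  gm <- mean(design)
  m_i <- apply(design, 1, mean)       # subjects
  m_j <- apply(design, 2, mean)       # sessions
  m_k <- apply(design, 3, mean)       # trials
  m_jk <- apply(design, c(2, 3), mean)
  m_ij <- apply(design, c(1, 2), mean)
  m_ik <- apply(design, c(1, 3), mean)

  ss_total <- sum((design - gm)^2)
  ss_subj <- a * b * sum((m_i - gm)^2)
  ss_a <- n * b * sum((m_j - gm)^2)
  ss_b <- n * a * sum((m_k - gm)^2)
  ss_ab <- n * sum((sweep(sweep(m_jk, 1, m_j), 2, m_k) + gm)^2)
  ss_as <- b * sum((sweep(sweep(m_ij, 1, m_i), 2, m_j) + gm)^2)
  ss_bs <- a * sum((sweep(sweep(m_ik, 1, m_i), 2, m_k) + gm)^2)
  ss_abs <- ss_total - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs

  eff <- data.frame(
    effect = c("session", "trial", "session:trial"),
    ss = c(ss_a, ss_b, ss_ab),
    df = c(a - 1, b - 1, (a - 1) * (b - 1)),
    err_ss = c(ss_as, ss_bs, ss_abs),
    err_df = c((n - 1) * (a - 1), (n - 1) * (b - 1),
               (n - 1) * (a - 1) * (b - 1)),
    stringsAsFactors = FALSE)
  eff$ms <- eff$ss / eff$df
  eff$err_ms <- eff$err_ss / eff$err_df
  eff$F <- eff$ms / eff$err_ms
  eff$p <- pf(eff$F, eff$df, eff$err_df, lower.tail = FALSE)
  eff$pes <- eff$ss / (eff$ss + eff$err_ss)

  # sphericity diagnostics per effect from the cell covariance; columns
  # ordered with session slowest / trial fastest to match effect_contrasts
  Y <- matrix(aperm(design, c(1, 3, 2)), n, a * b)
  V <- cov(Y)
  keys <- c("session", "trial", "interaction")
  eff$epsilon_gg <- NA_real_
  eff$mauchly_w <- NA_real_
  eff$mauchly_p <- NA_real_
  for (r in seq_len(3)) {
    C <- effect_contrasts(a, b, keys[r])
    S <- crossprod(C, V %*% C)
    eff$epsilon_gg[r] <- gg_epsilon(S)
    mt <- tryCatch(mauchly_sphericity(S, n, p_orig = a * b),
                   armkin_error = function(e) NULL)
    if (!is.null(mt)) {
      eff$mauchly_w[r] <- mt$W
      eff$mauchly_p[r] <- mt$p
    }
  }
  eff$p_gg <- pf(eff$F, eff$df * eff$epsilon_gg,
                 eff$err_df * eff$epsilon_gg, lower.tail = FALSE)
  eff$gg_applied <- switch(gg_policy,
    always = rep(TRUE, 3),
    never = rep(FALSE, 3),
    mauchly = !is.na(eff$mauchly_p) & eff$mauchly_p < alpha)
  eff$p_reported <- ifelse(eff$gg_applied, eff$p_gg, eff$p)

  structure(eff, class = c("rm_anova", "data.frame"),
            ss_total = ss_total, ss_subjects = ss_subj,
            n = n, a = a, b = b, grand_mean = gm,
            design = design, gg_policy = gg_policy, alpha = alpha)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%d subjects x %d x %d)\n",
              attr(x, "n"), attr(x, "a"), attr(x, "b")))
  df <- as.data.frame(x)
  df$F <- round(df$F, 2)
  print(df[, c("effect", "df", "err_df", "F", "p", "epsilon_gg",
               "p_reported", "gg_applied")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tukey HSD post-hoc contrasts for a within effect
#'
#' All pairwise comparisons of the levels of `effect`, using the effect's
#' own subject-by-effect interaction mean square as the error term and the
#' studentized-range distribution for the adjusted p-values. When the
#' omnibus test was Greenhouse-Geisser corrected, the error degrees of
#' freedom are shrunk by the same epsilon.
#'
#' @param fit An [rm_anova_2way()] result.
#' @param effect `"session"` or `"trial"`. Trial contrasts are pooled over
#'   sessions (and vice versa), which presumes no strong interaction; a
#'   warning is emitted if the omnibus for the effect is not significant.
#' @param gg_adjust Shrink error df by epsilon? Default: whatever the
#'   omnibus used.
#' @return A `data.frame` with `level_1`, `level_2`, `diff`, `se`, `q`,
#'   `p_adj`.
#' @export
posthoc_tukey <- function(fit, effect = c("session", "trial"),
                          gg_adjust = NULL) {
  effect <- match.arg(effect)
  stopifnot(inherits(fit, "rm_anova"))
  design <- attr(fit, "design")
  n <- attr(fit, "n")
  row <- as.data.frame(fit)[fit$effect == effect, ]
  if (row$p_reported >= attr(fit, "alpha"))
    warning(sprintf("omnibus %s effect is not significant (p = %.3f)",
                    effect, row$p_reported))
  if (is.null(gg_adjust)) gg_adjust <- row$gg_applied
  means <- if (effect == "session") apply(design, 2, mean)
           else apply(design, 3, mean)
  m_per_level <- n * (if (effect == "session") dim(design)[3] else dim(design)[2])
  df_err <- row$err_df * if (gg_adjust) row$epsilon_gg else 1
  se <- sqrt(row$err_ms / m_per_level)
  k <- length(means)
  pairs <- utils::combn(k, 2)
  lev <- names(means) %||% as.character(seq_len(k))
  res <- data.frame(
    level_1 = lev[pairs[1, ]],
    level_2 = lev[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    se = se, stringsAsFactors = FALSE)
  res$q <- abs(res$diff) / se
  res$p_adj <- ptukey(res$q, nmeans = k, df = df_err, lower.tail = FALSE)
  rownames(res) <- NULL
  res
}

#' Retention verdict from the session analysis
#'
#' A parameter's learning gains are considered retained when the last two
#' sessions do not differ: either the omnibus session effect is not
#' significant (vacuous retention, no learning to lose) or the S2 vs S3
#' post-hoc contrast is non-significant while earlier sessions may differ
#' from session 1.
#'
#' @param fit An [rm_anova_2way()] result for the 3-session design.
#' @param posthoc The session [posthoc_tukey()] table (computed if missing).
#' @param alpha Significance level.
#' @return A list with `retained` (logical), `learning` (logical: any
#'   S1-vs-later contrast significant), `s2_s3_p`, and the contrast table.
#' @export
retention_contrast <- function(fit, posthoc = NULL, alpha = 0.05) {
  stopifnot(inherits(fit, "rm_anova"))
  session_p <- fit$p_reported[fit$effect == "session"]
  if (session_p >= alpha) {
    return(list(retained = TRUE, learning = FALSE, s2_s3_p = NA_real_,
                session_p = session_p, contrasts = NULL))
  }
  if (is.null(posthoc))
    posthoc <- suppressWarnings(posthoc_tukey(fit, "session"))
  lab <- paste(posthoc$level_1, posthoc$level_2)
  a <- attr(fit, "a")
  last2 <- paste0("S", a - 1, " S", a)
  s2s3 <- posthoc$p_adj[lab == last2 |
                          lab == paste(a - 1, a)]
  s1later <- posthoc$p_adj[posthoc$level_1 %in% c("S1", "1")]
  list(retained = length(s2s3) == 1 && s2s3 >= alpha,
       learning = any(s1later < alpha),
       s2_s3_p = if (length(s2s3)) s2s3 else NA_real_,
       session_p = session_p,
       contrasts = posthoc)
}

#' Learning and retention analysis for every parameter
#'
#' Runs the complete-case two-way rm-ANOVA per kinematic parameter,
#' computes session and trial Tukey post-hocs for significant omnibus
#' effects (trial contrasts are pooled over sessions when the
#' session:trial interaction is not significant), and derives the
#' retention verdict from the S2 vs S3 contrast.
#'
#' @param tbl A long parameter table.
#' @param parameters Parameters to analyse (default: the six primary ones).
#' @param gg_policy,alpha Passed to [rm_anova_2way()].
#' @return A named list per parameter, each with `anova`, `posthoc_session`,
#'   `posthoc_trial`, `interaction_pooled` and `retention`; class
#'   `learning_analysis`.
#' @export
learning_analysis <- function(tbl,
                              parameters = setdiff(KIN_PARAMETERS, "PercPeakVel"),
                              gg_policy = "mauchly", alpha = 0.05) {
  out <- list()
  sessions <- sort(unique(tbl$session))
  trials <- sort(unique(tbl$trial))
  for (p in parameters) {
    fit <- tryCatch(
      rm_anova_2way(build_design(tbl, p, sessions = sessions, trials = trials),
                    gg_policy = gg_policy, alpha = alpha),
      armkin_error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("%s: %s", p, conditionMessage(fit)))
      next
    }
    sess_sig <- fit$p_reported[fit$effect == "session"] < alpha
    trial_sig <- fit$p_reported[fit$effect == "trial"] < alpha
    inter_sig <- fit$p_reported[fit$effect == "session:trial"] < alpha
    ph_s <- if (sess_sig) suppressWarnings(posthoc_tukey(fit, "session")) else NULL
    ph_t <- if (trial_sig) suppressWarnings(posthoc_tukey(fit, "trial")) else NULL
    out[[p]] <- list(anova = fit,
                     posthoc_session = ph_s,
                     posthoc_trial = ph_t,
                     interaction_pooled = !inter_sig,
                     retention = retention_contrast(fit, ph_s, alpha))
  }
  structure(out, class = "learning_analysis", alpha = alpha)
}
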