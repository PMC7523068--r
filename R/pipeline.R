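# End-to-end orchestration: extract -> screen -> aggregate -> learning ->
# reliability -> report, with an effective-config dump for provenance.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis chain with its documented
#' default. The effective configuration is serialized next to the outputs
#' of [run_pipeline()] so a result can always be traced to its settings.
#'
#' @param cutoff_hz,smoothing,min_displacement_cm See [kin_config()].
#' @param outlier_scope,quantile_rule See [remove_outliers()].
#' @param gg_policy,alpha See [rm_anova_2way()].
#' @param rel_sessions,rel_trials See [reliability_report()].
#' @param mdiff_multiplier See [mean_diff_ci()].
#' @param seed Seed recorded for provenance (used by simulation callers).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cutoff_hz = 6, smoothing = TRUE,
                            min_displacement_cm = 0.5,
                            outlier_scope = "global",
                            quantile_rule = "hinges",
                            gg_policy = "mauchly", alpha = 0.05,
                            rel_sessions = c(2, 3), rel_trials = 7:10,
                            mdiff_multiplier = "normal", seed = 1L) {
  structure(list(cutoff_hz = cutoff_hz, smoothing = smoothing,
                 min_displacement_cm = min_displacement_cm,
                 outlier_scope = outlier_scope,
                 quantile_rule = quantile_rule,
                 gg_policy = gg_policy, alpha = alpha,
                 rel_sessions = rel_sessions, rel_trials = rel_trials,
                 mdiff_multiplier = mdiff_multiplier, seed = seed),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop_armkin("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Loads (or accepts) a cohort of raw recordings, extracts the kinematic
#' parameter table, screens outliers with the Tukey method, runs the
#' learning/retention ANOVA and the test-retest reliability analysis, and
#' writes `params.csv`, `outliers.csv`, `anova.json`, `reliability.csv`,
#' `sweep.csv`, `summary.txt` and `config.json` to `output_dir`. Outputs
#' are deterministic given the inputs and configuration.
#'
#' @param input Either a directory of trial logs (see [load_cohort()]) or
#'   a list of `session_recording`s (e.g. from [synth_cohort()]).
#' @param output_dir Output directory, created if needed. `NULL` skips all
#'   file writing.
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `params`, `outlier_report`, `learning`,
#'   `reliability`, `sweep`, `summary` and `config`.
#' @export
run_pipeline <- function(input, output_dir = NULL,
                         config = pipeline_config()) {
  sessions <- if (is.character(input)) {
    with_stage("trajectory_io", load_cohort(input))
  } else input
  cfg <- kin_config(cutoff_hz = config$cutoff_hz,
                    smoothing = config$smoothing,
                    min_displacement_cm = config$min_displacement_cm)
  params <- with_stage("movement_kinematics", cohort_kinematics(sessions, cfg))
  screened <- with_stage("aggregation_outliers",
                         remove_outliers(params, scope = config$outlier_scope,
                                         rule = config$quantile_rule))
  learning <- with_stage("learning_stats",
                         learning_analysis(screened$table,
                                           gg_policy = config$gg_policy,
                                           alpha = config$alpha))
  reliability <- with_stage("reliability",
                            reliability_report(screened$table,
                                               sessions = config$rel_sessions,
                                               trials = config$rel_trials,
                                               multiplier = config$mdiff_multiplier))
  sweep <- with_stage("reliability",
                      reliability_vs_trials_sweep(screened$table,
                                                  sessions = config$rel_sessions))
  summary_txt <- render_summary(learning, reliability)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write.csv(params, file.path(output_dir, "params.csv"), row.names = FALSE)
    write.csv(screened$report, file.path(output_dir, "outliers.csv"),
              row.names = FALSE)
    jsonlite::write_json(learning_to_list(learning),
                         file.path(output_dir, "anova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(as.data.frame(reliability),
              file.path(output_dir, "reliability.csv"), row.names = FALSE)
    write.csv(sweep, file.path(output_dir, "sweep.csv"), row.names = FALSE)
    writeLines(summary_txt, file.path(output_dir, "summary.txt"))
    jsonlite::write_json(unclass(config), file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(params = params, outlier_report = screened$report,
                 learning = learning, reliability = reliability,
                 sweep = sweep, summary = summary_txt, config = config))
}

learning_to_list <- function(learning) {
  lapply(learning, function(l) {
    an <- as.data.frame(l$anova)
    list(anova = an,
         posthoc_session = l$posthoc_session,
         posthoc_trial = l$posthoc_trial,
         interaction_pooled = l$interaction_pooled,
         retention = l$retention[c("retained", "learning",
                                   "s2_s3_p", "session_p")])
  })
}

fmt_sig_sessions <- function(ph, alpha) {
  if (is.null(ph)) return("-")
  sig <- ph[ph$p_adj < alpha, , drop = FALSE]
  if (!nrow(sig)) return("-")
  paste(sprintf("%s vs %s", sig$level_1, sig$level_2), collapse = ", ")
}

#' Render a textual summary of the learning and reliability analyses
#'
#' Produces a learning-effect grid (per parameter: session and trial
#' F/p values and which levels differ, dashes when no effect) and a
#' reliability table (means, ICC with CI and classification, SEM, MDC95,
#' MDC%, mean difference with CI), in fixed-width text.
#'
#' @param learning A [learning_analysis()] result.
#' @param reliability A [reliability_report()] result.
#' @return Character vector of lines.
#' @export
render_summary <- function(learning, reliability) {
  alpha <- attr(learning, "alpha") %||% 0.05
  out <- c("Learning effect (two-way repeated-measures ANOVA)",
           sprintf("%-14s %-22s %-22s %-11s %s", "parameter",
                   "session effect", "trial effect", "interaction",
                   "retention"))
  for (p in names(learning)) {
    l <- learning[[p]]
    an <- as.data.frame(l$anova)
    cell <- function(eff) {
      r <- an[an$effect == eff, ]
      if (r$p_reported < alpha)
        sprintf("F=%.2f p=%.2g", r$F, r$p_reported)
      else "-"
    }
    ret <- if (isTRUE(l$retention$retained)) "retained" else "not retained"
    out <- c(out, sprintf("%-14s %-22s %-22s %-11s %s", p,
                          cell("session"), cell("trial"),
                          cell("session:trial"), ret))
    sig_s <- fmt_sig_sessions(l$posthoc_session, alpha)
    if (sig_s != "-")
      out <- c(out, sprintf("%-14s   sessions differing: %s", "", sig_s))
  }
  out <- c(out, "", "Test-retest reliability",
           sprintf("%-14s %-15s %-15s %-22s %-9s %-8s %-8s %s",
                   "parameter", "mean test(SD)", "mean retest(SD)",
                   "ICC (CI95)", "class", "MDC95", "MDC%", "mDiff (CI95)"))
  if (is.null(reliability)) {
    out <- c(out, "  NA")
    return(out)
  }
  for (i in seq_len(nrow(reliability))) {
    r <- reliability[i, ]
    out <- c(out, sprintf(
      "%-14s %-15s %-15s %-22s %-9s %-8.2f %-8.1f %s",
      r$parameter,
      sprintf("%.2f (%.2f)", r$mean_test, r$sd_test),
      sprintf("%.2f (%.2f)", r$mean_retest, r$sd_retest),
      sprintf("%.2f (%.2f to %.2f)", r$icc, r$icc_ci_low, r$icc_ci_high),
      ifelse(is.na(r$classification), "NA", r$classification),
      r$mdc95, r$mdc_pct,
      sprintf("%.2f (%.2f to %.2f)", r$mdiff, r$mdiff_ci_low,
              r$mdiff_ci_high)))
  }
  out
}
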