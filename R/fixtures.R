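# Packaged reference data.

#' Patient characteristics of the published 30-patient stroke cohort
#'
#' Transcription of the per-patient characteristics table of the published
#' 30-patient post-stroke cohort that performed this assessment protocol:
#' gender, age, dominant hand, time post-stroke (weeks), paretic side and
#' Upper-Extremity Fugl-Meyer Score (UE-FMS, 0-66; higher = less
#' impaired). Used for descriptive-statistics checks and to ground the
#' synthetic generator's impairment range.
#'
#' @return `data.frame` with one row per patient.
#' @export
patient_characteristics <- function() {
  read.csv(system.file("extdata", "stroke_cohort_characteristics.csv",
                       package = "armkin"), stringsAsFactors = FALSE)
}

#' Descriptive statistics of the patient characteristics table
#'
#' Mean and SD of age, time post-stroke and UE-FMS, recomputed from the
#' transcribed per-patient rows. Note that the recomputed post-stroke-time
#' mean (16.27 weeks) does not match the summary value printed alongside
#' the original table (14.7 weeks); the per-patient rows are taken as
#' authoritative and the discrepancy is surfaced rather than hidden.
#'
#' @return Named list of means and SDs.
#' @export
cohort_descriptives <- function() {
  d <- patient_characteristics()
  list(n = nrow(d),
       age_mean = mean(d$age_years), age_sd = sd(d$age_years),
       post_stroke_mean = mean(d$post_stroke_weeks),
       post_stroke_sd = sd(d$post_stroke_weeks),
       uefms_mean = mean(d$uefms), uefms_sd = sd(d$uefms),
       uefms_range = range(d$uefms))
}

#' Published session-level reliability summary for this task
#'
#' Session means and SDs (sessions 2 and 3, last four trials) and MDC95
#' values for the six kinematic parameters as published for the
#' 30-patient cohort. These printed values serve as arithmetic inputs:
#' mean differences and MDC% recomputed from them must reproduce the
#' published cells, and the synthetic generator is calibrated against
#' their scale.
#'
#' @return `data.frame` with columns `parameter`, `mean_test`, `sd_test`,
#'   `mean_retest`, `sd_retest`, `mdc95`.
#' @export
reference_session_means <- function() {
  read.csv(system.file("extdata", "published_session_means.csv",
                       package = "armkin"), stringsAsFactors = FALSE)
}
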