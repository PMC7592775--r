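# Accessors for the published per-subject and cohort-aggregate summary values
# of the original 34-subject clinical cohort, shipped as plain-text fixtures.

#' Published per-subject correlation/lag summary
#'
#' The printed per-subject summary of the original 34-subject clinical
#' cohort: time-domain Pearson r between the CVP and IJV-CSA traces
#' (`measured_r`), Pearson r between their autocorrelation curves (`acf_r`),
#' the cross-correlation lag in samples (`incremental_lag`, negative when the
#' CSA trace lags the CVP), the sampling interval (`dt`, s, printed rounded
#' to 3 decimals) and the lag in seconds (`lag_time`). Column means reproduce
#' the reported aggregates: mean measured r = -0.018 (SD 0.357), mean
#' autocorrelation r = 0.725 (SD 0.215), mean lag time -0.241 s (SD 0.175).
#'
#' @return a `data.frame` with 34 rows.
#' @export
published_subject_summary <- function() {
  path <- system.file("extdata", "published_subject_summary.csv",
                      package = "cvpulse", mustWork = TRUE)
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Published cohort-aggregate autocorrelation summary
#'
#' Cohort-level descriptives of the original 34-subject clinical cohort: for
#' each of the CVP and IJV-CSA signals, the across-subject n / mean / SD /
#' min / max of the per-subject signal mean, SD, median, min and max, and of
#' the autocorrelation r-values on the lag grid 0, 20, ..., 360 samples.
#'
#' @return a `data.frame` with one row per parameter.
#' @export
published_cohort_summary <- function() {
  path <- system.file("extdata", "published_cohort_acf_summary.csv",
                      package = "cvpulse", mustWork = TRUE)
  read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
}

#' Cohort-mean feature vector of the published cohort
#'
#' The across-subject means of the IJV-CSA features (mean CSA and
#' autocorrelation r-values on the lag grid) of the original clinical cohort,
#' as a one-row feature table suitable for [predict_published()]. Because OLS
#' passes through the predictor means, evaluating the published equation here
#' returns (up to coefficient rounding) the cohort's mean CVP.
#'
#' @return a one-row `data.frame` with `csa_mean` and `lag0..lag360`.
#' @export
published_mean_features <- function() {
  tab <- published_cohort_summary()
  row <- as.list(tab$csa_mean)
  names(row) <- tab$parameter
  out <- data.frame(subject_id = "cohort_mean",
                    csa_mean = row$signal_mean,
                    check.names = FALSE)
  for (nm in grep("^lag", tab$parameter, value = TRUE)) out[[nm]] <- row[[nm]]
  out
}
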