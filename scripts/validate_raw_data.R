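#!/usr/bin/env Rscript
# Optional validation against the original cohort's raw per-subject traces.
#
# The original study's raw data (per-subject CVP and IJV-CSA time series for
# the 34 analysed subjects) is distributed only as a supplementary
# spreadsheet attached to the source publication; it has no public accession
# and is not redistributed here. Given a local export of those traces, this
# script re-runs the full pipeline and compares the recomputed fit statistics
# with the printed ones:
#
#   in-sample     r2 = 0.612, mae = 1.455 cmH2O
#   10-fold CV    r2 = 0.498, mae = 2.436 cmH2O
#
# Usage:
#   Rscript scripts/validate_raw_data.R <data_dir>
#
# where <data_dir> contains one columnar text file per subject in the
# package's signal format (header time_s,csa_cm2,cvp_cmh2o; see
# ?cvpulse::read_signal), e.g. exported sheet-by-sheet from the
# supplementary spreadsheet.

suppressPackageStartupMessages(library(cvpulse))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1L) {
  message("usage: Rscript scripts/validate_raw_data.R <data_dir>")
  message("see the header of this script for the expected layout")
  quit(status = 2L)
}
data_dir <- args[[1L]]
if (!dir.exists(data_dir)) {
  message("data directory not found: ", data_dir)
  message("the raw cohort traces must be obtained from the original study's",
          " supplementary material; they are not shipped with this package")
  quit(status = 2L)
}

cfg <- default_config()
features <- cmd_features(data_dir, config = cfg)
fit <- cmd_fit(features, config = cfg)

cat(sprintf("subjects analysed: %d\n", nrow(features)))
cat(sprintf("selected predictors: %s\n",
            paste(fit$model$selected_predictors, collapse = ", ")))
cat(sprintf("in-sample: r2 = %.3f (printed 0.612), mae = %.3f (printed 1.455)\n",
            fit$model$r_squared, fit$model$mae))
cat(sprintf("%d-fold CV: r2 = %.3f (printed 0.498), mae = %.3f (printed 2.436)\n",
            fit$cv$k, fit$cv$r_squared_cv, fit$cv$mae_cv))

pub_pred <- predict_published(features)
obs <- features$cvp_mean_obs
pm <- fit_metrics(obs, pub_pred)
cat(sprintf("published coefficients on these traces: r2 = %.3f, mae = %.3f\n",
            pm$r_squared, pm$mae))
cls <- confusion_report(classify_cvp(obs), classify_cvp(pub_pred),
                        zero_division = "zero")
print(cls)
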