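# Pipeline orchestration: configuration handling and the four stage commands
# (simulate -> features -> fit -> predict). These functions are the
# programmatic surface behind the installed command-line script
# (`system.file("cli", "cvpulse.R", package = "cvpulse")`).

#' Default pipeline configuration
#'
#' Nested list of the tunable pipeline settings: band-pass filter
#' (`filter$low_hz` 0.5 Hz, `filter$high_hz` 10 Hz, `filter$order` 4,
#' `filter$enabled`, applied identically to both traces), synchronization
#' method, optional common resampling interval (`resample$dt`, `NULL` keeps
#' each subject's native grid), lag grid (`features$lag_step` 20,
#' `features$max_lag` 360 samples), selection strategy, cross-validation
#' (`cv$k` 10, `cv$seed`), and classification bounds in cmH2O.
#'
#' @return a named nested list (class `pipeline_config`).
#' @export
default_config <- function() {
  structure(list(
    filter = list(enabled = TRUE, low_hz = 0.5, high_hz = 10.0, order = 4L),
    sync = list(method = "none"),
    resample = list(dt = NULL),
    features = list(lag_step = 20L, max_lag = 360L),
    selection = list(strategy = "exhaustive"),
    cv = list(k = 10L, seed = 1L),
    classify = list(low_cmh2o = 2.72, high_cmh2o = 10.88)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified keys fall back to [default_config()]; the parsed configuration
#' round-trips identically through [write_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .stop_format("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (sect in names(user)) {
    if (!sect %in% names(cfg)) .stop_validation("unknown config section: ", sect)
    for (key in names(user[[sect]])) {
      if (!key %in% names(cfg[[sect]]))
        .stop_validation("unknown config key: ", sect, ".", key)
      # [key] <- list(...) keeps NULL-valued keys instead of deleting them
      cfg[[sect]][key] <- list(user[[sect]][[key]])
    }
  }
  for (key in c("order")) cfg$filter[[key]] <- as.integer(cfg$filter[[key]])
  cfg$features <- lapply(cfg$features, as.integer)
  cfg$cv <- lapply(cfg$cv, as.integer)
  cfg
}

#' Write a pipeline configuration to YAML
#'
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_filter_spec <- function(config)
  filter_spec(config$filter$low_hz, config$filter$high_hz, config$filter$order)

#' Simulate a cohort to a directory
#'
#' Generates a synthetic cohort ([generate_cohort()]) and writes one columnar
#' signal file per subject plus `ground_truth.csv` (true mean CVP, lag,
#' cardiac frequency and the drawn waveform parameters per subject).
#'
#' @param outdir output directory (created if absent). A non-empty existing
#'   directory is refused unless `force = TRUE`.
#' @param n number of subjects.
#' @param seed integer seed; the same invocation rewrites identical files.
#' @param config a `pipeline_config` (reserved; the generator itself is
#'   controlled by `spec`).
#' @param spec optionally a full [cohort_spec()]; `n` and `seed` override its
#'   corresponding fields.
#' @param force overwrite into a non-empty directory.
#' @return invisibly, the ground-truth `data.frame`.
#' @export
cmd_simulate <- function(outdir, n = 34L, seed = 1L,
                         config = default_config(), spec = NULL,
                         force = FALSE) {
  if (as.integer(n) < 2L) .stop_validation("n must be >= 2")
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    .stop_validation("output directory not empty (use force = TRUE): ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(spec)) spec <- cohort_spec(n_subjects = n, seed = seed)
  else { spec$n_subjects <- as.integer(n); spec$seed <- as.integer(seed) }
  cohort <- generate_cohort(spec)
  for (rec in cohort$records)
    write_signal(rec, file.path(outdir, paste0(rec$subject_id, ".csv")))
  gt <- cohort$ground_truth
  write.table(gt, file.path(outdir, "ground_truth.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(gt)
}

.preprocess_record <- function(record, config) {
  if (!is.null(config$resample$dt)) {
    for (fld in c("csa", "cvp", "ecg", "ecg_cvp"))
      if (!is.null(record[[fld]]))
        record[[fld]] <- resample_signal(record[[fld]], config$resample$dt)
  }
  if (config$sync$method != "none" && !is.null(record$cvp))
    record <- synchronize(record, config$sync$method)
  if (isTRUE(config$filter$enabled)) {
    fs <- .config_filter_spec(config)
    record$csa <- remove_noncardiac(record$csa, fs)
    if (!is.null(record$cvp)) record$cvp <- remove_noncardiac(record$cvp, fs)
  }
  if (!is.null(record$cvp)) record <- conform_lengths(record)
  record
}

#' Extract a feature table from a cohort directory
#'
#' Reads every per-subject signal file in `indir` (all delimited files except
#' `ground_truth.csv`), preprocesses each per the configuration (optional
#' resampling, synchronization, band-pass), extracts the lag-grid
#' autocorrelation features, and writes one table row per subject. Subjects
#' whose trace is too short for the lag grid are skipped with a warning; the
#' result flags partial success.
#'
#' @param indir cohort directory (as written by [cmd_simulate()]).
#' @param outfile optional output file for the feature table (CSV).
#' @param config a `pipeline_config`.
#' @return the feature `data.frame` (invisible when `outfile` given), with
#'   attributes `skipped` (character vector of subject ids) and, when the CVP
#'   trace was present, a `cvp_mean_obs` column holding each subject's
#'   observed mean CVP.
#' @export
cmd_features <- function(indir, outfile = NULL, config = default_config()) {
  if (!dir.exists(indir)) .stop_format("input directory not found: ", indir)
  files <- setdiff(list.files(indir, pattern = "\\.(csv|tsv|txt)$",
                              full.names = TRUE),
                   file.path(indir, "ground_truth.csv"))
  if (!length(files)) .stop_format("no signal files in ", indir)
  rows <- list(); skipped <- character(0)
  for (f in files) {
    rec <- read_signal(f)
    res <- tryCatch({
      rec <- .preprocess_record(rec, config)
      ft <- extract_features(rec, config$features$lag_step,
                             config$features$max_lag)
      row <- feature_table(list(ft))
      row$cvp_mean_obs <- if (!is.null(rec$cvp)) mean(rec$cvp$values) else NA_real_
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", rec$subject_id, ": ", conditionMessage(res),
              call. = FALSE)
      skipped <- c(skipped, rec$subject_id)
    } else rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) .stop_validation("every subject was skipped")
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  if (!is.null(outfile)) {
    write.table(out, outfile, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Fit and cross-validate the CVP model from a feature table
#'
#' Runs minimum-AIC subset selection over `csa_mean` plus the nonzero lag
#' columns, refits the winner, cross-validates it with the configured fold
#' count and seed, and optionally serializes the model ([write_model()]) and
#' a text report mirroring the published model-table layout (predictor,
#' coefficient, 95\% CI, p-value; model AIC, r2, mae; CV r2, mae).
#'
#' @param features feature table (`data.frame`) or path to a CSV written by
#'   [cmd_features()].
#' @param cvp_means numeric vector of observed mean CVP, or `NULL` to use the
#'   table's `cvp_mean_obs` column, or a path to a two-column
#'   (`subject_id,cvp_mean`) CSV.
#' @param model_out optional path for the serialized model.
#' @param report_out optional path for the text report.
#' @param config a `pipeline_config`.
#' @return list with `model` (a `cvp_model`) and `cv` (a `crossval_report`).
#' @export
cmd_fit <- function(features, cvp_means = NULL, model_out = NULL,
                    report_out = NULL, config = default_config()) {
  if (is.character(features)) features <- read.table(features, header = TRUE,
                                                     sep = ",", check.names = FALSE)
  if (is.null(cvp_means)) {
    if (!"cvp_mean_obs" %in% names(features) || anyNA(features$cvp_mean_obs))
      .stop_validation("no cvp_means given and feature table lacks complete cvp_mean_obs")
    cvp_means <- features$cvp_mean_obs
  } else if (is.character(cvp_means)) {
    tab <- read.table(cvp_means, header = TRUE, sep = ",")
    m <- match(features$subject_id, tab$subject_id)
    if (anyNA(m)) .stop_validation("cvp table missing subjects")
    cvp_means <- tab$cvp_mean[m]
  }
  candidates <- c("csa_mean",
                  lag_grid_names(config$features$lag_step,
                                 config$features$max_lag)[-1L])
  # cap the subset size so every CV training fold can still refit it
  k <- min(config$cv$k, nrow(features))
  train_min <- nrow(features) - ceiling(nrow(features) / k)
  model <- select_model(features, cvp_means, candidates,
                        strategy = config$selection$strategy,
                        max_predictors = train_min - 2L)
  cv <- cross_validate(features, cvp_means, model$selected_predictors,
                       k = k, seed = config$cv$seed)
  if (!is.null(model_out)) write_model(model, model_out)
  if (!is.null(report_out)) writeLines(model_report(model, cv), report_out)
  list(model = model, cv = cv)
}

#' Text report for a fitted model
#'
#' @param model a `cvp_model` with an attached `lm` fit.
#' @param cv optional `crossval_report`.
#' @return character vector of report lines.
#' @export
model_report <- function(model, cv = NULL) {
  stopifnot(inherits(model, "cvp_model"))
  lines <- c("CVP prediction model (response: mean CVP, cmH2O)",
             sprintf("n = %d subjects, %d predictors", model$n_subjects,
                     length(model$selected_predictors)),
             "")
  if (!is.null(model$lm_fit)) {
    sm <- summary(model$lm_fit)$coefficients
    ci <- stats::confint(model$lm_fit)
    nm <- gsub("`", "", rownames(sm))
    lines <- c(lines,
               sprintf("%-12s %10s %22s %8s", "predictor", "coef",
                       "95% CI", "p"),
               sprintf("%-12s %10.3f   (%8.2f, %8.2f) %8.3f",
                       nm, sm[, 1L], ci[, 1L], ci[, 2L], sm[, 4L]))
  } else {
    lines <- c(lines, sprintf("%-12s %10.3f", names(model$coefficients),
                              model$coefficients))
  }
  lines <- c(lines, "",
             sprintf("AIC = %.1f, r2 = %.3f (mae = %.3f cmH2O)",
                     model$aic, model$r_squared, model$mae))
  if (!is.null(cv))
    lines <- c(lines,
               sprintf("%d-fold CV: r2 = %.3f (mae = %.3f cmH2O), seed = %d",
                       cv$k, cv$r_squared_cv, cv$mae_cv, cv$seed))
  lines
}

#' Predict mean CVP for a feature table
#'
#' Applies a serialized model ([read_model()]), an in-memory `cvp_model`, or
#' the published fixed-coefficient equation (`published = TRUE`) to every row
#' of a feature table, optionally appending the three-category clinical
#' classification.
#'
#' @param features feature table (`data.frame`) or path to CSV.
#' @param model a `cvp_model`, or path to a model file; ignored when
#'   `published = TRUE`.
#' @param published use the published coefficients.
#' @param classify append a `cvp_class` column ([classify_cvp()]).
#' @param outfile optional output CSV.
#' @param config a `pipeline_config` (classification bounds).
#' @return `data.frame` with `subject_id`, `cvp_pred` and optionally
#'   `cvp_class` (invisible when `outfile` given).
#' @export
cmd_predict <- function(features, model = NULL, published = FALSE,
                        classify = FALSE, outfile = NULL,
                        config = default_config()) {
  if (is.character(features)) features <- read.table(features, header = TRUE,
                                                     sep = ",", check.names = FALSE)
  if (published) model <- published_cvp_model()
  else if (is.character(model)) model <- read_model(model)
  if (!inherits(model, "cvp_model"))
    .stop_validation("supply a model, a model file, or published = TRUE")
  pred <- predict(model, features)
  out <- data.frame(subject_id = if ("subject_id" %in% names(features))
    features$subject_id else seq_len(nrow(features)),
    cvp_pred = pred)
  if (classify)
    out$cvp_class <- classify_cvp(pred, c(config$classify$low_cmh2o,
                                          config$classify$high_cmh2o))
  if (!is.null(outfile)) {
    write.table(out, outfile, sep = ",", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
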