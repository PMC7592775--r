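# Domain containers: uniformly sampled physiological traces, per-subject
# records pairing IJV-CSA / CVP / ECG, and pressure values with units.

#' Conversion factor between mmHg and cmH2O
#'
#' Fixed at 1 mmHg = 1.35951 cmH2O (water at 4 degC, standard gravity), the
#' factor that maps the 2--8 mmHg normal CVP range onto 2.72--10.88 cmH2O.
#' @export
CMH2O_PER_MMHG <- 1.35951

.SIGNAL_UNITS <- c("cm2", "cmH2O", "au")

#' Uniformly sampled physiological time series
#'
#' A thin container for one trace: sample values, the sampling interval `dt`
#' (seconds), measurement units and a label. Time is represented implicitly as
#' `dt` times the 0-based sample index; absolute timestamps are not retained
#' because every downstream computation (autocorrelation lags, cross-correlation
#' lags) is index-based.
#'
#' @param values numeric vector of samples; all finite, length >= 2.
#' @param dt sampling interval in seconds (> 0).
#' @param units one of `"cm2"` (IJV cross-sectional area), `"cmH2O"` (pressure)
#'   or `"au"` (arbitrary units, e.g. ECG).
#' @param label free-text label.
#' @return An object of class `ts_signal`.
#' @examples
#' s <- ts_signal(sin(2 * pi * seq(0, 10, by = 0.01)), dt = 0.01, units = "cm2")
#' signal_duration(s)
#' @export
ts_signal <- function(values, dt, units = c("au", "cm2", "cmH2O"), label = "") {
  units <- units[1L]
  if (!units %in% .SIGNAL_UNITS)
    .stop_validation("units must be one of: ", paste(.SIGNAL_UNITS, collapse = ", "))
  values <- as.numeric(values)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .stop_validation("dt must be a single positive number, got ", format(dt))
  if (length(values) < 2L)
    .stop_validation("a signal needs at least 2 samples, got ", length(values))
  bad <- which(!is.finite(values))
  if (length(bad))
    .stop_validation("non-finite sample at index ", bad[1L])
  structure(list(values = values, dt = dt, units = units, label = label),
            class = "ts_signal")
}

#' @export
print.ts_signal <- function(x, ...) {
  cat(sprintf("<ts_signal> %s: %d samples @ dt=%g s (%.3f s), units=%s\n",
              if (nzchar(x$label)) x$label else "unlabelled",
              length(x$values), x$dt, signal_duration(x), x$units))
  invisible(x)
}

#' @export
length.ts_signal <- function(x) length(x$values)

#' Duration of a signal in seconds
#'
#' Defined as `(n - 1) * dt` for `n` samples.
#' @param signal a [ts_signal()].
#' @return duration in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "ts_signal"))
  (length(signal$values) - 1L) * signal$dt
}

.as_values <- function(x) if (inherits(x, "ts_signal")) x$values else as.numeric(x)

#' One subject's paired signal record
#'
#' Bundles a subject identifier with the IJV-CSA trace and, when available,
#' the synchronized CVP and ECG traces. When both CSA and CVP are present and
#' the record is marked synchronized, the traces must share length and `dt`.
#'
#' @param subject_id character scalar.
#' @param csa [ts_signal()] of IJV cross-sectional area (cm2).
#' @param cvp optional [ts_signal()] of central venous pressure (cmH2O).
#' @param ecg optional [ts_signal()] of the ECG, on the CSA grid.
#' @param ecg_cvp optional second ECG recorded alongside the CVP trace, used
#'   only as a synchronization anchor.
#' @param synchronized logical; have the traces been aligned to a common origin?
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, csa, cvp = NULL, ecg = NULL,
                           ecg_cvp = NULL, synchronized = FALSE) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    .stop_validation("subject_id must be a single string")
  stopifnot(inherits(csa, "ts_signal"))
  if (!is.null(cvp)) stopifnot(inherits(cvp, "ts_signal"))
  if (!is.null(ecg)) stopifnot(inherits(ecg, "ts_signal"))
  if (!is.null(ecg_cvp)) stopifnot(inherits(ecg_cvp, "ts_signal"))
  if (isTRUE(synchronized) && !is.null(cvp)) {
    if (length(csa$values) != length(cvp$values))
      .stop_validation("synchronized record needs equal-length csa/cvp traces (",
                       length(csa$values), " vs ", length(cvp$values), ")")
    if (abs(csa$dt - cvp$dt) > 1e-9)
      .stop_validation("synchronized record needs equal dt (",
                       csa$dt, " vs ", cvp$dt, ")")
  }
  structure(list(subject_id = subject_id, csa = csa, cvp = cvp, ecg = ecg,
                 ecg_cvp = ecg_cvp, synchronized = isTRUE(synchronized),
                 sync_shift = NA_integer_),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  have <- c("csa", if (!is.null(x$cvp)) "cvp", if (!is.null(x[["ecg"]])) "ecg")
  cat(sprintf("<subject_record> %s: %s; %d samples @ dt=%g s%s\n",
              x$subject_id, paste(have, collapse = "+"),
              length(x$csa$values), x$csa$dt,
              if (x$synchronized) " (synchronized)" else ""))
  invisible(x)
}

#' Pressure value with units
#'
#' @param magnitude numeric scalar.
#' @param units `"mmHg"` or `"cmH2O"`.
#' @return An object of class `pressure`.
#' @export
pressure <- function(magnitude, units = c("cmH2O", "mmHg")) {
  units <- match.arg(units)
  if (!is.numeric(magnitude) || length(magnitude) != 1L || !is.finite(magnitude))
    .stop_validation("magnitude must be a single finite number")
  structure(list(magnitude = magnitude, units = units), class = "pressure")
}

#' @export
print.pressure <- function(x, ...) {
  cat(sprintf("%g %s\n", x$magnitude, x$units)); invisible(x)
}

#' Convert a pressure between mmHg and cmH2O
#'
#' Uses the fixed factor [CMH2O_PER_MMHG] (1 mmHg = 1.35951 cmH2O), so the
#' 2--8 mmHg normal CVP range maps to 2.72--10.88 cmH2O. Idempotent when the
#' target units match the current units, and exactly invertible.
#'
#' @param p a [pressure()].
#' @param target_units `"mmHg"` or `"cmH2O"`.
#' @return a [pressure()] in the target units.
#' @examples
#' convert_pressure(pressure(8, "mmHg"), "cmH2O")  # 10.88 cmH2O
#' @export
convert_pressure <- function(p, target_units) {
  stopifnot(inherits(p, "pressure"))
  if (!is.character(target_units) || length(target_units) != 1L ||
      !target_units %in% c("mmHg", "cmH2O"))
    .stop_validation("unknown pressure unit: ", target_units)
  if (identical(p$units, target_units)) return(p)
  mag <- if (target_units == "cmH2O") p$magnitude * CMH2O_PER_MMHG
         else p$magnitude / CMH2O_PER_MMHG
  pressure(mag, target_units)
}

# --- columnar text I/O -------------------------------------------------------

.COLUMN_ROLES <- c(time = "time_s", csa = "csa_cm2", cvp = "cvp_cmh2o",
                   ecg = "ecg_au", ecg_cvp = "ecg_cvp_au")

.detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", "\t", ";"),
                   function(d) lengths(regmatches(header, gregexpr(d, header, fixed = TRUE))),
                   integer(1L))
  if (all(counts == 0L)) .stop_format("cannot detect delimiter in ", path)
  names(counts)[which.max(counts)]
}

#' Read a per-subject signal file
#'
#' Reads delimiter-separated columnar text (comma, tab or semicolon; one header
#' row) holding a time column plus any subset of CSA / CVP / ECG traces, and
#' validates uniform sampling. The canonical header is
#' `time_s, csa_cm2, cvp_cmh2o, ecg_au` (plus `ecg_cvp_au` for a second ECG
#' anchored to the CVP trace); `column_spec` remaps nonstandard headers.
#'
#' @param path file to read.
#' @param column_spec optional named character vector mapping file column names
#'   to roles among `time`, `csa`, `cvp`, `ecg`, `ecg_cvp`,
#'   e.g. `c(t = "time", area = "csa")`.
#' @param dt sampling interval in seconds, or `"from-file"` (default) to infer
#'   it from the time column. The time column must be uniform: any deviation
#'   larger than 1\% of `dt` is rejected.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @return a [subject_record()].
#' @seealso [write_signal()] for the lossless inverse.
#' @export
read_signal <- function(path, column_spec = NULL, dt = "from-file",
                        subject_id = NULL) {
  if (!file.exists(path)) .stop_format("file not found: ", path)
  delim <- .detect_delim(path)
  df <- read.table(path, header = TRUE, sep = delim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(column_spec)) {
    unknown <- setdiff(unname(column_spec), names(.COLUMN_ROLES))
    if (length(unknown))
      .stop_format("unknown column roles: ", paste(unknown, collapse = ", "))
    hit <- names(column_spec) %in% names(df)
    if (!all(hit))
      .stop_format("columns not in file: ",
                   paste(names(column_spec)[!hit], collapse = ", "))
    names(df)[match(names(column_spec), names(df))] <-
      .COLUMN_ROLES[unname(column_spec)]
  }
  if (!"time_s" %in% names(df)) .stop_format("missing required column time_s")
  for (cn in names(df)) {
    v <- df[[cn]]
    if (!is.numeric(v)) .stop_validation("non-numeric column ", cn)
    bad <- which(!is.finite(v))
    if (length(bad))
      .stop_validation("non-finite value in column ", cn, " at row ", bad[1L])
  }
  tm <- df$time_s
  if (length(tm) < 2L) .stop_validation("need at least 2 rows")
  steps <- diff(tm)
  dt_use <- if (identical(dt, "from-file")) median(steps) else as.numeric(dt)
  if (!is.finite(dt_use) || dt_use <= 0) .stop_validation("invalid dt: ", dt_use)
  dev <- max(abs(steps - dt_use))
  if (dev > 0.01 * dt_use)
    .stop_validation("time column not uniformly sampled: max deviation ",
                     format(dev), " s exceeds 1% of dt = ", format(dt_use), " s")
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  grab <- function(col, units, label)
    if (col %in% names(df)) ts_signal(df[[col]], dt_use, units, label) else NULL
  csa <- grab("csa_cm2", "cm2", "IJV-CSA")
  if (is.null(csa)) .stop_format("missing column csa_cm2 (IJV-CSA trace)")
  subject_record(subject_id, csa = csa,
                 cvp = grab("cvp_cmh2o", "cmH2O", "CVP"),
                 ecg = grab("ecg_au", "au", "ECG"),
                 ecg_cvp = grab("ecg_cvp_au", "au", "ECG (CVP monitor)"))
}

#' Write a per-subject signal file
#'
#' Serializes a [subject_record()] as delimiter-separated text with a header
#' naming the units (`time_s, csa_cm2, cvp_cmh2o, ecg_au, ecg_cvp_au`), at 15
#' significant digits so that [read_signal()] round-trips losslessly.
#'
#' @param record a [subject_record()].
#' @param path output file.
#' @param delim field delimiter, one of `","`, `"\t"`, `";"`.
#' @return `path`, invisibly.
#' @export
write_signal <- function(record, path, delim = ",") {
  stopifnot(inherits(record, "subject_record"))
  if (!delim %in% c(",", "\t", ";")) .stop_validation("unsupported delimiter")
  n <- length(record$csa$values)
  df <- data.frame(time_s = (seq_len(n) - 1L) * record$csa$dt)
  df$csa_cm2 <- record$csa$values
  for (fld in c("cvp", "ecg", "ecg_cvp")) {
    sig <- record[[fld]]
    if (is.null(sig)) next
    if (length(sig$values) != n || abs(sig$dt - record$csa$dt) > 1e-9)
      .stop_validation(fld, " trace not on the csa grid; synchronize/conform first")
    df[[.COLUMN_ROLES[[fld]]]] <- sig$values
  }
  ok <- tryCatch({
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(names(df), collapse = delim), con)
    # %.17g keeps doubles bit-exact through the text round trip
    body <- do.call(paste, c(lapply(df, function(col) sprintf("%.17g", col)),
                             sep = delim))
    writeLines(body, con)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok))
  invisible(path)
}
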