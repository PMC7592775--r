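# Preprocessing of paired traces: removal of non-cardiac (respiratory /
# thoracic-pump) frequency content, ECG-based synchronization, length
# conforming and resampling.

#' Band-pass filter specification
#'
#' Describes the zero-phase filter used to strip frequencies of non-cardiac
#' origin from a trace. The default passes 0.5--10 Hz: respiration in supine
#' adults sits below ~0.4 Hz while the cardiac fundamental is near 1 Hz, so a
#' 0.5 Hz lower edge separates the thoracic-pump contribution from the cardiac
#' one with margin on both sides.
#'
#' @param low_cutoff_hz lower band edge in Hz (>= 0; 0 disables high-pass).
#' @param high_cutoff_hz upper band edge in Hz (`Inf` disables low-pass).
#' @param order Butterworth design order for each (high-pass and low-pass)
#'   stage.
#' @param zero_phase apply the filter forward and backward so it introduces no
#'   phase lag (doubles the effective attenuation slope).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_cutoff_hz = 0.5, high_cutoff_hz = 10,
                        order = 4L, zero_phase = TRUE) {
  if (low_cutoff_hz < 0) .stop_validation("low_cutoff_hz must be >= 0")
  if (high_cutoff_hz <= low_cutoff_hz)
    .stop_validation("high_cutoff_hz must exceed low_cutoff_hz")
  order <- as.integer(order)
  if (order < 1L || order > 12L) .stop_validation("order must be in 1..12")
  structure(list(low_cutoff_hz = low_cutoff_hz,
                 high_cutoff_hz = high_cutoff_hz,
                 order = order, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# forward(-backward) filtering with odd-symmetric reflect padding to suppress
# edge transients on short (10-15 s) traces
.filt_padded <- function(filt, x, pad, zero_phase) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xx <- c(left, x, right)
  y <- signal::filter(filt, xx)
  if (zero_phase) y <- rev(signal::filter(filt, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Remove non-cardiac frequency content from a trace
#'
#' Applies a Butterworth band-pass (high-pass and low-pass stages in cascade,
#' each of `spec$order`) to suppress CSA variation driven by the thoracic pump
#' (respiration) and high-frequency noise while leaving the cardiac band
#' untouched. With `zero_phase = TRUE` the filter runs forward and backward,
#' so the output has no phase lag relative to the input. Edges are
#' odd-reflect padded before filtering and trimmed after, so the output has
#' the input's length.
#'
#' @param signal a [ts_signal()].
#' @param spec a [filter_spec()]; the default removes content below 0.5 Hz and
#'   above 10 Hz.
#' @return a filtered [ts_signal()] of the same length, dt and units.
#' @examples
#' t <- seq(0, 12, by = 0.008)
#' x <- ts_signal(sin(2 * pi * t) + 0.5 * sin(2 * pi * 0.25 * t), 0.008, "cm2")
#' y <- remove_noncardiac(x)  # the 0.25 Hz respiratory component is gone
#' @export
remove_noncardiac <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "ts_signal"), inherits(spec, "filter_spec"))
  nyq <- 1 / (2 * signal$dt)
  if (spec$low_cutoff_hz >= nyq)
    .stop_validation("low cutoff ", spec$low_cutoff_hz,
                     " Hz is at/above Nyquist (", nyq, " Hz)")
  if (is.finite(spec$high_cutoff_hz) && spec$high_cutoff_hz >= nyq)
    .stop_validation("high cutoff ", spec$high_cutoff_hz,
                     " Hz is at/above Nyquist (", nyq, " Hz)")
  n <- length(signal$values)
  if (n <= 3L * spec$order)
    .stop_validation("signal too short (", n, ") for filter order ", spec$order)
  x <- signal$values
  mu <- mean(x)
  y <- x - mu
  # pad long enough to flush the high-pass transient (~1 period of the low edge)
  pad <- max(3L * spec$order,
             if (spec$low_cutoff_hz > 0)
               as.integer(ceiling(1 / (spec$low_cutoff_hz * signal$dt))) else 0L)
  if (spec$low_cutoff_hz > 0) {
    hp <- signal::butter(spec$order, spec$low_cutoff_hz / nyq, type = "high")
    y <- .filt_padded(hp, y, pad, spec$zero_phase)
  }
  if (is.finite(spec$high_cutoff_hz)) {
    lp <- signal::butter(spec$order, spec$high_cutoff_hz / nyq, type = "low")
    y <- .filt_padded(lp, y, pad, spec$zero_phase)
  }
  # restore the trace mean: only the oscillatory content is being cleaned
  out <- signal
  out$values <- y + mu
  out
}

#' Detect R-peaks in an ECG trace
#'
#' Local maxima exceeding `mean + 2 * SD` of the trace, with a 0.3 s
#' refractory window (physiological upper bound ~200 bpm) that keeps only the
#' tallest peak inside any window.
#'
#' @param ecg a [ts_signal()] carrying the ECG.
#' @return integer vector of 1-based peak sample indices.
#' @export
detect_rpeaks <- function(ecg) {
  stopifnot(inherits(ecg, "ts_signal"))
  x <- ecg$values
  thr <- mean(x) + 2 * sd(x)
  n <- length(x)
  cand <- which(x > thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] >= x[cand - 1L] & x[cand] >= x[cand + 1L]]
  if (!length(cand)) return(integer(0))
  refr <- max(1L, round(0.3 / ecg$dt))
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[length(keep)] < refr) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else keep <- c(keep, i)
  }
  keep
}

.shift_trim <- function(record, shift) {
  # positive shift: the shared reference event appears `shift` samples later
  # on the csa side, so drop `shift` leading csa-side samples to align origins
  drop_head <- function(sig, k) {
    if (is.null(sig) || k == 0L) return(sig)
    sig$values <- sig$values[-seq_len(k)]
    sig
  }
  if (shift >= 0L) {
    record$csa <- drop_head(record$csa, shift)
    record[["ecg"]] <- drop_head(record[["ecg"]], shift)
  } else {
    record$cvp <- drop_head(record$cvp, -shift)
    record$ecg_cvp <- drop_head(record$ecg_cvp, -shift)
  }
  record
}

#' Synchronize the CVP and CSA traces of a record
#'
#' Aligns the two traces to a common time origin. With `method = "ecg_rpeak"`
#' the first R-peak of the ECG recorded with each trace is used as the anchor
#' (the ECG is a shared physiological clock); with `"cross_correlation"` the
#' lag maximizing the CVP-vs-CSA cross-correlation is removed; `"none"` marks
#' an already-aligned record as synchronized.
#'
#' @param record a [subject_record()] carrying `csa` and `cvp` on equal `dt`.
#'   For `ecg_rpeak`, `ecg` (CSA-side) and `ecg_cvp` (CVP-side) must both be
#'   present.
#' @param method one of `"ecg_rpeak"`, `"cross_correlation"`, `"none"`.
#' @return the record with traces shifted and trimmed to a common origin,
#'   `synchronized = TRUE`, and the applied shift (samples, positive meaning
#'   the CVP-side led) stored in `$sync_shift`.
#' @export
synchronize <- function(record,
                        method = c("ecg_rpeak", "cross_correlation", "none")) {
  stopifnot(inherits(record, "subject_record"))
  method <- match.arg(method)
  if (method == "none") {
    record$synchronized <- TRUE
    record$sync_shift <- 0L
    return(record)
  }
  if (is.null(record$cvp))
    .stop_validation("record has no cvp trace to synchronize")
  if (abs(record$csa$dt - record$cvp$dt) > 1e-9)
    .stop_validation("csa and cvp dt differ; resample first")
  if (method == "ecg_rpeak") {
    if (is.null(record[["ecg"]]) || is.null(record$ecg_cvp))
      stop(structure(class = c("cvpulse_sync_error", "error", "condition"),
                     list(message = "ecg_rpeak synchronization needs both ecg and ecg_cvp channels",
                          call = sys.call())))
    p_csa <- detect_rpeaks(record[["ecg"]])
    p_cvp <- detect_rpeaks(record$ecg_cvp)
    if (length(p_csa) < 2L || length(p_cvp) < 2L)
      stop(structure(class = c("cvpulse_sync_error", "error", "condition"),
                     list(message = "fewer than 2 R-peaks detected; cannot synchronize",
                          call = sys.call())))
    shift <- p_csa[1L] - p_cvp[1L]
  } else {
    lag <- cross_correlation_lag(record$cvp, record$csa)
    shift <- -lag$incremental_lag
  }
  record <- .shift_trim(record, as.integer(shift))
  record <- conform_lengths(record)
  record$sync_shift <- as.integer(shift)
  record
}

#' Truncate paired traces to a common length
#'
#' Both traces (and any ECG channels) are cut to the shorter common length,
#' keeping the leading samples so the synchronization origin (index 0) is
#' preserved.
#'
#' @param record a [subject_record()] with both `csa` and `cvp` on equal `dt`.
#' @return the record with equal-length traces, marked synchronized.
#' @export
conform_lengths <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  if (is.null(record$cvp)) .stop_validation("record has no cvp trace")
  if (abs(record$csa$dt - record$cvp$dt) > 1e-9)
    .stop_validation("csa and cvp dt differ (", record$csa$dt, " vs ",
                     record$cvp$dt, "); resample first")
  n <- min(length(record$csa$values), length(record$cvp$values))
  trim <- function(sig) {
    if (is.null(sig)) return(NULL)
    sig$values <- sig$values[seq_len(min(n, length(sig$values)))]
    sig
  }
  for (fld in c("csa", "cvp", "ecg", "ecg_cvp")) record[[fld]] <- trim(record[[fld]])
  record$synchronized <- TRUE
  record
}

#' Resample a signal onto a new uniform grid
#'
#' Linear interpolation onto a uniform grid with spacing `new_dt` spanning the
#' same duration. Linear (not spectral) interpolation is used deliberately:
#' the traces are short and heavily oversampled relative to the cardiac band,
#' and linear interpolation cannot ring.
#'
#' @param signal a [ts_signal()].
#' @param new_dt target sampling interval in seconds.
#' @return a resampled [ts_signal()].
#' @export
resample_signal <- function(signal, new_dt) {
  stopifnot(inherits(signal, "ts_signal"))
  if (!is.numeric(new_dt) || length(new_dt) != 1L || new_dt <= 0)
    .stop_validation("new_dt must be a single positive number")
  dur <- signal_duration(signal)
  if (new_dt > dur)
    .stop_validation("new_dt (", new_dt, " s) exceeds signal duration (",
                     dur, " s)")
  t_old <- (seq_along(signal$values) - 1L) * signal$dt
  t_new <- seq(0, dur, by = new_dt)
  out <- signal
  out$values <- stats::approx(t_old, signal$values, xout = t_new)$y
  out$dt <- new_dt
  out
}
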