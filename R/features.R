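# Feature extraction: autocorrelation r-values on the fixed lag grid, Pearson
# and cross-correlation between paired traces, periodogram peaks, and
# periodicity recovered from the autocorrelogram.

#' Autocorrelation r-values of a trace
#'
#' Computes, for each lag h = 0..`max_lag` (in samples), the autocorrelation
#' \deqn{r_h = \frac{\sum_t (y_t - \bar y)(y_{t+h} - \bar y)}
#'                  {\sum_t (y_t - \bar y)^2}}
#' with a single full-series mean and the lag-0 sum of squares as denominator
#' (biased normalization — the convention of `stats::acf`). `r_0` is exactly 1
#' and every `|r_h| <= 1`.
#'
#' @param signal a [ts_signal()] or numeric vector.
#' @param max_lag maximum lag in samples (`< length(signal)`).
#' @return numeric vector of length `max_lag + 1`, named `lag0`, `lag1`, ...
#' @examples
#' autocorrelation(c(1, 2, 3, 4, 5), 1)  # lag1 r-value is 0.4
#' @export
autocorrelation <- function(signal, max_lag) {
  y <- .as_values(signal)
  n <- length(y)
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L || max_lag >= n)
    .stop_validation("max_lag must be in 0..", n - 1L)
  d <- y - mean(y)
  denom <- sum(d * d)
  if (denom <= 0)
    stop(structure(class = c("cvpulse_degenerate_error", "error", "condition"),
                   list(message = "constant signal: autocorrelation undefined",
                        call = sys.call())))
  r <- vapply(0:max_lag, function(h) {
    sum(d[seq_len(n - h)] * d[seq_len(n - h) + h]) / denom
  }, numeric(1))
  names(r) <- paste0("lag", 0:max_lag)
  r
}

#' Names of the lag-grid feature columns
#'
#' @param lag_step grid step in samples.
#' @param max_lag maximum lag in samples.
#' @return character vector `lag0`, `lag20`, ..., `lag360` for the defaults.
#' @export
lag_grid_names <- function(lag_step = 20L, max_lag = 360L)
  paste0("lag", seq(0L, max_lag, by = lag_step))

#' Extract the per-subject autocorrelation feature vector
#'
#' The model's predictors: autocorrelation r-values of the IJV-CSA trace at
#' lags 0, `lag_step`, 2`lag_step`, ..., `max_lag` samples (19 values for the
#' default 0..360 step 20 grid), plus the arithmetic mean of the CSA trace.
#' Lags are counted in samples, not seconds: each subject keeps its own
#' sampling interval, mirroring how the features were defined on the original
#' cohort.
#'
#' @param record a [subject_record()] (or a bare [ts_signal()] CSA trace).
#' @param lag_step lag-grid step in samples.
#' @param max_lag maximum lag in samples; the CSA trace must be longer.
#' @return an object of class `acf_features`: list with `subject_id`,
#'   `lag_grid` (samples), `r_values` (named numeric), `csa_mean` (cm2) and
#'   `dt` (s).
#' @export
extract_features <- function(record, lag_step = 20L, max_lag = 360L) {
  if (inherits(record, "ts_signal"))
    record <- subject_record("unnamed", csa = record)
  stopifnot(inherits(record, "subject_record"))
  csa <- record$csa
  if (length(csa$values) <= max_lag)
    .stop_validation("csa trace (", length(csa$values),
                     " samples) must be longer than max_lag = ", max_lag)
  grid <- seq(0L, as.integer(max_lag), by = as.integer(lag_step))
  acf_full <- autocorrelation(csa, max_lag)
  r <- acf_full[grid + 1L]
  names(r) <- paste0("lag", grid)
  structure(list(subject_id = record$subject_id, lag_grid = grid,
                 r_values = r, csa_mean = mean(csa$values), dt = csa$dt),
            class = "acf_features")
}

#' @export
print.acf_features <- function(x, ...) {
  cat(sprintf("<acf_features> %s: csa_mean=%.4f cm2, %d lags (0..%d step %d)\n",
              x$subject_id, x$csa_mean, length(x$lag_grid),
              max(x$lag_grid), if (length(x$lag_grid) > 1L) diff(x$lag_grid)[1L] else 0L))
  invisible(x)
}

#' Assemble a per-subject feature table
#'
#' One row per subject with `subject_id`, `csa_mean`, `dt` and one column per
#' lag-grid r-value — the layout consumed by [fit_ols()], [select_model()] and
#' [predict_published()].
#'
#' @param features a list of `acf_features` (from [extract_features()]), or a
#'   list of [subject_record()]s which are run through [extract_features()]
#'   first.
#' @param ... passed to [extract_features()] when records are given.
#' @return a `data.frame`.
#' @export
feature_table <- function(features, ...) {
  if (inherits(features, "acf_features")) features <- list(features)
  features <- lapply(features, function(f) {
    if (inherits(f, "subject_record")) extract_features(f, ...) else f
  })
  stopifnot(all(vapply(features, inherits, logical(1), "acf_features")))
  grids <- unique(lapply(features, `[[`, "lag_grid"))
  if (length(grids) != 1L)
    .stop_validation("subjects have mismatched lag grids")
  rows <- lapply(features, function(f)
    data.frame(subject_id = f$subject_id, csa_mean = f$csa_mean, dt = f$dt,
               as.list(f$r_values), check.names = FALSE))
  do.call(rbind, rows)
}

#' Pearson correlation between two equal-length traces
#'
#' @param x,y [ts_signal()]s or numeric vectors of equal length with nonzero
#'   variance.
#' @return the product-moment correlation, in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  xv <- .as_values(x); yv <- .as_values(y)
  if (length(xv) != length(yv))
    .stop_validation("length mismatch: ", length(xv), " vs ", length(yv))
  if (var(xv) == 0 || var(yv) == 0)
    stop(structure(class = c("cvpulse_degenerate_error", "error", "condition"),
                   list(message = "zero-variance input to pearson_r",
                        call = sys.call())))
  stats::cor(xv, yv)
}

#' Lag between two traces by cross-correlation
#'
#' Finds the signed lag (in samples) at which the cross-correlation of `x`
#' against `y` is maximal, using the same normalization convention as R's
#' `ccf(x, y)`: the value at lag `k` correlates `x[t + k]` with `y[t]`. With
#' `x` the CVP trace and `y` the CSA trace, a CSA trace that lags (is delayed
#' behind) the CVP by `d` samples yields `incremental_lag = -d`.
#'
#' @param x,y [ts_signal()]s on equal grids (equal length and dt).
#' @param max_lag maximum |lag| searched, in samples; defaults to a quarter of
#'   the trace length.
#' @return an object of class `lag_result`: list with `incremental_lag`
#'   (samples, signed), `dt` (s), `lag_time` (s, `= incremental_lag * dt`) and
#'   `peak_r`.
#' @export
cross_correlation_lag <- function(x, y, max_lag = NULL) {
  stopifnot(inherits(x, "ts_signal"), inherits(y, "ts_signal"))
  if (length(x$values) != length(y$values))
    .stop_validation("traces must have equal length")
  if (abs(x$dt - y$dt) > 1e-9) .stop_validation("traces must share dt")
  n <- length(x$values)
  if (is.null(max_lag)) max_lag <- n %/% 4L
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) .stop_validation("max_lag must be < trace length")
  xv <- x$values - mean(x$values)
  yv <- y$values - mean(y$values)
  sx <- sqrt(sum(xv^2) / n); sy <- sqrt(sum(yv^2) / n)
  if (sx == 0 || sy == 0)
    stop(structure(class = c("cvpulse_degenerate_error", "error", "condition"),
                   list(message = "zero-variance input to cross_correlation_lag",
                        call = sys.call())))
  lags <- seq.int(-max_lag, max_lag)
  r <- vapply(lags, function(k) {
    if (k >= 0) idx <- seq_len(n - k) else idx <- seq_len(n + k) - k
    sum(xv[idx + k] * yv[idx]) / (n * sx * sy)
  }, numeric(1))
  best <- which.max(r)
  structure(list(incremental_lag = lags[best], dt = x$dt,
                 lag_time = lags[best] * x$dt, peak_r = r[best],
                 lags = lags, r = r),
            class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> lag %d samples (%.3f s), peak r = %.3f\n",
              x$incremental_lag, x$lag_time, x$peak_r))
  invisible(x)
}

# local maxima of a curve with a simple prominence rule: a peak's prominence
# is its height above the higher of the two minima separating it from its
# neighbouring (or boundary) higher ground
.find_peaks <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] >= v[3:n]) + 1L
  if (!length(idx) || min_prominence <= 0) return(idx)
  prom <- vapply(idx, function(i) {
    left <- v[seq_len(i - 1L)]
    right <- v[seq.int(i + 1L, n)]
    higher_l <- which(left > v[i]); higher_r <- which(right > v[i])
    base_l <- min(if (length(higher_l)) left[seq.int(max(higher_l), i - 1L)] else left)
    base_r <- min(if (length(higher_r)) right[seq_len(min(higher_r))] else right)
    v[i] - max(base_l, base_r)
  }, numeric(1))
  idx[prom >= min_prominence]
}

#' Dominant frequencies from the periodogram
#'
#' Amplitude spectrum of the mean-removed trace via FFT (no taper); peaks are
#' local maxima over a 3-bin neighbourhood, ranked by amplitude.
#'
#' @param signal a [ts_signal()] with at least 8 samples and nonzero variance.
#' @param k number of dominant frequencies to return (default 5).
#' @return an object of class `spectral_summary`: list with `frequencies_hz`
#'   and `amplitudes` (non-increasing), at most `k` entries.
#' @export
periodogram_topk <- function(signal, k = 5L) {
  stopifnot(inherits(signal, "ts_signal"))
  y <- signal$values
  n <- length(y)
  if (n < 8L) .stop_validation("need at least 8 samples")
  if (var(y) == 0)
    stop(structure(class = c("cvpulse_degenerate_error", "error", "condition"),
                   list(message = "constant signal: periodogram undefined",
                        call = sys.call())))
  amp <- Mod(stats::fft(y - mean(y)))[seq_len(n %/% 2L + 1L)] * 2 / n
  freqs <- (seq_len(n %/% 2L + 1L) - 1L) / (n * signal$dt)
  # interior local maxima (strict on the left, >= on the right over 3 bins)
  pk <- .find_peaks(amp)
  pk <- pk[freqs[pk] > 0]
  if (!length(pk)) pk <- which.max(amp[-1L]) + 1L
  ord <- order(amp[pk], decreasing = TRUE)
  pk <- pk[ord][seq_len(min(k, length(pk)))]
  structure(list(frequencies_hz = freqs[pk], amplitudes = amp[pk],
                 k = as.integer(k)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> dominant frequencies (Hz / amplitude):\n")
  for (i in seq_along(x$frequencies_hz))
    cat(sprintf("  %2d. %6.3f Hz  %g\n", i, x$frequencies_hz[i], x$amplitudes[i]))
  invisible(x)
}

#' Fundamental frequency from an autocorrelogram
#'
#' The autocorrelogram of a periodic signal peaks at multiples of the period,
#' so the signal frequency is `f = 1 / (D * dt)` where `D` is the lag distance
#' between successive autocorrelogram peaks. `D` is estimated as the mean
#' spacing of positive-lag local maxima with value above 0 and prominence at
#' least `min_prominence`.
#'
#' @param acf_values autocorrelation curve at lags 0, 1, 2, ... (as returned
#'   by [autocorrelation()]).
#' @param dt sampling interval in seconds.
#' @param min_prominence minimum peak prominence (default 0.05).
#' @return frequency in Hz.
#' @export
freq_from_autocorr <- function(acf_values, dt, min_prominence = 0.05) {
  v <- as.numeric(acf_values)
  pk <- .find_peaks(v, min_prominence)
  pk <- pk[pk > 1L & v[pk] > 0]
  if (!length(pk))
    stop(structure(class = c("cvpulse_noperiod_error", "error", "condition"),
                   list(message = "no positive-lag autocorrelogram peak: no periodicity detected",
                        call = sys.call())))
  lags <- pk - 1L  # 1-based index -> lag
  D <- if (length(lags) == 1L) lags else mean(diff(c(0L, lags)))
  1 / (D * dt)
}

#' Mean ensemble autocorrelogram across subjects
#'
#' Point-wise arithmetic mean of per-subject autocorrelation curves on a
#' common lag grid — the ensemble summary used to compare the aggregate CVP
#' and CSA autocorrelation shapes.
#'
#' @param curves a list of equal-length numeric curves, a numeric matrix with
#'   one row per subject, or a list of `acf_features` (their lag-grid
#'   r-values are used).
#' @return numeric vector: the mean curve.
#' @export
ensemble_mean_acf <- function(curves) {
  if (is.matrix(curves)) curves <- split(curves, row(curves))
  if (inherits(curves, "acf_features")) curves <- list(curves)
  curves <- lapply(curves, function(cv)
    if (inherits(cv, "acf_features")) cv$r_values else as.numeric(cv))
  lens <- unique(lengths(curves))
  if (length(lens) != 1L)
    .stop_validation("curves are not on a common lag grid")
  colMeans(do.call(rbind, curves))
}

#' Similarity between two autocorrelation curves
#'
#' Pearson correlation between two full-resolution autocorrelation curves.
#' Because the autocorrelation discards absolute phase, two traces that are
#' time-shifted copies of one another have near-identical autocorrelograms,
#' so this similarity stays high even when the time-domain correlation of the
#' traces themselves is destroyed by the shift.
#'
#' @param x_acf,y_acf equal-length autocorrelation curves.
#' @return Pearson r in \[-1, 1\].
#' @export
acf_similarity <- function(x_acf, y_acf) pearson_r(x_acf, y_acf)

#' Per-subject correlation/lag summary for paired traces
#'
#' Convenience wrapper producing one row of the per-subject summary layout:
#' time-domain Pearson r between CVP and CSA, similarity of their
#' autocorrelograms, and the cross-correlation lag.
#'
#' @param record a synchronized [subject_record()] with both traces.
#' @param max_lag maximum autocorrelation lag (samples) for the acf curves.
#' @return a one-row `data.frame` with columns `subject_id`, `measured_r`,
#'   `acf_r`, `incremental_lag`, `dt`, `lag_time`.
#' @export
subject_summary <- function(record, max_lag = 360L) {
  stopifnot(inherits(record, "subject_record"))
  if (is.null(record$cvp)) .stop_validation("record has no cvp trace")
  lag <- cross_correlation_lag(record$cvp, record$csa)
  data.frame(subject_id = record$subject_id,
             measured_r = pearson_r(record$cvp, record$csa),
             acf_r = acf_similarity(autocorrelation(record$cvp, max_lag),
                                    autocorrelation(record$csa, max_lag)),
             incremental_lag = lag$incremental_lag,
             dt = lag$dt,
             lag_time = lag$lag_time)
}
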