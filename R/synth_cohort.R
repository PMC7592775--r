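# Synthetic cohort generator: paired CVP / IJV-CSA / ECG waveforms with the
# statistical structure the analysis assumes (shared cardiac fundamental near
# 1 Hz, a secondary harmonic stronger in CVP than in CSA, respiratory-band
# modulation of the CSA only, a CSA-behind-CVP lag of order 0.2 s, additive
# noise), plus known ground truth for parameter-recovery tests.

#' Per-subject waveform specification
#'
#' Parameters of one synthetic CVP/CSA/ECG triple. Defaults reflect the
#' clinical cohort the pipeline was built for: cardiac fundamental 0.95 Hz, a
#' 2x harmonic that is strong in the CVP pulse and weak in the CSA pulse,
#' respiratory modulation at 0.25 Hz on the CSA only (thoracic-pump effect),
#' a CSA-behind-CVP lag near 0.24 s, mean CVP near 6 cmH2O with pulse
#' amplitude ~1.7 cmH2O, and mean CSA near 0.98 cm2 with pulse amplitude
#' ~0.07 cm2.
#'
#' @param cardiac_hz cardiac fundamental frequency (Hz).
#' @param secondary_ratio_cvp,secondary_ratio_csa amplitude of the 2x harmonic
#'   relative to the fundamental, per signal (in \[0, 1\]; CVP larger).
#' @param respiratory_hz respiratory frequency (Hz).
#' @param respiratory_amplitude respiratory amplitude on the CSA trace, as a
#'   fraction of the CSA cardiac amplitude.
#' @param lag_s delay of the CSA pulse behind the CVP pulse (s, >= 0);
#'   realized as an integer sample shift of `round(lag_s / dt)`.
#' @param noise_frac additive white-noise SD per trace, as a fraction of that
#'   trace's cardiac amplitude.
#' @param dt sampling interval (s), in \[0.003, 0.016\].
#' @param duration_s trace duration (s), in \[10, 15\] as acquired clinically.
#' @param cvp_mean,csa_mean trace means (cmH2O, cm2).
#' @param cvp_amplitude,csa_amplitude cardiac fundamental amplitudes.
#' @param third_ratio_cvp,third_ratio_csa amplitude of a 3x harmonic relative
#'   to the fundamental (0 disables; subject-to-subject variation in harmonic
#'   content is what makes the autocorrelation features informative).
#' @param am_depth beat-to-beat amplitude-modulation depth of the cardiac
#'   component (0 disables; mimics stroke-volume variability).
#' @param am_hz,am_phase frequency (Hz) and phase of the amplitude
#'   modulation.
#' @param resp_phase phase of the respiratory modulation (rad).
#' @param waveform `"harmonic"` (fundamental + harmonics; default) or
#'   `"acv"` (Gaussian-bump a/c/v venous-pulse template, for visual realism).
#' @return an object of class `waveform_spec`.
#' @export
waveform_spec <- function(cardiac_hz = 0.95,
                          secondary_ratio_cvp = 0.5,
                          secondary_ratio_csa = 0.15,
                          respiratory_hz = 0.25,
                          respiratory_amplitude = 0.3,
                          lag_s = 0.241,
                          noise_frac = 0.1,
                          dt = 0.008,
                          duration_s = 12,
                          cvp_mean = 5.998, csa_mean = 0.984,
                          cvp_amplitude = 1.7, csa_amplitude = 0.07,
                          third_ratio_cvp = 0, third_ratio_csa = 0,
                          am_depth = 0, am_hz = 0.08, am_phase = 0,
                          resp_phase = 0,
                          waveform = c("harmonic", "acv")) {
  waveform <- match.arg(waveform)
  spec <- list(cardiac_hz = cardiac_hz,
               secondary_ratio_cvp = secondary_ratio_cvp,
               secondary_ratio_csa = secondary_ratio_csa,
               respiratory_hz = respiratory_hz,
               respiratory_amplitude = respiratory_amplitude,
               lag_s = lag_s, noise_frac = noise_frac,
               dt = dt, duration_s = duration_s,
               cvp_mean = cvp_mean, csa_mean = csa_mean,
               cvp_amplitude = cvp_amplitude, csa_amplitude = csa_amplitude,
               third_ratio_cvp = third_ratio_cvp,
               third_ratio_csa = third_ratio_csa,
               am_depth = am_depth, am_hz = am_hz, am_phase = am_phase,
               resp_phase = resp_phase,
               waveform = waveform)
  ok_pos <- c("cardiac_hz", "dt", "duration_s", "cvp_amplitude", "csa_amplitude")
  for (nm in ok_pos)
    if (!is.finite(spec[[nm]]) || spec[[nm]] <= 0)
      .stop_validation(nm, " must be positive")
  ok_nonneg <- c("secondary_ratio_cvp", "secondary_ratio_csa",
                 "respiratory_amplitude", "lag_s", "noise_frac", "csa_mean",
                 "third_ratio_cvp", "third_ratio_csa", "am_depth", "am_hz")
  for (nm in ok_nonneg)
    if (!is.finite(spec[[nm]]) || spec[[nm]] < 0)
      .stop_validation(nm, " must be >= 0")
  if (spec$dt < 0.001 || spec$dt > 0.05)
    .stop_validation("dt out of the plausible acquisition range")
  n_harm <- if (spec$third_ratio_cvp > 0 || spec$third_ratio_csa > 0) 3 else 2
  if (n_harm * spec$cardiac_hz >= 1 / (2 * spec$dt))
    .stop_validation("harmonic content above Nyquist for this dt")
  structure(spec, class = "waveform_spec")
}

# cardiac pulse shape with unit fundamental amplitude
.cardiac_shape <- function(t, f, ratio2, ratio3, waveform) {
  if (waveform == "harmonic") {
    sin(2 * pi * f * t) + ratio2 * sin(2 * pi * 2 * f * t + pi / 4) +
      ratio3 * sin(2 * pi * 3 * f * t + pi / 3)
  } else {
    # a/c/v venous template: three Gaussian bumps per cycle (a and v
    # prominent, c smaller), plus the secondary harmonic
    ph <- (t * f) %% 1
    bump <- function(c0, w, a) a * exp(-((ph - c0)^2) / (2 * w^2))
    y <- bump(0.15, 0.05, 1.0) + bump(0.40, 0.04, 0.45) + bump(0.75, 0.06, 0.85)
    y <- y - mean(y)
    y / max(abs(y)) + ratio2 * sin(2 * pi * 2 * f * t + pi / 4)
  }
}

# run fn() under a private RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  fn()
}

#' Generate one synthetic subject
#'
#' Builds a paired CVP / IJV-CSA / ECG record on a common grid. The CVP trace
#' is `cvp_mean` plus the cardiac shape (fundamental + secondary harmonic)
#' plus noise; the CSA trace is `csa_mean` plus the same cardiac shape with a
#' weaker secondary harmonic, delayed by `round(lag_s / dt)` samples (index
#' shift with edge trimming, so both traces keep equal length), plus additive
#' respiratory modulation and noise. The ECG is a narrow Gaussian impulse
#' train phase-locked to the CVP cardiac component; `ecg_cvp` carries an
#' identical copy on the CVP side.
#'
#' @param spec a [waveform_spec()].
#' @param seed integer seed (the caller's RNG stream is left untouched).
#' @param subject_id identifier for the record.
#' @return a synchronized [subject_record()].
#' @export
generate_subject <- function(spec = waveform_spec(), seed = 1L,
                             subject_id = "synthetic") {
  stopifnot(inherits(spec, "waveform_spec"))
  .with_seed(seed, function() {
    n <- as.integer(round(spec$duration_s / spec$dt)) + 1L
    shift <- as.integer(round(spec$lag_s / spec$dt))
    t_ext <- (seq_len(n + shift) - 1L) * spec$dt
    # shared beat-to-beat amplitude envelope (stroke-volume variability)
    env <- 1 + spec$am_depth * sin(2 * pi * spec$am_hz * t_ext + spec$am_phase)
    card_cvp <- env * .cardiac_shape(t_ext, spec$cardiac_hz,
                                     spec$secondary_ratio_cvp,
                                     spec$third_ratio_cvp, spec$waveform)
    card_csa <- env * .cardiac_shape(t_ext, spec$cardiac_hz,
                                     spec$secondary_ratio_csa,
                                     spec$third_ratio_csa, spec$waveform)
    idx_lead <- seq_len(n) + shift   # CVP side: events `shift` samples early
    idx_lag <- seq_len(n)            # CSA side: delayed copy
    t <- (seq_len(n) - 1L) * spec$dt
    cvp_v <- spec$cvp_mean + spec$cvp_amplitude * card_cvp[idx_lead] +
      rnorm(n, 0, spec$noise_frac * spec$cvp_amplitude)
    resp <- spec$respiratory_amplitude * spec$csa_amplitude *
      sin(2 * pi * spec$respiratory_hz * t + spec$resp_phase)
    csa_v <- spec$csa_mean + spec$csa_amplitude * card_csa[idx_lag] + resp +
      rnorm(n, 0, spec$noise_frac * spec$csa_amplitude)
    # R-wave: narrow Gaussian at each cardiac period, locked to the CVP phase
    period <- 1 / spec$cardiac_hz
    ph <- (t_ext / period) %% 1
    ecg_ext <- exp(-((ph - 0.5)^2) / (2 * 0.02^2))
    ecg_v <- ecg_ext[idx_lead]
    subject_record(subject_id,
                   csa = ts_signal(csa_v, spec$dt, "cm2", "IJV-CSA (synthetic)"),
                   cvp = ts_signal(cvp_v, spec$dt, "cmH2O", "CVP (synthetic)"),
                   ecg = ts_signal(ecg_v, spec$dt, "au", "ECG (synthetic)"),
                   ecg_cvp = ts_signal(ecg_v, spec$dt, "au", "ECG (synthetic)"),
                   synchronized = TRUE)
  })
}

#' Cohort-level generator specification
#'
#' Distributions from which per-subject [waveform_spec()] parameters are
#' drawn. Defaults emulate the 34-subject clinical cohort: mean CVP ~
#' N(5.998, 2.874) cmH2O, mean CSA ~ N(0.984, 0.497) cm2 (truncated to
#' physiological positives), cardiac frequency ~ N(0.95, 0.1) Hz, CSA lag ~
#' N(0.241, 0.175) s truncated at 0, per-subject dt uniform on
#' \[0.003, 0.016\] s and duration uniform on \[10, 15\] s.
#'
#' When `ground_truth_model` is supplied (list with `intercept`, named
#' `coefficients` over feature columns, and `noise_sd` in cmH2O), each
#' subject's mean CVP is overridden by that linear function of its realized
#' autocorrelation features plus Gaussian noise — giving a cohort whose
#' feature-to-CVP map is known exactly, for end-to-end recovery tests.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer master seed; identical seeds reproduce the cohort
#'   bit-for-bit.
#' @param cvp_mean_mean,cvp_mean_sd,csa_mean_mean,csa_mean_sd,cardiac_hz_mean,cardiac_hz_sd,lag_mean_s,lag_sd_s
#'   distribution parameters (means/SDs of the per-subject draws).
#' @param dt_range,duration_range_s uniform ranges for per-subject dt and
#'   duration.
#' @param respiratory_hz_range,respiratory_amplitude_range,secondary_ratio_cvp_range,secondary_ratio_csa_range,third_ratio_cvp_range,third_ratio_csa_range,am_depth_range,am_hz_range
#'   uniform ranges for the per-subject waveform-shape draws (see
#'   [waveform_spec()]). Subject-to-subject variation in harmonic content,
#'   respiration and amplitude modulation is what gives the cohort's
#'   autocorrelation features full rank, so that feature-to-CVP models are
#'   identifiable.
#' @param noise_frac additive noise fraction, fixed across subjects.
#' @param ground_truth_model optional known feature-to-CVP linear model.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 34L, seed = 1L,
                        cvp_mean_mean = 5.998, cvp_mean_sd = 2.874,
                        csa_mean_mean = 0.984, csa_mean_sd = 0.497,
                        cardiac_hz_mean = 0.95, cardiac_hz_sd = 0.1,
                        lag_mean_s = 0.241, lag_sd_s = 0.175,
                        dt_range = c(0.003, 0.016),
                        duration_range_s = c(10, 15),
                        respiratory_hz_range = c(0.15, 0.35),
                        respiratory_amplitude_range = c(0.1, 0.5),
                        secondary_ratio_cvp_range = c(0.3, 0.7),
                        secondary_ratio_csa_range = c(0.05, 0.35),
                        third_ratio_cvp_range = c(0, 0.3),
                        third_ratio_csa_range = c(0, 0.15),
                        am_depth_range = c(0, 0.3),
                        am_hz_range = c(0.05, 0.12),
                        noise_frac = 0.1,
                        ground_truth_model = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) .stop_validation("n_subjects must be >= 2")
  for (nm in c("cvp_mean_sd", "csa_mean_sd", "cardiac_hz_sd", "lag_sd_s"))
    if (get(nm) < 0) .stop_validation(nm, " must be >= 0")
  if (!is.null(ground_truth_model)) {
    need <- c("intercept", "coefficients", "noise_sd")
    if (!all(need %in% names(ground_truth_model)))
      .stop_validation("ground_truth_model needs fields: ",
                       paste(need, collapse = ", "))
    if (ground_truth_model$noise_sd < 0)
      .stop_validation("ground_truth_model$noise_sd must be >= 0")
  }
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 cvp_mean_mean = cvp_mean_mean, cvp_mean_sd = cvp_mean_sd,
                 csa_mean_mean = csa_mean_mean, csa_mean_sd = csa_mean_sd,
                 cardiac_hz_mean = cardiac_hz_mean, cardiac_hz_sd = cardiac_hz_sd,
                 lag_mean_s = lag_mean_s, lag_sd_s = lag_sd_s,
                 dt_range = dt_range, duration_range_s = duration_range_s,
                 respiratory_hz_range = respiratory_hz_range,
                 respiratory_amplitude_range = respiratory_amplitude_range,
                 secondary_ratio_cvp_range = secondary_ratio_cvp_range,
                 secondary_ratio_csa_range = secondary_ratio_csa_range,
                 third_ratio_cvp_range = third_ratio_cvp_range,
                 third_ratio_csa_range = third_ratio_csa_range,
                 am_depth_range = am_depth_range, am_hz_range = am_hz_range,
                 noise_frac = noise_frac,
                 ground_truth_model = ground_truth_model),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject waveform parameters from the [cohort_spec()]
#' distributions, generates each subject with [generate_subject()], and
#' returns the records together with a ground-truth table (true mean CVP,
#' lag, cardiac frequency, dt, duration per subject). With a
#' `ground_truth_model`, each subject's mean CVP is set to the model's linear
#' function of its realized features plus noise, and the CVP trace is shifted
#' accordingly.
#'
#' @param spec a [cohort_spec()].
#' @return list with `records` (list of [subject_record()]) and
#'   `ground_truth` (`data.frame`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  runif_range <- function(n, r) runif(n, r[1L], r[2L])
  par <- .with_seed(spec$seed, function() {
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      cvp_mean = rnorm(n, spec$cvp_mean_mean, spec$cvp_mean_sd),
      csa_mean = pmax(0.15, rnorm(n, spec$csa_mean_mean, spec$csa_mean_sd)),
      cardiac_hz = pmax(0.6, rnorm(n, spec$cardiac_hz_mean, spec$cardiac_hz_sd)),
      lag_s = pmax(0, rnorm(n, spec$lag_mean_s, spec$lag_sd_s)),
      dt = runif_range(n, spec$dt_range),
      duration_s = runif_range(n, spec$duration_range_s),
      respiratory_hz = runif_range(n, spec$respiratory_hz_range),
      respiratory_amplitude = runif_range(n, spec$respiratory_amplitude_range),
      secondary_ratio_cvp = runif_range(n, spec$secondary_ratio_cvp_range),
      secondary_ratio_csa = runif_range(n, spec$secondary_ratio_csa_range),
      third_ratio_cvp = runif_range(n, spec$third_ratio_cvp_range),
      third_ratio_csa = runif_range(n, spec$third_ratio_csa_range),
      am_depth = runif_range(n, spec$am_depth_range),
      am_hz = runif_range(n, spec$am_hz_range),
      am_phase = runif(n, 0, 2 * pi),
      resp_phase = runif(n, 0, 2 * pi),
      sub_seed = (spec$seed + 7919L * seq_len(n)) %% 2147483647L)
  })
  records <- vector("list", n)
  for (i in seq_len(n)) {
    ws <- waveform_spec(cardiac_hz = par$cardiac_hz[i],
                        secondary_ratio_cvp = par$secondary_ratio_cvp[i],
                        secondary_ratio_csa = par$secondary_ratio_csa[i],
                        respiratory_hz = par$respiratory_hz[i],
                        respiratory_amplitude = par$respiratory_amplitude[i],
                        lag_s = par$lag_s[i], noise_frac = spec$noise_frac,
                        dt = par$dt[i], duration_s = par$duration_s[i],
                        cvp_mean = par$cvp_mean[i], csa_mean = par$csa_mean[i],
                        csa_amplitude = 0.07 * par$csa_mean[i] / 0.984,
                        third_ratio_cvp = par$third_ratio_cvp[i],
                        third_ratio_csa = par$third_ratio_csa[i],
                        am_depth = par$am_depth[i], am_hz = par$am_hz[i],
                        am_phase = par$am_phase[i],
                        resp_phase = par$resp_phase[i])
    records[[i]] <- generate_subject(ws, seed = par$sub_seed[i],
                                     subject_id = par$subject_id[i])
  }
  gtm <- spec$ground_truth_model
  if (!is.null(gtm)) {
    feats <- feature_table(lapply(records, extract_features))
    X <- .feature_matrix(feats, names(gtm$coefficients))
    eps <- .with_seed(spec$seed + 104729L,
                      function() rnorm(n, 0, gtm$noise_sd))
    new_mean <- gtm$intercept + drop(X %*% gtm$coefficients) + eps
    for (i in seq_len(n)) {
      delta <- new_mean[i] - par$cvp_mean[i]
      records[[i]]$cvp$values <- records[[i]]$cvp$values + delta
    }
    par$cvp_mean <- new_mean
  }
  par$lag_samples <- round(par$lag_s / par$dt)
  list(records = records, ground_truth = par)
}
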