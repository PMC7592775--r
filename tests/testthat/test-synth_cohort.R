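test_that("generate_subject embeds the requested structure", {
  # noise-free, respiration-free: cross-correlation recovers the exact
  # sample shift
  for (lag_s in c(0.12, 0.241, 0.4)) {
    ws <- waveform_spec(noise_frac = 0, respiratory_amplitude = 0,
                        lag_s = lag_s, dt = 0.008)
    rec <- generate_subject(ws, seed = 1)
    expect_identical(cross_correlation_lag(rec$cvp, rec$csa)$incremental_lag,
                     -as.integer(round(lag_s / 0.008)))
  }

  # trace mean concentrates on the requested mean
  ws <- waveform_spec(noise_frac = 0.1)
  rec <- generate_subject(ws, seed = 2)
  n <- length(rec$cvp$values)
  expect_lt(abs(mean(rec$cvp$values) - 5.998),
            3 * 0.1 * 1.7 / sqrt(n) + 0.02)  # noise SE + harmonic truncation

  # CVP periodogram ranks the fundamental first, its harmonic second
  sp <- periodogram_topk(rec$cvp, k = 3)
  expect_lt(abs(sp$frequencies_hz[1] - 0.95), 0.1)
  expect_lt(abs(sp$frequencies_hz[2] - 1.90), 0.15)

  # ECG carries detectable R-peaks at the cardiac rate
  pk <- detect_rpeaks(rec$ecg)
  expect_gt(length(pk), 8)
  expect_equal(median(diff(pk)) * rec$ecg$dt, 1 / 0.95, tolerance = 0.02)

  expect_error(waveform_spec(dt = -1), "dt")
  expect_error(waveform_spec(lag_s = -0.1), "lag_s")
  expect_error(waveform_spec(cardiac_hz = 12, dt = 0.025), "Nyquist")
})

test_that("generate_subject leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_subject(waveform_spec(), seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("cohorts are seed-reproducible and match configured distributions", {
  co1 <- generate_cohort(cohort_spec(n_subjects = 34, seed = 5))
  co2 <- generate_cohort(cohort_spec(n_subjects = 34, seed = 5))
  expect_identical(co1, co2)
  co3 <- generate_cohort(cohort_spec(n_subjects = 34, seed = 6))
  expect_false(identical(co1$ground_truth, co3$ground_truth))

  gt <- co1$ground_truth
  expect_true(all(gt$dt >= 0.003 & gt$dt <= 0.016))
  expect_true(all(gt$duration_s >= 10 & gt$duration_s <= 15))
  expect_true(all(gt$lag_s >= 0))
  # drawn csa means within 2 SE of the configured centre (truncation at 0.15
  # adds a small positive bias, covered by the SE allowance)
  expect_lt(abs(mean(gt$csa_mean) - 0.984), 2 * 0.497 / sqrt(34) + 0.05)
  expect_lt(abs(mean(gt$cvp_mean) - 5.998), 2 * 2.874 / sqrt(34))
})

test_that("a known ground-truth model is recoverable end-to-end", {
  truth <- list(intercept = 6,
                coefficients = c(csa_mean = 2.8, lag40 = -10, lag180 = -8),
                noise_sd = 0)
  co <- generate_cohort(cohort_spec(n_subjects = 40, seed = 17,
                                    ground_truth_model = truth))
  ft <- feature_table(lapply(co$records, extract_features))
  y <- co$ground_truth$cvp_mean
  # zero noise: the regression surface is exact
  m <- fit_ols(ft, y, names(truth$coefficients))
  expect_gt(m$r_squared, 0.99)
  expect_equal(unname(m$coefficients[names(truth$coefficients)]),
               unname(truth$coefficients), tolerance = 1e-6)
  # the generated CVP trace mean equals the model's value
  expect_equal(mean(co$records[[1]]$cvp$values),
               y[1], tolerance = 0.05)
})

test_that("cohort defaults reproduce the qualitative decorrelation pattern", {
  co <- generate_cohort(cohort_spec(n_subjects = 24, seed = 77))
  ss <- do.call(rbind, lapply(co$records, subject_summary))
  # time-domain correlation scattered around zero, autocorrelograms aligned
  expect_lt(abs(mean(ss$measured_r)), 0.35)
  expect_gt(sd(ss$measured_r), 0.15)
  expect_gt(mean(ss$acf_r), 0.6)
  # recovered lags track the generating lags (sign convention: csa lags cvp;
  # near-zero generating lags can land at a slightly positive estimate)
  expect_gte(mean(ss$incremental_lag <= 0), 0.8)
})
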