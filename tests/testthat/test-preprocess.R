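test_that("band-pass keeps the cardiac tone and removes respiratory content", {
  dt <- 0.008
  t <- seq(0, 12, by = dt)
  cardiac <- sin(2 * pi * t)
  resp <- sin(2 * pi * 0.25 * t)

  # pure in-band tone passes nearly unchanged (edges discarded)
  f1 <- remove_noncardiac(ts_signal(cardiac, dt, "cm2"))
  keep <- seq(round(1 / dt), length(t) - round(1 / dt))
  expect_lt(max(abs(f1$values[keep] - cardiac[keep])), 0.05)

  # two-tone: >= 20 dB attenuation at 0.25 Hz, <= 1 dB change at 1 Hz
  f2 <- remove_noncardiac(ts_signal(cardiac + resp, dt, "cm2"))
  bandpow <- function(v, f0) {
    n <- length(v)
    amp <- Mod(stats::fft(v - mean(v)))[seq_len(n %/% 2 + 1)]
    freqs <- (seq_len(n %/% 2 + 1) - 1) / (n * dt)
    sum(amp[abs(freqs - f0) < 0.08]^2)
  }
  x <- cardiac + resp
  expect_gt(10 * log10(bandpow(x, 0.25) / bandpow(f2$values, 0.25)), 20)
  expect_lt(abs(10 * log10(bandpow(x, 1) / bandpow(f2$values, 1))), 1)

  # zero signal maps to zero
  z <- remove_noncardiac(ts_signal(rep(0, 1000) + 0 * t[1:1000], dt, "cm2"))
  expect_equal(max(abs(z$values)), 0, tolerance = 1e-12)

  expect_error(remove_noncardiac(ts_signal(cardiac, dt, "cm2"),
                                 filter_spec(high_cutoff_hz = 80)), "Nyquist")
})

test_that("filtering is linear and zero-phase", {
  dt <- 0.008
  t <- seq(0, 12, by = dt)
  set.seed(4)
  x <- sin(2 * pi * t) + 0.3 * sin(2 * pi * 1.7 * t)
  y <- cos(2 * pi * 0.8 * t) + 0.2 * sin(2 * pi * 2.3 * t)
  fs <- filter_spec()
  f <- function(v) remove_noncardiac(ts_signal(v, dt, "cm2"), fs)$values
  lhs <- f(2 * x + 3 * y)
  rhs <- 2 * f(x) + 3 * f(y)
  # means are restored additively, so compare mean-removed responses
  expect_equal(lhs - mean(lhs), rhs - mean(rhs), tolerance = 1e-9)

  # zero-phase: no lag between a band-limited input and its filtered output
  sig <- ts_signal(x, dt, "cm2")
  lag <- cross_correlation_lag(sig, remove_noncardiac(sig, fs))
  expect_identical(lag$incremental_lag, 0L)
})

test_that("ECG R-peak synchronization recovers a constructed offset", {
  dt <- 0.005
  t <- seq(0, 12, by = dt)
  ph <- (t * 1) %% 1
  spike <- exp(-((ph - 0.5)^2) / (2 * 0.02^2))
  n <- length(spike)
  delay <- 30L
  ecg_csa <- c(rep(0, delay), spike[seq_len(n - delay)])  # csa-side starts late
  rec <- subject_record("sync",
                        csa = ts_signal(sin(2 * pi * t) + 1, dt, "cm2"),
                        cvp = ts_signal(sin(2 * pi * t) + 6, dt, "cmH2O"),
                        ecg = ts_signal(ecg_csa, dt, "au"),
                        ecg_cvp = ts_signal(spike, dt, "au"))
  out <- synchronize(rec, "ecg_rpeak")
  expect_identical(out$sync_shift, delay)
  expect_true(out$synchronized)
  expect_identical(length(out$csa$values), length(out$cvp$values))

  # method none is the identity apart from the flag
  same <- synchronize(rec, "none")
  expect_identical(same$csa$values, rec$csa$values)
  expect_true(same$synchronized)

  rec$ecg <- NULL
  expect_error(synchronize(rec, "ecg_rpeak"), class = "cvpulse_sync_error")
})

test_that("conform_lengths truncates to the common leading window", {
  a <- ts_signal(seq_len(1200) + 0, 0.01, "cm2")
  b <- ts_signal(seq_len(1000) * 2, 0.01, "cmH2O")
  rec <- conform_lengths(subject_record("c", a, b))
  expect_length(rec$csa$values, 1000)
  expect_length(rec$cvp$values, 1000)
  expect_identical(rec$csa$values, a$values[1:1000])  # leading samples kept
  # equal lengths: identity; never increases length
  rec2 <- conform_lengths(rec)
  expect_identical(rec2$csa$values, rec$csa$values)
  bad <- subject_record("d", a, ts_signal(1:100, 0.02, "cmH2O"))
  expect_error(conform_lengths(bad), "dt")
})

test_that("resampling is exact on affine signals and stable on sinusoids", {
  ramp <- ts_signal(seq(0, 5, by = 0.01), 0.01, "cm2")
  half <- resample_signal(ramp, 0.005)
  expect_equal(half$values, seq(0, 5, by = 0.005), tolerance = 1e-12)
  same <- resample_signal(ramp, 0.01)
  expect_equal(same$values, ramp$values, tolerance = 1e-12)

  s <- sine_signal(freq = 1, dt = 0.01, duration = 10)
  up_down <- resample_signal(resample_signal(s, 0.005), 0.01)
  # linear-interpolation error bound for f'' <= (2*pi)^2 on step h = 0.005
  expect_lt(max(abs(up_down$values - s$values)), 2 * (2 * pi)^2 * 0.005^2 / 8)
  expect_error(resample_signal(s, 100), "duration")
})
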