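test_that("autocorrelation matches its definition on hand-checked cases", {
  # deviations (-2,-1,0,1,2): lag-1 numerator 4, denominator 10
  r <- autocorrelation(c(1, 2, 3, 4, 5), 1)
  expect_equal(unname(r), c(1, 0.4), tolerance = 1e-15)
  expect_error(autocorrelation(rep(3, 50), 5),
               class = "cvpulse_degenerate_error")
  expect_error(autocorrelation(1:10, 10), "max_lag")
})

test_that("fast autocorrelation equals the double-loop oracle and stats::acf", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(30:200, 1)
    y <- rnorm(n) + sin(seq_len(n) / 5)
    max_lag <- sample(5:25, 1)
    r <- autocorrelation(y, max_lag)
    expect_equal(unname(r), acf_oracle(y, max_lag), tolerance = 1e-12)
    ref <- stats::acf(y, lag.max = max_lag, plot = FALSE,
                      demean = TRUE)$acf[, 1, 1]
    expect_equal(unname(r), as.numeric(ref), tolerance = 1e-10)
  }
  # sinusoid with integer period peaks again at one period
  p <- 100L
  y <- sin(2 * pi * seq_len(1200) / p)
  r <- autocorrelation(y, 150)
  expect_identical(unname(which.max(r[60:150])) + 59L - 1L, p)  # local max at lag P
})

test_that("extract_features selects the lag grid and the CSA mean", {
  s <- sine_signal(freq = 1, dt = 0.01, duration = 10, amp = 0.05)
  s$values <- s$values + 0.98
  ft <- extract_features(subject_record("g", s))
  expect_identical(ft$lag_grid, seq(0L, 360L, by = 20L))
  expect_length(ft$r_values, 19)
  expect_equal(unname(ft$r_values["lag0"]), 1)
  expect_equal(ft$csa_mean, 0.98, tolerance = 0.05 / length(s$values) + 1e-9)
  full <- autocorrelation(s, 360)
  expect_equal(unname(ft$r_values), unname(full[ft$lag_grid + 1]),
               tolerance = 1e-15)
  short <- ts_signal(rnorm(300), 0.01, "cm2")
  expect_error(extract_features(subject_record("s", short)), "max_lag")
})

test_that("pearson_r behaves as the product-moment correlation", {
  x <- ts_signal(rnorm(100) + 1, 0.01, "cm2")
  neg <- x; neg$values <- -x$values
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, neg), -1)
  expect_error(pearson_r(x, ts_signal(rnorm(50), 0.01)), "length")
  expect_error(pearson_r(x, ts_signal(rep(2, 100), 0.01)),
               class = "cvpulse_degenerate_error")
})

test_that("cross_correlation_lag finds constructed shifts with ccf sign convention", {
  x <- sine_signal(freq = 1, dt = 0.008, duration = 12, harmonic = 0.3)
  n <- length(x$values)
  for (d in c(0L, 12L, 30L)) {
    y <- x
    y$values <- c(rep(0, d), x$values[seq_len(n - d)])  # y delayed behind x
    res <- cross_correlation_lag(x, y)
    expect_identical(res$incremental_lag, -d)
    expect_equal(res$lag_time, -d * 0.008, tolerance = 1e-12)
    # brute-force argmax over all admissible lags agrees
    brute <- sapply(-res$lags[length(res$lags)]:res$lags[length(res$lags)],
                    function(k) {
      xv <- x$values - mean(x$values); yv <- y$values - mean(y$values)
      idx <- if (k >= 0) seq_len(n - k) else seq_len(n + k) - k
      sum(xv[idx + k] * yv[idx])
    })
    expect_identical(res$incremental_lag,
                     (-res$lags[length(res$lags)]:res$lags[length(res$lags)])[which.max(brute)])
  }
  # agreement with stats::ccf on a noisy pair
  set.seed(9)
  a <- ts_signal(rnorm(400), 0.01); b <- ts_signal(rnorm(400), 0.01)
  ours <- cross_correlation_lag(a, b, max_lag = 40)
  ref <- stats::ccf(a$values, b$values, lag.max = 40, plot = FALSE,
                    demean = TRUE)
  expect_identical(ours$incremental_lag,
                   as.integer(ref$lag[, 1, 1][which.max(ref$acf[, 1, 1])]))
})

test_that("a sample-resolved lag_time reproduces the printed per-subject value", {
  # printed row: incremental lag -4 at dt 0.009 s -> -0.036 s, which the
  # summary prints as -0.035 because its dt column is rounded to 3 decimals
  expect_equal(-4 * 0.009, -0.036)
  tab <- published_subject_summary()
  row <- tab[tab$subject_id == 1, ]
  expect_equal(row$incremental_lag, -4)
  expect_equal(abs(row$incremental_lag * row$dt - row$lag_time) <= 0.001, TRUE)
})

test_that("periodogram_topk ranks constructed tones correctly", {
  one <- sine_signal(freq = 1, dt = 0.01, duration = 10)
  sp <- periodogram_topk(one)
  bin <- 1 / (length(one$values) * 0.01)
  expect_lt(abs(sp$frequencies_hz[1] - 1), bin + 1e-12)

  t <- seq(0, 12, by = 0.006)
  two <- ts_signal(sin(2 * pi * 0.95 * t) + 0.5 * sin(2 * pi * 1.90 * t),
                   0.006, "cmH2O")
  sp2 <- periodogram_topk(two)
  bin2 <- 1 / (length(two$values) * 0.006)
  expect_lt(abs(sp2$frequencies_hz[1] - 0.95), bin2 + 1e-12)
  expect_lt(abs(sp2$frequencies_hz[2] - 1.90), bin2 + 1e-12)
  expect_true(all(diff(sp2$amplitudes) <= 1e-12))
  expect_error(periodogram_topk(ts_signal(rep(1, 100), 0.01)),
               class = "cvpulse_degenerate_error")
})

test_that("freq_from_autocorr implements f = 1/(D*dt)", {
  # D = 100 samples at dt = 0.01 -> 1 Hz
  r <- autocorrelation(sine_signal(1, dt = 0.01, duration = 10)$values, 350)
  expect_equal(freq_from_autocorr(r, 0.01), 1, tolerance = 0.02)
  # direct arithmetic: D = 175, dt = 0.006 -> 0.952 Hz; same D, halved dt doubles f
  acf_peak175 <- cos(2 * pi * (0:600) / 175)
  expect_equal(freq_from_autocorr(acf_peak175, 0.006), 1 / (175 * 0.006),
               tolerance = 1e-9)
  expect_equal(freq_from_autocorr(acf_peak175, 0.003),
               2 * freq_from_autocorr(acf_peak175, 0.006), tolerance = 1e-12)
  # generating-frequency recovery across the cardiac band
  for (f0 in c(0.5, 1.1, 2.0, 3.0)) {
    dt <- 0.004
    sig <- sine_signal(f0, dt = dt, duration = 14)
    r <- autocorrelation(sig$values, min(length(sig$values) - 1, 1200))
    fhat <- freq_from_autocorr(r, dt)
    quantum <- abs(1 / (round(1 / (f0 * dt)) * dt) - 1 / ((round(1 / (f0 * dt)) + 1) * dt))
    expect_lt(abs(fhat - f0), quantum + 1e-9)
  }
  expect_error(freq_from_autocorr(seq(1, 0, length.out = 50), 0.01),
               class = "cvpulse_noperiod_error")
})

test_that("ensemble_mean_acf averages curves point-wise", {
  a <- cos(2 * pi * (0:100) / 40)
  expect_equal(ensemble_mean_acf(list(a)), a)
  expect_equal(max(abs(ensemble_mean_acf(list(a, -a)))), 0)
  expect_equal(ensemble_mean_acf(rbind(a, 3 * a)), 2 * a)
  expect_error(ensemble_mean_acf(list(a, a[-1])), "common lag grid")
})

test_that("autocorrelation similarity survives time shifts that destroy Pearson r", {
  # the methodology's central claim: a delay decorrelates the traces but
  # barely perturbs their autocorrelograms
  x <- sine_signal(freq = 1, dt = 0.005, duration = 14, harmonic = 0.4)
  n <- length(x$values)
  r_time <- c(); r_acf <- c()
  for (lag_s in seq(0, 0.5, by = 0.125)) {
    d <- round(lag_s / 0.005)
    y <- x
    y$values <- c(x$values[(d + 1):n], x$values[seq_len(d)])
    r_time <- c(r_time, pearson_r(x, y))
    r_acf <- c(r_acf, acf_similarity(autocorrelation(x, 400),
                                     autocorrelation(y, 400)))
  }
  expect_equal(r_time[1], 1)
  expect_lt(min(r_time), 0)          # quarter-period shift destroys correlation
  expect_true(all(r_acf > 0.99))
  expect_equal(acf_similarity(autocorrelation(x, 400), autocorrelation(x, 400)), 1)
})
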