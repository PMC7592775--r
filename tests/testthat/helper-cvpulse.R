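# Shared fixtures and independent oracles, built in code at test time.

# sinusoid-plus-harmonic trace, the canonical in-band test signal
sine_signal <- function(freq = 1, dt = 0.008, duration = 12, amp = 1,
                        harmonic = 0, units = "cm2", phase = 0) {
  t <- seq(0, duration, by = dt)
  ts_signal(amp * sin(2 * pi * freq * t + phase) +
              harmonic * amp * sin(2 * pi * 2 * freq * t), dt, units)
}

# literal double-loop evaluation of the autocorrelation r-value definition:
# single full-series mean, lag-0 denominator
acf_oracle <- function(y, max_lag) {
  n <- length(y)
  ybar <- mean(y)
  denom <- 0
  for (t in seq_len(n)) denom <- denom + (y[t] - ybar)^2
  r <- numeric(max_lag + 1)
  for (h in 0:max_lag) {
    num <- 0
    for (t in seq_len(n - h)) num <- num + (y[t] - ybar) * (y[t + h] - ybar)
    r[h + 1] <- num / denom
  }
  r
}

# brute-force all-subsets minimum-AIC search via lm(), independent of the
# compiled scan (same AIC definition, independent numerics and enumeration)
aic_bruteforce <- function(features, y, candidates, max_k = length(y) - 2L) {
  n <- length(y)
  best <- list(aic = Inf, sel = NULL)
  for (k in 0:min(length(candidates), max_k)) {
    sets <- if (k == 0) list(character(0))
    else apply(combn(candidates, k), 2, identity, simplify = FALSE)
    for (sel in sets) {
      df <- data.frame(y = y, features[, sel, drop = FALSE], check.names = FALSE)
      fml <- if (k == 0) y ~ 1
      else stats::reformulate(sprintf("`%s`", sel), response = "y")
      rss <- sum(stats::residuals(lm(fml, data = df))^2)
      aic <- n * log(max(rss, 1e-12) / n) + 2 * (k + 1)
      if (aic < best$aic - 1e-10) best <- list(aic = aic, sel = sel)
    }
  }
  best
}

# random feature table for model-fitting tests (generic regression surface)
random_features <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  data.frame(subject_id = sprintf("S%02d", seq_len(n)), X, check.names = FALSE)
}

# feature row with every published-equation input set to a given value
flat_feature_row <- function(value = 0) {
  cols <- c("csa_mean", paste0("lag", c(40, 80, 100, 120, 140, 180,
                                        220, 240, 280, 320)))
  row <- as.data.frame(as.list(setNames(rep(value, length(cols)), cols)))
  row
}
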