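test_that("fit_ols recovers exact linear structure and matches normal equations", {
  ft <- random_features(30, 4, seed = 2)
  # exact linear response, zero noise
  y <- 3 * ft$f1 + 1.5
  m <- fit_ols(ft, y, "f1")
  expect_equal(unname(m$coefficients["f1"]), 3, tolerance = 1e-9)
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(m$mae, 0, tolerance = 1e-9)

  # intercept-only model
  set.seed(5)
  y2 <- rnorm(30, 7)
  m0 <- fit_ols(ft, y2, character(0))
  expect_equal(m0$intercept, mean(y2), tolerance = 1e-12)
  expect_equal(m0$r_squared, 0, tolerance = 1e-12)

  # independent normal-equations oracle
  y3 <- 2 * ft$f1 - ft$f2 + rnorm(30, 0, 0.3)
  m3 <- fit_ols(ft, y3, c("f1", "f2", "f3"))
  Z <- cbind(1, as.matrix(ft[, c("f1", "f2", "f3")]))
  beta <- solve(t(Z) %*% Z, t(Z) %*% y3)
  expect_equal(unname(m3$coefficients[c("(Intercept)", "f1", "f2", "f3")]),
               unname(drop(beta)), tolerance = 1e-8)
  # stored coefficients reproduce stored fitted values
  expect_equal(predict(m3, ft), m3$fitted, tolerance = 1e-9)

  ft$dup <- ft$f1
  expect_error(fit_ols(ft, y3, c("f1", "dup")),
               class = "cvpulse_singular_error")
})

test_that("exhaustive AIC selection matches brute-force enumeration", {
  # signal predictor vs pure-noise decoy
  ft <- random_features(40, 2, seed = 3)
  y <- 3 * ft$f1 + rnorm(40, 0, 0.01)
  m <- select_model(ft, y, c("f1", "f2"))
  expect_identical(m$selected_predictors, "f1")

  # single pure-noise candidate: intercept-only wins at large n
  set.seed(8)
  ftn <- random_features(200, 1, seed = 8)
  yn <- rnorm(200)
  mn <- select_model(ftn, yn, "f1")
  expect_identical(mn$selected_predictors, character(0))

  # full agreement with the lm()-based oracle over all subsets
  for (seed in 1:3) {
    ft2 <- random_features(35, 8, seed = seed + 10)
    set.seed(seed + 50)
    y2 <- 2 * ft2$f2 - 1.2 * ft2$f5 + rnorm(35, 0, 1)
    m2 <- select_model(ft2, y2, paste0("f", 1:8))
    oracle <- aic_bruteforce(ft2, y2, paste0("f", 1:8))
    expect_setequal(m2$selected_predictors, oracle$sel)
    expect_equal(m2$aic, oracle$aic, tolerance = 1e-8)
  }
  expect_error(select_model(ft, y, character(0)), "empty candidate")
})

test_that("greedy selection finds strong predictors when exhaustive is infeasible", {
  ft <- random_features(60, 5, seed = 12)
  set.seed(13)
  y <- 4 * ft$f1 - 3 * ft$f4 + rnorm(60, 0, 0.5)
  m <- select_model(ft, y, paste0("f", 1:5), strategy = "greedy")
  expect_true(all(c("f1", "f4") %in% m$selected_predictors))
})

test_that("in-sample R2 is monotone under nesting of the selected set", {
  ft <- random_features(40, 6, seed = 31)
  set.seed(32)
  y <- ft$f1 - 2 * ft$f3 + rnorm(40, 0, 0.8)
  m <- select_model(ft, y, paste0("f", 1:6))
  sel <- m$selected_predictors
  if (length(sel) > 0) {
    for (drop_i in seq_along(sel)) {
      sub <- fit_ols(ft, y, sel[-drop_i])
      expect_lte(sub$r_squared, m$r_squared + 1e-12)
    }
  }
})

test_that("the published equation reproduces its printed anchor points", {
  # all inputs zero -> the intercept
  expect_equal(predict_published(flat_feature_row(0)), -10.014, tolerance = 1e-12)
  # cohort-mean inputs -> the cohort mean CVP up to coefficient rounding
  pred <- predict_published(published_mean_features())
  expect_lt(abs(pred - 5.998), 0.05)
  # affine form: doubling inputs doubles (prediction - intercept)
  p1 <- predict_published(flat_feature_row(0.1))
  p2 <- predict_published(flat_feature_row(0.2))
  expect_equal(p2 + 10.014, 2 * (p1 + 10.014), tolerance = 1e-9)
  # missing required lag column
  bad <- flat_feature_row(0); bad$lag40 <- NULL
  expect_error(predict_published(bad), "lag40")
  # a model built from the published coefficients agrees with predict_published
  m <- published_cvp_model()
  row <- flat_feature_row(0.3)
  expect_equal(predict(m, row), predict_published(row), tolerance = 1e-12)
})

test_that("predict is the affine combination of selected features", {
  ft <- random_features(25, 3, seed = 41)
  set.seed(42)
  y <- 1 + ft$f1 + rnorm(25, 0, 0.2)
  m <- fit_ols(ft, y, c("f1", "f2"))
  means <- ft[1, ]; means$f1 <- mean(ft$f1); means$f2 <- mean(ft$f2)
  expect_equal(unname(predict(m, means)), mean(y), tolerance = 1e-9)  # OLS identity
  expect_error(predict(m, ft[, "f1", drop = FALSE]), "f2")
})

test_that("fit_metrics matches hand-computed cases", {
  expect_equal(fit_metrics(c(1, 2, 3), c(1, 2, 3)), list(r_squared = 1, mae = 0))
  m <- fit_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$r_squared, 1); expect_equal(m$mae, 1)
  m2 <- fit_metrics(c(1, 2, 3), c(1, 3, 2))
  expect_equal(m2$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m2$r_squared, 0.25, tolerance = 1e-12)
  expect_error(fit_metrics(c(1, 2, 3), c(1, 1, 1)),
               class = "cvpulse_degenerate_error")
})

test_that("cross-validation is seeded, fold-balanced and honest", {
  ft <- random_features(34, 4, seed = 61)
  set.seed(62)
  y <- 2 * ft$f1 + rnorm(34, 0, 0.5)

  cv1 <- cross_validate(ft, y, "f1", k = 10, seed = 7)
  cv2 <- cross_validate(ft, y, "f1", k = 10, seed = 7)
  expect_identical(cv1, cv2)  # bit-reproducible
  expect_identical(sort(unique(cv1$fold_assignments)), 1:10)
  expect_lte(diff(range(table(cv1$fold_assignments))), 1)

  # noiseless linear response: near-perfect out-of-fold prediction
  cvp <- cross_validate(ft, 3 * ft$f2 - 1, "f2", k = 5, seed = 1)
  expect_lt(cvp$mae_cv, 1e-9)
  expect_gt(cvp$r_squared_cv, 1 - 1e-9)

  # leave-one-out pools n predictions
  loo <- cross_validate(ft, y, "f1", k = 34, seed = 3)
  expect_length(loo$predictions, 34)

  # CV error exceeds in-sample error on average over seeds
  in_mae <- fit_ols(ft, y, c("f1", "f2", "f3"))$mae
  cv_maes <- vapply(1:25, function(s)
    cross_validate(ft, y, c("f1", "f2", "f3"), k = 5, seed = s)$mae_cv,
    numeric(1))
  expect_gt(mean(cv_maes), in_mae)

  expect_error(cross_validate(ft, y, "f1", k = 50, seed = 1), "k <= n")
})

test_that("post-hoc power reproduces the printed effect size and conventions", {
  pw <- posthoc_power(0.612, 34, 11)
  expect_equal(round(pw$cohens_f2, 3), 1.577)
  expect_equal(round(pw$power, 2), 0.99)
  expect_equal(posthoc_power(0.5, 34, 11)$cohens_f2, 1)
  null <- posthoc_power(0, 30, 3)
  expect_equal(null$cohens_f2, 0)
  expect_equal(null$power, 0.05, tolerance = 1e-12)
  expect_error(posthoc_power(1, 34, 11),
               class = "cvpulse_infinite_effect_error")
})

test_that("model serialization round-trips predictions", {
  ft <- random_features(25, 3, seed = 71)
  set.seed(72)
  y <- ft$f1 - ft$f3 + rnorm(25, 0, 0.2)
  m <- fit_ols(ft, y, c("f1", "f3"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$coefficients[names(m$coefficients)], m$coefficients)
  expect_equal(predict(back, ft), predict(m, ft), tolerance = 1e-12)
  expect_equal(back$r_squared, m$r_squared, tolerance = 1e-12)
})
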