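# Linear modelling of mean CVP from autocorrelation features: OLS fit,
# exhaustive minimum-AIC subset selection, prediction (refitted or published
# coefficients), k-fold cross-validation, fit metrics and post-hoc power.

# Gaussian linear-model AIC with constants dropped; additive constants cancel
# in subset comparison
.aic_lm <- function(n, rss, k) n * log(rss / n) + 2 * (k + 1)

.feature_matrix <- function(features, predictors) {
  if (inherits(features, "acf_features")) features <- feature_table(list(features))
  stopifnot(is.data.frame(features))
  missing_p <- setdiff(predictors, names(features))
  if (length(missing_p))
    .stop_validation("missing predictors in feature table: ",
                     paste(missing_p, collapse = ", "))
  as.matrix(features[, predictors, drop = FALSE])
}

#' Fit mean CVP on a fixed predictor set by ordinary least squares
#'
#' @param features feature table ([feature_table()] layout) with one row per
#'   subject.
#' @param cvp_means numeric vector of observed mean CVP (cmH2O), one per row.
#' @param predictors character vector of feature-column names (possibly empty
#'   for an intercept-only model), e.g. `c("csa_mean", "lag40")`.
#' @return an object of class `cvp_model`: coefficients (named, plus
#'   `(Intercept)`), `selected_predictors`, `aic`, `r_squared`, `mae`,
#'   `n_subjects`, `fitted`, and the underlying `lm` fit.
#' @export
fit_ols <- function(features, cvp_means, predictors) {
  X <- .feature_matrix(features, predictors)
  y <- as.numeric(cvp_means)
  n <- length(y)
  if (nrow(X) != n) .stop_validation("features rows != length(cvp_means)")
  if (n <= length(predictors) + 1L)
    .stop_validation("need n > predictors + 1 (n = ", n, ", p = ",
                     length(predictors), ")")
  df <- data.frame(.cvp = y, X, check.names = FALSE)
  fml <- if (length(predictors))
    stats::reformulate(sprintf("`%s`", predictors), response = ".cvp")
  else .cvp ~ 1
  fit <- lm(fml, data = df)
  if (length(predictors) && any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop(structure(class = c("cvpulse_singular_error", "error", "condition"),
                   list(message = paste0("singular design; collinear predictors: ",
                                         paste(gsub("`", "", bad), collapse = ", ")),
                        call = sys.call())))
  }
  fitted_y <- unname(fitted(fit))
  rss <- sum((y - fitted_y)^2)
  cf <- coef(fit)
  names(cf) <- gsub("`", "", names(cf))
  structure(list(coefficients = cf,
                 selected_predictors = predictors,
                 intercept = unname(cf["(Intercept)"]),
                 aic = .aic_lm(n, max(rss, 1e-12), length(predictors)),
                 r_squared = if (var(y) > 0) 1 - rss / sum((y - mean(y))^2) else NA_real_,
                 mae = mean(abs(y - fitted_y)),
                 n_subjects = n, fitted = fitted_y, lm_fit = fit),
            class = "cvp_model")
}

#' @export
print.cvp_model <- function(x, ...) {
  cat(sprintf("<cvp_model> %d predictors, n = %s, AIC = %s, r2 = %s, mae = %s cmH2O\n",
              length(x$selected_predictors),
              if (is.na(x$n_subjects)) "?" else x$n_subjects,
              if (is.na(x$aic)) "-" else sprintf("%.2f", x$aic),
              if (is.na(x$r_squared)) "-" else sprintf("%.3f", x$r_squared),
              if (is.na(x$mae)) "-" else sprintf("%.3f", x$mae)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict mean CVP from features with a fitted model
#'
#' `intercept + sum(coefficient * feature)` over the model's selected
#' predictors.
#'
#' @param object a `cvp_model`.
#' @param newdata feature table or single `acf_features`.
#' @param ... unused.
#' @return numeric vector of predicted mean CVP (cmH2O), one per row.
#' @export
predict.cvp_model <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata, object$selected_predictors)
  beta <- object$coefficients[object$selected_predictors]
  drop(object$intercept + if (length(beta)) X %*% beta else 0)
}

#' Select the minimum-AIC predictor subset
#'
#' Scores every admissible subset of the candidate predictors (subset size at
#' most `max_predictors`, default `n - 2`) by
#' `AIC = n*log(RSS/n) + 2*(k+1)` and refits the winner. The exhaustive
#' strategy scans all `2^p` subsets via Cholesky solves on precomputed
#' normal-equation cross-products (compiled kernel; the default 20-candidate
#' set means 1,048,576 subsets, a few seconds of work). The greedy strategy is
#' forward stepwise by AIC, for candidate sets too large to enumerate. Ties
#' break toward fewer predictors, then lexicographically.
#'
#' @param features feature table.
#' @param cvp_means observed mean CVP per row (cmH2O).
#' @param candidate_predictors character vector of candidate columns; default
#'   `csa_mean` plus the lag grid `lag20..lag360` (lag0 is identically 1 and
#'   carries no information).
#' @param strategy `"exhaustive"` (all subsets, <= 20 candidates) or
#'   `"greedy"` (forward stepwise).
#' @param max_predictors admissibility cap on subset size.
#' @return the selected, refitted `cvp_model`.
#' @export
select_model <- function(features, cvp_means,
                         candidate_predictors = c("csa_mean",
                                                  lag_grid_names()[-1L]),
                         strategy = c("exhaustive", "greedy"),
                         max_predictors = NULL) {
  strategy <- match.arg(strategy)
  if (!length(candidate_predictors))
    .stop_validation("empty candidate predictor set")
  X <- .feature_matrix(features, candidate_predictors)
  y <- as.numeric(cvp_means)
  n <- length(y)
  if (nrow(X) != n) .stop_validation("features rows != length(cvp_means)")
  if (is.null(max_predictors)) max_predictors <- n - 2L
  max_predictors <- min(max_predictors, n - 2L)
  p <- length(candidate_predictors)
  if (strategy == "exhaustive") {
    if (p > 20L)
      .stop_validation("exhaustive strategy limited to 20 candidates (got ",
                       p, "); use strategy = \"greedy\"")
    Z <- cbind(1, X)
    res <- exhaustive_aic_cpp(crossprod(Z), drop(crossprod(Z, y)),
                              sum(y * y), n, as.integer(max_predictors))
    sel <- candidate_predictors[res$selected]
  } else {
    sel <- character(0)
    best <- .aic_lm(n, max(sum((y - mean(y))^2), 1e-12), 0L)
    repeat {
      if (length(sel) >= max_predictors) break
      remaining <- setdiff(candidate_predictors, sel)
      if (!length(remaining)) break
      trial <- vapply(remaining, function(cand) {
        fit <- tryCatch(fit_ols(features, y, c(sel, cand)),
                        error = function(e) NULL)
        if (is.null(fit)) Inf else fit$aic
      }, numeric(1))
      if (min(trial) < best - 1e-10) {
        best <- min(trial)
        sel <- c(sel, remaining[which.min(trial)])
      } else break
    }
  }
  fit_ols(features, y, sel)
}

# Published fixed-coefficient model: intercept and slopes of the refined
# regression reported for the original 34-subject clinical cohort.
.PUBLISHED_COEF <- c(
  `(Intercept)` = -10.014,
  csa_mean = 2.836,
  lag40 = -32.469, lag80 = -22.015, lag100 = -7.590, lag120 = -18.417,
  lag140 = -14.016, lag180 = -23.054, lag220 = -11.470, lag240 = -5.513,
  lag280 = -8.478, lag320 = -7.059)

#' The published fixed-coefficient CVP model
#'
#' The refined minimum-AIC regression reported for the original 34-subject
#' clinical cohort: mean CVP (cmH2O) as a fixed linear combination of the mean
#' IJV-CSA and the CSA autocorrelation r-values at lags 40, 80, 100, 120, 140,
#' 180, 220, 240, 280 and 320 samples, with intercept -10.014. Its in-sample
#' performance on that cohort was r2 = 0.612 (mae 1.455 cmH2O), falling to
#' r2 = 0.498 (mae 2.436 cmH2O) under 10-fold cross-validation.
#'
#' @return a `cvp_model` with fixed coefficients (no fit statistics).
#' @export
published_cvp_model <- function() {
  structure(list(coefficients = .PUBLISHED_COEF,
                 selected_predictors = names(.PUBLISHED_COEF)[-1L],
                 intercept = unname(.PUBLISHED_COEF[1L]),
                 aic = NA_real_, r_squared = NA_real_, mae = NA_real_,
                 n_subjects = NA_integer_, fitted = NULL, lm_fit = NULL),
            class = "cvp_model")
}

#' Predict mean CVP with the published coefficients
#'
#' Evaluates the published fixed-coefficient equation (see
#' [published_cvp_model()]) on one or more feature vectors. With all features
#' zero the prediction is the intercept, -10.014 cmH2O.
#'
#' @param features feature table or `acf_features` containing `csa_mean` and
#'   the r-values at lags 40, 80, 100, 120, 140, 180, 220, 240, 280, 320.
#' @return numeric vector of predicted mean CVP (cmH2O).
#' @export
predict_published <- function(features)
  predict(published_cvp_model(), features)

#' In-sample fit metrics
#'
#' `r_squared` is the squared Pearson correlation of observed vs predicted;
#' `mae` the mean absolute error in cmH2O.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return named list `r_squared`, `mae`.
#' @export
fit_metrics <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted) || length(observed) < 2L)
    .stop_validation("observed and predicted must be equal length >= 2")
  if (var(observed) == 0 || var(predicted) == 0)
    stop(structure(class = c("cvpulse_degenerate_error", "error", "condition"),
                   list(message = "zero variance in observed or predicted values",
                        call = sys.call())))
  list(r_squared = stats::cor(observed, predicted)^2,
       mae = mean(abs(observed - predicted)))
}

#' k-fold cross-validation of a CVP model
#'
#' Subjects are shuffled with the given seed and dealt round-robin into `k`
#' folds (sizes differing by at most one). For each fold the model
#' coefficients are refitted on the remaining folds with the FIXED predictor
#' set and the held-out subjects predicted; metrics are pooled over all
#' out-of-fold predictions. With `reselect = TRUE` the subset selection itself
#' is re-run inside each training fold (a stricter protocol), and the selected
#' sets are reported per fold.
#'
#' @param features feature table.
#' @param cvp_means observed mean CVP (cmH2O).
#' @param predictors fixed predictor set to refit per fold.
#' @param k number of folds (default 10); `k = n` gives leave-one-out.
#' @param seed integer seed controlling the fold shuffle (bit-reproducible).
#' @param reselect re-run [select_model()] inside each fold.
#' @param ... passed to [select_model()] when `reselect = TRUE`.
#' @return an object of class `crossval_report`: `k`, `r_squared_cv`,
#'   `mae_cv`, `fold_assignments`, `predictions`, `seed` (and `fold_selected`
#'   when reselecting).
#' @export
cross_validate <- function(features, cvp_means, predictors, k = 10L,
                           seed = 1L, reselect = FALSE, ...) {
  y <- as.numeric(cvp_means)
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L || k > n) .stop_validation("need 2 <= k <= n (k = ", k,
                                        ", n = ", n, ")")
  if (inherits(features, "acf_features")) features <- feature_table(list(features))
  perm <- local({
    rng <- .lecuyer_rng(seed)
    order(rng(n))
  })
  folds <- integer(n)
  folds[perm] <- rep_len(seq_len(k), n)
  preds <- numeric(n)
  fold_selected <- vector("list", k)
  for (fold in seq_len(k)) {
    test <- which(folds == fold)
    train <- which(folds != fold)
    sel <- predictors
    if (reselect) {
      m <- select_model(features[train, , drop = FALSE], y[train], ...)
      sel <- m$selected_predictors
      fold_selected[[fold]] <- sel
      fit <- m
    } else {
      fit <- fit_ols(features[train, , drop = FALSE], y[train], sel)
    }
    preds[test] <- predict(fit, features[test, , drop = FALSE])
  }
  metrics <- fit_metrics(y, preds)
  structure(list(k = k, r_squared_cv = metrics$r_squared,
                 mae_cv = metrics$mae, fold_assignments = folds,
                 predictions = preds, seed = as.integer(seed),
                 fold_selected = if (reselect) fold_selected else NULL),
            class = "crossval_report")
}

# small deterministic RNG independent of R's global stream so that CV fold
# assignment never perturbs (or is perturbed by) user code using set.seed()
.lecuyer_rng <- function(seed) {
  s <- as.double((as.integer(seed) %% 2147483562L) + 1L)
  s2 <- as.double(((as.integer(seed) %/% 3L) %% 2147483398L) + 1L)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      s <<- (s * 40014) %% 2147483563
      s2 <<- (s2 * 40692) %% 2147483399
      z <- (s - s2) %% 2147483562
      out[i] <- (z + 1) / 2147483563
    }
    out
  }
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %d-fold (seed %d): r2_cv = %.3f, mae_cv = %.3f cmH2O\n",
              x$k, x$seed, x$r_squared_cv, x$mae_cv))
  invisible(x)
}

#' Post-hoc power of a multiple regression
#'
#' Cohen's effect size `f2 = r2 / (1 - r2)`; achieved power from the
#' noncentral F distribution with `df1 = n_predictors`,
#' `df2 = n - n_predictors - 1` and noncentrality `lambda = f2 * n` (the
#' dominant convention for post-hoc multiple-regression power; conventions
#' using `f2 * (df1 + df2 + 1)` coincide with it here since
#' `df1 + df2 + 1 = n`).
#'
#' @param r_squared in-sample r2 of the model, in \[0, 1).
#' @param n number of subjects.
#' @param n_predictors number of slope coefficients.
#' @param alpha test size (default 0.05).
#' @return an object of class `power_report`: `cohens_f2`, `alpha`, `power`,
#'   `n`, `n_predictors`.
#' @export
posthoc_power <- function(r_squared, n, n_predictors, alpha = 0.05) {
  if (!is.finite(r_squared) || r_squared < 0 || r_squared > 1)
    .stop_validation("r_squared must be in [0, 1]")
  if (r_squared == 1)
    stop(structure(class = c("cvpulse_infinite_effect_error", "error", "condition"),
                   list(message = "r_squared = 1: infinite effect size",
                        call = sys.call())))
  n <- as.integer(n); n_predictors <- as.integer(n_predictors)
  if (n <= n_predictors + 1L) .stop_validation("need n > n_predictors + 1")
  f2 <- r_squared / (1 - r_squared)
  df1 <- n_predictors
  df2 <- n - n_predictors - 1L
  power <- pf(qf(1 - alpha, df1, df2), df1, df2, ncp = f2 * n,
              lower.tail = FALSE)
  structure(list(cohens_f2 = f2, alpha = alpha, power = power,
                 n = n, n_predictors = n_predictors),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("<power_report> f2 = %.3f, power = %.3f (alpha = %g, n = %d, p = %d)\n",
              x$cohens_f2, x$power, x$alpha, x$n, x$n_predictors))
  invisible(x)
}

#' Serialize a CVP model as flat key-value text
#'
#' One `key<TAB>value` pair per line: each coefficient by predictor name,
#' plus `(Intercept)`, `aic`, `r_squared`, `mae`, `n_subjects`. Read back with
#' [read_model()].
#'
#' @param model a `cvp_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cvp_model"))
  kv <- c(model$coefficients,
          aic = model$aic, r_squared = model$r_squared, mae = model$mae,
          n_subjects = as.numeric(model$n_subjects))
  writeLines(sprintf("%s\t%.17g", names(kv), unname(kv)), path)
  invisible(path)
}

#' Read a CVP model from flat key-value text
#'
#' @param path file written by [write_model()].
#' @return a `cvp_model` (prediction-capable; no `lm` fit attached).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) .stop_format("file not found: ", path)
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  if (any(lengths(lines) != 2L)) .stop_format("malformed model file: ", path)
  vals <- vapply(lines, function(x) as.numeric(x[2L]), numeric(1))
  names(vals) <- vapply(lines, `[[`, character(1), 1L)
  meta <- c("aic", "r_squared", "mae", "n_subjects")
  cf <- vals[setdiff(names(vals), meta)]
  if (!"(Intercept)" %in% names(cf)) .stop_format("model file lacks (Intercept)")
  structure(list(coefficients = cf,
                 selected_predictors = setdiff(names(cf), "(Intercept)"),
                 intercept = unname(cf["(Intercept)"]),
                 aic = unname(vals["aic"]), r_squared = unname(vals["r_squared"]),
                 mae = unname(vals["mae"]),
                 n_subjects = as.integer(vals["n_subjects"]),
                 fitted = NULL, lm_fit = NULL),
            class = "cvp_model")
}
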