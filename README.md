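# cvpulse

Non-invasive estimation of mean central venous pressure (CVP) from the
jugular venous pulse.

## The problem

CVP — the pressure in the right atrium at end-diastole — guides fluid
management in intensive care, but measuring it requires a central venous
catheter, an invasive procedure with real complication risk. The internal
jugular vein (IJV) is a thin-walled, floppy vessel whose cross-sectional
area (CSA) pulses with right-atrial pressure, and that pulsation is easy to
record non-invasively with B-mode ultrasound. The catch is that the IJV-CSA
trace is a poor *time-domain* surrogate for the CVP trace: it lags the
pressure wave by a subject-specific fraction of a second and is contaminated
by respiration, so the two traces correlate poorly even when they share the
same cardiac rhythm.

`cvpulse` implements the autocorrelation work-around. The autocorrelation
function of a trace,

    r_h = sum_t (y_t - ybar)(y_{t+h} - ybar) / sum_t (y_t - ybar)^2 ,

depends only on the trace's spectral content, not its phase — so a pure time
delay between CVP and CSA leaves their autocorrelograms aligned even while
it destroys their Pearson correlation. The package therefore predicts mean
CVP (cmH2O) by linear regression on the CSA autocorrelation r-values at lags
0, 20, ..., 360 samples plus the mean CSA (cm2), with the predictor subset
chosen by exhaustive minimum-AIC search over all 2^20 combinations
(`AIC = n log(RSS/n) + 2(k+1)`), validated by seeded k-fold cross-validation,
and the prediction classified into low / normal / high CVP against the
2.72–10.88 cmH2O (2–8 mmHg) normal range.

The package covers the full pipeline for anyone reproducing or extending
this methodology: columnar signal I/O, zero-phase band-pass removal of
thoracic-pump (respiratory) content, ECG-anchored synchronization of paired
traces, feature extraction (autocorrelation, cross-correlation lag,
periodogram peaks, autocorrelogram periodicity `f = 1/(D dt)`), model
selection and cross-validation, prediction with refitted or published
fixed coefficients, classification with sensitivity/accuracy/Cohen's kappa,
and a seeded synthetic-cohort waveform generator with known ground truth.

## Worked example

Simulate a 34-subject cohort whose mean CVP is a known sparse linear
function of its waveform features (plus 0.5 cmH2O noise), then let the
pipeline find that structure back:

```r
library(cvpulse)

truth <- list(intercept = 6,
              coefficients = c(csa_mean = 2.8, lag40 = -10, lag180 = -8),
              noise_sd = 0.5)
co <- generate_cohort(cohort_spec(n_subjects = 34, seed = 42,
                                  ground_truth_model = truth))
ft <- feature_table(lapply(co$records, extract_features))
y  <- co$ground_truth$cvp_mean

model <- select_model(ft, y)           # exhaustive min-AIC over 2^20 subsets
model
#> <cvp_model> 3 predictors, n = 34, AIC = -38.75, r2 = 0.993, mae = 0.387 cmH2O
#> (Intercept)    csa_mean       lag40      lag180
#>      5.9984      2.9123     -9.7826     -8.0602

cross_validate(ft, y, model$selected_predictors, k = 10, seed = 1)
#> <crossval_report> 10-fold (seed 1): r2_cv = 0.992, mae_cv = 0.427 cmH2O

confusion_report(classify_cvp(y), classify_cvp(predict(model, ft)))
#> <confusion_report> true class (rows) x predicted class (cols)
#>         predicted
#> true     low normal high
#>   low      3      0    0
#>   normal   0     11    0
#>   high     0      0   20
#> sensitivity: low 100.0%, normal 100.0%, high 100.0%
#> accuracy: 100.0%  kappa: 1.000  (n = 34)
```

The selector recovers exactly the generating predictors (`csa_mean`,
`lag40`, `lag180`) with coefficients within a few percent of truth; the
out-of-fold error (0.43 cmH2O) sits just above the injected noise floor
(0.5 cmH2O would be the irreducible SD), and every subject lands in its
true clinical class. On cohorts with *no* built-in feature-to-CVP link the
same pipeline honestly reports near-zero cross-validated r² — see the
vignette for what the generator does and does not emulate.

To apply the fixed coefficients published for the original 34-patient
clinical cohort to your own feature table instead of refitting:

```r
predict_published(ft)            # mean CVP in cmH2O, one value per subject
published_cvp_model()            # the equation itself (intercept -10.014)
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "cvpulse.R", package = "cvpulse")` with subcommands
`simulate`, `features`, `fit` and `predict`.

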