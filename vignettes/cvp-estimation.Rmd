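---
title: "Estimating central venous pressure from the jugular venous pulse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating central venous pressure from the jugular venous pulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvpulse)
```

## The model

`cvpulse` estimates a subject's *mean* central venous pressure (CVP, cmH2O)
from the internal jugular vein cross-sectional area (IJV-CSA, cm2) pulse
recorded by transverse B-mode ultrasound over 10–15 s. The underlying
observation is spectral: the CVP and IJV-CSA pulses are driven by the same
cardiac source, so they share frequency content even though a subject-specific
transmission delay (on the order of 0.2 s) and respiratory modulation make
their time-domain correlation unreliable. The autocorrelation function

$$ r_h = \frac{\sum_t (y_t - \bar y)(y_{t+h} - \bar y)}
              {\sum_t (y_t - \bar y)^2} $$

is phase-blind — by the Wiener–Khinchin relation it is the Fourier transform
of the power spectrum — so a pure delay leaves it unchanged, and its r-values
at fixed lags summarize the waveform's spectral shape in a handful of
numbers. The estimator is then ordinary least squares:

$$ \widehat{\mathrm{CVP}} = \beta_0 + \beta_c \cdot \overline{\mathrm{CSA}}
   + \sum_{h \in H} \beta_h \, r_h , $$

with the lag set $H$ chosen from the grid $\{20, 40, \ldots, 360\}$ samples
(plus the mean-CSA term) by exhaustively scoring **all** subsets with
$\mathrm{AIC} = n \log(\mathrm{RSS}/n) + 2(k+1)$ and keeping the minimum.
The mean-CSA predictor matters because $r_h$ is scale-free: the
autocorrelation encodes waveform *shape*, and mean CSA restores the
*level* information that the normalization removes.

Assumptions worth stating explicitly:

* the traces are uniformly sampled and long enough to cover several cardiac
  and two or three respiratory cycles (length must exceed the 360-sample
  maximum lag);
* the relationship between the lag r-values and mean CVP is approximately
  linear across subjects — plausible only because the cohort's CSA
  autocorrelograms are dominated by a common near-1 Hz cardiac fundamental;
* subjects are in sinus rhythm; arrhythmia or severe tricuspid pathology
  would break the periodic-waveform premise.

## Pipeline stages and their parameters

**Preprocessing.** `remove_noncardiac()` applies a zero-phase Butterworth
band-pass, by default 0.5–10 Hz, order 4 per stage (high-pass and low-pass
cascaded, run forward and backward). 0.5 Hz separates supine respiration
(≲ 0.4 Hz, the thoracic-pump contribution to CSA) from the cardiac
fundamental (~1 Hz); 10 Hz removes measurement noise while keeping every
harmonic that shapes the venous waveform. Zero-phase filtering is essential
because the downstream statistic of interest *is* a lag. Edges are
odd-reflect padded by at least one full period of the low cutoff before
filtering: on a 10–15 s trace, a high-pass transient that is not flushed
would leak into a third of the record, and the naive "a few filter orders"
padding is far too short at these cutoffs. The filter re-adds the trace
mean after band-passing, since mean CSA is itself a model predictor and
must survive preprocessing. `synchronize()` aligns paired traces on the
first common ECG R-peak (local maxima above mean + 2 SD with a 0.3 s
refractory window — the ECG is used only as a time anchor, so a full QRS
detector would be over-engineering); `conform_lengths()` truncates both
traces to the common leading window. `resample_signal()` is linear
interpolation — the traces are heavily oversampled relative to the cardiac
band, and linear interpolation cannot ring.

**Features.** `autocorrelation()` follows the r-value definition literally:
one full-series mean, lag-0 denominator (the `stats::acf` convention; tests
verify equality with both a literal double-loop evaluation at 1e-12 and
`stats::acf` itself). The lag grid is counted in **samples, not seconds**,
even though the sampling interval varies by a factor of five across
subjects (0.003–0.016 s): that is how the features were defined on the
original cohort, each subject analysed on its own grid. The pipeline
exposes `resample$dt` in the configuration for users who prefer a common
grid, but the default mirrors the original per-subject convention.
`cross_correlation_lag()` maximizes the signed correlation (not |r|) over
lags up to a quarter of the trace length, with the `ccf(x, y)` sign
convention chosen so that a CSA trace delayed behind the CVP yields a
*negative* incremental lag, matching the published per-subject summary.
`freq_from_autocorr()` implements $f = 1/(D\,dt)$ with $D$ the mean spacing
of positive autocorrelogram peaks of prominence at least 0.05 — the
prominence floor exists because measurement noise decorates the
autocorrelogram with sub-0.05 ripples that are not periodicity.
`periodogram_topk()` is the plain mean-removed FFT amplitude spectrum
(no taper), peaks being 3-bin local maxima.

**Model selection.** The exhaustive scan solves each subset's normal
equations by Cholesky factorization of the relevant submatrix of the
precomputed cross-product matrix, in compiled code: the full
$2^{20}$-subset scan over 20 candidates costs well under a second, so
"all possible combinations" is taken at face value rather than
approximated. Subsets larger than $n-2$ are inadmissible (they would leave
fewer than one residual degree of freedom); near-singular subsets are
skipped rather than scored on a numerically meaningless RSS (pivot
tolerance 1e-12 relative); exact AIC ties (within 1e-10) break toward
fewer predictors, then lexicographically, making selection deterministic.
A greedy forward search is provided for candidate sets beyond 20. The AIC
constant terms are dropped; they cancel in subset comparison.

**Validation and inference.** `cross_validate()` shuffles subjects with a
dedicated seeded generator (independent of R's global RNG stream, so fold
assignment neither perturbs nor is perturbed by user code), deals them
round-robin into k folds (sizes differ by at most one), refits the
*coefficients* per fold while keeping the selected predictor *set* fixed —
validating "the refined model" — and pools out-of-fold predictions;
`reselect = TRUE` re-runs selection inside each training fold for the
stricter protocol. CV r² is the squared correlation of pooled out-of-fold
predictions with observations. `posthoc_power()` uses Cohen's
$f^2 = r^2/(1-r^2)$ and the noncentral F distribution with noncentrality
$\lambda = f^2 n$; power conventions differ in whether $\lambda$ uses $n$
or $df_1 + df_2 + 1$, but the two coincide for a model with intercept, and
this convention reproduces the published power value (0.993 from
$r^2 = 0.612$, $n = 34$, 11 predictors) — treat the power number as
approximate across software.

**Classification.** The normal CVP range is 2–8 mmHg; with the fixed
conversion 1 mmHg = 1.35951 cmH2O (chosen because it reproduces the
published 2.72–10.88 cmH2O bounds at two decimals; 1.36 would too, and the
difference is far below clinical resolution) the bounds are closed:
values exactly at 2.72 or 10.88 cmH2O classify as normal, an explicit
decision where the verbal "within the normal range" is ambiguous. Cohen's
kappa is unweighted over the three classes. A class with no true members
reports sensitivity as not-applicable by default, with
`zero_division = "zero"` available to replicate the convention of
reporting 0% for an empty class.

## The synthetic cohort: what it does and does not emulate

`generate_subject()` builds each trace as mean + cardiac series + noise:
the CVP pulse is a fundamental near 0.95 Hz plus a strong 2× harmonic; the
CSA pulse is the same shape with a much weaker 2× harmonic, delayed by an
integer sample shift of `round(lag_s/dt)` (edge-trimmed so both traces stay
equal length), plus additive respiratory modulation on the CSA only — the
thoracic pump acts on the vein, not on the right atrium in this
approximation. The ECG is a narrow Gaussian impulse train phase-locked to
the CVP cardiac component. Cohort-level draws reproduce the clinical
cohort's reported statistics: mean CVP ~ N(5.998, 2.874) cmH2O, mean CSA ~
N(0.984, 0.497) cm2 (truncated positive), lag ~ N(0.241, 0.175) s truncated
at zero, per-subject dt uniform on [0.003, 0.016] s and duration on
[10, 15] s — dt deliberately varies so that the samples-versus-seconds lag
grid question is exercised, not hidden.

Per-subject waveform-shape parameters (harmonic ratios, a small third
harmonic, respiratory rate and amplitude, and a beat-to-beat
amplitude-modulation depth emulating stroke-volume variability) are drawn
from ranges rather than fixed. This is not cosmetic: if every subject
shares the same harmonic structure, every lag feature collapses onto a
smooth function of the single latent quantity (cardiac frequency × dt),
the cohort feature matrix is effectively rank-one, and *no* selector can
tell `lag40` apart from a combination of `lag20` and `lag60`. A generator
intended to support ground-truth recovery tests must produce an
identifiable design, and real cohorts supply that identifiability through
exactly this kind of morphological heterogeneity.

What the generator does **not** emulate: the physiological a/c/v triple-peak
morphology is off by default (a Gaussian-bump template is available via
`waveform = "acv"` but the harmonic series is sufficient for every
computation in scope); there is no nonstationarity beyond slow amplitude
modulation, no motion artifact, no arrhythmia, no measurement dropout, and
— most importantly — no *physiological* coupling between waveform features
and mean CVP. A cohort generated without `ground_truth_model` has mean CVP
drawn independently of the CSA features, so a pipeline run on it should
(and does) report near-zero cross-validated r²; passing recovery tests on
`ground_truth_model` cohorts demonstrates that the *machinery* finds linear
structure when it exists, not that such structure exists in patients.

## Numerical choices and degenerate inputs

* Constant (zero-variance) traces raise degenerate-signal errors in
  autocorrelation, correlation and periodogram code rather than returning
  NaN.
* Signal files are written at 17 significant digits so the text round trip
  is bit-exact; time-column uniformity is enforced to 1% of dt on read.
* An RSS below 1e-12 (exact interpolation) is floored before the log in the
  AIC so that noiseless test cohorts select the smallest exact subset via
  the tie-break rather than comparing logs of rounding error.
* Published-equation prediction is a fixed affine map; with every input
  zero it returns exactly the intercept, −10.014 cmH2O, which doubles as a
  machine-checkable anchor for the coefficient table.
* The published per-subject summary prints dt to three decimals, so its
  lag-time column is reproducible from its own lag and dt columns only to
  ±0.001 s × |lag|; tests assert consistency at that granularity, not
  beyond it.

## Open decisions taken

* The text accompanying the published prediction equation refers to lags
  "20–340", while the equation itself and its coefficient table list lags
  40–320; the implementation follows the equation and table.
* Whether the original analysis filtered the traces before computing
  correlations is not documented; the pipeline default applies the same
  band-pass to both traces, with `filter$enabled = FALSE` to disable.
* Whether the published in-sample errors are in-sample on all 34 subjects
  is implied but not explicit; the optional raw-data validation script
  treats them as in-sample.

## Problem sizes used by the test-suite

The suite's heavier checks use 50 cohorts of n = 100 subjects for selection
recovery (noise SD 0.5 cmH2O), one cohort of n = 200 at noise SD 0.1 for
coefficient-bias bounds, 100 random signals against the double-loop
autocorrelation oracle, a 12-candidate (4096-subset) `lm()` enumeration as
the selection oracle, and one full 2^20-subset scan on a 34-subject cohort.
These sizes were chosen to make the statistical assertions stable across
seeds while keeping a complete run in the low minutes on one core.

## Limitations

The package reproduces and exercises a proof-of-concept methodology built
on 34 subjects without heart failure, arrhythmia or valvular disease; the
published coefficients should be treated as cohort-specific until refitted
on larger and broader samples. Ultrasound video segmentation (producing the
CSA trace from B-mode clips) is upstream of this package and out of scope:
the pipeline starts at columnar time series.
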