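---
title: "Separating and decoding aperiodic and oscillatory M/EEG activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating and decoding aperiodic and oscillatory M/EEG activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irasadecode)
```

## The analysis problem

Electrophysiological power spectra mix two qualitatively different kinds
of activity: a broadband *aperiodic* (1/f-like, "fractal") component,
summarized by its log-log slope (the negated spectral exponent $\chi$),
its intercept (offset), and its broadband power; and band-limited
*oscillatory* activity riding on top of it (theta, alpha, beta). Because
conventional band power confounds the two, any claim that a cognitive
variable is coded by "alpha power" or by "broadband shifts" requires
separating them first.

This package implements that separation with irregular-resampling
auto-spectral analysis (IRASA) and builds a complete multivariate
decoding pipeline on the six resulting per-trial signals (`bb_power`,
`slope`, `intercept`, `theta`, `alpha`, `beta`): pseudo-trial averaging,
PCA plus linear support-vector classification under repeated
cross-validation, cross-task generalization matrices, Haufe projection
of classifier weights to interpretable activation patterns, permutation
tests on within-subject spatial pattern correlations, and
Procrustes-aligned condition geometry. A synthetic-data generator with
fully known ground truth makes every stage testable without access to
recorded data.

## IRASA: how the separation works

For a segment $x(t)$ of duration $T$ the mixed spectrum is a single
Hann-tapered periodogram. For each resampling factor $h$ in the set
$\{1.10, 1.15, \dots, 1.90\}$ the segment is Fourier-resampled by $h$
and by $1/h$, and both branch spectra are computed *at the nominal
sampling rate*: resampling therefore acts as a time
stretch/compression. A narrow-band oscillation at $f_0$ moves to
$f_0/h$ in one branch and $f_0 h$ in the other, while the self-similar
$1/f^\chi$ background keeps its shape — its branch scale factors
$h^{1-\chi}$ and $h^{\chi-1}$ cancel exactly in the geometric mean
$\sqrt{P_h(f)\,P_{1/h}(f)}$. The aperiodic spectrum is the median of
these geometric means across the $h$ set; the oscillatory spectrum is
the mixed spectrum minus the aperiodic one (signed — truncating
negative values would bias downstream decoding).

The compressed branch has an effective Nyquist frequency of
$f_s/(2h_{max})$; with `fs = 200` Hz and $h_{max} = 1.9$ this is
`r round(frequency_bound(200, 1.9), 2)` Hz, so a 1–30 Hz analysis grid
is comfortably estimable. Configuration validation rejects grids above
the bound.

### Estimator conventions

Several conventions are forced by the short (1.2 s) single-trial
window and are fixed here explicitly:

* **PSD estimator.** One Hann-tapered modified periodogram per
  segment. The native resolution of a 1.2 s window is 0.83 Hz while
  the analysis grid is the integer 1–30 Hz, so every spectrum is
  linearly interpolated onto the grid; all IRASA branches share the
  native axis $k/T$ because resampling leaves the duration unchanged.
  Grid frequencies that fall below the first spectral bin of the
  coarsest compressed branch (possible at 1–2 Hz) take that bin's
  value; this affects only displayed values below 3 Hz, outside every
  band and outside the aperiodic fit range.
* **Aggregation across $h$.** Median (the original method's choice,
  robust to residual oscillatory peaks); switchable to the mean via
  `irasa_config(h_agg = "mean")`.
* **Aperiodic fit.** Ordinary least squares of $\log_{10} P$ on
  $\log_{10} f$ over 3–30 Hz, matching the broadband-power range, with
  the intercept defined at 1 Hz ($\log f = 0$). Per-trial spectra are
  fitted per trial; IRASA is computed per epoch because decoding needs
  single-trial features (averaging raw series first would cancel the
  non-phase-locked oscillations of interest).
* **Bands.** Theta 3–7, alpha 8–12, beta 15–30 Hz; the 13–14 Hz gap
  between alpha and beta is intentional and preserved.

### Known estimator limitations

Two properties of single-periodogram IRASA at a 1.2 s window are worth
stating because the test suite measures them:

* **Multiplicative bias.** Each branch periodogram value is
  $\chi^2_2$-distributed around its expectation; the geometric mean of
  two such values followed by a median across $h$ sits roughly 25%
  below the true aperiodic level. The bias is multiplicative and
  frequency-flat over the fit range, so slopes are unaffected (recovery
  across $\chi \in \{0.5, 1, 1.5, 2\}$ is accurate to better than
  0.1), and the oscillatory spectrum inherits a small positive offset
  (about 13% of the aperiodic level on white noise). Standardization
  removes both effects from the decoding features.
* **Oscillation leakage.** A strong oscillation contaminates the
  aperiodic estimate near $f_0/h$ and $f_0 h$: the Hann main lobe
  half-width of a 1.2 s window is $2/T \approx 1.7$ Hz, comparable to
  the shifts $f_0(1 - 1/h) \le 4.7$ Hz, so at some frequencies more
  than half of the $h$ branches are contaminated and the median no
  longer rejects the peak. At the generator's default oscillation
  (unit amplitude on a unit-variance $\chi = 1.5$ background — a
  ~30-fold peak-to-background ratio at 10 Hz, the strong end of
  realistic alpha) this shifts the fitted slope by about 0.10; weaker,
  more typical oscillations shift it proportionally less. This is a
  property of the published method at short windows, not of this
  implementation, and is left visible in the acceptance suite rather
  than patched by deviating from the canonical median-of-geometric-mean
  combination.

## Preprocessing

The pipeline consumes epoched data after upstream artifact processing.
Three steps are provided: peak-to-peak epoch rejection with
kind-specific thresholds (defaults 350 µV EEG, 5000 fT magnetometer,
4000 fT/cm gradiometer), evoked-potential subtraction, and windowing to
the 0.3–1.5 s analysis interval (half-open on the sample grid, so
exactly 240 samples at 200 Hz). Evoked subtraction removes the
cell-mean time series within each finest labelled cell
(subject × task × content × demand); a coarser grouping would leave
condition-mean differences behind as phase-locked artifacts. Induced
(random-phase) oscillations survive the subtraction by construction;
the simulator's ground truth verifies >99% transient-energy removal
with single-trial alpha power preserved within a few percent (the
subtraction removes exactly $1/n$ of induced power for $n$ trials per
cell).

## Decoding

For each subject, subtask and signal, a binary contrast (hard vs easy,
or colour vs alphanumeric) is decoded from the channels-by-trials
feature matrix:

1. **Pseudo-trials.** Random groups of 4 trials per class are
   averaged; remainder trials are dropped and class counts equalized by
   removing surplus pseudo-trials from the larger class. Averaging
   trades trial count for signal-to-noise.
2. **Standardization.** Per-feature mean/SD from the training portion
   only; this is what makes mixed channel kinds (V, T, T/m — nine
   orders of magnitude apart) commensurable.
3. **PCA.** Fitted on the training folds; the smallest number of
   leading components reaching 99% cumulative variance is retained and
   the test fold is projected onto the same basis.
4. **Classifier.** Linear SVM with cost 1 (the conventional default;
   results are insensitive in the explored range). Performance is the
   AUC of the continuous decision values.
5. **Repetition.** Stratified 5-fold cross-validation, with the entire
   procedure — including a fresh pseudo-trial draw — repeated (25 times
   by default) and averaged, so results do not depend on one particular
   set of trial averages.

Cross-task generalization trains on all pseudo-trials of one subtask
(no fold split) and tests on another; standardization and PCA use
training-subtask statistics only, which prevents test-set leakage where
the convention is ambiguous. The two directions of each pair are
averaged, giving a symmetric subtask × subtask matrix whose diagonal
holds within-subtask cross-validated AUC.

All randomness descends from one master seed through a documented
integer-mixing scheme (`derive_seed`), so every run is bit-reproducible.

## Activation patterns

Linear classifier weights are extraction filters and cannot be read as
per-feature signal strength. The Haufe transform multiplies the
(back-projected) weight vector by the feature covariance — estimated
from the standardized pseudo-trials the classifier was fitted on —
yielding a pattern proportional to the univariate class contrast for a
linear model. Patterns are normalized to unit norm (they are defined
only up to positive scale), z-scored across features, and averaged
across subjects and subtasks. Positive values mean more signal in the
hard (or colour) class; with the simulator's default demand effect (a
broadband power *decrease* under high demand) the broadband pattern is
negative at modulated channels, and its correlation with the known
modulation map exceeds 0.8 at the default effect size.

Display thresholding keeps features whose |value| ranks at or above a
percentile (default 60th) of all |values|; ranking magnitudes rather
than signed values retains both increases and decreases, which is what
the signed display requires. Ties at the cutoff are all kept.

## Inference

Group-level decoding is tested with one-sample t tests against
chance (0.5), one-tailed because below-chance decoding is
uninterpretable, with Benjamini–Hochberg FDR correction across each
analysis family. Spatial-pattern similarity is tested by permutation:
the observed statistic is the mean over participants of the Pearson
correlation between two patterns; each of K = 1000 permutations
shuffles the feature order of one pattern independently within each
participant; the p value uses the add-one estimator
$(1 + \#\{|r_{null}| \ge |r_{obs}|\})/(K+1)$, which never returns zero.
The test is two-tailed on the magnitude because correlations of both
signs are interpretable; calibration simulations confirm uniform null
p values.

## Condition geometry

Trials are averaged within each of the 12 design cells
(3 tasks × 2 contents × 2 demands), embedded per task in the first two
principal components, aligned across tasks by Procrustes rotation
*without scaling* (vegan's implementation; the full orthogonal group
including reflections, since nothing in the problem fixes chirality),
averaged, and then aligned again across participants with the first
participant (sorted ID) as the deterministic reference. PCA is fitted
per task before alignment; rigid alignment preserves all
within-embedding distances to numerical precision.

## The synthetic-data generator

`gen_epoch_set()` emulates the essential generative structure of a
task-based M/EEG study: per-subject aperiodic exponents
($\chi \sim N(1.5, 0.2)$, the typical cognitive-task range), power-law
backgrounds synthesized by FFT-domain spectral shaping of white noise
(exact target spectrum in expectation, $O(n \log n)$), random-phase
oscillations with per-trial frequency jitter (induced activity), an
optional phase-locked raised-cosine transient (evoked activity), white
sensor noise, and multiplicative condition effects applied through
per-channel maps in $[0,1]$ (factor $g$ at map weight $m$ scales
amplitude by $g^m$, hence power by $g^{2m}$). Channel kinds carry
distinct nominal scales (V, T, T/m) so that standardization is
exercised, and every applied factor is recorded in a ground-truth
object used as the recovery oracle.

Defaults were chosen once as plausible study conditions: a demand
factor of 0.8 (20% amplitude, 36% power reduction under high demand,
in the direction of demand-related broadband decreases), a demand slope
shift of +0.1, a content factor of 0.9 on a complementary channel map,
one 10 Hz oscillation of unit amplitude with 2 Hz jitter and a 0.8
demand factor, and 64 channels rather than a full 370-sensor array
(decoding behaviour is dimension-generic; the count is configurable).
Real-study effect sizes are unknown in physical units, so these are
free parameters of the simulation, not calibrations to any data set.

What the generator does *not* emulate — and what passing tests
therefore cannot show about recorded data: volume conduction and
realistic sensor covariance (channel maps are abstract mixing weights,
not lead fields), non-stationarity within epochs, artifacts, knees or
bends in the aperiodic spectrum, correlated trial-to-trial state
fluctuations, and subject-level variability beyond the exponent.

## Problem sizes and numerical choices

The validation suite runs, per claim: slope recovery on 200 epochs ×
64 channels of pure $\chi = 1.5$ background; oscillation isolation on
200 matched-seed epoch pairs; null decoding calibration on 20 simulated
subjects (24 trials per condition, 16 channels) through the full
feature-extraction and decoding stack at 5 repetitions, plus 50
feature-level null runs for the test-size check; effect detection on
12 subjects; and generalization on 10 subjects × 3 subtasks (two
sharing a modulation map, one orthogonal). These sizes were chosen so
that group-level standard errors are small relative to the claims being
checked while the whole suite stays desk-scale.

Degenerate inputs are handled explicitly: zero-variance features are
dropped (with a warning naming them) before standardization; all-equal
group AUCs (possible at ceiling) short-circuit the t statistic to
$\pm\infty$/0 rather than erroring; non-positive aperiodic power inside
the fit range raises an error naming the offending frequencies;
singleton condition cells refuse evoked subtraction (the residual would
be identically zero).
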