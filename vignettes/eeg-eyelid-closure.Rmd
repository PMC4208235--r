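---
title: "Estimating eyelid closure from occipital EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating eyelid closure from occipital EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perclosr)
library(dplyr)
```

## The problem

PERCLOS — the percentage of time within a minute that the eyes are at least
80% closed — is the best-validated in-vehicle drowsiness measure. It is
conventionally computed from video of the driver's face, which fails at
night, with glasses, and costs substantial computation. `perclosr`
implements an EEG-only alternative: the eyelid closure degree (ECD, the
fraction of the pupil covered, 0 = fully open, 1 = fully closed) has an
approximately linear relationship with the alpha-band power share of the
occipital EEG, because closing the eyes removes visual input and the visual
cortex falls into the alpha rhythm. Estimating ECD from a single occipital
channel turns PERCLOS into a band-pass filter plus a fitted line — cheap
enough for real-time use on a wearable sensor.

## The model

For an EEG window from one channel, the power percentage of band
$z \in \{\theta, \alpha, \beta\}$ is

$$\mathrm{Per}(z) = \frac{P(z)}{P(\theta) + P(\alpha) + P(\beta)} \times 100\%$$

where $P(z)$ is the summed squared-magnitude of the Hamming-windowed DFT
over the band's frequency bins. Two time-domain features complement it: the
RMS amplitude $\sqrt{\tfrac1n \sum_i s_i^2}$ and the normalized Shannon
entropy of a 10-bin amplitude histogram,
$-\sum_j p_j \log_{10} p_j / \log_{10} k$.

The estimator itself is a one-feature regression of observed ECD on the O2
alpha power percentage: either the closed-form simple linear fit
($\hat\beta = \mathrm{Cov}(f, \mathrm{ECD})/\mathrm{Var}(f)$,
$\hat\alpha = \overline{\mathrm{ECD}} - \hat\beta \bar f$) or an
$\varepsilon$-insensitive support vector regression with linear, RBF
($K = e^{-g\|u-v\|^2}$) or polynomial ($K = (g\,u\!\cdot\!v + c_0)^d$)
kernel. Closure values are grouped into five ranges — FO $[0, 0.2)$,
SC $[0.2, 0.4)$, HC $[0.4, 0.6)$, AC $[0.6, 0.8)$, FC $[0.8, 1]$ — with
boundary values belonging to the upper group. The real-time monitor labels
each second of EEG with a group and raises PERCLOS alarms from the share of
FC seconds in the trailing minute.

## Pipeline stages and their parameters

**Band-pass filtering.** All analysis runs on the 4–30 Hz band, which
removes delta (and with it the 0.5–2 Hz energy of eye-blink artifacts) and
gamma/EMG. The filter is a linear-phase Hamming-window FIR, 257 taps at
128 Hz (about 1.6 Hz transition width, single-pass stopband below −50 dB at
2 Hz). Offline the filter is applied forward and backward (zero phase, so
segment boundaries stay aligned; the magnitude response is squared).
The streaming path uses a single causal pass with the 128-sample group
delay compensated, which in a live deployment means each per-second label
appears with about one second of latency.

**Blink removal on the closure trace.** A blink is a maximal run of
samples at or above 0.9 closure lasting less than 0.4 s (the upper bound of
a normal blink). Such runs are replaced by the value immediately preceding
the run; a run at the very start of a trace is back-filled from the first
following sub-threshold value, since "previous value" is undefined there.
Runs of 0.4 s or longer are genuine closures and are never touched, which
makes the operation idempotent. Sustained full closure therefore labels FC,
while a spike to 1.0 is treated as a blink.

**Segment selection.** Drivers do not hold closure levels on command, so
for each group the longest maximal run of same-labelled (blink-cleaned)
samples represents that group, truncated to its first 10 s. The paired EEG
slice is located by sample-index-to-seconds conversion with
nearest-sample rounding — the 7 Hz trace and 128 Hz EEG have no shared
clock, and this keeps alignment within one ECD sample period. Groups a
driver never reached are reported as missing rather than imputed.

**Features.** Band intervals are $\theta\,[4, 8)$, $\alpha\,[8, 13)$,
$\beta\,[13, 30]$: the textbook band edges leave 7–8 and 12–13 Hz
unassigned, but a power *share* presumes a partition of the analysis band,
so the gaps are closed upward and every DFT bin inside 4–30 Hz is counted
exactly once (a bin belongs to a band if its centre frequency does). No
zero padding is used; the resolution is $1/T$. Windows shorter than the
nominal 10 s — down to the 1 s real-time windows — are analysed whole,
without padding. The entropy sums over the $k$ histogram bins, not over
samples: a per-sample sum would count each bin's probability once per
sample and can exceed 1 before normalization, so the per-bin form is the
one that is actually bounded in $[0, 1]$.

**SVR internals.** Features and targets are min–max scaled to $[0, 1]$
before solving (predictions are unscaled on output), so `epsilon` and
`cost` live on the closure-fraction scale; the reported MSE magnitudes
(~0.005–0.03) only make sense on that scale. The default
$\varepsilon = 0.01$; the default cost grid for tuning is log-spaced
(`0.01, 0.1, 1, 10, 16.59, 46.62, 100, 500`, including the published
operating points), because the exhaustive 50 000-point grid crossed with
subject-wise cross-validation is impractical as a default — it remains
available via `full_grid = TRUE`. Grid-search ties break deterministically
toward smaller `cost`, then smaller `gamma`/`degree`. The polynomial
kernel defaults to $g = 1, c_0 = 0$, so degree 1 reduces exactly to the
linear kernel. Fitting is delegated to LibSVM (via `e1071`) at a dual
tolerance of $10^{-6}$; prediction is the package's own kernel expansion
from the stored dual coefficients, so serialized models (JSON) predict
identically without the solver.

**Evaluation.** Leave-one-subject-out: each subject's pairs form one test
fold, the model is fitted on everyone else. Fold metrics are the mean
squared error and the squared Pearson correlation between estimated and
observed closure. A fold with fewer than three pairs is reported but
flagged non-comparable — a line always passes through two points — and is
excluded from comparative aggregates, while still contributing to other
subjects' training folds. Group-level accuracy counts a prediction as
correct when the clipped estimate falls in the observed group's range;
subjects lacking a group are excluded from that group's denominator.
Bland–Altman agreement uses differences in the direction
estimated − observed and limits at bias ± 2 SD (exactly 2, not 1.96).
Subgroup comparisons use the classical pooled-variance two-sample t-test
(`welch = TRUE` switches); the degenerate zero-variance, equal-means case
returns $t = 0, p = 1$. Sex-stratified summaries conventionally exclude
the incomplete subjects, while the daylight summaries keep all ten drivers
per condition — `aggregate_report()` takes the exclusion list explicitly
for this reason.

**The PERCLOS monitor.** One-second windows, non-overlapping and aligned
to stream start (no overlap is assumed anywhere). PERCLOS is computed over
a *sliding* trailing 60 s window — whether the minute should slide or
tumble is genuinely open; sliding reacts faster and never misses an
episode that straddles a tumbling boundary. For elapsed times under a
minute the denominator is the elapsed seconds. Alarms are crisp
thresholds: advisory at PERCLOS ≥ 0.08 (4.8 s of closure per minute) and
warning at ≥ 0.12 (7.2 s); no hysteresis by default.

## What the synthetic generator emulates

No recordings ship with the package; every test input is generated.

* **Closure traces** (7 Hz): per-interval plateaus drawn uniformly inside
  the scheduled group's range (with a small margin and jitter so samples
  stay strictly inside), plus blink spikes — Poisson arrivals, peak drawn
  from $[0.9, 1]$, duration under 0.4 s — that *replace* the underlying
  samples, as a real eyelid does.
* **EEG** (128 Hz): each channel is a sum of three band carriers whose
  instantaneous power fractions follow linear laws in the local
  (interpolated) closure value. The default laws are
  $\alpha\% = 20 + 0.64\,E$, $\theta\% = 25 - 0.14\,E$,
  $\beta\% = 55 - 0.50\,E$ (with $E$ = ECD in percent): alpha rises and
  beta falls with closure. The alpha law holds exactly after clipping;
  theta and beta split the remainder in the ratio of their laws, so the
  three fractions always sum to one. Each carrier is a coherent
  quasi-sinusoid at a random mid-band frequency (e.g. an individual alpha
  peak between 9.5 and 11.5 Hz) carrying 85% of the band power
  (`tonality`), plus brick-wall band-limited Gaussian noise synthesized in
  the frequency domain, with the combined carrier's short-time power
  flattened over a half-second scale. The stabilization matters: raw
  Gaussian band noise leaves only a handful of independent spectral bins
  in a one-second window, so its band-power share fluctuates by tens of
  percent — while genuine band rhythms, above all closed-eye alpha, hold a
  far steadier envelope. Without it the per-second labels of the real-time
  path would be noise-dominated for any generator law.
* **Cohort tables**: each subject gets a perturbed alpha law (intercept
  SD 3 points, slope SD 0.04), one observation per realized group with
  alpha-percentage noise of 3.2 points — about 0.05 in closure fraction at
  the default slope — and Bernoulli dropout of non-FO groups at rate 0.1,
  mimicking drivers who never reached deep closure; FO is never dropped
  because every driver starts alert.

The generator deliberately does **not** emulate: the 1/f broadband
background and spindle/transient morphology of real EEG, eye-movement and
EMG artifacts in the EEG itself (the study removed those with ICA and
video evidence, which is out of scope here), absolute amplitude calibration
(the device's microvolt scale is unspecified and every in-scope feature
except RMS is scale-free), or non-linear saturation of the alpha–closure
relationship. Passing tests therefore demonstrate that the estimation
machinery is correct and recovers known laws from data with the assumed
structure — not that the linear law holds for any particular driver.

## Validation choices and problem sizes

The validation suite closes the loop generator → features → model →
evaluation: band percentages measured on generated EEG match the
configured laws within a few points on 10 s windows; a 20-subject cohort
at the default noise gives a pooled leave-one-subject-out fold $r^2$ near
0.98, rising monotonically to exactly 1 as the observation noise is
removed. The end-to-end demonstration calibrates a linear SVR on a
five-plateau trial, then monitors a 10-minute synthetic drive whose final
minute contains a 10 s full-closure episode: the warning alarm fires
during the episode (peak PERCLOS $10/60 \approx 0.167$) and never during
the alert phase. These sizes — 20 subjects, 90-odd pairs, a 10-minute
stream — match the scale of the original study design and keep the whole
suite fast.

Per-second label agreement with a scripted schedule sits around 93% and
varies a few points with the random plateau draws: a plateau that lands
near a group boundary genuinely straddles two labels. That is a property
of the five-group quantization, not of the estimator — mid-closure groups
are the hardest in real data too.

## Known limitations

* The linear alpha–closure law is assumed, not learned; subjects whose
  alpha does not track closure (2 of 20 in the reference cohort at the
  best channel) will be estimated poorly.
* The blink-removal rule needs the closure trace, so it cleans reference
  ECD data, not the EEG; the real-time path relies solely on the 4–30 Hz
  band-pass to suppress blink energy in the EEG.
* The EDF reader is minimal (standard EDF, uniform rate, int16 records)
  and read-only.
* RMS is the one feature that depends on the arbitrary amplitude scale;
  it is computed and stored but plays no role in the shipped estimator.
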