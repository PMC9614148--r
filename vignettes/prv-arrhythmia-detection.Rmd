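---
title: "Detecting life-threatening arrhythmias from pulse rate variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting life-threatening arrhythmias from pulse rate variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Extreme bradycardia (EB), extreme tachycardia (ET), ventricular
tachycardia (VT) and ventricular flutter (VF) are rhythm disturbances that
can precede fatal cardiovascular events. All four leave a clear signature
in the beat-to-beat timing of the arterial pulse, so they can be screened
from a single continuous arterial blood pressure (ABP) channel — a signal
that wearable cuffs and catheter monitors already provide — without ECG
electrodes. The operational definitions used throughout this package are
rate/duration rules on the instantaneous beat rate:

| class | rule |
|---|---|
| EB | rate below 40 bpm for at least 5 consecutive beats |
| ET | rate above 140 bpm for at least 17 beats |
| VT | at least 5 beats above 100 bpm with reduced pulse amplitude |
| VF | a rapid oscillation (flutter) lasting at least 4 s |

`prvdetect` implements the whole chain: denoising, pulse peak detection,
pulse-rate-variability (PRV) extraction, a 19-statistic feature battery,
random-forest feature selection, three classifiers, and chance-corrected
evaluation — plus a synthetic ABP generator so that every stage can be
validated against known ground truth.

## Denoising with integer-coefficient filters

Two causal IIR filters whose coefficients are integers over a power-of-two
gain handle the three dominant noise classes. The notch filter

$$F_1(z) = z^{-(R-P)N/2} - \left[\frac{1 - z^{-R}}{Q\,(1 - z^{-P})}\right]^N,
\qquad P = f_s/f_1,\; R = PQ,$$

subtracts a comb band-pass from a pure delay, so its magnitude is exactly
zero at 0 Hz (baseline drift) and at every multiple of the mains frequency
$f_1$ (AC interference), with linear phase in between. With the defaults
($f_s = 250$ Hz, $f_1 = 50$ Hz, $N = 2$, $Q = 64$) the design integers are
$P = 5$, $R = 320$ and the recursion is

$$y_1(n) = 2y_1(n-5) - y_1(n-10) + \tfrac{1}{4096}\big[{-x(n)}
+ 4096x(n-315) - 8190x(n-320) + 4096x(n-325) - x(n-640)\big].$$

The low-pass filter is a cascaded comb-integrator
$F_2(z) = [(1-z^{-C})/(C(1-z^{-1}))]^N$ with $C = f_s/f_2$; at the
defaults ($f_2 = 62.5$ Hz, $N = 2$) $C = 4$ and the single-stage recursion
$y_2(n) = y_2(n-1) + \tfrac14[x(n) - x(n-4)]$ is applied twice. It removes
EMG-like high-frequency noise with unit DC gain and a monotone passband.

Numerical policy:

* **Initial state.** All filter states start at zero; the leading samples
  spanned by the impulse responses ($NR + NC = 648$ at the defaults) are
  flagged on the output record and skipped by beat detection.
* **Alignment.** Both filters are linear-phase; the cascade delays the
  passband by $(R-P)N/2 + N(C-1)/2 = 318$ samples. `preprocess()` advances
  its output by that amount so beat positions land on raw-record
  coordinates, and flags the final 318 samples (whose aligned values would
  need future input) as invalid for detection.
* **Implementation.** The denominator $(1-z^{-P})^N$ couples only samples
  that are $P$ apart, so the recursion is evaluated as $P$ independent
  strands of an order-$N$ recursion — identical arithmetic to the
  per-sample difference equation, vectorized. The test suite verifies
  equality against a generic direct-form IIR routine to $10^{-9}$.
* **Order of the cascade.** Notch before low-pass. For LTI systems the
  order is mathematically irrelevant; the convention is fixed so transient
  flags and delays are well defined.

## Pulse peak detection

The detector works in five stages, each with an explicit tunable:

1. **Spectral gating.** A sliding 1 s window of band-limited energy
   (Butterworth band-pass, 0.5–10 Hz — the plausible range of pulse
   fundamentals and their first harmonics) masks regions with no pulsatile
   activity (`gate_frac`, default 5% of the peak band energy).
2. **Candidates + adaptive threshold.** Local maxima of the band-limited
   waveform must exceed a moving median plus `threshold_k` (default 1.0)
   moving median-absolute-deviations, computed over 2 s windows. The raw
   (unscaled) MAD is used deliberately: for near-sinusoidal flutter the
   1.4826 normal-consistency factor would push the threshold above the
   oscillation peaks.
3. **Refinement.** Each candidate moves to the local maximum of the
   filtered waveform within ±0.05 s, after a 5-sample moving average that
   absorbs residual high-frequency noise around the flat systolic apex.
4. **Refractory period.** 0.2 s (no rate above 300 bpm); the larger peak
   wins.
5. **Dicrotic suppression.** At slow rates the dicrotic wave separates
   from the systolic downslope into its own local maximum at ~40% of the
   pulse height. A peak below `dicrotic_frac` (default 0.45) of *both*
   neighbouring peak amplitudes is removed. Using the *smaller* neighbour
   protects genuine low-amplitude runs (VT at 60%, VF at 30% of normal
   amplitude), whose members always have at least one similar-sized
   neighbour.

Records carrying ground-truth annotations can bypass detection entirely
(`use_annotations = TRUE`), the programmatic counterpart of manually
calibrated peak positions.

From detected peaks, `compute_prv()` forms the beat-to-beat series: rate
$PRV(i) = 60 f_s / (Peaks(i{+}1) - Peaks(i))$ in bpm, interval $PPI(i)$ in
ms, and the pulse amplitude series $APM(i)$. Windowing into fixed-beat
segments defaults to 16 beats with step 1: 16 beats is small enough to sit
inside the shortest mandated episode (17 ET beats) yet large enough that
every feature below is defined; the step-1 overlap maximizes the number of
training segments per record. Both are configurable, and all validation
states its window explicitly.

## The 19-feature battery

Computed per segment, in fixed order; $S(i)$ denotes the rate series of
length $n$.

**Time domain** (on rates in bpm unless noted): `Mean`; `Std` (sample
standard deviation, $1/(n-1)$); `RMSD` $= \sqrt{\sum (S(i{+}1)-S(i))^2 /
(n-1)}$; `nRMSD` $=$ RMSD/Mean; `PNN40`, `PNN70` — the fraction of
successive *interval* differences exceeding 40 / 70 ms (computed on the
PPI series in ms, since the thresholds are in ms; the denominator is the
number of difference pairs); `Mid` (median); `IQR` — the quartile *ratio*
$S_{75}/S_{25}$ (dimensionless, clusters near 1; quartiles by linear
interpolation); `RMSD_APM` — the RMSD operator on the amplitude series.

**Frequency domain**: `LF_HF`, the ratio of autoregressive spectral power
in 0.04–0.15 Hz to 0.15–0.4 Hz of the interval series. The PPI series is
resampled at 4 Hz by cubic spline over cumulative beat time (linear
interpolation measurably attenuates modulation near the top of the HF
band at ordinary beat rates), mean-centred, fitted with a Burg AR model of
order 16, and the parametric density integrated by trapezoid on a
1024-point grid. A segment must cover at least 25 s (one LF cycle);
shorter segments yield the missing-value sentinel, as does zero HF power.

**Nonlinear**: Poincaré statistics
$Sd_1 = \sqrt{\tfrac{1}{n-1}\sum (S(i{+}1)-S(i))^2/2}$,
$Sd_2 = \sqrt{\tfrac{1}{n-1}\sum (S(i{+}1)+S(i)-2\bar S)^2/2}$, their
ratio `Sd1_Sd2` and ellipse area `Se` $= \pi Sd_1 Sd_2$; the turning point
ratio `TPR_PR` (count of strict interior extrema over $n$); normalized
Shannon entropy `ShE_PR` (16 equal-width bins over the segment range,
normalized by $\log_2 16$ so the value lies in $[0,1]$; a degenerate
segment gives 0); sample entropy `SamE_PR`
$= -\ln(B^{m+1}(r)/B^m(r))$ with $m = 2$, Chebyshev distance,
self-matches excluded, both template lengths counted over the same $n-m$
start positions, and tolerance $r = 0.25 \cdot \mathrm{sd}$ of the segment
(the conventional reading of a unitless 0.25; an absolute tolerance is
configurable); the tolerance-corrected `CSampEn`
$= SamE + \ln(2r) - \ln(\overline S)$, computed on the same units as its
input series; permutation entropy `PE_PR` (ordinal patterns of order
$m = 5$, ties broken by index order, natural log — order 5 is the largest
for which the pattern space is meaningfully sampled by short segments);
and the amplitude-series variants `SamE_APM`, `TPR_APM`.

**Sentinel policy.** Degenerate statistics (too-short coverage for LF/HF,
zero $Sd_2$, zero template matches at either sample-entropy length, zero
tolerance) return tagged `NA` values, never silent `NaN`. Downstream
learning imputes them with training-set medians, fitted on the training
split only.

## Feature selection and classifiers

A random forest (100 trees, `mtry` $= \lfloor\sqrt{19}\rfloor = 4$)
provides two importance scores: out-of-bag permutation importance (mean
decrease in accuracy, unscaled) and total Gini impurity decrease. Features
are ranked by the mean of the two rank positions (ties broken by the
accuracy score) and the top $k = 15$ kept, recorded as a 0/1 flag per
feature.

* **Decision tree** — CART with the Gini criterion, grown to purity
  (no complexity penalty, minimum split 2, minimum leaf 1). The headline
  classifier: fast, deterministic given the data, and the strongest
  performer on this task.
* **Extreme learning machine** — one hidden layer of 300 units with fixed
  random input weights $IW \sim U[-1,1]$ and thresholds $B \sim U[0,1]$,
  sinusoidal activations $H = \sin(X IW^\top + B)$, and output weights
  solved in closed form, $LW = H^+ T$, against the one-hot label matrix.
  The pseudo-inverse truncates at the standard
  $\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max}$ tolerance so
  the residual is the true least-squares minimum (verified against an
  independent QR solution). Features are standardized with training-set
  statistics before the random projection; prediction takes the class of
  the maximum output.
* **Back-propagation network** — two sigmoid hidden layers of 15 units
  (both sigmoid; only one layer's activation is conventionally pinned
  down, so the same choice is applied to both and exposed as config), a
  softmax output over the five classes, cross-entropy loss, BFGS
  quasi-Newton training with analytic gradients, at most 3000 iterations
  or a loss of 0.001. The input width follows the selected feature count
  and the output width the class count — the only layer sizes consistent
  with the feature vector. Non-convergence returns the model with a flag
  and a warning rather than failing.

All three share the same schema-checked `predict()` (features aligned by
name, unknown schemas rejected) and the same median imputation fitted at
training time.

## Evaluation

Counts are tallied into a class-by-class confusion matrix $Q$ over the
fixed label universe (healthy = 1, EB = 2, ET = 3, VT = 4, VF = 5).
Accuracy is $100 \cdot \mathrm{tr}(Q)/M$ with $M$ the evaluated sample
count — the multi-class form that reduces to $(TN+TP)/(TN+FP+TP+FN)$ for
two classes. Cohen's kappa uses observed agreement $p_1 = \sum_t Q_{tt}/M$
and chance agreement $p_2 = \sum_t Q_{t+}Q_{+t}/M^2$; these only normalize
correctly when $M$ is the total count and the sums run over classes, which
is how they are implemented. The per-class variant is

$$\kappa(i) = \frac{P_{tt} - P_{t+}P_{+t}}{P_{+t} - P_{t+}P_{+t}},$$

implemented exactly in this asymmetric form (the denominator uses the
*column* proportion); a zero denominator yields a sentinel. The evaluation
protocol is a repeated uniform random 80/20 hold-out — 100 repetitions by
default, unstratified, split over segments — reporting mean ± sd of
accuracy, kappa and per-class kappa. A subject-wise split is available as
an option for leakage-free evaluation but is not the default protocol.

## The synthetic generator

The generator exists so that every upstream claim can be tested against
known ground truth; it emulates the *rhythm*, not the hemodynamics.

* **Background rhythm**: AR(1) beat-to-beat rate modulation with
  coefficient 0.8 and marginal standard deviation `variability`
  (default 3 bpm) around `base_rate` (default 75 bpm) — a plausible
  short-range-correlated resting rhythm.
* **Episodes**: each arrhythmic record embeds one episode meeting its
  defining rule with margin — EB beats drawn from 32–38 bpm, ET from
  150–165 bpm, VT from 110–135 bpm at 60% amplitude, VF as a 4.5 Hz
  oscillation at 30% amplitude lasting at least 4 s. By default the
  episode fills the record up to a 4-beat lead-in/out, mirroring the burst
  segments a monitor would flag. The rules are asserted symbolically on
  the generated interval sequences in the test suite, independent of any
  detection.
* **VF frequency**: flutter is rendered at 4.5 Hz (270 bpm). A 5 Hz
  oscillation would sit exactly on the 300 bpm refractory bound of the
  detector, where integer sample rounding makes alternate cycles
  undetectable by construction; 4.5 Hz stays inside the flutter band
  while remaining a detectable rhythm. The frequency is configurable.
* **Waveform**: each beat is a two-Gaussian pulse — systolic width
  0.08 s, dicrotic wave at 40% amplitude offset by 0.3 of the beat
  interval with width 0.12 s — on a constant 80-unit baseline, with
  per-beat amplitude jitter (sd 2 units around 40). At ordinary rates the
  dicrotic wave merges into the downslope as a shoulder, as in real ABP;
  at bradycardic rates it separates, which is exactly the case the
  detector's dicrotic-suppression stage must handle. Annotations store
  the rendered local maxima (superposed tails shift the apex by about a
  sample from the nominal beat time).
* **Noise**: mains interference (5-unit sinusoid at 50 Hz), baseline
  drift (8 units split across 0.05 and 0.1 Hz — within the band the notch
  actually suppresses), and EMG-like noise (white noise high-passed at
  70 Hz, sd 2 units).

What it does **not** emulate: real pulse morphology and its beat-to-beat
shape variation, motion artifacts, sensor saturation, ectopy within
otherwise normal rhythm, or between-subject variability. Passing tests
therefore demonstrate that the pipeline is implemented correctly and that
its stages compose — not that the reported synthetic classification
accuracy transfers to clinical recordings, where class overlap is far
larger.

## Validation problem sizes

Routine validation uses records of 60 beats, a 2000-segment five-class
dataset (400 segments per class, 16-beat windows, step 1), 10 hold-out
repetitions for the end-to-end check, 100-signal batches for the
difference-equation equivalence, and 200 random short sequences per
statistic for the brute-force oracle comparisons. These sizes make the
full suite run in about a minute while keeping every check statistically
meaningful; all are parameters, not constants.

## Known limitations

* The peak detector is tuned for the synthetic morphology; real ABP with
  severe artifacts would need the motion-artifact handling that is out of
  scope here.
* Step-1 overlapping windows share beats between training and test
  segments under the segment-wise split; this mirrors the reference
  protocol, but the subject-wise option should be preferred when
  estimating generalization.
* WFDB input is not supported in this build; records enter as two-column
  CSV (seconds, pressure) or are constructed in code.
* The per-class kappa keeps the printed asymmetric denominator; swapping
  row for column proportions changes the value on non-symmetric confusion
  matrices.
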