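---
title: "Model-based inference of autonomic arousal from thermal imaging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based inference of autonomic arousal from thermal imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firiglm)
```

## The problem

Functional infrared imaging (fIRI) reduces a thermal video of the face to
a region-of-interest (ROI) averaged temperature trace, typically from the
nose tip, sampled at 10 Hz. Sympathetic arousal drives vasoconstriction
and sudomotor activity, which transiently cool the skin; the stereotyped
temperature deflection after a brief arousing stimulus is the thermal
impulse response (TIR). `firiglm` models such traces with a general
linear model (GLM): the trace is a weighted sum of known predictors —
each the convolution of a canonical response function (CRF) with an
impulse train marking stimulus onsets — plus an intercept, nuisance
terms, and error. The fitted weights carry the inference: a weight
significantly different from zero flags a stimulus-locked autonomic
response, exactly as GLMs on the phasic skin conductance response (SCR)
are used for electrodermal data.

## The canonical response function

The CRF is a Gaussian-smoothed causal bi-exponential,

$$\tilde h(t) \;=\; s\,\bigl[N * (E_1 + E_2)\bigr](t),
\qquad
N(x) = \tfrac{1}{\sqrt{2\pi}\,\sigma} e^{-(x-\tau)^2/2\sigma^2},
\qquad
E_i(t) = e^{-\lambda_i t}\,\mathbf 1[t \ge 0],$$

with polarity $s = -1$ by default (arousal cools the nose tip; a
positive-going response simply yields a negative weight). The
exponentials are taken causal: the defining integral does not state
their support, and the causal choice both matches the exponentially
modified Gaussian family used for SCR modelling and makes the
convolution integrable.

Each Gaussian-by-causal-exponential term has a closed form through the
scaled complementary error function. With $\mu = t - \tau$ and
$b = (\lambda\sigma^2 - \mu)/(\sqrt 2\,\sigma)$,

$$[N * E](t) = \tfrac12\,\mathrm{erfcx}(b)\,e^{-\mu^2/2\sigma^2},$$

which is overflow-safe except for $b \ll 0$, where
$\mathrm{erfcx}(b) \approx 2e^{b^2}$ and the term reduces to
$e^{\lambda^2\sigma^2/2 - \lambda\mu}$ (the pure exponential tail); the
implementation branches at $b \le -25$, where the neglected remainder is
below $e^{-625}$. `crf_numeric_oracle()` retains a brute-force
trapezoid-rule evaluation of the convolution integral (FFT-accelerated,
with interpolation to requested times) purely as an independent
cross-check; the test suite verifies agreement to better than $10^{-6}$
relative over $[-10, 120]$ s for randomly drawn parameter sets.

The packaged thermal parameter set is $\tau = 10.3734$ s,
$\sigma = 6.7601$ s, $\lambda_1 = 0.0765$ s$^{-1}$,
$\lambda_2 = 0.0994$ s$^{-1}$. Note that $\tau$ sets the event-to-peak
scale but is not the peak time itself: convolved with the slow
exponentials the packaged kernel peaks near 17 s. The default
discretization (10 Hz, 90 s support, truncation tolerance $10^{-6}$ of
peak) covers roughly $\tau$ plus three times the slowest decay constant;
because the kernel is still about $4\times10^{-3}$ of peak at 90 s,
truncation at the default tolerance only engages for longer supports.
`scr_crf_default()` is a *synthetic* stand-in in the same family with
faster dynamics and positive polarity — a configurable placeholder, not
a published electrodermal kernel.

## Event-related paradigm and designs

The stimulation design is event-related: 1 s white-noise bursts in
single-stimulus trials and double-stimulus trials with inter-stimulus
intervals (ISIs) of 2, 5.5 or 9 s; eight single trials and eight double
trials per ISI (32 trials); trial order randomized; each trial's last
stimulus followed by 30, 35 or 40 s of silence; 2 min of rest plus a
10 s lead-in before the first stimulus. `build_paradigm()` is a pure
function of its configuration and seed. The design does not state
whether the three silence durations are balanced across trials, so they
are drawn independently and uniformly by default
(`balanced_silences = TRUE` switches to balanced assignment).

Stimuli are represented as single-sample unit impulses at the
nearest-sample onset ("stick functions"), not 1 s boxcars: the stimulus
duration is two orders of magnitude below the response time scale.
Predictors are discrete convolutions of sticks with a sampled,
unit-peak-normalized kernel, truncated to the analysis window; the
intercept is appended by default. Epochs are half-open
$[\text{onset}, \text{onset} + 30\,\text{s})$ windows — 300 samples at
10 Hz.

## Carryover: why windows need a nuisance regressor

The packaged CRF decays with 10–13 s time constants, so a response is
far from extinguished 30–40 s after its stimulus — that is, when the
*next* trial begins. Every analysis window therefore rides on the
superposed tails of earlier trials. Left unmodelled, these tails bias
the weight split between overlapping predictors ISI-dependently: in
noiseless synthetic data the test suite measures the first weight of a
unit double response inflated beyond 1.2 at ISI 2 s and deflated below
0.9 at 9 s. Because the tails of all prior events share the
kernel's shape at known lags, a single nuisance regressor — the summed
unit-amplitude kernel tails of all events preceding the window within
the kernel support — absorbs them; with it, noiseless recovery is exact
at every ISI. The same logic cleans single-stimulus epochs before
template extraction: `clean_single_epochs()` regresses each epoch
jointly on the canonical within-window response, the predicted carryover
curve, and an intercept, and subtracts only the carryover and offset
parts. Carryover handling is on by default (`carryover = "canonical"`)
in `linearity_test()` and `run_dual_glm()`; `"none"` reproduces the bare
two-predictor-plus-intercept analysis. When traces have been low-pass
filtered, the carryover kernel should live in the same band: pass
`filter_kernel(...)` via `carry_kernel`.

## Preprocessing

fIRI traces: zero-phase third-order Butterworth low-pass at 0.4 Hz, then
artifact correction, then z-transformation — filtering and sample
substitution act on the raw scale, standardization last. SCR traces
(phasic input; tonic/phasic decomposition is out of scope): zero-phase
third-order band-pass 0.01–5 Hz, decimation to 10 Hz (keep every
$k$-th sample; the 5 Hz band edge is at the target Nyquist), then
z-transformation. "Zero-lag third-order Butterworth" is read as naming
the design order of the single pass; the forward–backward cascade that
makes it zero-phase doubles the magnitude rolloff, which matches common
usage. Edge transients are controlled by demeaning before filtering and
odd-reflection padding scaled to the slowest critical frequency.

Tracking-failure artifacts (the ROI tracker losing the nose tip shows up
as variance bursts) are flagged by a rolling-variance detector
(`flag_tracking_failures()`, default window 10 samples, robust z
threshold 5) as an automated surrogate for the visual inspection a
library cannot require; flagged or externally supplied intervals are
repaired by replacing contaminated samples with the mean of the six
clean samples on each side (12 in total; one-sided at trace
boundaries).

## Effective degrees of freedom

Filtered physiological traces are strongly autocorrelated, so the 300
samples of a window are far from 300 independent observations. The
correction expresses the signal's smoothness as the full width at half
maximum (FWHM, in samples) of an equivalent Gaussian smoothing kernel
and counts $n/\text{FWHM}$ equivalent samples:
$\mathrm{df} = \lfloor n/\text{FWHM}\rfloor - p$, with $p$ the number of
fitted parameters including the intercept. For a 300-sample epoch with
the study-average FWHM of 12 samples and one parameter this gives
$\lfloor 300/12\rfloor - 1 = 24$.

The FWHM estimator matches a Gaussian main lobe to the power spectrum
*by moments*: with $\sigma_\nu$ the power-weighted RMS frequency of the
tapered periodogram (cycles/sample),
$\text{FWHM} = \sqrt{\ln 2}/(\pi\sigma_\nu)$, floored at one sample. A
literal half-power crossing of a smoothed periodogram was prototyped
first and rejected: at these window lengths the crossing is dominated by
periodogram noise and by the smoother's own bandwidth. The moment
version evaluates to $\sqrt{\ln 2}\cdot\sqrt{12}/\pi \approx 0.92$ on an
exactly flat spectrum (reported as 1), recovers Gaussian smoothing
widths in simulation (suite-verified medians within 20% for widths of 6
and 12 samples), and — reassuringly — comes out near 12 samples on
0.4 Hz-low-passed 10 Hz noise (suite-verified median between 9 and 14),
consonant with the 12-sample study average the correction was designed
around.
Inference can use a per-window estimate (`fwhm = "estimate"`) or a fixed
study-average width (`fwhm = 12`).

Zero-residual fits are treated as the noiseless limit: a nonzero weight
is reported detected with $p \to 0$, a zero weight with $t = 0$,
$p = 1$.

## Linearity and time-invariance validation

**Linearity.** If responses superpose linearly, the second stimulus of a
double trial must earn the same weight regardless of how soon it follows
the first. Per subject, single-stimulus epochs provide a response
template (first principal component); each double-trial window is fitted
with two predictors built from that template (plus carryover and
intercept); weight pairs passing the significance criterion (both
predictors significant by default; `"either"` available) are
log-transformed, checked per cell with Shapiro–Wilk, and submitted to a
3 (ISI) × 2 (repetition) repeated-measures ANOVA with `aov` error
strata, cell means aggregated per subject, incomplete subjects excluded
listwise, no sphericity correction. A linear, time-invariant system
shows no ISI main effect and no interaction. Non-positive weights cannot
be log-transformed and are excluded with a reported count.

The template PCA is uncentered by default in this pipeline: with
z-scored traces the stereotyped response lives in the epoch *mean*, and
per-time-point centering would discard it, leaving a template dominated
by noise whenever between-trial amplitude spread is modest. `first_pc()`
itself defaults to centered (the usual PCA convention) with a degenerate
rule — identical epochs yield the normalized mean epoch with explained
fraction 1 — and both callers expose the choice.

Two intrinsic artifacts of this retain-significant-then-log procedure
deserve emphasis. First, selection: when detection power differs across
ISIs (the 2 s predictors are nearly collinear after low-pass filtering),
retaining only significant pairs biases the retained weights
ISI-dependently. Second, Jensen's inequality: the log of an unbiased but
noisier estimate has a lower mean, so ISI-dependent estimator variance
masquerades as an ISI effect in log space. Both artifacts scale with
estimation noise and vanish in the low-noise limit; the package's
null-calibration tests therefore run the full pipeline on low-noise
synthetic cohorts (white-noise SD 0.02 z-units, drift 0.02, retention
≈100%), where twenty 53-subject replicates show no ISI main effect in
at least 90% of replicates — the behaviour a calibrated 5% test should
produce. At realistic noise the artifacts are measurable and are
a limitation of the procedure itself, not of its implementation.

**Time-invariance.** If the TIR is a stereotyped template, the variance
it fails to explain across pooled single-stimulus epochs should be
*smaller* than the spontaneous fIRI variance at rest. The statistic is
the variance ratio $F = \text{rest fraction}/\text{residual fraction}$,
with all fractions on the uncentered task mean square so that the ratio
equals the plain variance ratio between the rest signal and the
template-unexplained epoch residual. Both degrees of freedom use the
equivalent-samples rule: the denominator from a single epoch's length
(24 at FWHM 12 — the printed arithmetic), the numerator from the pooled
rest length, since that is the data actually estimating the rest
variance. A numerator df of 1 would make the test blind to variance
ratios around 2 (critical value 4.26), which is why the package does not
adopt it; the matched-variance null gives $F \approx 1$ and a 2:1
noise-to-rest construction is reliably detected in the test suite.

## Robust CRF fitting

`fit_crf_params()` matches the CRF shape to a template by iteratively
reweighted least squares with Tukey bi-square weights (tuning constant
4.685, the standard 95%-efficiency value; scale from the median absolute
residual; at most 500 reweighting rounds; convergence at relative
parameter change $<10^{-8}$). The inner weighted problems are solved by
Levenberg–Marquardt (`minpack.lm::nls.lm`) with $\sigma$ and the decay
rates on the log scale to enforce positivity. A free amplitude parameter
absorbs the target's scale — normalizing the target by its raw maximum
would let a single outlier rescale it — and its sign sets the polarity;
the returned shape is unit-peak. A multi-start grid ($\tau \in \{5, 10,
15\}$ s, $\sigma \in \{3, 7\}$ s, unordered decay pairs from
$\{0.05, 0.1, 0.2\}$ s$^{-1}$, bracketing physiological time scales)
guards against local minima; the winner is chosen by median absolute
residual, a robust score a plain RSS would get wrong in the presence of
outliers. The two decay rates are exchangeable and are reported sorted
ascending.

One empirical caveat: over a 30 s window the four-parameter family is
nearly degenerate — parameter sets with $\tau$ differing by a few
percent and $\lambda_2$ by a factor of two can produce curves within
$10^{-5}$ of each other. Noiseless self-generated targets are still
recovered to machine precision (the exact zero wins the multi-start),
but from noisy templates only the *shape*, $\tau$ and $\sigma$ are
stably estimated; the decay pair should not be over-interpreted.

## Paired comparison against GLM-SCR

`run_dual_glm()` analyses each trial's 30 s window in both channels with
modality-specific kernels and shared sticks, then `confusion_matrix()`
cross-tabulates detections with GLM-SCR as the reference and
`sensitivity_specificity()` converts counts to percentages (full
precision kept; display rounded to one decimal). Detections are counted
per event by default, with per-trial aggregation (any significant
predictor) as an option; the comparison machinery is symmetric, so
swapping channels exactly transposes the matrix.

## The synthetic cohort generator

`simulate_subject()` implements exactly the generative model the GLM
assumes: every responding event adds a scaled, time-shifted copy of the
modality's normalized CRF; slow drift (three random-phase sinusoids with
periods of 60–300 s plus 0.05 Hz-low-passed noise, mimicking spontaneous
thermoregulatory oscillations) and white sensor noise are added on top.
Default levels — amplitude 1 ± 0.2 z-units between trials, noise SD
0.3 (fIRI) / 0.15 (SCR), drift SD 0.3 / 0.05 — describe a plausibly
noisy z-scored recording in which single events are detectable but not
trivially so. Habituation is off by default
(`response_probability = 1`) and can be enabled as a response-omission
probability; an optional attenuation of the second response at the
shortest ISI injects a controlled nonlinearity for power probes. The
same per-event amplitude drives both channels (up to a gain), so the
synthetic gold-standard comparison is meaningful. Both channels are
simulated at 10 Hz; the 1 kHz acquisition path is exercised by dedicated
preprocessing tests rather than in every simulation.

What the generator does *not* emulate: biophysical heat transfer,
response-shape variability across subjects (everyone shares the
generating CRF), movement artifacts beyond variance bursts, and
habituation dynamics beyond Bernoulli omission. Passing tests on this
cohort therefore demonstrate that the pipeline recovers what its own
model class generates — calibration and internal consistency — not that
real thermal data satisfy the model.

## Problem sizes and numerical choices

The test suite and acceptance checks use: 50 random parameter sets for
the closed-form/oracle equivalence (tolerance $10^{-6}$ relative, 1 ms
quadrature step); 2000 simulated null windows for type-I calibration
(binomial tolerance ±1.5 points around 5%); twenty 53-subject replicates
for the linearity null calibration; and 20 seeds for the
variance-ratio construction of the time-invariance check. Ties and
degenerate cases are handled explicitly: all-zero fitting targets return
a flagged degenerate result; constant traces refuse z-transformation and
spectral estimation; schedules validate strict onset monotonicity;
rank-deficient designs are rejected rather than silently pseudo-solved.

## Known limitations

* The per-event significance filter plus log transform biases retained
  weights at realistic noise (selection and Jensen effects above); the
  package reports candidate counts, retained counts and excluded
  non-positive weights so users can see the filter at work.
* The decay pair of the CRF is weakly identified from 30 s templates.
* The carryover regressor assumes equal carryover amplitudes across
  preceding events (one shared coefficient); amplitude heterogeneity
  leaves a small residual that behaves as noise, not bias.
* The SCR default kernel is a stand-in; quantitative SCR conclusions
  require a validated electrodermal CRF supplied by the user.
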