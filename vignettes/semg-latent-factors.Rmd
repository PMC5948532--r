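---
title: "Latent factors limiting myoelectric interface performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent factors limiting myoelectric interface performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(myofactors)
```

`myofactors` studies why the fidelity of surface-electromyography (sEMG)
gesture interfaces varies so strongly between users. It provides a complete
synthetic test bed: a forward model of forearm muscles under a circular
8-electrode bracelet, the signal-processing and classification chain of a
cursor-control interface, the performance indices used to score it, an
ICA-based localisation of muscle sources with the synergist–antagonist
coefficient (SAC), and a decision-quality analysis of pursuit-game traces.
This vignette explains the models, the tunable parameters, and the design
decisions, in the package's own terms.

## The forward model of the recording

Eight electrodes are equally spaced around the forearm; five muscles
dominate wrist gestures: *flexor carpi radialis* (FR), *extensor carpi
radialis longus* (ER), *extensor digitorum* (ED), *extensor carpi ulnaris*
(EU) and *flexor carpi ulnaris* (FU). Each muscle is a spatially localised
source whose activity mixes linearly onto the electrodes,

$$x(t) = A \sum_k W_k \, s_k(t)\,c_k(t) + \varepsilon(t),$$

where $W_k$ is the loading column of source $k$ (peaked at electrodes 2,
4, 5, 6, 8 respectively, with small spill-over to circular neighbours),
$s_k(t)$ the activation envelope, $c_k(t)$ a zero-mean unit-variance
band-limited (20–450 Hz at 1 kHz) Gaussian carrier — the standard
amplitude-modulated-noise surrogate for raw sEMG — $A \in (0,1]$ the
subject's amplitude attenuation, and $\varepsilon$ additive sensor noise
(`noise_sd`, default 0.25 in the arbitrary units in which a fully active
source has unit carrier variance). Raw sEMG has no natural physical units
here; only ratios of signal to noise matter.

The activation envelope combines four ingredients:

* a per-gesture **template** level per muscle (`default_activation_templates()`),
  with synergist pairs following wrist biomechanics (flexion drives FR+FU,
  extension ER+EU+ED, radial deviation FR+ER, ulnar deviation EU+FU);
  compound (diagonal) gestures take the $1/\sqrt2$-scaled sum of their two
  parents so total power stays comparable;
* **antagonist co-activation**: the latent coordination factor
  `co_activation` $\in [0,1)$ drives each gesture's antagonist pair at that
  fraction of the synergist level;
* 100 ms linear onset/offset **ramps** (`ramp_ms`), avoiding step transients;
* within-gesture **effort variability**: a slow (≤ 3 Hz) Gaussian
  fluctuation per muscle (`effort_cv`, default 0.5) and a log-normal
  per-repetition drive jitter (`segment_jitter_sd`, default 0.35). These
  model motor-unit drive variability and uninstructed effort differences
  between repetitions. They matter twice: they are what makes the five
  source time courses statistically separable for ICA, and they are the
  dominant source of classifier error on high-quality recordings.

Two latent factors define a subject. `co_activation` lowers the
synergist–antagonist coefficient and blurs the distinction between
opposing gestures. `attenuation` scales the signal (not the sensor noise)
and is mapped to a body-fat index by
$\mathrm{BF} = 4 - (36/\ln 10)\,\ln A$: tissue attenuates bioelectric
amplitude roughly exponentially with fat thickness, so body fat is linear
in log-attenuation; attenuation 1 corresponds to 4 % and attenuation 0.1
to 40 %, matching the range hand-to-hand fat monitors report. Cohorts draw
attenuation log-uniformly, i.e. body fat uniformly. This map replaces a
simpler linear alternative because it both reflects the physics and
linearises the observed relation between log-error and body fat.

## Features and classifiers

The data flow is split into trailing 200 ms windows at a 100 ms step;
per channel the windowed RMS $V(t)$ is the feature vector, and the mean
power $P(t)$ (mean absolute value pooled over window and channels) is the
effort proxy for proportional control. Windows are causal and stamped at
their right edge, matching real-time operation; partial leading windows
are dropped and a frame's label is the majority sample label (frames
spanning transitions can be discarded with `drop_transitions`).

The gesture classifier is a single-hidden-layer perceptron (8 inputs,
8 logistic hidden units, 4 directional logistic outputs $q = (q_l, q_r,
q_u, q_d)$), trained by full-batch backpropagation on the squared error.
Basic gestures are one-hot targets; a compound gesture sets its two parent
outputs to 1/2; rest is all-zero. An optional 7-output mode adds
fist/palm/rest classes. Biases are included by default (`use_bias = FALSE`
reproduces the literal bias-free neuron). Inputs are normalised per
channel by the maximal training RMS, a per-subject calibration that
improves conditioning. Two numerical choices deserve a note:

* **learning rate 2** (not a sub-unit value): with the mean-squared error
  averaged over frames and outputs, gradients are tiny; sub-unit rates do
  not approach the error floor within the ~5000-epoch budget that
  full-batch training realistically gets. The default reaches test errors
  around 0.02 on clean subjects within that budget.
* **early stopping with patience 50** on the test-error minimum rather
  than a literal "stop on first increase", which is fragile under epoch-
  to-epoch noise; the returned model is the test-error minimiser.

The baseline is standard linear discriminant analysis (`MASS::lda`) on
the same RMS vectors, restricted to the four basic gestures. Performance
is scored by precision/recall/F per gesture (macro averaging for the
pooled value; an undefined measure is reported missing, not zero — and
when a classifier is only ever shown known gestures, FN = 0 means recall
is 1), by the mean squared output error
$E_{MS} = \frac{1}{NM}\sum_n \lVert q_n - u_n \rVert^2$ over all eight
gestures, and by the per-subject index $R_e = \ln(E_{MS}/E_m)$, the log
ratio to the cohort median, which symmetrises the skewed error
distribution.

On *clean* subjects — full amplitude, minimal co-activation, steady
repeatable effort (`effort_cv` 0.25, `segment_jitter_sd` 0.15) — the
network and the discriminant baseline are nearly indistinguishable
(per-gesture F differences well under 0.1). Under strong effort
variability the discriminant baseline degrades faster: its pooled-
covariance assumption is violated by multiplicative amplitude noise,
while the network's nonlinearity copes. This is why the parity analysis
(`analysis/02_classifiers.R`) defines its benchmark on clean subjects.

## Proportional control

Cursor velocity is the rectified relative mean power,
$v = \max(0, P/P_{max} - p_{th})$, and the displacement per control tick
is $\Delta = 20\,v\,(q_r - q_l,\; q_u - q_d)$ in screen units (x
rightward, y upward). $P_{max}$ comes from an explicit maximal-effort
calibration segment; $p_{th}$ defaults to the 95th percentile of relative
rest-state power, which suppresses involuntary drift at rest. The control
tick equals the feature step (100 ms).

## Muscle-source localisation and the SAC

Because windowed RMS envelopes of a linear mixture are themselves
approximately a linear mixture of the per-source envelopes, ICA applied
to the RMS matrix recovers loadings and activations. The implementation
(`decompose_sources()`) uses FastICA (deflation, log-cosh contrast, via
the `ica` package) with one refinement: the unmixing is estimated on
first-differenced frames ("innovations"). Temporal filtering leaves the
mixing matrix of a linear model unchanged, and differencing cancels the
gesture on/off structure that all muscles share — which is *dependent*
across sources and misleads ICA — while the independent within-gesture
fluctuations that carry the identifying information dominate the
differences. The estimated unmixing is then applied to the full centred
RMS matrix; components are ordered by variance accounted for, sign-fixed
so the peak loading entry is positive, and localised to their peak
electrode. Automatic retention keeps components explaining at least 5 %
of variance with unique peak electrodes; on recordings of the four basic
gestures from the default model this retains five components peaked at
electrodes 2, 4, 5, 6 and 8.

The synergist–antagonist coefficient uses raw electrode RMS (channels 2,
4, 6, 8 — FR, ER, EU, FU; the ICA serves only to justify that electrode ↔
muscle map). For each basic gesture, with synergist sum $S_k$ and
antagonist sum $A_k$ of the mean RMS at those electrodes,

$$\mathrm{SAC} = \ln\Big(\tfrac14 \sum_{k=1}^{4} S_k / A_k\Big).$$

SAC = 0 means synergists and antagonists are equally active; positive
values mean cleaner reciprocal activation. Because each ratio cancels any
global amplitude gain, SAC is insensitive to the body-fat attenuation —
exactly, in the noise-free forward model. With additive sensor noise the
measured RMS acquires a floor that compresses the ratios at very low
amplitude; `mean_rms_per_gesture(rest_correct = TRUE)` therefore
subtracts the rest-state noise power per channel (clipped at 10 % of the
floor, below which activity is unmeasurable) before forming the ratios.
This removes most, not all, of the compression: at the lowest
attenuations measured SAC still shrinks toward zero. That residual
coupling is a measurement limitation of this synthetic world, not a
property of the coefficient.

## The pursuit game and decision quality

A target moves along a piecewise-linear path at constant per-segment
speed inside an 800 × 600 arena. The best direction for a constant-speed
pursuer solves $\lVert\omega_p\rVert t^* = \lVert d + \omega_c
t^*\rVert$ for the interception time ($d$ the cursor→target vector), a
quadratic whose smallest positive root is taken; if none exists (slow or
stationary pursuer, receding faster target) the fallback aims one time
step ahead of the target. The angular deviation $\alpha(t_i)$ is the
signed angle (counter-clockwise positive) from the best direction to the
actual cursor velocity, estimated by forward differences on traces
downsampled to at most 100 points (~50 ms spacing, endpoints preserved).
Circular statistics summarise $\{\alpha\}$: a 36-bin histogram with bins
centred on zero, the modal bin location, and the circular standard
deviation $\sqrt{-2\ln \bar R}$.

Gesture fidelity uses the emitted direction vector
$\delta = (q_r - q_l, q_u - q_d)$: a gesture is *optimal* when
$(\delta, n)/\lVert\delta\rVert_2 > d_{th} = 0.6$ (a cone of half-angle
$\arccos 0.6 \approx 0.93$ rad around the best direction), otherwise
*incorrect*. Gestures are then grouped by prevalent direction. The
prevalence rule assigns each gesture to the single dominant axis (the
component larger relative to its own standard deviation, thresholded at
$0.2\sigma$), so the eight optimal/incorrect sets are disjoint and their
rates sum to at most 1; the alternative of thresholding both axes
independently would double-count diagonal gestures. $\sigma$ is computed
per component over the whole trace.

The simulated user intends the best direction but acts with a reaction
delay and angular noise, quantised to the eight gesture directions. A
per-gesture articulation error rate models "problematic" gestures by slow
switching: transitions into or out of such a gesture are delayed by
0.3–0.8 s with the stated probability, the previous gesture perseverating
meanwhile. A problematic gesture is therefore evoked late when needed
(fewer optimal instances) and lingers when no longer appropriate (more
incorrect instances) — the signature the rate analysis is designed to
detect. Because motion is quantised to eight directions, even a perfect
policy shows angular deviations up to half the 45° sector; "deviation
≈ 0" is only ever true up to that discretisation.

## The cohort study

`run_synthetic_study()` composes everything: it draws a cohort
(`n_subjects = 20` by default), simulates a train and a test recording
per subject (two repetitions of rest + G1–G8, ~33 s each), trains the
network (up to 3000 epochs), and measures $E_{MS}$, $R_e$, SAC
(rest-corrected), body fat, and the score of a 60 s game trial in which
the subject's *own trained network* sits in the control loop — the
intended gesture is articulated as a random held-out feature frame and
classified, so classification error degrades play mechanically rather
than by assumption. Three ordinary least-squares regressions summarise
the cohort: $R_e \sim \mathrm{SAC}$ (negative slope: better muscle
coordination, lower error), $R_e \sim \mathrm{BF}$ (positive slope:
more fat, lower SNR, higher error), and score $\sim R_e$ (negative
slope: synthetic-test error predicts game performance). At these problem
sizes a full study runs in well under a minute on one core, and the
slopes are sign-stable and significant at $p < 0.05$ across replicate
cohorts.

## What the synthetic world does and does not show

The generator reproduces the statistical structure the analysis relies
on: localised linear mixing, amplitude-modulated carriers, latent
co-activation and attenuation factors, and realistic effort variability.
It deliberately omits motor-unit action potentials, electrode shift,
sweat artefacts, fatigue drift, and muscle crosstalk beyond linear
volume conduction. Passing tests therefore demonstrate that the
*analysis chain* is correct and sensitive to the factors it claims to
measure — not that real forearms obey the model. Known limitations worth
restating: ICA separability here is driven by within-gesture effort
fluctuations (real recordings add richer temporal structure); measured
SAC retains some attenuation dependence at very low SNR even after rest
correction; and the eight-direction quantisation bounds how small
angular deviations can get.
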