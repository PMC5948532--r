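# myofactors

Surface electromyography (sEMG) interfaces translate forearm muscle
activity, recorded by a bracelet of eight skin electrodes, into computer
commands. Their mean accuracy is good, but performance varies enormously
between users, and the causes are largely *latent*: properties of the
user, not of the classifier. `myofactors` is an analysis workflow for
studying two such factors — the coordination of synergist and antagonist
muscles, and the amount of subcutaneous fat attenuating the signal — and
for quantifying decision quality when the interface is used dynamically,
in a pursuit ("pacman") game. Everything runs on synthetic data from a
forward model of the recording, so the full chain is testable without any
human recordings. It is aimed at researchers developing myoelectric
interfaces and at anyone who needs a reproducible test bed for sEMG
processing chains.

## The methods in brief

* **Features.** The 8-channel flow `x(t)` (1 kHz) is cut into 200 ms
  windows at a 100 ms step; per channel the windowed RMS
  `V(t) = sqrt(mean x²)` is the feature vector, and the mean power
  `P(t) = mean |x|` pooled over channels drives proportional control:
  cursor velocity `v = max(0, P/P_max − p_th)` and displacement
  `Δ = 20·v·(q_r − q_l, q_u − q_d)`.
* **Classifiers.** A single-hidden-layer perceptron (8 logistic hidden
  units, 4 directional outputs `q`) trained by backpropagation with
  early stopping; compound (diagonal) gestures are encoded by target 1/2
  on the two parent outputs. A linear-discriminant baseline runs on the
  same features. Accuracy is scored by per-gesture precision/recall/F,
  by the mean squared output error `E_MS = mean ‖q − u‖²/M`, and by the
  per-subject index `Re = ln(E_MS / median E_MS)`.
* **Muscle localisation and SAC.** Windowed RMS envelopes follow the
  linear mixing model `V(t) = Σ_k W_k s_k(t)`; FastICA recovers five
  sources whose loadings peak at electrodes 2, 4, 5, 6, 8 — matching the
  five dominant forearm muscles. The synergist–antagonist coefficient
  `SAC = ln(¼ Σ_k S_k/A_k)` compares synergist and antagonist mean RMS
  (electrodes 2, 4, 6, 8) per basic gesture: 0 means undifferentiated
  co-contraction, positive means clean reciprocal activation, and the
  ratio form cancels any global amplitude gain.
* **Game decision analysis.** From cursor/target traces, the best
  interception direction `n` solves `‖ω_p‖ t* = ‖d + ω_c t*‖` (smallest
  positive root, with a one-step-lookahead fallback); the signed angular
  deviation `α = ∠(ω_p, n)` is summarised by circular statistics, and
  emitted gestures are classified optimal/incorrect by the cone test
  `(δ, n)/‖δ‖ > 0.6` (≈0.93 rad) with per-direction prevalence rates.
* **Synthetic cohorts.** Subjects differ in latent antagonist
  co-activation (drives SAC down and error up) and amplitude attenuation
  (maps to a 4–40 % body-fat index and drives the signal-to-noise ratio
  down). The study regresses `Re ~ SAC`, `Re ~ BF` and `Score ~ Re`.

## Worked example

```r
library(myofactors)

model   <- muscle_model()                       # 5 muscles on 8 electrodes
subject <- subject_profile(co_activation = 0.2, attenuation = 0.9)
rec     <- simulate_recording(model, subject, coordination_sequence(), seed = 101)
fs      <- rms_windows(rec)                     # 200 ms / 100 ms RMS frames

ic <- decompose_sources(fs, m = NULL, seed = 1) # ICA, automatic retention
ic$m                                            # 5
sort(ic$localization)                           # 2 4 5 6 8

sac(mean_rms_per_gesture(fs))                   # synergist-antagonist coefficient
```

```
 gesture synergist antagonist    ratio
      G1      1.61       0.46     3.52
      G2      1.66       0.46     3.63
      G3      1.58       0.46     3.44
      G4      1.61       0.46     3.55
SAC = 1.26
```

Five components, localised exactly at the electrodes the forward model
drives, and a strongly positive SAC for this well-coordinated subject
(ratios ≈ 3.5 mean its synergists are 3.5× more active than its
antagonists). Sweeping the latent co-activation factor from 0.05 to 0.8
lowers SAC monotonically from 1.32 to 0.40
(`analysis/03_muscle_coordination.R`).

The full cohort study (`analysis/04_latent_factors.R`, 20 subjects,
seed 1) prints:

```
<cohort_result> 20 subjects, median E_MS = 0.0662
  re_sac    slope   -0.401 +/- 0.028  (p = 2.79e-11)
  re_bf     slope    0.019 +/- 0.002  (p = 1.87e-07)
  score_re  slope  -14.397 +/- 2.645  (p = 3.6e-05)
```

Better muscle coordination (higher SAC) predicts lower classification
error; more body fat predicts higher error (about +0.02 log-error per
percentage point); and subjects with lower synthetic-test error score
more in the game their own trained network controls.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | example recording + cohort, CSV/JSON interchange files |
| `02_classifiers.R` | network vs discriminant parity on clean subjects (per-gesture F) |
| `03_muscle_coordination.R` | ICA localisation table, SAC vs co-activation sweep |
| `04_latent_factors.R` | 20-subject cohort study and the three regressions |
| `05_game_analysis.R` | angular-deviation histograms and optimal/incorrect gesture rates |

The methods vignette (`vignettes/semg-latent-factors.Rmd`) documents the
forward model, every tunable parameter, and the design decisions.

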