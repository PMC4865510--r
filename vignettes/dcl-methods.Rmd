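---
title: "Quantifying driver mental fatigue from multimodal biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying driver mental fatigue from multimodal biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcltools)
```

## The problem and the measurements

Mental fatigue from sleep deprivation is a major cause of traffic accidents,
and unlike physical fatigue it is hard for a driver to counteract
deliberately. `dcltools` implements a multimodal analysis that contrasts two
driving conditions — *well-rested* (at least a full night's sleep) and
*sleep-deprived* (no sleep) — from four simultaneously recorded signal
types:

* **EEG** (64 scalp channels, 512 Hz): spectral power redistributes with
  vigilance. Under sleep deprivation, alpha-band (8–13 Hz) relative power
  rises over centro-parietal cortex and beta-band (13–30 Hz) relative power
  falls fronto-centrally.
* **ECG** (2 chest channels): heart rate is lower in the sleep-deprived
  state (roughly 62 vs 70 beats/min on average).
* **EOG** (horizontal + vertical): blink rate; measured, but excluded from
  the fatigue index because it does not separate the conditions reliably.
* **fNIRS** (8 prefrontal channels × 2 wavelengths, 10 Hz): prefrontal
  oxygenation rises while an alert driver attends to the task and stays
  flat or drifts slightly negative under fatigue.

The original study's recordings were never deposited, so the package ships a
seeded synthetic generator that emulates these condition contrasts with
known ground truth; every downstream stage is tested against that ground
truth.

## Processing chain

Each 30-minute session is cut into 10-second trials (180 per session) shared
by all modalities; the two acquisition computers are synchronized by
start/end triggers before segmentation.

**EEG.** Ocular artifacts can be removed by logistic infomax ICA
(components whose absolute correlation with an EOG channel exceeds 0.7 are
zeroed), then the data are band-passed 1–50 Hz with a zero-phase 4th-order
Butterworth filter. Per trial and channel, a Welch power spectral density
(2-s Hamming segments, 50% overlap, 0.5 Hz resolution) is integrated over
the five canonical bands — delta 1–4, theta 4–8, alpha 8–13, beta 13–30,
gamma 30–50 Hz, half-open intervals so shared edges are never counted
twice — and normalized by the summed band power to *relative power levels*
(RPL), which sum to 1 and damp session/subject variability. Alpha RPL is
averaged over a centro-parietal channel set (default CP2, CP4, CP6, P2, P4,
P6) and beta RPL over a fronto-central set (Fz, FCz, FC1, FC2, Cz); both
lists are configurable because the underlying regional effects are broad.

**ECG.** Both chest channels are band-passed 0.1–30 Hz, linearly detrended,
and R-peaks are detected as local maxima above `mean + 2.5 sd` with a 0.3-s
refractory period (a ~200 bpm ceiling). Because the threshold is built from
the trace's own statistics, detection is invariant to amplitude scaling.
Heart rate is the per-minute peak count, averaged over the two channels to
reduce detection error; the per-trial classification feature is the mean
RR interval within each 10-s trial.

**EOG.** The vertical channel is band-passed 0.1–10 Hz and thresholded at
`mean + 3 sd`, with an absolute 50 µV floor: blinks are stereotyped
large-amplitude deflections, and without a floor a blink-free noise trace
would always yield spurious statistical-threshold crossings.

**fNIRS.** Light intensities over the first 30 s form the per-channel,
per-wavelength baseline. Optical-density changes
$OD_\lambda = \log_{10}(I_{b,\lambda}/I_{t,\lambda})$ at 735 and 850 nm are
inverted through the modified Beer–Lambert law,

$$\Delta HbO =
\frac{OD_{\lambda_1}\varepsilon_{HbR,\lambda_2} -
      OD_{\lambda_2}\varepsilon_{HbR,\lambda_1}}
     {d \cdot DPF\,(\varepsilon_{HbO,\lambda_1}\varepsilon_{HbR,\lambda_2}
      - \varepsilon_{HbO,\lambda_2}\varepsilon_{HbR,\lambda_1})},$$

and analogously for $\Delta HbR$, with extinction coefficients
$\varepsilon_{HbO} = (0.4646, 1.1596)$ and
$\varepsilon_{HbR} = (1.2959, 0.7861)$ mM⁻¹cm⁻¹, emitter–detector
separation $d = 3$ cm and the unknown differential path length factor fixed
at 1 so concentrations carry the unit mM/DPF. The logarithm base (10, the
optical-density convention) is configurable since conventions differ.
A 0.01 Hz zero-phase high-pass removes baseline drift and a 10-s/50%-overlap
moving-mean smoother suppresses fast fluctuations; the per-trial feature is
the within-trial mean concentration change averaged over the 8 channels.

## The Driving Condition Level

Three per-minute features — the fronto-central-beta over centro-parietal-
alpha RPL ratio, the HbO amplitude, and heart rate — are min–max normalized
to $[0,1]$ and summed:

$$\mathrm{DCL} = a\,\mathrm{norm}(\beta/\alpha\ \mathrm{RPL}) +
  b\,\mathrm{norm}(HbO) + c\,\mathrm{norm}(HR), \qquad 0 \le \mathrm{DCL} \le 3$$

with unit weights by default (each weight on the 0–1 grid in steps of 0.1
for the optional exhaustive weight search, ties broken to the
lexicographically smallest triple). Higher DCL means a more alert state; all
three components are larger when alert, so heart rate enters directly. The
session DCL is the mean of the per-minute values, and the *relative DCL*

$$\mathrm{rDCL}\,(\%) = 100 - 100\cdot
  \mathrm{DCL}_{\text{sleep-deprived}} / \mathrm{DCL}_{\text{well-rested}}$$

expresses the fatigue-induced drop in percent.

Two normalization details were genuinely open and are resolved as follows:

* **Pooled bounds.** Normalization bounds are fitted on the pooled minutes
  of *both* conditions of a subject. rDCL compares the two sessions on one
  scale; per-condition bounds would force both sessions toward the same
  $[0,1]$ spread and destroy the contrast. The pooling is configurable.
* **Outlier shrinkage.** Values outside mean ± 2 sd are shrunk to the
  min/max of the remaining values before the bounds are taken. The test is
  applied leave-one-out — each value is compared against the spread of the
  *other* values — because a single extreme value inflates the pooled sd
  enough to mask itself, which would make the rule a no-op exactly when it
  is needed.

The DCL difference between conditions decomposes additively into the three
modality contributions (`modality_contributions()`), which sum exactly to
the difference under unit weights.

## Classification and fusion

Trials are split respecting time: repetition $r$ (of 30) circularly shifts
the 180-trial order by $6r$ trials, takes the first 126 as the training
block and the last 54 as the test block, then drops the final 6 trials
(one minute) of each block, leaving 120 training and 48 test trials per
condition with a one-minute buffer between blocks. The circular-shift
reading of the "sliding window" keeps the published block sizes for all 30
repetitions; a non-circular variant would run out of trials after nine
shifts.

Each modality is classified with Fisher's linear discriminant,
$w = (S_{\text{pooled}} + \lambda I)^{-1}(\mu_1 - \mu_0)$, the boundary at
the projected midpoint of the class means, and a small ridge
$\lambda = 10^{-3}\,\mathrm{tr}(S)/p$ for numerical stability. Boundary
ties go to the well-rested class. Fusion stacks the classifiers: the
discriminant scores of the per-modality models are the features of a
second-level FLDA. The second level is trained on *out-of-fold* scores
(contiguous 5-fold within the training block) — training it on in-sample
scores would optimistically bias the fused accuracy.

Paired condition contrasts use an exact two-sided Wilcoxon signed-rank
test. The null distribution of the positive-rank sum is built by a shift
convolution over the (doubled, hence integer) ranks — exactly the
distribution over all $2^n$ sign assignments, valid under ties and cheap
for any practical $n$; zero differences are dropped.

## The synthetic generator

`simulate_session()` produces one session from a `session_params()` object;
`well_rested_params()` and `sleep_deprived_params()` encode the two
conditions:

| parameter | well-rested | sleep-deprived |
|---|---|---|
| heart rate (bpm) | 70, drifting −0.15/min | 62, flat |
| alpha gain, centro-parietal | 1.0 | 1.5 |
| beta gain, fronto-central | 1.4 | 1.0 |
| HbO trend (mM/DPF per min) | +0.015 | −0.002 |
| blink rate (per min) | 12 | 15 |

The heart rates are the two study-level condition means; the alert-session
heart-rate drift encodes the observed narrowing of the condition gap over
the half hour; the HbO trends encode "gradually rising" versus
"flat/slightly negative". The regional band gains are direction-only
choices: no effect magnitudes are published for the RPL changes, so the
presets are built to make effect *directions*, not magnitudes,
reproducible.

Mechanically: EEG channels are sums of five band-limited noise processes
(4th-order Butterworth band-passed white noise, one per canonical band,
with per-region alpha/beta amplitude gains) plus white sensor noise; ECG is
a Mexican-hat QRS template train (80 ms width) at the instantaneous rate
with timing jitter; EOG carries Poisson-timed 250-ms raised-cosine blinks
of 200 µV on a slow baseline wander; fNIRS intensities are produced by
running a ground-truth hemodynamic course (linear trend + 0.02 Hz slow
oscillation + noise, with $\Delta HbR = -0.4\,\Delta HbO$) *forward*
through the same Beer–Lambert model the analysis inverts, overlaid with a
multiplicative slow exponential drift (time constant 600 s, removed by the
0.01 Hz high-pass) and additive sensor noise. All randomness comes from one
seed with deterministically derived per-modality substreams, so identical
parameters give bit-identical sessions.

What the generator does *not* emulate: volume conduction and realistic
spatial covariance across EEG channels, heart-rate variability structure
beyond white jitter, pulse/respiration physiology in the optical signals,
eye movements other than blinks, and real artifact morphology. Passing
tests therefore demonstrate correctness of the algorithms under the stated
signal model, not field performance on real recordings.

## Numerical choices and degenerate inputs

* Zero-phase (forward–backward) filtering throughout, so R-peak and blink
  timings are not shifted; the series mean is removed before filtering
  (never added back, DC being in every stop-band here), which avoids edge
  transients on long-period high-pass filters.
* Welch band powers use rectangle integration on the 0.5 Hz grid with
  half-open band membership; an all-zero spectrum is an error at the RPL
  stage (zero total power).
* ICA uses the natural-gradient logistic infomax rule on whitened data with
  block updates, an annealed learning rate (×0.9 whenever the update
  direction swings by more than 60°) and a restart at halved rate on
  blow-up. The logistic nonlinearity targets super-Gaussian sources (spiky
  artifacts); strongly sub-Gaussian sources separate less sharply, which
  the tests acknowledge with a wider tolerance for a sinusoidal source.
* Degenerate inputs error loudly rather than silently: sessions shorter
  than one trial, non-positive light intensities, all-identical
  normalization inputs, a rejection threshold that would remove every IC,
  single-class classifier fits, and all-zero difference vectors in the
  signed-rank test.
* EDF output digitizes against the 8-character header rendering of each
  channel's physical range (rounded outward), so a write–read round trip
  is exact up to one 16-bit quantization step of that range.

## Problem sizes in the tests

The unit and acceptance suites run the full chain on reduced sessions —
typically 2–10 minutes at 128 Hz, with feature extraction restricted to the
region channels — which preserves every structural constant that matters
(trials per minute, split block proportions, baseline and smoothing
windows) while keeping the suite fast. The 180-trial/120-48-split
bookkeeping is always checked at full size, and the seed-robustness checks
(heart-rate recovery within ±1 bpm, effect directions, fusion gain over the
best single modality) run over 20 independent seeds.

## Limitations

The index is calibrated within subject and session pair: pooled-bounds
normalization needs both conditions before rDCL can be computed, so online
use requires a pre-recorded alert baseline. Linearity of each feature in
fatigue level is assumed by the sum construction but not guaranteed. The
blink feature is computed and reported but deliberately excluded from the
DCL, mirroring its poor separability between conditions.
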