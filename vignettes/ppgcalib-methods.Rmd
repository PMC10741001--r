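---
title: "Methods: calibration-interval hypertension screening from PPG scalograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration-interval hypertension screening from PPG scalograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ppgcalib)
```

This vignette is the package's account of its science: the model behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic cohort does and does not emulate, and the numerical
decisions that were genuinely open.

## The screening problem

Photoplethysmography measures blood-volume changes optically and is cheap
to acquire continuously; arterial blood pressure (ABP) is the ground truth
but needs a catheter or cuff. The pipeline asks whether the *shape* of the
PPG pulse carries enough information to classify a subject as normotensive
(NTS) or hypertensive (HTS), where the label comes from the ABP channel:
the recording-level systolic blood pressure (SBP) is the arithmetic mean of
the ABP waveform's systolic peaks, and SBP > 130 mmHg defines HTS.

The central experimental variable is **calibration**: labeled measurements
of the *same subject* included in training, so that later measurements are
classified relative to them. The calibration interval is the time gap
between those training measurements and the validation measurement, binned
as < 1 h, 1–6 h, 6–24 h, and > 24 h. The scientific expectation is that
classification degrades as this gap grows when subjects' pressures evolve.

## Synthetic cohort generator

Real ICU waveform archives cannot be bundled, so `generate_cohort()`
simulates the statistical structure the analysis needs. It is first-class,
tested code, not a fixture.

**Pulse model.** Each PPG beat is a sum of three positive lobes on the beat
phase $u \in [0,1)$ (wrapped Gaussians, so the waveform is continuous
across beats): a systolic peak, a reflected wave, and a dicrotic component.
Hypertension — stiffer arteries — narrows the systolic upstroke, raises and
advances the reflected wave, and damps the dicrotic wave; `morphology_effect`
scales this class contrast (1 by default, 0 erases it). Each subject draws
idiosyncratic perturbations of its class template (lobe positions, widths,
amplitudes), giving every subject a recognisable signature, which is what
makes calibration meaningful. ABP beats use a fixed shape scaled per beat so
that the sampled systolic peak equals the per-beat target pressure exactly;
with per-beat pressure noise and additive PPG noise disabled the generator
is analytically predictable, which several tests exploit.

**Beat-to-beat variability.** Heart-rate jitter is Gaussian with a 2 bpm
standard deviation and PPG amplitude jitter multiplicative at 2% — enough
realism to prevent degenerate, literally periodic signals without
destroying class separability. A test pins the intended property: a
nearest-centroid classifier on beat-averaged pulses separates 20 subjects'
recordings with accuracy above 0.9.

**Pressure levels and drift.** Baseline SBP is uniform per class
(NTS 100–125, HTS 135–165 mmHg; the configuration refuses ranges that
straddle 130 mmHg unless drift is enabled or explicitly overridden). With
`drift_mmHg_per_hour` > 0 each subject's pressure moves linearly in time
with a random sign. Pulse *shape*, however, stays tied to the subject's
baseline class by default: we model morphology as a chronic vascular trait
while the acute pressure (and hence the label) drifts. This choice is what
lets the calibration experiment reproduce the expected degradation — a
network that has memorised a subject's signature together with its
calibration-time label goes stale once drift moves the subject across the
threshold. `morphology_drift_frac` interpolates toward shape that tracks
current pressure for users who want the opposite assumption.

**Schedules.** Timestamps come from per-subject rules (`uniform`, cycled
`gaps`, `paired`, or explicit offsets). The default gap cycle (30 min ×3,
2 h ×2, 8 h ×2, 30 h) populates all four interval bins. The default cohort
shape is 69 subjects (45 NTS, 24 HTS) and 974 recordings of 120 s at
125 Hz, the cohort scale this pipeline is designed around; recordings are
distributed as evenly as possible with the remainder to the earliest
subjects. Nothing in the generator prescribes how many recordings per
subject a real archive would have — that distribution is a choice, not an
inference.

**What is not emulated.** Arrhythmias, motion artifacts, sensor dropout,
quantisation, baseline wander, and any physiologically validated
hemodynamics. Passing tests therefore show the pipeline is correct and
sensitive to the structure it assumes; they do not show field performance
on real recordings.

## Preprocessing

Filtering uses a Chebyshev type II band-pass, 0.5–10 Hz, 40 dB stop band,
designed with order parameter 4 in the common DSP-toolbox convention (four
poles per band edge). It runs at the native 125 Hz, forward-backward for
zero phase — pulse morphology must not be skewed before it becomes an
image — over an odd (point-reflected) extension long enough for the 0.5 Hz
edge transient to die out, so output length equals input length. The
filter is kept in transfer-function form; tests verify the realised
response directly against the transfer function evaluated on the unit
circle (5 Hz pass-band gain, ≥ 40 dB at 20 Hz, exact DC rejection).

Decimation 125 → 25 Hz is plain subsampling: the signal is already
band-limited to 10 Hz against a 12.5 Hz output Nyquist, so no second
anti-aliasing filter is applied, and a decimated sinusoid matches its
closed form to machine precision.

Segmentation cuts 10-s windows (250 samples at 25 Hz), 12 per 120-s
recording; a shorter remainder is dropped with a warning. Each window
inherits the recording's SBP and label and a 1-based `parity_index`.

Peak detection for SBP (the paper-level operation "mean of the systolic
peaks" needs an algorithm): local maxima with minimum spacing 0.33 s
(≤ 180 bpm) and prominence ≥ 10 mmHg against the deeper flanking valley;
flat-topped peaks are kept, since quantised pressure traces plateau.
A value exactly at 130 mmHg is labeled NTS — the threshold is an open
boundary on the hypertensive side — and the threshold is configurable.
"Significant fluctuation" is operationalised as *any* mixed labels across a
subject's recordings; that is the strictest reading, and it is applied by
default but switched off for drift experiments, where fluctuation is the
object of study rather than an artifact.

## Scalograms and the cone of influence

The continuous wavelet transform uses the analytic Morse wavelet with
symmetry γ = 3 and time-bandwidth product P² = 60 (frequency-domain
exponent β = P²/γ = 20), implemented as an FFT filter bank: one band per
voice, 12 voices per octave, on a logarithmic frequency grid from
2/duration Hz (0.2 Hz for 10-s segments — below that, no complete wavelet
fits the window) to the Nyquist frequency (12.5 Hz). For 250-sample
segments this gives a 72 × 250 magnitude matrix. The FFT implies circular
boundary conditions; the affected region is exactly what the cone of
influence marks, so no additional padding is applied. One mid-band scale is
cross-checked in the tests against direct time-domain convolution with a
numerically sampled wavelet.

The cone of influence is computed from the wavelet's e-folding time: the
mother envelope $|\psi(t)|$ falls to $1/e$ of its peak at $t_e$ (found
numerically from the frequency-domain form, once, then memoised), and the
boundary frequency at distance $d$ from the nearer segment edge is
$f_{\mathrm{coi}}(d) = \omega_p t_e / (2\pi d)$ with $\omega_p$ the
wavelet's peak angular frequency. The boundary is symmetric about the
segment midpoint and capped at the top analysis frequency.

**Rendering decisions** (the source method names no colormap, scaling, or
frequency limits, so these are pinned here and configurable): magnitudes
are normalised per image to [0, 1] — which makes rendering exactly
invariant to input amplitude, asserted by a test — and mapped through
viridis; log-scaling is off by default. The coloured raster is resized
bilinearly to 224 × 224, and the cone of influence is then traced as a
1-pixel-wide exactly white line in output coordinates, so interpolation
cannot dilute it. Regions outside the cone are marked, never masked.
Frequencies descend from image top to bottom, i.e. low frequencies sit at
the bottom, pinned by a two-tone regression test. No axes, ticks, or
margins: pixels carry only the scalogram.

## Calibration splits

For each bin, each subject's longest chronological chain of recordings
with every consecutive gap inside `[lower, upper)` is found greedily: from
each candidate start, the next link is the earliest later recording whose
gap qualifies; the longest chain wins, ties to the earliest start. (The
source procedure does not define chain extraction; greedy-earliest is the
simplest rule consistent with "1st, 3rd, … segments spaced at each
interval", and the tests re-derive it by brute force.) Chains shorter than
two leave the subject unselected.

Odd chain positions contribute all 12 of their images to training, even
positions to validation; all images of unselected subjects join training;
images of a selected subject's recordings *outside* its chain are used in
neither set, which is why train + validation ≤ total. Every interior
validation recording lies chronologically between two training recordings
of its subject — the calibration semantics — and a leakage audit (no image
in both sets, no unselected-subject image in validation) is part of the
test suite. Bins are processed independently; a recording may sit in
different chains for different bins. An empty bin yields a warning and a
skipped report, not an error.

## Classifier

`build_model()` constructs a convolutional network ending in a 2-output
fully connected layer and softmax, accepting 224 × 224 × 3 images. The two
scratch backbones reduce the input to a standardised 32 × 32 grayscale
plane (luminance, then 7 × 7 average pooling) before their convolutional
stages; `tiny-test-cnn` is conv(5×5, 8)–pool–conv(3×3, 16)–pool–dense,
about 2,500 parameters. The reduction keeps the published input contract
while making CPU training take seconds, and the information the scratch
pipeline needs — band positions and intensities — survives it.
Standardisation is per image rather than per batch so that a prediction
never depends on what else is in its batch. The pretrained backbone names
(`googlenet`, `resnet18`, `resnet50`) are recognised but raise an
informative error: their weights are not bundled, and shipping a scratch
network under a pretrained architecture's name would be misleading.

Training is mini-batch Adam on softmax cross-entropy. Defaults follow the
fine-tuning regime this design comes from: initial learning rate 10⁻⁴,
batch 128, at most 20 epochs. For the scratch backbones at desk scale the
package's tests and examples use learning rate 3·10⁻³ and batch 32 — a
randomly initialised 2,500-parameter network needs a larger step than a
pretrained feature extractor being fine-tuned. Validation runs once per
epoch (equivalently, every ⌊n_train/batch⌋ iterations); early stopping
halts after 3 checks without a new best validation loss and restores the
best weights, so the restored checkpoint's validation loss equals the
minimum observed — asserted by a test with an adversarial validation set.
Gradients are verified against finite differences. All randomness
(initialisation, shuffling) is governed by the configuration seed, and
probability ties resolve to NTS. No data augmentation is applied.

## Evaluation

With HTS positive: accuracy, sensitivity, specificity, and F1 in its count
form $2TP/(2TP+FP+FN)$, which equals the harmonic mean of precision and
recall. The source text's verbal gloss of F1 ("harmonic mean of
sensitivity and accuracy") is inconsistent with its own count formula; the
count form is canonical here, and `compute_metrics(verbose = TRUE)` reports
the harmonic-mean-of-Se-and-Acc value alongside for transparency. Zero
denominators yield `NaN` with a warning; metrics are computed per
sub-segment image by default, with an optional per-recording majority vote.
Percentages are a rendering concern (`print`, two decimals); the tibbles
hold fractions.

`run_experiment()` composes the whole pipeline per bin, in bin order, and
only renders images some split actually uses; `max_images_per_set` thins
manifests deterministically (label-stratified, evenly spaced) for
desk-scale runs.

## Problem sizes used by the tests

The suite exercises the study-shaped cohort (69 subjects, 974 recordings,
11,688 sub-segments) through preprocessing for the accounting identities,
and uses 20-subject cohorts for the learning checks: drift-free with
half-hour spacing for short-interval label recovery (validation accuracy
above 0.85 across three seeds), and a drifting cohort (1 mmHg/h, gap cycle
spanning 30 min to 30 h, ≤ 300 images per bin) for the degradation trend,
where mean validation accuracy over three seeds is non-increasing from the
< 1 h to the > 24 h bin. These sizes are the package's chosen desk-scale
study conditions; the pipeline itself has no scale-dependent switches.

## Known limitations

* The synthetic generator is phenomenological; none of its parameters are
  fitted to real waveforms, and results on it bound nothing about clinical
  data.
* The scratch backbones are deliberately small; they demonstrate the
  pipeline's correctness and signal, not attainable clinical accuracy.
* Chain extraction is one defensible reading of an under-specified
  procedure; alternative chain rules could shift split accounting.
* The FFT filter bank's circular boundary is marked by the cone of
  influence rather than removed by padding; magnitudes outside the cone
  are edge-affected by construction.
* Per-image normalisation discards absolute PPG amplitude. That is
  intentional (optical amplitude is device- and site-dependent) but means
  any genuinely informative amplitude differences are invisible to the
  classifier.
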