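---
title: "ecgflow: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecgflow: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
what each stage computes, which tunable parameters matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and where the design was genuinely open and a choice had to be
made. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The pipeline at a glance

A record is a single-lead ECG trace in millivolts, 65,536 samples at
128 Hz in the reference geometry (about 8.5 minutes). The pipeline is the
two-step flow of a streaming deployment, emulated locally:

1. **streaming anomaly detection** — consecutive 10-s windows are
   preprocessed, cut into 200-sample chunks, and scored by an LSTM
   autoencoder trained on normal rhythm; windows containing any chunk above
   the reconstruction-error threshold are triggered;
2. **batch classification** — a triggered record is scattering-transformed
   and classified into ARR (arrhythmia), CHF (congestive heart failure), or
   NSR (normal sinus rhythm), alongside rule-based screening alerts from
   hand-engineered interval features.

Cloud services in the original deployment concept (streams, queues,
storage, notification) are represented by function calls and the
filesystem; the computation, not the hosting, is what the package
reproduces.

## Synthetic ECG generator

The generator is the package's data source and ground-truth oracle. Each
beat is a sum of five Gaussian bumps (P, Q, R, S, T) plus a raised-cosine
ST plateau, placed on an RR-interval process; the whole record rides at the
isoelectric (ISO) level. Per-class presets:

* **NSR** — the normal-values column of the reference interval table:
  heart rate 78.06 ± 0.84 bpm, QRS amplitude 0.86 mV, QRS time 0.062 s,
  PR 0.13 s, QT 0.338 s, ST −0.035 mV, ISO −0.294 mV. Regular rhythm:
  RR ~ Normal(60/hr, sd chosen so beat-to-beat rate has the preset sd).
* **ARR** — the same morphology on an irregular RR process: each interval
  is multiplied by `1 + 0.3·u`, `u ~ Uniform(−1, 1)`. Arrhythmia is
  represented purely as rhythm irregularity; this is the synthetic
  convention most directly tied to how an arrhythmic beat perturbs the RR
  series.
* **CHF** — a conventional surrogate, not a clinical claim: reduced
  heart-rate variability (hr sd 0.3 bpm) and a depressed ST level
  (−0.15 mV).
* **TACHY / HYPER** — the tachycardia-detection and hyperglycemia-detection
  columns of the same table, exposed as printed. The physiological basis of
  an ECG-borne glycemia signature is not established; the preset simply
  reproduces the printed interval values without interpretation.

Every record carries its ground-truth fiducials (R peaks, wave extrema,
QRS onset/offset, T offset) as an attribute, so the detectors downstream
are tested by parameter recovery rather than against annotation files.
`add_noise()` adds exactly the artifacts the preprocessing stage removes:
a sub-1-Hz sinusoidal baseline wander and white noise; `generate_dataset()`
defaults to a mild dose of both (0.05 mV wander, 0.01 mV noise).

What the generator does **not** emulate: real QRS morphology variants
(bundle-branch shapes, ectopic beats), muscle-artifact noise, electrode
motion spikes, respiration-coupled amplitude modulation, or inter-patient
variability. Passing tests therefore demonstrate internal correctness and
parameter recovery under the stated conditions, not clinical performance —
the original study's real-data numbers (e.g. 100% three-class accuracy)
live on PhysioNet recordings that this package deliberately does not
require.

Geometric details worth knowing: the T bump has σ = 40 ms with its peak
placed so that the QT offset lands at `QRS onset + QT`; the ST plateau runs
from just after the QRS offset to the T peak with 20% raised-cosine ramps.
The ST measurement window (60–100 ms after the QRS offset) then sits on the
flat part of the plateau, though a small positive bias from the T-wave tail
(a few hundredths of a millivolt) remains — visible in the worked example's
ST estimate.

## Preprocessing

No wavelet transform was available in the environment's R stack, so the
package carries its own periodized orthogonal DWT (pyramid algorithm,
standard db4 coefficients, verified in the tests by perfect reconstruction
and energy preservation). Choices:

* **Boundary handling: periodization** (with reflection padding to a
  multiple of `2^level` for awkward lengths) rather than symmetric
  extension. The transform is then exactly orthogonal, which makes
  detrending an orthogonal projection — applying it twice equals applying
  it once to machine precision — and perfect reconstruction exact. For
  multi-minute records the boundary choice is immaterial.
* **Detrending = approximation-band removal** at level
  `floor(log2(fs)) − 2` (5 at 128 Hz), i.e. the 0–2 Hz band, which contains
  baseline wander but little QRS energy. This keeps the whole preprocessing
  stage inside one transform stack instead of mixing in polynomial fits.
* **Denoising = universal soft threshold** `σ√(2 ln N)` with
  `σ = median(|finest details|)/0.6745`. The rule is the textbook default;
  a fixed threshold is exposed for users who want a manual operating point.

## Hand-engineered features and screening

R peaks come from a Pan–Tompkins-style chain (5–15 Hz band-pass,
derivative, squaring, 150 ms integration, adaptive threshold at half the
running mean of the last eight accepted peak heights, 200 ms refractory).
Delineation is windowed extremum search (Q/S minima within ±80 ms, P
maximum in [−250, −80] ms, T maximum in [120, 450] ms) with
slope-threshold walk-outs for the QRS boundaries and a decay-to-10%
walk-out for the T offset. Windows are conventions chosen inside standard
physiologic ranges; the tests hold them to ±25 ms (R) and ±40 ms (P, T)
against generator ground truth.

Interval definitions: PR = P peak → QRS onset; QT = QRS onset → T offset;
ST level = mean amplitude 60–100 ms after the QRS offset; ISO level = mean
amplitude 80–20 ms before the P peak; QRS amplitude = R height above ISO.
HRV is reported both as SDNN and RMSSD since either convention is common.

Screening thresholds ship as an editable CSV
(`inst/extdata/normal_limits.csv`): tachycardia above 100 bpm (clinical
convention — the source system stores its thresholds manually and does not
print them), irregular rhythm above RMSSD 0.05 s, ST deviation beyond
0.1 mV from the normal −0.035 mV (about three reported standard
deviations). Boundary equality never flags, and flags are monotone in the
offending statistic.

## Wavelet time scattering

The transform is implemented from scratch in the frequency domain:

* Morlet-type analytic band-pass filters
  `ψ̂_λ(f) = g(f−λ) − g(λ)·g(f)` (g Gaussian), which are exactly zero at
  DC; layer 1 tiles 8 wavelets per octave, layer 2 one per octave, from
  0.4 cycles/sample down to the layer cutoffs 1.7/T and 0.75/T. The
  cutoffs are the two frozen constants that set the path count; 1.7/T is
  used rather than the grid-coincident 1.6/T so the filter count does not
  hinge on floating-point rounding.
* Wavelet bandwidth σ(λ) = λ(2^{1/Q} − 1), making adjacent filters cross
  near one standard deviation.
* The scaling filter φ is Gaussian with time std T/4; S0/S1/S2 are
  critically subsampled at hop T by spectral folding, giving
  `signal_length / T` frames (8 for the reference geometry).
* Second-order paths obey the energy-propagation pruning rule
  `λ₂ < 2σ(λ₁)`.
* Each wavelet layer is scaled so the Littlewood–Paley sum
  `|φ̂|² + Σ(|ψ̂(f)|² + |ψ̂(−f)|²)` stays ≤ 1 while φ keeps unit DC gain;
  each propagation layer is then non-expansive, and a constant signal
  passes through S0 unchanged.

With the default geometry this enumerates 1 + 88 + 410 = 499 paths — the
reference feature-set size — and 499×8 ≈ 6.1% of the raw record. The
source description mentions an "invariance scale 15" whose units are
unclear; T is instead fixed at 8192 samples (64 s), the value that yields
the printed 8-frame geometry. Whether the printed 499 includes the
zeroth-order row is likewise unstated; the implementation counts it as
path 1 and documents the breakdown. The tests hold the implementation to a
naive O(N²) time-domain convolution oracle (relative error < 1e-8 on
1,024-sample signals), shift stability (< 10% relative change for circular
shifts up to T/8), and non-expansion on random signal pairs.

Scattering uses Morlet filters even though db4 is named in the source's
scattering discussion: the modulus-of-analytic-filter cascade requires
analytic band-pass filters, the Q = [8,1] geometry matches a Morlet
scattering design, and db4 is retained where it belongs, in the denoising
stage.

## LSTM autoencoder anomaly detection

Architecture per the reference model summary: encoder LSTM (sequence →
final hidden state), dropout 0.2 on the latent, a repeat vector, decoder
LSTM (sequence → sequence), and a time-distributed linear head of width 1;
MAE loss under Adam (the squared-error objective is selectable). Records
are cut into non-overlapping 200-sample chunks; each chunk is min-max
normalized to [0, 1] so reconstruction losses are on a scale comparable
across chunks (the source does not describe its normalization; per-chunk
min-max is the convention adopted here, and it places the computed losses
and thresholds in the same decade as the published 0.0072/0.078 means and
0.068/0.02 cutoffs, which are both exposed as constants).

No deep-learning backend exists in the R environment, so the LSTM cell
(sigmoid input/forget/output gates, tanh candidate and state — the
standard gate equations), backpropagation through time, and the
Adam/SGD-momentum/RMSprop updates are implemented in C++
(Rcpp/Armadillo). Correctness is established by finite-difference gradient
checking during development and, in the suite, by convergence,
determinism, and parameter-shape tests (a 256-unit layer stacks
4×256 = 1024 input-weight gate rows). Two training details matter in
practice and are defaults of the trainer: global gradient-norm clipping at
1.0 and a step learning-rate decay (×0.5 at half the epoch budget, ×0.25
at three quarters); without them the reconstruction objective destabilizes
at useful learning rates. The decoder emits the chunk in reverse order
(flipped back before scoring) — the classic sequence-autoencoder target
reversal that gives the decoder's first step a local dependency on the
encoder's last input; with the forward target the model stalls at the
constant-predictor plateau for far longer.

The threshold is the 0.98 quantile of the normal-chunk error distribution,
mirroring the published observation that 98% of normal losses fall below
the useful cutoff; the printed operating points remain available via
`ae_thresholds()`. The package's reference experiment
(`ae_separation_experiment()`) trains on chunks from six clean synthetic
NSR records (8,192 samples each; 48 hidden units, 250 epochs at learning
rate 0.02, batch 16, dropout 0 — sizes chosen so the experiment runs in
minutes on one CPU) and evaluates chunk-level discrimination of held-out
NSR versus ARR records. Two empirical notes behind that configuration:
the experiment trains with the squared-error objective, whose decaying
gradients fit the waveform faster than MAE's constant-magnitude sign
gradients (scoring is always MAE, so thresholds stay on the published
scale); and latent dropout, kept at 0.2 in the architecture default,
is set to 0 here — at this small hidden size it injects enough noise into
the only information pathway to destroy the normal/anomalous error
separation. The published 98% anomaly accuracy on PhysioNet data is not
reproducible at the desk; the suite instead requires chunk accuracy ≥ 0.9
and an anomaly/normal mean-error ratio ≥ 3 under these synthetic
conditions.

## Classification

* **Split** — stratified 70/30 with largest-remainder rounding; 162
  records give the reference 113/49 arithmetic.
* **mRMR** — greedy MID (relevance − mean redundancy) on 10-bin
  equal-frequency discretizations, with plug-in mutual information. The
  original study used a proprietary ranking routine; MID is the standard
  published scheme and is documented as an approximation. Constant
  features get relevance 0 and sort last.
* **KNN** — from scratch: Euclidean distance, majority vote, ties broken
  by smaller summed distance then lower class index; held equal to an
  exhaustive-search oracle in the tests.
* **Classical families** — delegated to the established backends (rpart,
  MASS::lda, e1071 naive Bayes and SVMs, randomForest with `mtry = p` for
  bagging) behind one interface; libsvm's multi-class machinery is the
  one-against-one decomposition, c(c−1)/2 = 3 binary machines for three
  classes. For these learners each record is summarized by its
  frame-averaged scattering vector, optionally truncated to the top-k
  mRMR features (the reference feature-subset sizes 499/60/20 are all
  reachable through `n_top_features`).
* **LSTM sequence classifier** — each record enters as its 8-frame
  sequence of scattering vectors (the sequence reading of the reference
  architecture: input dimension 499, 300 hidden units, output mode
  "last", fully connected 3 + softmax). Inputs are standardized per path.
  The reference hyper-parameter row (Adam, rate 0.1, 150 epochs,
  mini-batch 1000 — treated as full batch when it exceeds the training
  set) is the config default; the package's own tests train smaller
  problems at rate 0.01 for 30 epochs, which reaches the required ≥ 0.95
  accuracy on well-separated synthetic features in seconds.
* **Metrics** — confusion matrix, per-class and macro precision/recall/F1
  (0/0 reported as 0 with a warning flag), and one-vs-rest ROC/PRC by
  threshold sweep over the unique scores with trapezoidal AUC — exact step
  curves, checked against a Mann–Whitney oracle.

## End-to-end driver and problem sizes

`run_e2e()` chains simulate → preprocess → split → train/calibrate the
autoencoder on NSR training chunks → scattering → mRMR → classifier →
evaluation, writes `metrics.json` and a manifest (seed, split indices,
threshold, versions), and is deterministic end to end given its seed. The
default configuration is deliberately desk-scale — 24/12/12 records of
16,384 samples (eight 2,048-sample frames), a 32-unit autoencoder trained
60 epochs, cubic SVM on the top-60 features — so a full run takes a couple
of minutes; the determinism tests use a further reduced configuration. The
full-scale 162 × 65,536 geometry is exercised where it is the claim itself
(dataset generation and round-trip, the 499 × 8 scattering geometry, the
113/49 split) rather than in every stage.

## Known limitations

* The generator's class differences are deliberately simple; classifiers
  separate the synthetic classes essentially perfectly, so the
  classification tests demonstrate machinery, not clinical difficulty.
* The autoencoder experiment's error ratio depends on training length;
  underfitted models reconstruct everything equally poorly and lose the
  separation (this is the practical reason for the clipping/decay
  defaults).
* WFDB support covers the common single-signal format-16 header/dat pair
  only — enough to read typical exported PhysioNet records, not the full
  format zoo.
* ST-level estimates carry a small positive bias from T-wave overlap (see
  the generator section); screening margins absorb it.
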