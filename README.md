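# ecgflow

An end-to-end, desk-scale pipeline for one-dimensional ECG analysis in R:

* **Preprocessing** — baseline-wander removal and denoising with a
  periodized db4 wavelet pyramid (detrending by approximation-band removal,
  universal soft thresholding of the detail bands).
* **Hand-engineered features** — Pan–Tompkins-style R-peak detection, P/QRS/T
  delineation, the classical interval statistics (heart rate, QRS time and
  amplitude, PR, QT, ST and ISO levels, SDNN/RMSSD), and rule-based
  screening alerts (tachycardia, irregular rhythm, ST deviation) against an
  editable normal-value table.
* **Wavelet time scattering** — a from-scratch 1-D scattering transform
  (Morlet filter banks, modulus nonlinearities, Gaussian low-pass
  averaging): for a 65,536-sample record at 128 Hz with quality factors
  Q = [8, 1] and invariance scale T = 8192 samples it produces a
  499-path × 8-frame representation, a ~94% reduction of the raw signal.
* **Anomaly detection** — an LSTM autoencoder (encoder → dropout → repeat
  vector → decoder → time-distributed linear head, written in
  Rcpp/Armadillo with full backpropagation through time) trained on
  200-sample chunks of normal rhythm with MAE loss; chunks whose
  reconstruction error exceeds a threshold calibrated at the 0.98 quantile
  of the normal error distribution are flagged.
* **Classification** — ARR / CHF / NSR discrimination from scattering
  features: mRMR feature ranking and a from-scratch KNN, classical learners
  (trees, LDA, naive Bayes, one-against-one SVMs, bagged trees) behind a
  uniform interface, an LSTM sequence classifier (300 hidden units, softmax
  head), and full evaluation metrics (confusion, precision/recall/F1,
  one-vs-rest ROC/PRC/AUC).
* **Synthetic data** — a Gaussian-bump ECG generator with per-class rhythm
  presets (regular, tachycardic, irregular, low-HRV/ST-depressed) and
  controllable baseline wander and noise, emitting ground-truth fiducials
  so every detector in the package is testable without external data.

The model at the core of the scattering stage is the usual cascade

```
S0 = x * phi,   S1(j1) = |x * psi_j1| * phi,   S2(j1,j2) = ||x * psi_j1| * psi_j2| * phi
```

with all convolutions circular, critical subsampling at hop T, and
second-order paths kept only when the second filter's center frequency lies
inside the first filter's bandwidth.

## Worked example

```r
library(ecgflow)

# a minute of synthetic normal-sinus ECG at 128 Hz, plus the artifacts the
# preprocessing stage removes
rec   <- generate_record("NSR", n_samples = 60 * 128, fs = 128, seed = 4)
noisy <- add_noise(rec, baseline_amp = 0.2, baseline_freq = 0.3,
                   white_sd = 0.05, seed = 9)
clean <- preprocess_signal(noisy$samples, denoise_config(), fs = 128)

# RMSE to the detrended clean record: 0.19 mV before cleanup, 0.045 after
features <- compute_features(rec, fs = 128)
print(features)
#> <interval_features> 77 beats; HR 77.92 +/- 0.81 bpm; QRS 0.067 s; PR 0.128 s;
#>   QT 0.323 s; ST -0.025 mV; SDNN 0.0080 s; RMSSD 0.0120 s
print(screen(features))
#> <alert_report> no alerts
```

The detected rate (77.9 bpm) recovers the preset's 78.06 bpm, the QT
estimate sits within a few tens of milliseconds of the preset 0.338 s, and
no screening rule fires — as expected for normal rhythm. A tachycardic
preset (119.89 bpm) instead raises the `tachycardia` flag.

Scattering geometry of a full-length record:

```r
bank <- scattering_filter_bank(65536, 128, c(8, 1), 8192)
sf   <- scattering_transform(generate_record("NSR", seed = 1), bank)
dim(sf$coefficients)
#> [1] 499   8
```

The whole study — simulate, preprocess, train the autoencoder on normal
training chunks, calibrate, scatter, rank, classify, evaluate — runs from
one seed:

```r
res <- run_e2e(pipeline_config(seed = 7), out_dir = "run")
res$metrics$accuracy
#> [1] 1
```

(default desk-scale configuration: 48 records of 16,384 samples, cubic SVM
on the top-60 mRMR-ranked scattering features; about 2–3 minutes on one
CPU). `run/metrics.json` and `run/manifest.json` hold the metrics and the
full reproducibility manifest.

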