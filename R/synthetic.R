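# Synthetic ECG generation: Gaussian-bump beat morphology on an RR-interval
# process, with per-class presets tied to the published interval statistics
# (normal / tachycardic / hyperglycemic columns) and synthetic conventions
# for ARR (irregular RR) and CHF (low HRV, ST depression).

#' Per-class generator parameter presets
#'
#' Interval statistics for the `"NSR"` preset come from the normal-values
#' column of the reference feature table (heart rate 78.06 bpm, QRS amplitude
#' 0.86 mV, QRS time 0.062 s, PR 0.13 s, QT 0.338 s, ST -0.035 mV, ISO
#' -0.294 mV). `"TACHY"` and `"HYPER"` expose the tachycardia-detection and
#' hyperglycemia-detection columns as printed, without physiological
#' interpretation. `"ARR"` is the normal morphology on an irregular RR
#' process (jitter fraction 0.3); `"CHF"` is a conventional synthetic
#' surrogate: reduced heart-rate variability and a depressed ST level. These
#' are simulation conventions, not clinical claims.
#'
#' @param label One of `"NSR"`, `"ARR"`, `"CHF"`, `"TACHY"`, `"HYPER"`.
#' @return A `generator_params` list; see [generator_params()].
#' @export
class_preset <- function(label = c("NSR", "ARR", "CHF", "TACHY", "HYPER")) {
  label <- match.arg(label)
  base <- list(
    hr_mean = 78.06, hr_std = 0.84,
    qrs_amp_mean = 0.86, qrs_duration_mean = 0.062,
    pr_interval_mean = 0.13, qt_interval_mean = 0.338,
    st_level_mean = -0.035, iso_level_mean = -0.294,
    rhythm = "regular", rr_jitter_frac = 0)
  p <- switch(label,
    NSR = base,
    ARR = utils::modifyList(base, list(rhythm = "irregular",
                                       rr_jitter_frac = 0.3)),
    CHF = utils::modifyList(base, list(hr_std = 0.3,
                                       st_level_mean = -0.15)),
    TACHY = utils::modifyList(base, list(
      hr_mean = 119.89, hr_std = 0.98, qrs_amp_mean = 1.182,
      qrs_duration_mean = 0.145, pr_interval_mean = 0.13,
      qt_interval_mean = 0.34, st_level_mean = -0.213,
      iso_level_mean = 0.21)),
    HYPER = utils::modifyList(base, list(
      hr_mean = 84.07, hr_std = 0.85, qrs_amp_mean = 0.635,
      qrs_duration_mean = 0.056, pr_interval_mean = 0.141,
      qt_interval_mean = 0.339, st_level_mean = 0.11,
      iso_level_mean = -0.326)))
  do.call(generator_params, p)
}

#' Validate and build synthetic-ECG generator parameters
#'
#' @param hr_mean Mean heart rate, bpm (> 0).
#' @param hr_std Heart-rate standard deviation, bpm (>= 0).
#' @param qrs_amp_mean R-wave amplitude above the isoelectric level, mV.
#' @param qrs_duration_mean QRS onset-to-offset duration, s.
#' @param pr_interval_mean P-peak to QRS-onset interval, s.
#' @param qt_interval_mean QRS-onset to T-offset interval, s.
#' @param st_level_mean ST-segment level, mV (absolute, like the ISO level).
#' @param iso_level_mean Isoelectric baseline level, mV.
#' @param rhythm `"regular"` (RR ~ Normal) or `"irregular"` (multiplicative
#'   uniform RR jitter, the arrhythmia convention).
#' @param rr_jitter_frac Coefficient of RR jitter for irregular rhythm,
#'   in `[0, 1)`.
#' @param seed Optional integer seed stored with the parameters.
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(hr_mean = 78.06, hr_std = 0.84,
                             qrs_amp_mean = 0.86, qrs_duration_mean = 0.062,
                             pr_interval_mean = 0.13, qt_interval_mean = 0.338,
                             st_level_mean = -0.035, iso_level_mean = -0.294,
                             rhythm = c("regular", "irregular"),
                             rr_jitter_frac = 0, seed = NULL) {
  rhythm <- match.arg(rhythm)
  if (hr_mean <= 0) stop("generator_params: hr_mean must be > 0")
  if (hr_std < 0) stop("generator_params: hr_std must be >= 0")
  if (rr_jitter_frac < 0 || rr_jitter_frac >= 1) {
    stop("generator_params: rr_jitter_frac must be in [0, 1)")
  }
  for (nm in c("qrs_duration_mean", "pr_interval_mean", "qt_interval_mean")) {
    if (get(nm) <= 0) stop(sprintf("generator_params: %s must be > 0", nm))
  }
  # one beat's structure must fit between consecutive R peaks; P of the next
  # beat may ride on the T of the current one (physiologic at high rates)
  min_rr <- (60 / hr_mean) * (1 - rr_jitter_frac)
  span_after_r <- qt_interval_mean + qrs_duration_mean / 2
  span_before_r <- pr_interval_mean + qrs_duration_mean / 2 + 0.075
  if (span_after_r >= min_rr || span_before_r >= min_rr) {
    stop("generator_params: intervals imply overlapping beats at this heart rate")
  }
  structure(list(hr_mean = hr_mean, hr_std = hr_std,
                 qrs_amp_mean = qrs_amp_mean,
                 qrs_duration_mean = qrs_duration_mean,
                 pr_interval_mean = pr_interval_mean,
                 qt_interval_mean = qt_interval_mean,
                 st_level_mean = st_level_mean,
                 iso_level_mean = iso_level_mean,
                 rhythm = rhythm, rr_jitter_frac = rr_jitter_frac,
                 seed = seed),
            class = "generator_params")
}

# add one beat (gaussian P/Q/R/S/T bumps + smooth ST plateau) in place.
# t_r: R-peak time (s). Returns the per-beat fiducial times (s).
beat_times <- function(p) {
  d <- p$qrs_duration_mean
  sig_r <- d / 5
  q_t <- -d / 3; s_t <- d / 3
  qrs_on <- -d / 2; qrs_off <- d / 2
  p_t <- qrs_on - p$pr_interval_mean
  t_off <- qrs_on + p$qt_interval_mean
  sig_t <- 0.04
  t_t <- t_off - 2 * sig_t
  list(p = p_t, q = q_t, r = 0, s = s_t, t = t_t,
       qrs_on = qrs_on, qrs_off = qrs_off, t_off = t_off,
       sig_r = sig_r, sig_qs = d / 8, sig_p = 0.025, sig_t = sig_t)
}

#' Generate one synthetic ECG record
#'
#' Beats are a sum of Gaussian bumps (P, Q, R, S, T) plus a raised-cosine ST
#' plateau, placed on an RR process: regular rhythm draws
#' RR ~ Normal(60/hr_mean, sd) with sd chosen so that the beat-to-beat heart
#' rate has standard deviation `hr_std`; irregular rhythm multiplies each RR
#' by `1 + rr_jitter_frac * u`, `u ~ Uniform(-1, 1)`. Ground-truth fiducials
#' (R peaks, per-beat P/Q/S/T extrema, QRS onset/offset, T offset, all in
#' sample indices) are attached as attribute `"fiducials"` so downstream
#' detectors can be oracle-tested without annotation files.
#'
#' @param label Class label for the record; also selects the preset when
#'   `params` is missing (`"NSR"`, `"ARR"`, `"CHF"`; `"UNKNOWN"` uses NSR).
#' @param n_samples Record length in samples (>= fs, i.e. at least 1 s).
#' @param fs Sampling rate, Hz.
#' @param params A [generator_params()] object; defaults to
#'   [class_preset()] for `label`.
#' @param seed Integer seed (overrides `params$seed`).
#' @return An [ecg_record()] with attribute `"fiducials"` (data.frame).
#' @export
generate_record <- function(label = "NSR", n_samples = 65536, fs = 128,
                            params = NULL, seed = NULL) {
  if (is.null(params)) {
    params <- class_preset(if (label %in% c("NSR", "ARR", "CHF")) label else "NSR")
  }
  if (n_samples < fs) stop("generate_record: need at least 1 s of samples")
  seed <- if (!is.null(seed)) seed else if (!is.null(params$seed)) params$seed else 1L
  rng <- local({ set.seed(seed); NULL }) # seed global RNG deterministically
  dur <- n_samples / fs
  rr_base <- 60 / params$hr_mean
  n_beats_max <- ceiling(dur / (rr_base * (1 - params$rr_jitter_frac))) + 3L
  rr <- if (params$rhythm == "regular") {
    # sd of RR from hr_std: hr = 60/rr => sd_rr ~= 60*hr_std/hr^2
    sd_rr <- 60 * params$hr_std / params$hr_mean^2
    stats::rnorm(n_beats_max, rr_base, sd_rr)
  } else {
    rr_base * (1 + params$rr_jitter_frac *
                 stats::runif(n_beats_max, -1, 1))
  }
  rr <- pmax(rr, rr_base * 0.4)
  bt <- beat_times(params)
  # first R far enough in that the P wave (and its ISO window) fits
  t_first <- -bt$p + 0.15
  r_times <- t_first + c(0, cumsum(rr))
  r_times <- r_times[r_times < dur - bt$t_off - 0.1]
  t_grid <- (seq_len(n_samples) - 1) / fs
  x <- rep(params$iso_level_mean, n_samples)
  amp_p <- 0.12; amp_t <- 0.28
  amp_q <- -0.12 * params$qrs_amp_mean
  amp_s <- -0.18 * params$qrs_amp_mean
  add_bump <- function(x, t0, amp, sig) {
    lo <- max(1L, floor((t0 - 4 * sig) * fs) + 1L)
    hi <- min(n_samples, ceiling((t0 + 4 * sig) * fs) + 1L)
    idx <- lo:hi
    x[idx] <- x[idx] + amp * exp(-((t_grid[idx] - t0)^2) / (2 * sig^2))
    x
  }
  st_rel <- params$st_level_mean - params$iso_level_mean
  fid <- vector("list", length(r_times))
  for (b in seq_along(r_times)) {
    tr <- r_times[b]
    x <- add_bump(x, tr + bt$p, amp_p, bt$sig_p)
    x <- add_bump(x, tr + bt$q, amp_q, bt$sig_qs)
    x <- add_bump(x, tr,        params$qrs_amp_mean, bt$sig_r)
    x <- add_bump(x, tr + bt$s, amp_s, bt$sig_qs)
    x <- add_bump(x, tr + bt$t, amp_t, bt$sig_t)
    # smooth ST plateau from just after the QRS offset up to the T peak
    # (raised-cosine 20% edge ramps); the ST measurement window sits on the
    # flat part, and the plateau maximum coincides with the T peak
    st_lo <- tr + bt$qrs_off + 0.01
    st_hi <- tr + bt$t
    if (st_hi > st_lo && abs(st_rel) > 0) {
      lo <- max(1L, floor(st_lo * fs) + 1L)
      hi <- min(n_samples, ceiling((st_hi + 0.2 * (st_hi - st_lo)) * fs) + 1L)
      idx <- lo:hi
      u <- (t_grid[idx] - st_lo) / (st_hi - st_lo)
      w <- ifelse(u < 0, 0,
                  ifelse(u < 0.2, 0.5 - 0.5 * cos(pi * u / 0.2),
                         ifelse(u <= 1, 1,
                                ifelse(u <= 1.2,
                                       0.5 + 0.5 * cos(pi * (u - 1) / 0.2), 0))))
      x[idx] <- x[idx] + st_rel * w
    }
    to_idx <- function(t) as.integer(round(t * fs)) + 1L
    fid[[b]] <- data.frame(
      beat = b,
      p = to_idx(tr + bt$p), q = to_idx(tr + bt$q), r = to_idx(tr),
      s = to_idx(tr + bt$s), t = to_idx(tr + bt$t),
      qrs_on = to_idx(tr + bt$qrs_on), qrs_off = to_idx(tr + bt$qrs_off),
      t_off = to_idx(tr + bt$t_off))
  }
  fiducials <- do.call(rbind, fid)
  rec <- ecg_record(x, fs = fs,
                    label = if (label %in% ECG_LABELS) label else "UNKNOWN",
                    record_id = sprintf("%s_sim", label))
  attr(rec, "fiducials") <- fiducials
  rec
}

#' Add baseline wander and white noise to a record
#'
#' `output = input + baseline_amp * sin(2*pi*baseline_freq*t + phase) +
#' Normal(0, white_sd)`, with the phase and noise drawn deterministically
#' from `seed`.
#'
#' @param record An [ecg_record()].
#' @param baseline_amp Baseline-wander amplitude, mV (>= 0).
#' @param baseline_freq Wander frequency, Hz (must be < 1, the wander band).
#' @param white_sd White-noise standard deviation, mV (>= 0).
#' @param seed Integer seed.
#' @return The noisy [ecg_record()]; ground-truth fiducials are preserved.
#' @export
add_noise <- function(record, baseline_amp = 0.1, baseline_freq = 0.3,
                      white_sd = 0.02, seed = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (baseline_freq >= 1) stop("add_noise: baseline_freq must be < 1 Hz")
  if (baseline_amp < 0 || white_sd < 0) {
    stop("add_noise: amplitudes must be >= 0")
  }
  set.seed(seed)
  n <- length(record$samples)
  t <- (seq_len(n) - 1) / record$fs
  phase <- stats::runif(1, 0, 2 * pi)
  x <- record$samples +
    baseline_amp * sin(2 * pi * baseline_freq * t + phase) +
    (if (white_sd > 0) stats::rnorm(n, 0, white_sd) else 0)
  out <- ecg_record(x, fs = record$fs, label = record$label,
                    record_id = record$record_id)
  attr(out, "fiducials") <- attr(record, "fiducials")
  out
}

#' Generate a labelled synthetic dataset
#'
#' Applies the per-class presets and derives one sub-seed per record from
#' `seed`, so the whole dataset is reproducible from a single integer.
#' Record ids encode class and index (`"ARR_001"`, ...). By default a mild
#' dose of baseline wander and white noise is added (the artifacts the
#' preprocessing stage removes); set both to 0 for clean records.
#'
#' @param n_per_class Named counts, e.g. `c(ARR = 96, CHF = 30, NSR = 36)`
#'   (the class balance of the reference corpus).
#' @param n_samples Samples per record (default 65536).
#' @param fs Sampling rate, Hz (default 128).
#' @param seed Integer master seed.
#' @param baseline_amp,white_sd Noise levels passed to [add_noise()]; both 0
#'   disables the noise stage.
#' @return An [ecg_dataset()]; each record keeps its `"fiducials"` attribute.
#' @export
generate_dataset <- function(n_per_class = c(ARR = 96, CHF = 30, NSR = 36),
                             n_samples = 65536, fs = 128, seed = 1L,
                             baseline_amp = 0.05, white_sd = 0.01) {
  if (any(n_per_class < 1)) stop("generate_dataset: counts must be >= 1")
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% ECG_LABELS)) {
    stop("generate_dataset: n_per_class must be named with class labels")
  }
  records <- list(); k <- 0L
  for (cls in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cls]])) {
      k <- k + 1L
      sub_seed <- (as.integer(seed) %% 100000L) * 10000L + k
      rec <- generate_record(cls, n_samples = n_samples, fs = fs,
                             seed = sub_seed)
      if (baseline_amp > 0 || white_sd > 0) {
        rec <- add_noise(rec, baseline_amp = baseline_amp,
                         white_sd = white_sd, seed = sub_seed + 1L)
      }
      rec$record_id <- sprintf("%s_%03d", cls, i)
      records[[k]] <- rec
    }
  }
  ecg_dataset(records)
}
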