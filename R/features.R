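# Hand-engineered ECG features: Pan-Tompkins style R-peak detection, wave
# delineation by windowed extremum search, interval/HRV statistics, and
# rule-based screening against a stored normal-value table.

#' Detect R peaks (Pan-Tompkins style)
#'
#' Chain: band-pass 5-15 Hz (2nd-order Butterworth, zero phase), derivative,
#' squaring, 150 ms moving-window integration, then peak picking with a
#' 200 ms refractory period and an adaptive threshold (half the running mean
#' of the last eight accepted integrated peak heights). Each accepted peak is
#' refined to the maximum of the band-passed signal within +/- 100 ms.
#'
#' @param signal Numeric vector (mV) or an [ecg_record()].
#' @param fs Sampling rate, Hz (ignored for `ecg_record` input).
#' @return Integer vector of R-peak sample indices (possibly empty; a flat
#'   or degenerate signal yields an empty result, not an error).
#' @export
detect_r_peaks <- function(signal, fs = 128) {
  if (inherits(signal, "ecg_record")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  n <- length(signal)
  if (n < 2 * fs) stop("detect_r_peaks: need at least 2 s of signal")
  if (stats::sd(signal) < 1e-12) return(integer(0))
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, signal - mean(signal)))
  dx <- c(diff(xf), 0)
  sq <- dx^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  refract <- round(0.2 * fs)
  # local maxima of the integrated signal
  is_max <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_max & mwi > 0)
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-mwi[cand])]
  # greedy refractory suppression, then chronological adaptive pass
  keep <- logical(n)
  sel <- integer(0)
  for (i in cand) {
    if (!length(sel) || all(abs(sel - i) > refract)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  thr <- 0.25 * max(mwi[seq_len(min(n, 3 * fs))])
  recent <- numeric(0)
  accepted <- integer(0)
  for (i in sel) {
    if (mwi[i] > thr) {
      accepted <- c(accepted, i)
      recent <- utils::tail(c(recent, mwi[i]), 8L)
      thr <- 0.5 * mean(recent)
    }
  }
  if (!length(accepted)) return(integer(0))
  # refine to the local maximum of the band-passed signal
  half <- round(0.1 * fs)
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, as.integer(i) - half); hi <- min(n, as.integer(i) + half)
    as.integer(lo + which.max(xf[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after refinement
  if (length(peaks) > 1L) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if (p - out[length(out)] > refract) out <- c(out, p)
      else if (signal[p] > signal[out[length(out)]]) out[length(out)] <- p
    }
    peaks <- out
  }
  peaks
}

#' Delineate P, Q, S, T waves and QRS boundaries around each R peak
#'
#' Local extremum search in physiologic windows relative to each R peak:
#' Q = minimum in `[R-80 ms, R]`, S = minimum in `[R, R+80 ms]`,
#' P = maximum in `[R-250 ms, R-80 ms]`, T = maximum in `[R+120 ms, R+450 ms]`.
#' QRS onset/offset by slope-threshold walk-out from Q and S (walk until the
#' absolute slope falls below 5% of the maximum QRS slope, at most 60 ms).
#' The T offset is estimated by walking right from the T peak until the
#' amplitude has decayed to 10% of the peak height above baseline (at most
#' 160 ms). Beats whose windows run off the ends of the signal are dropped.
#'
#' @param signal Numeric vector (mV) or an [ecg_record()].
#' @param fs Sampling rate, Hz.
#' @param r_peaks Integer vector of R-peak indices (from [detect_r_peaks()]).
#' @return A `fiducial_set`: data.frame with columns `beat`, `p`, `q`, `r`,
#'   `s`, `t`, `qrs_on`, `qrs_off`, `t_off` (sample indices), possibly with
#'   zero rows.
#' @export
delineate <- function(signal, fs = 128, r_peaks = NULL) {
  if (inherits(signal, "ecg_record")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks(signal, fs)
  empty <- data.frame(beat = integer(0), p = integer(0), q = integer(0),
                      r = integer(0), s = integer(0), t = integer(0),
                      qrs_on = integer(0), qrs_off = integer(0),
                      t_off = integer(0))
  class(empty) <- c("fiducial_set", "data.frame")
  if (!length(r_peaks)) return(empty)
  n <- length(signal)
  ms <- function(x) max(1L, round(x * fs / 1000))
  rows <- list()
  for (b in seq_along(r_peaks)) {
    r <- r_peaks[b]
    if (r - ms(250) < 1L || r + ms(450) > n) next  # truncated first/last beat
    q_win <- (r - ms(80)):r
    s_win <- r:(r + ms(80))
    p_win <- (r - ms(250)):(r - ms(80))
    t_win <- (r + ms(120)):(r + ms(450))
    q <- q_win[which.min(signal[q_win])]
    s <- s_win[which.min(signal[s_win])]
    p <- p_win[which.max(signal[p_win])]
    tt <- t_win[which.max(signal[t_win])]
    # slope walk-out for QRS boundaries
    slope <- abs(diff(signal[(r - ms(80)):(r + ms(80))]))
    slope_thr <- 0.05 * max(slope)
    on <- q
    lim <- max(1L, q - ms(60))
    while (on > lim && abs(signal[on] - signal[on - 1L]) > slope_thr) on <- on - 1L
    off <- s
    lim <- min(n, s + ms(60))
    while (off < lim && abs(signal[off + 1L] - signal[off]) > slope_thr) off <- off + 1L
    # T offset: decay to 10% of T height above local baseline
    base <- mean(signal[p_win])
    t_h <- signal[tt] - base
    toff <- tt
    lim <- min(n, tt + ms(160))
    while (toff < lim && (signal[toff] - base) > 0.1 * t_h) toff <- toff + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      beat = b, p = p, q = q, r = r, s = s, t = tt,
      qrs_on = on, qrs_off = off, t_off = toff)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$beat <- seq_len(nrow(out))
  class(out) <- c("fiducial_set", "data.frame")
  out
}

#' Compute interval and HRV features from delineated beats
#'
#' Definitions: heart rate from successive RR intervals (bpm); PR = P peak to
#' QRS onset (s); QT = QRS onset to T offset (s); QRS time = onset to offset
#' (s); QRS amplitude = R height minus the isoelectric (ISO) level (mV);
#' ISO level = mean amplitude in `[P-80 ms, P-20 ms]`; ST level = mean
#' amplitude in `[QRS offset + 60 ms, QRS offset + 100 ms]` (mV, absolute
#' like ISO); SDNN = sd of RR; RMSSD = root-mean-square of successive RR
#' differences. With fewer than 2 beats the rate/HRV fields are `NA` while
#' amplitude fields are still computed.
#'
#' @param signal Numeric vector (mV) or an [ecg_record()].
#' @param fs Sampling rate, Hz.
#' @param fiducials A `fiducial_set` from [delineate()].
#' @return An `interval_features` list with fields `hr_mean`, `hr_std`,
#'   `qrs_amp_mean`, `qrs_amp_std`, `qrs_time_mean`, `qrs_time_std`,
#'   `pr_mean`, `pr_std`, `qt_mean`, `qt_std`, `st_mean`, `st_std`,
#'   `iso_mean`, `iso_std`, `hrv_sdnn`, `hrv_rmssd`, `n_beats`.
#' @export
compute_features <- function(signal, fs = 128, fiducials = NULL) {
  if (inherits(signal, "ecg_record")) {
    fs <- signal$fs
    signal <- signal$samples
  }
  if (is.null(fiducials)) fiducials <- delineate(signal, fs)
  f <- fiducials
  n <- length(signal)
  ms <- function(x) max(1L, round(x * fs / 1000))
  win_mean <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(n, max(lo, hi))
    mean(signal[lo:hi])
  }
  nb <- nrow(f)
  iso <- if (nb) vapply(seq_len(nb), function(i)
    win_mean(f$p[i] - ms(80), f$p[i] - ms(20)), numeric(1)) else numeric(0)
  st <- if (nb) vapply(seq_len(nb), function(i)
    win_mean(f$qrs_off[i] + ms(60), f$qrs_off[i] + ms(100)), numeric(1)) else numeric(0)
  qrs_amp <- if (nb) signal[f$r] - iso else numeric(0)
  qrs_time <- if (nb) (f$qrs_off - f$qrs_on) / fs else numeric(0)
  pr <- if (nb) (f$qrs_on - f$p) / fs else numeric(0)
  qt <- if (nb) (f$t_off - f$qrs_on) / fs else numeric(0)
  sd0 <- function(x) if (length(x) >= 2) stats::sd(x) else if (length(x)) 0 else NA_real_
  mn <- function(x) if (length(x)) mean(x) else NA_real_
  if (nb >= 2) {
    rr <- diff(f$r) / fs
    hr <- 60 / rr
    hr_mean <- mean(hr); hr_std <- sd0(hr)
    sdnn <- sd0(rr)
    rmssd <- if (length(rr) >= 2) sqrt(mean(diff(rr)^2)) else 0
  } else {
    hr_mean <- hr_std <- sdnn <- rmssd <- NA_real_
  }
  structure(list(
    hr_mean = hr_mean, hr_std = hr_std,
    qrs_amp_mean = mn(qrs_amp), qrs_amp_std = sd0(qrs_amp),
    qrs_time_mean = mn(qrs_time), qrs_time_std = sd0(qrs_time),
    pr_mean = mn(pr), pr_std = sd0(pr),
    qt_mean = mn(qt), qt_std = sd0(qt),
    st_mean = mn(st), st_std = sd0(st),
    iso_mean = mn(iso), iso_std = sd0(iso),
    hrv_sdnn = sdnn, hrv_rmssd = rmssd,
    n_beats = nb), class = "interval_features")
}

#' @export
print.interval_features <- function(x, ...) {
  cat(sprintf("<interval_features> %d beats; HR %.2f +/- %.2f bpm; QRS %.3f s; PR %.3f s; QT %.3f s; ST %.3f mV; SDNN %.4f s; RMSSD %.4f s\n",
              x$n_beats, x$hr_mean, x$hr_std, x$qrs_time_mean,
              x$pr_mean, x$qt_mean, x$st_mean, x$hrv_sdnn, x$hrv_rmssd))
  invisible(x)
}

#' Default normal-value screening thresholds
#'
#' Shipped as an editable CSV (`inst/extdata/normal_limits.csv`), seeded
#' from the normal column of the reference feature table. Rules:
#' tachycardia when `hr_mean > hr_max` (100 bpm, clinical convention);
#' irregular rhythm when `hrv_rmssd > rmssd_max`; ST deviation when
#' `|st_mean - st_normal| > st_dev_max`.
#'
#' @return Named list of thresholds.
#' @export
normal_limits <- function() {
  path <- system.file("extdata", "normal_limits.csv", package = "ecgflow")
  if (nzchar(path) && file.exists(path)) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    as.list(stats::setNames(tab$value, tab$name))
  } else {
    list(hr_max = 100, rmssd_max = 0.05, st_normal = -0.035, st_dev_max = 0.1)
  }
}

#' Screen interval features against normal-value thresholds
#'
#' Flags: `tachycardia` iff `hr_mean > hr_max`; `irregular_rhythm` iff
#' `hrv_rmssd > rmssd_max`; `st_deviation` iff
#' `|st_mean - st_normal| > st_dev_max`. Boundary equality never flags.
#' `NA` statistics (too few beats) never flag.
#'
#' @param features An `interval_features` object from [compute_features()].
#' @param thresholds Named list as returned by [normal_limits()].
#' @return An `alert_report`: list with `flags` (named logicals),
#'   `triggering_values` (statistic behind each raised flag), and
#'   `thresholds_used`.
#' @export
screen <- function(features, thresholds = normal_limits()) {
  need <- c("hr_max", "rmssd_max", "st_normal", "st_dev_max")
  missing <- setdiff(need, names(thresholds))
  if (length(missing)) {
    stop(sprintf("screen: missing threshold(s): %s",
                 paste(missing, collapse = ", ")))
  }
  gt <- function(x, lim) isTRUE(!is.na(x) && x > lim)
  flags <- list(
    tachycardia = gt(features$hr_mean, thresholds$hr_max),
    irregular_rhythm = gt(features$hrv_rmssd, thresholds$rmssd_max),
    st_deviation = gt(abs(features$st_mean - thresholds$st_normal),
                      thresholds$st_dev_max))
  trig <- list()
  if (flags$tachycardia) trig$tachycardia <- features$hr_mean
  if (flags$irregular_rhythm) trig$irregular_rhythm <- features$hrv_rmssd
  if (flags$st_deviation) trig$st_deviation <- features$st_mean
  structure(list(flags = flags, triggering_values = trig,
                 thresholds_used = thresholds[need]),
            class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  up <- names(Filter(isTRUE, x$flags))
  cat(sprintf("<alert_report> %s\n",
              if (length(up)) paste("ALERT:", paste(up, collapse = ", "))
              else "no alerts"))
  invisible(x)
}
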