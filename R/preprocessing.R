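# Wavelet detrending and denoising. The discrete wavelet transform is
# implemented in-package (periodized orthogonal pyramid algorithm with the
# standard Daubechies filter coefficients): detrending removes the coarsest
# approximation band, denoising soft-thresholds the detail bands.

# Daubechies scaling (low-pass decomposition) filters; db4 is the default
# because its scaling function resembles the QRS morphology.
DB_FILTERS <- list(
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

wavelet_filters <- function(name) {
  h <- DB_FILTERS[[name]]
  if (is.null(h)) {
    stop(sprintf("unknown wavelet '%s' (available: %s)", name,
                 paste(names(DB_FILTERS), collapse = ", ")))
  }
  L <- length(h)
  # quadrature mirror: g[k] = (-1)^k h[L-1-k]  (0-based)
  g <- rev(h) * (-1)^(seq_len(L) - 1)
  list(h = h, g = g)
}

# one level of the periodized DWT: x (even length) -> list(approx, detail)
dwt_step <- function(x, h, g) {
  n <- length(x)
  L <- length(h)
  # y_a[k] = sum_m h[m] x[(2k + m) mod n], downsampled circular correlation
  idx0 <- seq(1L, n, by = 2L)
  a <- numeric(n / 2); d <- numeric(n / 2)
  for (m in seq_len(L)) {
    xi <- x[((idx0 + m - 2L) %% n) + 1L]
    a <- a + h[m] * xi
    d <- d + g[m] * xi
  }
  list(approx = a, detail = d)
}

idwt_step <- function(a, d, h, g) {
  n2 <- length(a)
  n <- 2L * n2
  L <- length(h)
  x <- numeric(n)
  for (m in seq_len(L)) {
    pos <- ((seq(1L, n, by = 2L) + m - 2L) %% n) + 1L
    x[pos] <- x[pos] + h[m] * a + g[m] * d
  }
  x
}

# full periodized pyramid: returns list(details = list(level1..levelJ), approx)
dwt_pyramid <- function(x, wavelet = "db4", level) {
  f <- wavelet_filters(wavelet)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a, f$h, f$g)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(details = details, approx = a)
}

idwt_pyramid <- function(decomp, wavelet = "db4") {
  f <- wavelet_filters(wavelet)
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step(a, decomp$details[[j]], f$h, f$g)
  }
  a
}

#' Wavelet denoising/detrending configuration
#'
#' @param wavelet Wavelet name (`"db4"` default, `"db2"` also available).
#' @param decomposition_level Pyramid depth; default `floor(log2(fs)) - 2`
#'   (5 at 128 Hz, putting the approximation band at 0-2 Hz where baseline
#'   wander lives).
#' @param threshold_rule `"universal"` (`sigma * sqrt(2 log N)` with the
#'   noise scale `sigma` estimated as `MAD(finest details)/0.6745`) or
#'   `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold Threshold in mV for `threshold_rule = "fixed"`.
#' @param detrend_levels How many coarsest approximation bands [detrend()]
#'   removes (default 1: only the final approximation).
#' @param denoise_levels How many of the finest detail bands
#'   [wavelet_denoise()] thresholds (default 2, i.e. above fs/8 — broadband
#'   noise concentrates there while the diagnostic ECG bands stay
#'   untouched).
#' @return A `denoise_config` list.
#' @export
denoise_config <- function(wavelet = "db4", decomposition_level = NULL,
                           threshold_rule = c("universal", "fixed"),
                           fixed_threshold = NULL, detrend_levels = 1L,
                           denoise_levels = 2L) {
  threshold_rule <- match.arg(threshold_rule)
  if (threshold_rule == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold < 0)) {
    stop("denoise_config: fixed rule needs a non-negative fixed_threshold")
  }
  structure(list(wavelet = wavelet,
                 decomposition_level = decomposition_level,
                 threshold_rule = threshold_rule,
                 fixed_threshold = fixed_threshold,
                 detrend_levels = as.integer(detrend_levels),
                 denoise_levels = as.integer(denoise_levels)),
            class = "denoise_config")
}

resolve_level <- function(config, n, fs) {
  level <- config$decomposition_level
  if (is.null(level)) level <- max(1L, floor(log2(fs)) - 2L)
  if (level < 1L || 2^level > n) {
    stop(sprintf("signal too short (%d samples) for decomposition level %d",
                 n, level))
  }
  as.integer(level)
}

# extend x at both ends by a margin of antisymmetric (point-symmetric)
# reflection — continuous in value and slope, so the periodized transform's
# wrap effects stay far from the retained samples — then pad to a multiple
# of 2^level; returns the extended vector and the original sample indices
pad_reflect <- function(x, block, margin = 16L * block) {
  n <- length(x)
  m <- min(margin, n - 1L)
  left <- 2 * x[1] - x[rev(seq_len(m) + 1L)]
  right <- 2 * x[n] - x[n - seq_len(m)]
  ext <- c(left, x, right)
  n_pad <- (block - length(ext) %% block) %% block
  if (n_pad > 0L) {
    tail_ref <- ext[length(ext) - seq_len(min(n_pad, length(ext))) + 1L]
    while (length(tail_ref) < n_pad) {
      tail_ref <- c(tail_ref, rev(tail_ref))[seq_len(n_pad)]
    }
    ext <- c(ext, tail_ref)
  }
  list(x = ext, idx = m + seq_len(n))
}

#' Remove baseline trend by wavelet approximation removal
#'
#' Decomposes the (reflection-extended) signal to `decomposition_level`,
#' zeroes the coarsest `detrend_levels` approximation/detail bands, and
#' reconstructs. Up to boundary effects this is an orthogonal projection,
#' so applying it twice changes almost nothing. Length is preserved; output
#' mean is approximately zero.
#'
#' @param signal Numeric vector (or an [ecg_record()]).
#' @param config A [denoise_config()].
#' @param fs Sampling rate (used only for the default level); taken from the
#'   record when `signal` is an `ecg_record`.
#' @return The detrended signal, same type as the input.
#' @export
detrend <- function(signal, config = denoise_config(), fs = 128) {
  if (inherits(signal, "ecg_record")) {
    out <- signal
    out$samples <- detrend(signal$samples, config, fs = signal$fs)
    return(out)
  }
  if (length(signal) < 2L) stop("detrend: signal too short")
  level <- resolve_level(config, length(signal), fs)
  p <- pad_reflect(signal, 2L^level)
  dec <- dwt_pyramid(p$x, config$wavelet, level)
  dec$approx[] <- 0
  extra <- config$detrend_levels - 1L
  if (extra > 0L) {
    for (j in seq.int(level, by = -1L, length.out = min(extra, level))) {
      dec$details[[j]][] <- 0
    }
  }
  idwt_pyramid(dec, config$wavelet)[p$idx]
}

#' Wavelet denoising by soft thresholding of detail coefficients
#'
#' Soft-thresholds the finest `denoise_levels` detail bands with the
#' universal threshold `sigma * sqrt(2 log N)`,
#' `sigma = MAD(finest details) / 0.6745` (or a fixed threshold), then
#' reconstructs. The approximation band and the coarse (diagnostic) detail
#' bands are untouched, so combine with [detrend()] for baseline removal.
#'
#' @inheritParams detrend
#' @return The denoised signal, same type as the input.
#' @export
wavelet_denoise <- function(signal, config = denoise_config(), fs = 128) {
  if (inherits(signal, "ecg_record")) {
    out <- signal
    out$samples <- wavelet_denoise(signal$samples, config, fs = signal$fs)
    return(out)
  }
  if (length(signal) < 2L) stop("wavelet_denoise: signal too short")
  level <- resolve_level(config, length(signal), fs)
  p <- pad_reflect(signal, 2L^level)
  dec <- dwt_pyramid(p$x, config$wavelet, level)
  thr <- if (config$threshold_rule == "fixed") {
    config$fixed_threshold
  } else {
    sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
    sigma * sqrt(2 * log(length(p$x)))
  }
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  for (j in seq_len(min(config$denoise_levels, level))) {
    dec$details[[j]] <- soft(dec$details[[j]])
  }
  idwt_pyramid(dec, config$wavelet)[p$idx]
}

#' Detrend then denoise in one call
#' @inheritParams detrend
#' @return The cleaned signal, same type as the input.
#' @export
preprocess_signal <- function(signal, config = denoise_config(), fs = 128) {
  wavelet_denoise(detrend(signal, config, fs), config, fs)
}
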