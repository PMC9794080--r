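# 1-D wavelet time scattering, implemented from scratch in the frequency
# domain. A cascade of analytic (Morlet-type) wavelet filter banks and
# modulus nonlinearities, each followed by low-pass averaging with a Gaussian
# scaling filter phi of time support T (the invariance scale) and critical
# subsampling at hop T. Orders: S0 = x * phi; S1(j1) = |x * psi_j1| * phi;
# S2(j1,j2) = ||x * psi_j1| * psi_j2| * phi; second-order paths are pruned
# to frequency-decreasing pairs (energy propagation).
#
# Frozen design constants (these, together with Q = [8, 1] and T = 8192
# samples, give the 499-path geometry on a 65,536-sample record):
#   - highest wavelet center frequency LAM_MAX = 0.4 cycles/sample
#   - wavelet frequency sd sigma(lambda) = lambda * (2^(1/Q) - 1)
#   - layer-k low-frequency cutoffs: 1.7/T (layer 1), 0.75/T (layer 2);
#     both sit strictly between grid frequencies, so the filter counts are
#     robust to rounding
#   - pruning rule: keep (j1, j2) iff lambda_j2 < 2 * sigma(lambda_j1)
SCAT_LAM_MAX <- 0.4
SCAT_MIN_FREQ_FACTORS <- c(1.7, 0.75)
SCAT_PRUNE_FACTOR <- 2

# zero-mean Morlet-type analytic band-pass filter, sampled on the N-point
# frequency grid (cycles/sample in [0, 1))
morlet_hat <- function(N, lambda, sigma) {
  f <- (seq_len(N) - 1) / N
  g <- exp(-((f - lambda)^2) / (2 * sigma^2))
  # subtract a scaled Gaussian at DC so that psi_hat(0) is exactly 0
  kappa <- exp(-lambda^2 / (2 * sigma^2))
  g - kappa * exp(-f^2 / (2 * sigma^2))
}

gauss_lowpass_hat <- function(N, sigma_f) {
  f <- (seq_len(N) - 1) / N
  f <- pmin(f, 1 - f)  # symmetric low-pass over the circle
  exp(-f^2 / (2 * sigma_f^2))
}

# center-frequency grids per layer (cycles/sample, descending)
scat_centers <- function(Q, min_freq, lam_max = SCAT_LAM_MAX) {
  lam <- lam_max / (2^(1 / Q))^(0:400)
  lam[lam >= min_freq]
}

# independent of the FilterBank object: enumerate paths from the layer
# center-frequency grids and the pruning rule
scat_enumerate_paths <- function(lam1, sig1, lam2,
                                 prune_factor = SCAT_PRUNE_FACTOR) {
  paths <- list(data.frame(order = 0L, j1 = NA_integer_, j2 = NA_integer_,
                           freq1 = NA_real_, freq2 = NA_real_))
  for (i in seq_along(lam1)) {
    paths[[length(paths) + 1L]] <-
      data.frame(order = 1L, j1 = i, j2 = NA_integer_,
                 freq1 = lam1[i], freq2 = NA_real_)
  }
  for (i in seq_along(lam1)) {
    for (k in seq_along(lam2)) {
      if (lam2[k] < prune_factor * sig1[i]) {
        paths[[length(paths) + 1L]] <-
          data.frame(order = 2L, j1 = i, j2 = k,
                     freq1 = lam1[i], freq2 = lam2[k])
      }
    }
  }
  out <- do.call(rbind, paths)
  # order: S0, then S1 by descending center frequency, then S2 lexicographic
  out[order(out$order, out$j1, out$j2, na.last = FALSE), , drop = FALSE]
}

#' Build the wavelet time scattering filter bank
#'
#' Morlet-type analytic band-pass filters tiled logarithmically with
#' `quality_factors[1]` wavelets per octave in the first layer and
#' `quality_factors[2]` in the second, from 0.4 cycles/sample down to the
#' layer's low-frequency cutoff, plus a Gaussian scaling filter `phi` whose
#' time support is the invariance scale `T`. All filters are defined on the
#' `signal_length`-point frequency grid. The wavelet layers are normalized so
#' the Littlewood-Paley sum `|phi|^2 + sum |psi|^2` stays at or below 1
#' (making every propagation layer non-expansive) while `phi` keeps unit DC
#' gain.
#'
#' With the defaults (65,536 samples, 128 Hz, Q = `c(8, 1)`, T = 8192) the
#' bank yields 499 scattering paths (1 zeroth order + 88 first order + 410
#' second order) and 8 frames per record.
#'
#' @param signal_length Record length in samples; must be a power of two.
#' @param fs Sampling rate, Hz (metadata; the geometry is in samples).
#' @param quality_factors Wavelets per octave for the two layers.
#' @param invariance_scale Averaging scale T in samples; a power of two
#'   dividing `signal_length`.
#' @param max_order Highest scattering order (2; 0 or 1 also allowed).
#' @return A `scattering_filter_bank`: list with the frequency-domain
#'   filters, the path table, and the output geometry (`n_paths`,
#'   `n_frames`, `frame_hop`).
#' @export
scattering_filter_bank <- function(signal_length = 65536, fs = 128,
                                   quality_factors = c(8, 1),
                                   invariance_scale = 8192,
                                   max_order = 2) {
  N <- signal_length; T <- invariance_scale
  is_pow2 <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
  if (!is_pow2(N)) stop("scattering_filter_bank: signal_length must be a power of two")
  if (!is_pow2(T) || N %% T != 0) {
    stop("scattering_filter_bank: invariance_scale must be a power of two dividing signal_length")
  }
  if (length(quality_factors) != 2 || any(quality_factors < 1)) {
    stop("scattering_filter_bank: quality_factors must be two values >= 1")
  }
  Q1 <- quality_factors[1]; Q2 <- quality_factors[2]
  lam1 <- scat_centers(Q1, SCAT_MIN_FREQ_FACTORS[1] / T)
  lam2 <- scat_centers(Q2, SCAT_MIN_FREQ_FACTORS[2] / T)
  sig1 <- lam1 * (2^(1 / Q1) - 1)
  sig2 <- lam2 * (2^(1 / Q2) - 1)
  # phi: time std T/4 samples => frequency sd 1/(2*pi*(T/4)) cycles/sample
  sigma_phi <- 2 / (pi * T)
  phi <- gauss_lowpass_hat(N, sigma_phi)
  psi1 <- vapply(seq_along(lam1),
                 function(i) morlet_hat(N, lam1[i], sig1[i]), numeric(N))
  psi2 <- vapply(seq_along(lam2),
                 function(i) morlet_hat(N, lam2[i], sig2[i]), numeric(N))
  # Littlewood-Paley normalization per layer, keeping phi at unit DC gain:
  # scale each layer's psi set by 1/b so that
  # |phi(f)|^2 + (1/b^2) * sum_i (|psi_i(f)|^2 + |psi_i(-f)|^2) <= 1 for all f
  lp_b <- function(psi) {
    s <- rowSums(psi^2)
    s <- s + rev(s)                       # analytic filters: add mirrored band
    max(sqrt(max(s / pmax(1 - phi^2, 1e-12))), 1)
  }
  psi1 <- psi1 / lp_b(psi1)
  psi2 <- psi2 / lp_b(psi2)
  # pruning uses the unnormalized (geometric) bandwidths sig1
  paths <- scat_enumerate_paths(lam1, sig1, lam2)
  if (max_order < 2) paths <- paths[paths$order <= max_order, , drop = FALSE]
  rownames(paths) <- NULL
  structure(list(
    signal_length = N, fs = fs, quality_factors = quality_factors,
    invariance_scale = T, max_order = max_order,
    centers1 = lam1, sigmas1 = sig1, centers2 = lam2, sigmas2 = sig2,
    psi1 = psi1, psi2 = psi2, phi = phi,
    paths = paths, n_paths = nrow(paths),
    n_frames = N %/% T, frame_hop = T), class = "scattering_filter_bank")
}

#' @export
print.scattering_filter_bank <- function(x, ...) {
  cat(sprintf("<scattering_filter_bank> N=%d @ %g Hz, Q=[%s], T=%d: %d paths (%d order-1, %d order-2) x %d frames\n",
              x$signal_length, x$fs,
              paste(x$quality_factors, collapse = ","), x$invariance_scale,
              x$n_paths, sum(x$paths$order == 1), sum(x$paths$order == 2),
              x$n_frames))
  invisible(x)
}

# smooth with phi (frequency domain Z = X * phi_hat) and critically subsample
# at hop T: fold the spectrum to M = N/T bins and take a length-M inverse FFT
smooth_subsample <- function(X, phi, M) {
  Z <- X * phi
  N <- length(Z)
  Zf <- rowSums(matrix(Z, nrow = M))
  Re(stats::fft(Zf, inverse = TRUE)) / N
}

#' Apply the wavelet time scattering transform to one signal
#'
#' @param signal Numeric vector of length `bank$signal_length`, or an
#'   [ecg_record()].
#' @param bank A [scattering_filter_bank()].
#' @return A `scattering_features` object: list with `coefficients`
#'   (`n_paths x n_frames` matrix, rows ordered S0, then S1 by descending
#'   center frequency, then S2 lexicographically), `paths` (the bank's path
#'   table), and `frame_hop`.
#' @export
scattering_transform <- function(signal, bank) {
  if (inherits(signal, "ecg_record")) signal <- signal$samples
  stopifnot(inherits(bank, "scattering_filter_bank"))
  N <- bank$signal_length
  if (length(signal) != N) {
    stop(sprintf("scattering_transform: signal length %d != bank signal_length %d",
                 length(signal), N))
  }
  M <- bank$n_frames
  X <- stats::fft(signal)
  coef <- matrix(0, nrow = bank$n_paths, ncol = M)
  coef[1, ] <- smooth_subsample(X, bank$phi, M)
  if (bank$max_order >= 1) {
    n1 <- length(bank$centers1)
    order1_rows <- which(bank$paths$order == 1L)
    order2 <- bank$paths[bank$paths$order == 2L, , drop = FALSE]
    row_of_o2 <- which(bank$paths$order == 2L)
    for (i in seq_len(n1)) {
      u1 <- Mod(stats::fft(X * bank$psi1[, i], inverse = TRUE)) / N
      U1 <- stats::fft(u1)
      coef[order1_rows[i], ] <- smooth_subsample(U1, bank$phi, M)
      if (bank$max_order >= 2) {
        ks <- order2$j2[order2$j1 == i]
        rows <- row_of_o2[order2$j1 == i]
        for (m in seq_along(ks)) {
          u2 <- Mod(stats::fft(U1 * bank$psi2[, ks[m]], inverse = TRUE)) / N
          coef[rows[m], ] <- smooth_subsample(stats::fft(u2), bank$phi, M)
        }
      }
    }
  }
  structure(list(coefficients = coef, paths = bank$paths,
                 frame_hop = bank$frame_hop),
            class = "scattering_features")
}

#' @export
print.scattering_features <- function(x, ...) {
  cat(sprintf("<scattering_features> %d paths x %d frames (hop %d samples)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$frame_hop))
  invisible(x)
}

#' Scattering features for a whole dataset
#'
#' Stacks per-record scattering coefficient matrices into an
#' `n_paths x n_frames x n_records` array (for the default bank and 113
#' records this is the 499 x 8 x 113 training tensor).
#'
#' @param dataset An [ecg_dataset()]; all records must have
#'   `bank$signal_length` samples.
#' @param bank A [scattering_filter_bank()].
#' @param verbose Print progress every 10 records.
#' @return List with `tensor` (3-D array, record ids on the third dimname),
#'   `paths`, and `labels`.
#' @export
feature_tensor <- function(dataset, bank, verbose = FALSE) {
  stopifnot(inherits(dataset, "ecg_dataset"))
  lens <- vapply(dataset$records, function(r) length(r$samples), integer(1))
  if (any(lens != bank$signal_length)) {
    stop("feature_tensor: all records must match bank$signal_length")
  }
  n <- length(dataset$records)
  tensor <- array(0, dim = c(bank$n_paths, bank$n_frames, n),
                  dimnames = list(NULL, NULL, dataset_ids(dataset)))
  for (i in seq_len(n)) {
    tensor[, , i] <- scattering_transform(dataset$records[[i]], bank)$coefficients
    if (verbose && i %% 10 == 0) message(sprintf("scattering %d/%d", i, n))
  }
  list(tensor = tensor, paths = bank$paths, labels = dataset_labels(dataset))
}

#' Flatten a scattering tensor to per-frame feature vectors
#'
#' Each of the `n_frames` columns of every record becomes one observation of
#' length `n_paths`, the per-frame view used when training sequence models
#' frame by frame.
#'
#' @param tensor `n_paths x n_frames x n_records` array.
#' @return List with `X` (`(n_frames * n_records) x n_paths` matrix) and
#'   `record` (record index per row).
#' @export
flatten_frames <- function(tensor) {
  d <- dim(tensor)
  X <- t(matrix(tensor, nrow = d[1]))
  list(X = X, record = rep(seq_len(d[3]), each = d[2]))
}

# per-record feature matrix for classical learners: mean over frames
record_feature_matrix <- function(tensor) {
  t(apply(tensor, c(1, 3), mean))
}
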