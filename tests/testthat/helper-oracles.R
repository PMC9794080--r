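# Independent oracles: written from first principles, deliberately avoiding
# the implementation paths they check.

# direct O(N^2) circular convolution
naive_circ_conv <- function(x, h) {
  N <- length(x)
  out <- complex(length.out = N)
  for (n in seq_len(N)) {
    idx <- ((n - seq_len(N)) %% N) + 1
    out[n] <- sum(x * h[idx])
  }
  out
}

# time-domain scattering oracle over a bank's filters
naive_scattering <- function(x, bank) {
  N <- bank$signal_length
  M <- bank$n_frames
  filt_time <- function(hat) stats::fft(hat + 0i, inverse = TRUE) / N
  phi_t <- filt_time(bank$phi)
  smooth <- function(u) {
    Re(naive_circ_conv(u, phi_t))[seq(1, N, by = bank$frame_hop)]
  }
  co <- matrix(0, bank$n_paths, M)
  co[1, ] <- smooth(x)
  p <- bank$paths
  u1_cache <- list()
  for (r in seq_len(nrow(p))[-1]) {
    j1 <- p$j1[r]
    key <- as.character(j1)
    if (is.null(u1_cache[[key]])) {
      u1_cache[[key]] <- Mod(naive_circ_conv(x, filt_time(bank$psi1[, j1])))
    }
    u1 <- u1_cache[[key]]
    if (p$order[r] == 1) {
      co[r, ] <- smooth(u1)
    } else {
      u2 <- Mod(naive_circ_conv(u1, filt_time(bank$psi2[, p$j2[r]])))
      co[r, ] <- smooth(u2)
    }
  }
  co
}

# path count straight from the frozen design rules
enumerate_paths_bruteforce <- function(T, Q1 = 8, Q2 = 1, lam_max = 0.4,
                                       fmin1 = 1.7 / T, fmin2 = 0.75 / T) {
  l1 <- c(); f <- lam_max
  while (f >= fmin1) { l1 <- c(l1, f); f <- f / 2^(1 / Q1) }
  l2 <- c(); f <- lam_max
  while (f >= fmin2) { l2 <- c(l2, f); f <- f / 2^(1 / Q2) }
  n2 <- 0L
  for (a in l1) n2 <- n2 + sum(l2 < 2 * a * (2^(1 / Q1) - 1))
  1L + length(l1) + n2
}

# exhaustive-search KNN with the documented tie-break chain
oracle_knn <- function(trX, trY, teX, k) {
  lev <- levels(trY)
  vapply(seq_len(nrow(teX)), function(i) {
    d <- sqrt(colSums((t(trX) - teX[i, ])^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    v <- table(factor(trY[nn], levels = lev))
    top <- names(v)[v == max(v)]
    if (length(top) > 1) {
      ss <- vapply(top, function(cl) sum(d[nn[trY[nn] == cl]]), numeric(1))
      top <- top[ss == min(ss)]
    }
    top[1]
  }, character(1))
}

# plug-in mutual information by direct double loop
oracle_mi <- function(a, b) {
  a <- as.integer(as.factor(a)); b <- as.integer(as.factor(b))
  n <- length(a); mi <- 0
  for (va in unique(a)) for (vb in unique(b)) {
    pab <- sum(a == va & b == vb) / n
    if (pab > 0) {
      mi <- mi + pab * log(pab / (sum(a == va) / n * sum(b == vb) / n))
    }
  }
  mi
}

# reduced end-to-end configuration used by determinism checks
small_e2e_config <- function(seed = 7L) {
  pipeline_config(
    n_per_class = c(ARR = 6, CHF = 4, NSR = 6),
    n_samples = 4096, invariance_scale = 512,
    ae = ae_config(hidden_units = 12L, dropout_rate = 0, epochs = 6L,
                   batch_size = 64L, learn_rate = 0.01),
    classifier = "svm_cubic", n_top_features = 30L, seed = seed)
}
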