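# The scattering transform is the package's own frequency-domain
# implementation; the reference here is a naive O(N^2) time-domain
# convolution oracle plus an independent path enumerator.

# brute-force path count straight from the frozen design rules, written
# independently of the bank constructor
test_that("the default bank yields the 499 x 8 feature geometry", {
  bank <- scattering_filter_bank(65536, 128, c(8, 1), 8192)
  expect_equal(bank$n_paths, 499L)
  expect_equal(bank$n_frames, 8L)
  expect_equal(sum(bank$paths$order == 0), 1L)
  sf <- scattering_transform(numeric(65536), bank)
  expect_equal(dim(sf$coefficients), c(499L, 8L))
  expect_true(all(sf$coefficients == 0))
  # matches the independent enumerator, and the size-reduction bound
  expect_equal(bank$n_paths, enumerate_paths_bruteforce(8192))
  expect_lte(bank$n_paths * bank$n_frames, 0.07 * 65536)
})

test_that("path counts equal brute-force enumeration on small banks", {
  for (geom in list(c(1024, 256), c(2048, 256), c(4096, 1024))) {
    bank <- scattering_filter_bank(geom[1], 128, c(8, 1), geom[2])
    expect_equal(bank$n_paths, enumerate_paths_bruteforce(geom[2]),
                 info = paste(geom, collapse = "/"))
  }
})

test_that("wavelets are zero mean and pairing obeys the pruning rule", {
  bank <- small_bank()
  expect_lt(max(abs(bank$psi1[1, ])), 1e-6)
  expect_lt(max(abs(bank$psi2[1, ])), 1e-6)
  o2 <- bank$paths[bank$paths$order == 2, ]
  expect_true(all(o2$freq2 < 2 * bank$sigmas1[o2$j1]))
  # order-0 first, order-1 by descending frequency
  expect_equal(bank$paths$order[1], 0L)
  f1 <- bank$paths$freq1[bank$paths$order == 1]
  expect_true(all(diff(f1) < 0))
})

test_that("constant signals produce only the zeroth-order path", {
  bank <- small_bank()
  sf <- scattering_transform(rep(2.5, 1024), bank)
  expect_equal(unname(sf$coefficients[1, ]), rep(2.5, 4), tolerance = 1e-8)
  expect_lt(max(abs(sf$coefficients[-1, ])), 1e-10)
})

test_that("the FFT implementation matches the naive convolution oracle", {
  bank <- scattering_filter_bank(1024, 128, c(2, 1), 256)
  set.seed(5)
  for (sig in list(rnorm(1024),
                   generate_record("NSR", 1024, 128, seed = 2)$samples)) {
    fast <- scattering_transform(sig, bank)$coefficients
    slow <- naive_scattering(sig, bank)
    expect_lt(norm(fast - slow, "F") / norm(slow, "F"), 1e-8)
  }
})

test_that("scattering is stable to shifts up to T/8", {
  N <- 8192; T <- 1024
  bank <- scattering_filter_bank(N, 128, c(8, 1), T)
  x <- generate_record("NSR", N, 128, seed = 11)$samples
  Sx <- scattering_transform(x, bank)$coefficients
  for (s in c(T / 32, T / 8)) {
    xs <- c(x[(s + 1):N], x[1:s])
    Ss <- scattering_transform(xs, bank)$coefficients
    expect_lt(norm(Ss - Sx, "F") / norm(Sx, "F"), 0.1)
  }
})

test_that("the transform is non-expansive on random pairs", {
  N <- 2048
  bank <- scattering_filter_bank(N, 128, c(8, 1), 256)
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(N); b <- a + rnorm(N, 0, 0.3)
    Sa <- scattering_transform(a, bank)$coefficients
    Sb <- scattering_transform(b, bank)$coefficients
    expect_lte(norm(Sa - Sb, "F") / sqrt(sum((a - b)^2)), 1.05)
  }
})

test_that("feature tensors stack records and track permutations", {
  d <- generate_dataset(c(NSR = 2, ARR = 1), n_samples = 1024, seed = 4,
                        baseline_amp = 0, white_sd = 0)
  bank <- small_bank()
  ft <- feature_tensor(d, bank)
  expect_equal(dim(ft$tensor), c(bank$n_paths, 4L, 3L))
  expect_equal(ft$labels, c("NSR", "NSR", "ARR"))
  # single record keeps a singleton last axis
  d1 <- ecg_dataset(d$records[1])
  expect_equal(dim(feature_tensor(d1, bank)$tensor)[3], 1L)
  # permuting records permutes only the last axis
  dp <- ecg_dataset(d$records[c(3, 1, 2)])
  ftp <- feature_tensor(dp, bank)
  expect_equal(ftp$tensor[, , 1], ft$tensor[, , 3])
  expect_equal(ftp$tensor[, , 2], ft$tensor[, , 1])
  # flattened per-frame view
  fl <- flatten_frames(ft$tensor)
  expect_equal(dim(fl$X), c(12L, bank$n_paths))
  expect_equal(fl$X[5, ], ft$tensor[, 1, 2])
})

test_that("invalid geometries are rejected", {
  expect_error(scattering_filter_bank(1000, 128, c(8, 1), 256), "power of two")
  expect_error(scattering_filter_bank(1024, 128, c(8, 1), 300), "power of two")
  bank <- small_bank()
  expect_error(scattering_transform(numeric(512), bank), "length")
  d <- generate_dataset(c(NSR = 1), n_samples = 2048, seed = 1)
  expect_error(feature_tensor(d, bank), "signal_length")
})
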