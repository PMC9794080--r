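test_that("generated NSR records recover the preset heart rate", {
  rec <- generate_record("NSR", n_samples = 60 * fs_default, seed = 4)
  gt <- attr(rec, "fiducials")
  true_hr <- 60 / mean(diff(gt$r) / fs_default)
  expect_lt(abs(true_hr - 78.06), 1)
  # empirical HR converges within 2*hr_std at 60 s
  expect_lt(abs(true_hr - 78.06), 2 * 0.84)
})

test_that("regular rhythm at 60 bpm gives equally spaced peaks", {
  p <- generator_params(hr_mean = 60, hr_std = 0, rhythm = "regular")
  rec <- generate_record("NSR", n_samples = 10 * fs_default, params = p,
                         seed = 1)
  r <- attr(rec, "fiducials")$r
  expect_true(length(r) %in% c(10L, 11L))
  spacing <- diff(r)
  expect_lte(max(spacing) - min(spacing), 1)
})

test_that("generation is deterministic given the seed", {
  a <- generate_record("ARR", n_samples = 4096, seed = 42)
  b <- generate_record("ARR", n_samples = 4096, seed = 42)
  expect_identical(a$samples, b$samples)
  expect_identical(attr(a, "fiducials"), attr(b, "fiducials"))
  d1 <- generate_dataset(c(NSR = 2, ARR = 2), n_samples = 2048, seed = 9)
  d2 <- generate_dataset(c(NSR = 2, ARR = 2), n_samples = 2048, seed = 9)
  expect_identical(dataset_matrix_for_test(d1), dataset_matrix_for_test(d2))
})

test_that("irregular rhythm has much larger RR variability than regular", {
  cv <- function(rec) {
    rr <- diff(attr(rec, "fiducials")$r)
    stats::sd(rr) / mean(rr)
  }
  ratios <- vapply(1:3, function(s) {
    cv(generate_record("ARR", n_samples = 60 * fs_default, seed = s)) /
      cv(generate_record("NSR", n_samples = 60 * fs_default, seed = s))
  }, numeric(1))
  expect_true(all(ratios >= 3))
})

test_that("ground-truth fiducials always lie inside the record", {
  for (s in 1:4) {
    for (cls in c("NSR", "ARR", "CHF")) {
      rec <- generate_record(cls, n_samples = 2048, seed = s)
      gt <- attr(rec, "fiducials")
      expect_true(all(gt >= 1))
      expect_true(all(gt[, c("p", "q", "r", "s", "t", "qrs_on",
                             "qrs_off", "t_off")] <= length(rec$samples)))
      expect_true(all(diff(gt$r) > 0))
      expect_true(all(gt$qrs_on < gt$qrs_off))
    }
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(hr_mean = -5), "hr_mean")
  expect_error(generator_params(rr_jitter_frac = 1), "rr_jitter_frac")
  # intervals too long for the beat period
  expect_error(generator_params(hr_mean = 150, qt_interval_mean = 0.45),
               "overlapping")
  expect_error(generate_record("NSR", n_samples = 64), "1 s")
})

test_that("add_noise is additive, sinusoidal, and seeded", {
  rec <- generate_record("NSR", n_samples = 2048, seed = 2)
  same <- add_noise(rec, baseline_amp = 0, white_sd = 0, seed = 1)
  expect_equal(same$samples, rec$samples)

  wander <- add_noise(rec, baseline_amp = 0.5, baseline_freq = 0.3,
                      white_sd = 0, seed = 3)
  diffsig <- wander$samples - rec$samples
  # pure sinusoid of the stated frequency: fit amplitude/phase exactly
  t <- (seq_along(diffsig) - 1) / rec$fs
  fitted <- stats::lm(diffsig ~ sin(2 * pi * 0.3 * t) + cos(2 * pi * 0.3 * t))
  expect_lt(max(abs(stats::residuals(fitted))), 1e-9)
  amp <- sqrt(sum(stats::coef(fitted)[2:3]^2))
  expect_equal(amp, 0.5, tolerance = 1e-9)

  n1 <- add_noise(rec, baseline_amp = 0.2, white_sd = 0.05, seed = 7)
  n2 <- add_noise(rec, baseline_amp = 0.2, white_sd = 0.05, seed = 7)
  expect_identical(n1$samples, n2$samples)
  expect_error(add_noise(rec, baseline_freq = 2), "baseline_freq")
})

test_that("generate_dataset encodes classes in ids and honours counts", {
  d <- generate_dataset(c(NSR = 1), n_samples = 1024, seed = 3)
  expect_equal(length(d$records), 1L)
  expect_equal(d$records[[1]]$label, "NSR")
  expect_match(d$records[[1]]$record_id, "^NSR_001$")
  expect_error(generate_dataset(c(NSR = 0)), "counts")
  expect_error(generate_dataset(c(5, 5)), "named")
})
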