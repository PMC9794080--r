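test_that("chunking arithmetic and normalization contracts hold", {
  expect_equal(ncol(chunk_signal(numeric(65536), 200)), 327L)
  x <- rnorm(400)
  ch <- chunk_signal(x, 200, normalize = FALSE)
  expect_equal(ncol(ch), 2L)
  expect_equal(as.numeric(ch), x)  # concatenation reproduces the signal
  expect_equal(ncol(chunk_signal(rnorm(399), 200)), 1L)
  expect_error(chunk_signal(rnorm(100), 200), "shorter")

  chn <- chunk_signal(x, 200, normalize = TRUE)
  expect_true(all(chn >= 0 & chn <= 1))
  # inversion from stored offset/scale
  inv <- sweep(sweep(chn, 2, attr(chn, "scale"), "*"), 2,
               attr(chn, "offset"), "+")
  expect_equal(as.numeric(inv), x, tolerance = 1e-12)
  # constant chunk maps to zeros with unit scale
  cc <- chunk_signal(rep(5, 200), 200)
  expect_true(all(cc == 0))
  expect_equal(attr(cc, "scale"), 1)
})

test_that("the autoencoder reports its architecture honestly", {
  m <- build_ae(ae_config(chunk_len = 8, hidden_units = 256, seed = 1))
  # 4 stacked gates: 1024 input-weight rows for 256 units
  expect_equal(dim(m$weights$enc$W), c(1024L, 1L))
  expect_equal(dim(m$weights$enc$U), c(1024L, 256L))
  expect_equal(dim(m$weights$Wo), c(1L, 256L))
  small <- build_ae(ae_config(chunk_len = 4, hidden_units = 1, seed = 2))
  y <- ecgflow:::.cpp_ae_predict(small$weights, matrix(rnorm(8), 4, 2))
  expect_true(all(is.finite(y)))
  expect_equal(dim(y), c(4L, 2L))
})

test_that("reconstruction error is MAE with exact degenerate values", {
  chunks <- matrix(1, 4, 3)
  identity_model <- function(ch) ch
  expect_equal(reconstruction_error(identity_model, chunks), rep(0, 3))
  zero_model <- function(ch) ch * 0
  expect_equal(reconstruction_error(zero_model, chunks), rep(1, 3))
  expect_error(reconstruction_error(function(ch) ch[1:2, ], chunks),
               "shape")
})

test_that("training reduces loss and is reproducible", {
  # constant-valued chunks are representable by output biases alone; the
  # squared-error objective converges to the exact fit (the MAE objective
  # oscillates around it at the learning-rate scale)
  X <- matrix(0.7, 30, 20)
  cfg <- ae_config(chunk_len = 30, hidden_units = 8, dropout_rate = 0,
                   epochs = 50, batch_size = 10, learn_rate = 0.05,
                   loss = "mse", seed = 5)
  m <- train_ae(build_ae(cfg), X)
  expect_lt(utils::tail(m$history, 1), 1e-3)

  chunks <- record_chunks("NSR", seeds = 1:2, n_samples = 4096)
  cfg2 <- ae_config(hidden_units = 12, epochs = 8, batch_size = 20,
                    learn_rate = 5e-3, seed = 9)
  m1 <- train_ae(build_ae(cfg2), chunks)
  expect_lt(utils::tail(m1$history, 1), m1$history[1])
  m2 <- train_ae(build_ae(cfg2), chunks)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$enc$W, m2$weights$enc$W)
})

test_that("threshold calibration matches closed forms", {
  set.seed(1)
  u <- stats::runif(5000)
  expect_equal(calibrate_threshold(u, 0.98), 0.98, tolerance = 0.01)
  expect_equal(calibrate_threshold(rep(0.3, 50)), 0.3)
  expect_error(calibrate_threshold(stats::runif(5)), "at least 10")
  # flagged fraction of the calibration set <= 1 - q + 1/n
  thr <- calibrate_threshold(u, 0.98)
  expect_lte(mean(u > thr), 1 - 0.98 + 1 / length(u))
})

test_that("detection flags exactly the chunks above threshold", {
  scorer <- function(ch) ch * 0  # error == chunk mean |x|
  x <- c(rep(0.0072, 200), rep(0.078, 200))
  res <- detect_anomalies(scorer, x, threshold = 0.068, chunk_len = 200,
                          normalize = FALSE)
  # the two published mean losses against the published 0.068 cutoff
  expect_equal(unname(res$flags), c(FALSE, TRUE))
  expect_true(res$record_flag)
  expect_equal(res$per_chunk_error, c(0.0072, 0.078))

  below <- detect_anomalies(scorer, rep(0.01, 400), threshold = 0.068,
                            chunk_len = 200, normalize = FALSE)
  expect_false(below$record_flag)
  expect_error(detect_anomalies(scorer, x, threshold = -1), "threshold")
})

test_that("raising the threshold never increases the flag count", {
  set.seed(4)
  errs <- stats::runif(100)
  scorer <- function(ch) ch * 0
  x <- as.numeric(matrix(rep(errs, each = 10), nrow = 10))
  counts <- vapply(c(0.1, 0.3, 0.5, 0.9), function(thr) {
    sum(detect_anomalies(scorer, x, thr, chunk_len = 10,
                         normalize = FALSE)$flags)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the published operating thresholds are exposed and persist", {
  thr <- ae_thresholds()
  expect_equal(thr$max_loss, 0.068)
  expect_equal(thr$strict, 0.02)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(list(threshold = thr$max_loss), path)
  expect_identical(read_report(path)$threshold, 0.068)
})
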