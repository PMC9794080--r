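# Shared fixtures, built in code at test time.

fs_default <- 128

# small clean synthetic records, memoized per test file run
nsr_record <- function(seconds = 30, seed = 4, label = "NSR") {
  generate_record(label, n_samples = seconds * fs_default, fs = fs_default,
                  seed = seed)
}

# chunk matrices for the autoencoder experiments
record_chunks <- function(label, seeds, n_samples = 8192, chunk_len = 200) {
  do.call(cbind, lapply(seeds, function(s)
    chunk_signal(generate_record(label, n_samples, fs_default, seed = s),
                 chunk_len)))
}

# a small scattering bank for fast structural tests
small_bank <- function(N = 1024, Q = c(2, 1), T = 256) {
  scattering_filter_bank(N, fs_default, Q, T)
}

# well-separated synthetic 3-class "scattering feature" tensors
separable_feature_tensor <- function(n_per_class = 60, D = 60, L = 8,
                                     seed = 7, sd = 0.5) {
  set.seed(seed)
  mus <- replicate(3, rnorm(D), simplify = FALSE)
  names(mus) <- c("ARR", "CHF", "NSR")
  n <- 3 * n_per_class
  tens <- array(0, dim = c(D, L, n))
  y <- rep(names(mus), each = n_per_class)
  for (k in seq_len(3)) {
    idx <- ((k - 1) * n_per_class + 1):(k * n_per_class)
    tens[, , idx] <- array(rnorm(D * L * n_per_class,
                                 mean = rep(mus[[k]], L * n_per_class),
                                 sd = sd),
                           dim = c(D, L, n_per_class))
  }
  list(tensor = tens, labels = y)
}

dataset_matrix_for_test <- function(d) {
  do.call(rbind, lapply(d$records, `[[`, "samples"))
}

# one shared trained autoencoder per test session (training is the
# expensive step; several pipeline tests reuse it)
.shared <- new.env(parent = emptyenv())

shared_ae <- function() {
  if (is.null(.shared$ae)) {
    cfg <- ae_config(hidden_units = 32L, dropout_rate = 0, epochs = 120L,
                     batch_size = 32L, learn_rate = 0.01, seed = 77L)
    # train on preprocessed chunks, matching the streaming scoring path
    chunks <- do.call(cbind, lapply(1:5, function(s) {
      rec <- generate_record("NSR", 8192, fs_default, seed = s)
      chunk_signal(preprocess_signal(rec$samples, fs = fs_default), 200)
    }))
    model <- train_ae(build_ae(cfg), chunks)
    errs <- reconstruction_error(model, chunks)
    .shared$ae <- list(model = model, calib_errors = errs)
  }
  .shared$ae
}
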