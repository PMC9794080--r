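# End-to-end orchestration: a local emulation of the two-step deployment —
# streaming anomaly detection over consecutive 10-s windows, then batch
# classification with screening alerts — plus a reproducibility driver that
# runs the whole study (simulate, preprocess, train, calibrate, classify,
# evaluate) from one seed.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the global seed. The defaults
#' are a desk-scale study: 16,384-sample records at 128 Hz (128 s, eight
#' 2048-sample scattering frames), 24/12/12 records per class, an
#' autoencoder with 32 hidden units trained 60 epochs on the NSR training
#' chunks, and a cubic-SVM classifier on frame-averaged scattering features.
#'
#' @param n_per_class Named record counts per class.
#' @param n_samples Samples per record (power of two).
#' @param fs Sampling rate, Hz.
#' @param window_seconds Streaming window length (default 10 s).
#' @param invariance_scale Scattering averaging scale T in samples
#'   (default `n_samples / 8` so every record gives 8 frames).
#' @param denoise A [denoise_config()].
#' @param ae An [ae_config()].
#' @param ae_quantile Calibration quantile for the anomaly threshold.
#' @param classifier `"lstm"` or a classical family name
#'   (see [train_classical()]).
#' @param classifier_config An [lstm_classifier_config()] when
#'   `classifier = "lstm"`; otherwise a params list.
#' @param train_fraction Train fraction for the stratified split.
#' @param n_top_features Feature-subset size applied after mRMR ranking for
#'   classical learners (`NULL` = all features).
#' @param thresholds Screening thresholds, see [normal_limits()].
#' @param seed Global seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_per_class = c(ARR = 24, CHF = 12, NSR = 12),
                            n_samples = 16384, fs = 128,
                            window_seconds = 10,
                            invariance_scale = NULL,
                            denoise = denoise_config(),
                            ae = ae_config(hidden_units = 32L, epochs = 60L,
                                           batch_size = 64L,
                                           learn_rate = 0.01),
                            ae_quantile = 0.98,
                            classifier = "svm_cubic",
                            classifier_config = NULL,
                            train_fraction = 0.7,
                            n_top_features = 60L,
                            thresholds = normal_limits(),
                            seed = 7L) {
  if (is.null(invariance_scale)) invariance_scale <- n_samples / 8
  if (window_seconds * fs < ae$chunk_len) {
    stop("pipeline_config: window_seconds x fs must cover one AE chunk")
  }
  structure(list(n_per_class = n_per_class, n_samples = n_samples, fs = fs,
                 window_seconds = window_seconds,
                 invariance_scale = invariance_scale,
                 denoise = denoise, ae = ae, ae_quantile = ae_quantile,
                 classifier = classifier,
                 classifier_config = classifier_config,
                 train_fraction = train_fraction,
                 n_top_features = n_top_features,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Streaming anomaly detection over consecutive windows
#'
#' Splits the record into consecutive non-overlapping windows of
#' `window_seconds`, preprocesses each (detrend + denoise), scores its
#' chunks with the trained autoencoder, and flags windows containing any
#' chunk above the threshold. Flagged windows form the trigger list that
#' gates batch classification.
#'
#' @param record An [ecg_record()].
#' @param model A trained `lstm_ae`.
#' @param threshold Reconstruction-error cutoff.
#' @param config A [pipeline_config()] (window length, denoise settings).
#' @return List with `windows` (one `reconstruction_result` per window),
#'   `triggered` (data.frame of flagged windows with sample spans), and
#'   `n_windows`.
#' @export
run_streaming_detection <- function(record, model, threshold,
                                    config = pipeline_config()) {
  stopifnot(inherits(record, "ecg_record"))
  if (!inherits(model, "lstm_ae") || !model$trained) {
    stop("run_streaming_detection: a trained autoencoder model is required")
  }
  win_len <- round(config$window_seconds * record$fs)
  n <- length(record$samples)
  if (n < win_len) stop("run_streaming_detection: record shorter than one window")
  n_windows <- n %/% win_len
  windows <- vector("list", n_windows)
  trig <- list()
  for (w in seq_len(n_windows)) {
    span <- ((w - 1) * win_len + 1):(w * win_len)
    x <- preprocess_signal(record$samples[span], config$denoise, record$fs)
    res <- detect_anomalies(model, x, threshold)
    windows[[w]] <- res
    if (res$record_flag) {
      trig[[length(trig) + 1L]] <- data.frame(
        window = w, start = span[1], end = span[length(span)],
        max_error = max(res$per_chunk_error))
    }
  }
  list(windows = windows,
       triggered = if (length(trig)) do.call(rbind, trig)
                   else data.frame(window = integer(0), start = integer(0),
                                   end = integer(0), max_error = numeric(0)),
       n_windows = n_windows)
}

#' Batch classification of a triggered record
#'
#' Classification operates on the full record (the scattering bank is built
#' for the configured record length); the trigger list only gates whether it
#' runs. Emits the predicted class, per-class scores, and the interval
#' screening alert report.
#'
#' @param record An [ecg_record()].
#' @param classifier A fitted classifier (`lstm_classifier` or
#'   `ecgflow_classifier`) as produced by [run_e2e()].
#' @param bank The [scattering_filter_bank()] the classifier was trained
#'   with.
#' @param config A [pipeline_config()].
#' @param triggered Optional trigger data.frame from
#'   [run_streaming_detection()]; when supplied and empty, classification
#'   is skipped and the report says so.
#' @param ranking Optional `feature_ranking` used at training time (for
#'   classical learners with a feature subset).
#' @return List with `status` (`"classified"` or `"no anomaly"`),
#'   `prediction`, `scores`, `alerts`.
#' @export
run_batch_classification <- function(record, classifier, bank,
                                     config = pipeline_config(),
                                     triggered = NULL, ranking = NULL) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.null(triggered) && nrow(triggered) == 0L) {
    return(list(status = "no anomaly", prediction = NULL, scores = NULL,
                alerts = NULL))
  }
  if (length(record$samples) != bank$signal_length) {
    stop(sprintf(paste0(
      "run_batch_classification: record length %d != bank signal_length %d; ",
      "pad or crop the record to the bank length first"),
      length(record$samples), bank$signal_length))
  }
  clean <- preprocess_signal(record$samples, config$denoise, record$fs)
  sf <- scattering_transform(clean, bank)
  if (inherits(classifier, "lstm_classifier")) {
    tens <- array(sf$coefficients, dim = c(dim(sf$coefficients), 1L))
    pred <- predict(classifier, tens, type = "class")
    scores <- predict(classifier, tens, type = "prob")[1, ]
  } else {
    feats <- matrix(rowMeans(sf$coefficients), nrow = 1)
    if (!is.null(ranking) && !is.null(config$n_top_features)) {
      keep <- ranking$order[seq_len(min(config$n_top_features,
                                        length(ranking$order)))]
      feats <- feats[, keep, drop = FALSE]
    }
    colnames(feats) <- paste0("X", seq_len(ncol(feats)))
    pred <- predict(classifier, feats, type = "class")
    scores <- predict(classifier, feats, type = "prob")[1, ]
  }
  alerts <- screen(compute_features(clean, record$fs), config$thresholds)
  list(status = "classified", prediction = as.character(pred),
       scores = as.list(scores), alerts = alerts)
}

#' Run the full study end to end
#'
#' simulate -> preprocess -> train the autoencoder on NSR training chunks ->
#' calibrate the anomaly threshold -> scattering features -> mRMR ranking ->
#' train the classifier on the stratified training split -> evaluate on the
#' held-out split -> write `metrics.json`, `manifest.json`, and the anomaly
#' summary under `out_dir`. Fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param verbose Print stage progress.
#' @return List with `dataset`, `split`, `ae` (model, threshold,
#'   calibration errors), `bank`, `ranking`, `classifier`, `metrics`,
#'   `anomaly_eval`, and `manifest`.
#' @export
run_e2e <- function(config = pipeline_config(), out_dir = NULL,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("e2e stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seed <- config$seed

  say("stage 1/7: simulate (%d records)", sum(config$n_per_class))
  dataset <- stage("simulate",
    generate_dataset(config$n_per_class, n_samples = config$n_samples,
                     fs = config$fs, seed = seed))
  labels <- dataset_labels(dataset)

  say("stage 2/7: preprocess")
  clean <- stage("preprocess", lapply(dataset$records, function(r) {
    preprocess_signal(r$samples, config$denoise, r$fs)
  }))

  say("stage 3/7: split")
  split <- stage("split",
    split_dataset(labels, train_fraction = config$train_fraction,
                  stratified = TRUE, seed = seed + 1L))

  say("stage 4/7: train autoencoder on NSR training chunks")
  ae_res <- stage("anomaly_ae", {
    nsr_train <- intersect(split$train, which(labels == "NSR"))
    chunks <- do.call(cbind, lapply(clean[nsr_train], chunk_signal,
                                    chunk_len = config$ae$chunk_len))
    cfg <- config$ae
    cfg$seed <- seed + 2L
    model <- train_ae(build_ae(cfg), chunks, cfg)
    errs <- reconstruction_error(model, chunks)
    thr <- calibrate_threshold(errs, config$ae_quantile)
    # chunk-level evaluation on held-out records
    nsr_test <- intersect(split$test, which(labels == "NSR"))
    anom_test <- intersect(split$test, which(labels == "ARR"))
    err_nsr <- unlist(lapply(clean[nsr_test], function(x)
      reconstruction_error(model, chunk_signal(x, cfg$chunk_len))))
    err_anom <- unlist(lapply(clean[anom_test], function(x)
      reconstruction_error(model, chunk_signal(x, cfg$chunk_len))))
    acc <- (sum(err_nsr <= thr) + sum(err_anom > thr)) /
      (length(err_nsr) + length(err_anom))
    list(model = model, threshold = thr, calib_errors = errs,
         eval = list(mean_normal_error = mean(err_nsr),
                     mean_anomaly_error = mean(err_anom),
                     chunk_accuracy = acc))
  })

  say("stage 5/7: scattering features")
  bank <- stage("scattering", scattering_filter_bank(
    signal_length = config$n_samples, fs = config$fs,
    invariance_scale = config$invariance_scale))
  tens <- stage("scattering", {
    out <- array(0, dim = c(bank$n_paths, bank$n_frames, length(clean)))
    for (i in seq_along(clean)) {
      out[, , i] <- scattering_transform(clean[[i]], bank)$coefficients
    }
    out
  })

  say("stage 6/7: rank features and train classifier (%s)", config$classifier)
  Xrec <- t(apply(tens, c(1, 3), mean))  # records x paths, frame-averaged
  ranking <- stage("mrmr",
    rank_features_mrmr(Xrec[split$train, , drop = FALSE], labels[split$train]))
  clf_res <- stage("classify", {
    if (config$classifier == "lstm") {
      cfg <- config$classifier_config %||%
        lstm_classifier_config(input_dim = bank$n_paths, epochs = 40L,
                               learn_rate = 0.01, seed = seed + 3L)
      model <- train_lstm_classifier(tens[, , split$train, drop = FALSE],
                                     labels[split$train], cfg)
      pred <- predict(model, tens[, , split$test, drop = FALSE])
      scores <- predict(model, tens[, , split$test, drop = FALSE], "prob")
    } else {
      keep <- ranking$order[seq_len(min(config$n_top_features %||% ncol(Xrec),
                                        ncol(Xrec)))]
      Xtr <- Xrec[split$train, keep, drop = FALSE]
      Xte <- Xrec[split$test, keep, drop = FALSE]
      colnames(Xtr) <- colnames(Xte) <- paste0("X", seq_along(keep))
      model <- train_classical(config$classifier, Xtr, labels[split$train],
                               config$classifier_config %||% list())
      pred <- predict(model, Xte, type = "class")
      scores <- predict(model, Xte, type = "prob")
    }
    list(model = model, pred = pred, scores = scores)
  })

  say("stage 7/7: evaluate")
  metrics <- stage("evaluate",
    evaluate_predictions(labels[split$test], clf_res$pred, clf_res$scores))

  manifest <- list(
    seed = seed,
    n_records = length(dataset$records),
    class_counts = as.list(dataset$class_counts),
    n_train = length(split$train), n_test = length(split$test),
    train_indices = split$train, test_indices = split$test,
    ae_threshold = ae_res$threshold,
    ae_config = unclass(config$ae),
    bank = list(n_paths = bank$n_paths, n_frames = bank$n_frames,
                invariance_scale = bank$invariance_scale),
    classifier = config$classifier,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("ecgflow")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(list(
      accuracy = metrics$accuracy,
      macro_f1 = metrics$macro_f1,
      per_class = metrics$per_class,
      confusion = unclass(metrics$confusion),
      anomaly = ae_res$eval), file.path(out_dir, "metrics.json"))
    write_report(manifest, file.path(out_dir, "manifest.json"))
  }

  list(dataset = dataset, split = split, ae = ae_res, bank = bank,
       ranking = ranking, classifier = clf_res$model, metrics = metrics,
       anomaly_eval = ae_res$eval, manifest = manifest)
}
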