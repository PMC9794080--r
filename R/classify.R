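# Multi-class ECG classification: stratified splitting, from-scratch mRMR
# feature ranking and KNN, classical learners delegated to established
# backends, a from-scratch LSTM sequence classifier, and full evaluation
# metrics (confusion, precision/recall/F1, ROC/PRC/AUC).

#' Stratified train/test split
#'
#' Training size is `floor(train_fraction * n_total)`; under stratification
#' the per-class allocation is proportional with largest-remainder rounding
#' (162 records at fraction 0.7 give the reference 113/49 split). The split
#' is deterministic given `seed`, disjoint, and exhaustive.
#'
#' @param labels Character/factor vector of class labels (or an
#'   [ecg_dataset()]).
#' @param train_fraction In (0, 1); default 0.7.
#' @param stratified Allocate proportionally per class (default TRUE).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, train_fraction = 0.7, stratified = TRUE,
                          seed = 1L) {
  if (inherits(labels, "ecg_dataset")) labels <- dataset_labels(labels)
  n <- length(labels)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("split_dataset: train_fraction must be in (0, 1)")
  }
  n_train <- floor(train_fraction * n)
  set.seed(seed)
  if (!stratified) {
    train <- sort(sample.int(n, n_train))
    return(list(train = train, test = setdiff(seq_len(n), train)))
  }
  tab <- table(labels)
  if (any(tab == 0)) stop("split_dataset: class with zero members")
  exact <- as.numeric(tab) * train_fraction
  base <- floor(exact)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra_order <- order(exact - base, decreasing = TRUE)
    base[extra_order[seq_len(rem)]] <- base[extra_order[seq_len(rem)]] + 1
  }
  train <- integer(0)
  for (k in seq_along(tab)) {
    idx <- which(labels == names(tab)[k])
    train <- c(train, sort(sample(idx, base[k])))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

# ---- mutual information / mRMR ---------------------------------------------

# equal-frequency discretization into at most n_bins bins
discretize_ef <- function(x, n_bins = 10L) {
  if (length(unique(x)) <= 1L) return(rep(1L, length(x)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# MI (nats) between two integer/factor codings, plug-in estimate
mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rank features by minimum redundancy maximum relevance (mRMR)
#'
#' Greedy MID (mutual-information difference) scheme: features are
#' discretized into equal-frequency bins, relevance is the mutual
#' information `I(feature; label)`, redundancy is the mean MI with the
#' already-selected features, and each step picks the feature maximizing
#' `relevance - redundancy`. The full ordering is returned; a constant
#' feature has relevance 0 and sorts last among ties.
#'
#' @param X Numeric matrix, observations x features.
#' @param y Class labels (>= 2 classes).
#' @param n_bins Discretization bins (default 10).
#' @return A `feature_ranking`: list with `order` (feature indices, best
#'   first — a permutation of all columns) and `scores` (the
#'   relevance-minus-redundancy score at selection, in `order`'s order;
#'   first entry is the pure relevance).
#' @export
rank_features_mrmr <- function(X, y, n_bins = 10L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("rank_features_mrmr: features must be finite")
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("rank_features_mrmr: need >= 2 classes")
  p <- ncol(X)
  disc <- lapply(seq_len(p), function(j) discretize_ef(X[, j], n_bins))
  relevance <- vapply(disc, mi_discrete, numeric(1), b = y)
  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)  # sum of MI with selected features
  while (length(remaining)) {
    red <- if (length(selected)) red_sum[remaining] / length(selected) else 0
    sc <- relevance[remaining] - red
    # deterministic tie-break: higher relevance, then lower index
    best <- remaining[order(-sc, -relevance[remaining], remaining)[1]]
    selected <- c(selected, best)
    scores <- c(scores, (relevance[best] -
                           if (length(selected) > 1)
                             red_sum[best] / (length(selected) - 1) else 0))
    remaining <- setdiff(remaining, best)
    if (length(remaining)) {
      add <- vapply(remaining, function(j) mi_discrete(disc[[j]], disc[[best]]),
                    numeric(1))
      red_sum[remaining] <- red_sum[remaining] + add
    }
  }
  structure(list(order = selected, scores = scores, relevance = relevance),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  k <- min(10L, length(x$order))
  cat(sprintf("<feature_ranking> %d features; top %d: %s\n",
              length(x$order), k,
              paste(x$order[seq_len(k)], collapse = ", ")))
  invisible(x)
}

#' K-nearest-neighbour classification (from scratch)
#'
#' Euclidean distance `d = sqrt(sum((x_i - xhat)^2))`; majority vote among
#' the `k` nearest training points. Ties are broken by the smallest summed
#' distance of the tied classes' voters, then by the lowest class index
#' (factor level order).
#'
#' @param train_X,train_y Training matrix (n x p) and labels.
#' @param test_X Test matrix (m x p).
#' @param k Number of neighbours (1 <= k <= n).
#' @return Factor of predicted labels (levels of `train_y`).
#' @export
knn_classify <- function(train_X, train_y, test_X, k = 5L) {
  train_X <- as.matrix(train_X); test_X <- as.matrix(test_X)
  if (nrow(train_X) == 0) stop("knn_classify: empty training set")
  if (k < 1 || k > nrow(train_X)) stop("knn_classify: k must be in [1, n_train]")
  train_y <- as.factor(train_y)
  lev <- levels(train_y)
  # squared distances via the expansion ||a-b||^2 = ||a||^2 + ||b||^2 - 2ab'
  d2 <- outer(rowSums(test_X^2), rowSums(train_X^2), "+") -
    2 * tcrossprod(test_X, train_X)
  d2[d2 < 0] <- 0
  preds <- character(nrow(test_X))
  for (i in seq_len(nrow(test_X))) {
    nn <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- table(factor(train_y[nn], levels = lev))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl)
        sum(sqrt(d2[i, nn[train_y[nn] == cl]])), numeric(1))
      top <- top[sums == min(sums)]
    }
    preds[i] <- top[1]  # lowest class index among remaining ties
  }
  factor(preds, levels = lev)
}

# ---- classical learner family ---------------------------------------------

CLASSICAL_FAMILIES <- c("tree", "lda", "naive_bayes", "svm_linear",
                        "svm_quadratic", "svm_cubic", "svm_rbf", "knn",
                        "bagged_trees")

#' Train a classical classifier family
#'
#' A thin, uniform wrapper over established backends: `tree` (rpart),
#' `lda` (MASS), `naive_bayes` (e1071), the SVM variants (e1071/libsvm,
#' which trains a one-against-one decomposition: `c*(c-1)/2` binary
#' machines, i.e. 3 machines for 3 classes), `knn` (the package's own
#' [knn_classify()]), and `bagged_trees` (randomForest with `mtry = p`,
#' i.e. bagging). Probabilities are available for every family via
#' `predict(fit, newdata, type = "prob")`.
#'
#' @param family One of `"tree"`, `"lda"`, `"naive_bayes"`, `"svm_linear"`,
#'   `"svm_quadratic"`, `"svm_cubic"`, `"svm_rbf"`, `"knn"`, `"bagged_trees"`.
#' @param X Numeric matrix, observations x features.
#' @param y Class labels.
#' @param params Optional list of backend parameters (e.g. `k` for knn,
#'   `cost` for SVMs, `ntree` for bagging).
#' @return An `ecgflow_classifier` with fields `family`, `fit`, `levels`,
#'   and for SVMs `n_binary_machines`.
#' @export
train_classical <- function(family, X, y, params = list()) {
  if (!family %in% CLASSICAL_FAMILIES) {
    stop(sprintf("train_classical: unknown family '%s'", family))
  }
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  df <- data.frame(X)
  df$.y <- y
  c_classes <- nlevels(y)
  fit <- switch(family,
    tree = rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          minsplit = params$minsplit %||% 5)),
    lda = MASS::lda(X, grouping = y),
    naive_bayes = e1071::naiveBayes(X, y),
    svm_linear = e1071::svm(X, y, kernel = "linear",
                            cost = params$cost %||% 1, probability = TRUE),
    svm_quadratic = e1071::svm(X, y, kernel = "polynomial", degree = 2,
                               coef0 = 1, cost = params$cost %||% 1,
                               probability = TRUE),
    svm_cubic = e1071::svm(X, y, kernel = "polynomial", degree = 3,
                           coef0 = 1, cost = params$cost %||% 1,
                           probability = TRUE),
    svm_rbf = e1071::svm(X, y, kernel = "radial",
                         cost = params$cost %||% 1, probability = TRUE),
    knn = list(train_X = X, train_y = y, k = params$k %||% 5L),
    bagged_trees = randomForest::randomForest(
      X, y, mtry = ncol(X), ntree = params$ntree %||% 100))
  out <- structure(list(family = family, fit = fit, levels = levels(y)),
                   class = "ecgflow_classifier")
  if (startsWith(family, "svm_")) {
    out$n_binary_machines <- c_classes * (c_classes - 1) / 2
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ecgflow_classifier <- function(x, ...) {
  extra <- if (!is.null(x$n_binary_machines)) {
    sprintf(" (%d binary machines, one-against-one)", x$n_binary_machines)
  } else ""
  cat(sprintf("<ecgflow_classifier> family %s, classes: %s%s\n",
              x$family, paste(x$levels, collapse = "/"), extra))
  invisible(x)
}

#' @export
predict.ecgflow_classifier <- function(object, newdata,
                                       type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  lev <- object$levels
  fam <- object$family
  if (fam == "knn") {
    cls <- knn_classify(object$fit$train_X, object$fit$train_y, newdata,
                        k = object$fit$k)
    if (type == "class") return(cls)
    pr <- matrix(0, nrow(newdata), length(lev), dimnames = list(NULL, lev))
    pr[cbind(seq_len(nrow(newdata)), match(as.character(cls), lev))] <- 1
    return(pr)
  }
  if (fam == "tree") {
    df <- data.frame(newdata)
    pr <- predict(object$fit, df, type = "prob")
    if (type == "prob") return(pr[, lev, drop = FALSE])
    return(factor(lev[max.col(pr[, lev, drop = FALSE], "first")], levels = lev))
  }
  if (fam == "lda") {
    p <- predict(object$fit, newdata)
    if (type == "class") return(factor(as.character(p$class), levels = lev))
    return(p$posterior[, lev, drop = FALSE])
  }
  if (fam == "naive_bayes") {
    if (type == "class") return(predict(object$fit, newdata))
    return(predict(object$fit, newdata, type = "raw")[, lev, drop = FALSE])
  }
  if (startsWith(fam, "svm_")) {
    p <- predict(object$fit, newdata, probability = TRUE)
    if (type == "class") return(factor(as.character(p), levels = lev))
    pr <- attr(p, "probabilities")
    return(pr[, lev, drop = FALSE])
  }
  # bagged_trees
  if (type == "class") return(predict(object$fit, newdata))
  predict(object$fit, newdata, type = "prob")[, lev, drop = FALSE]
}

# ---- LSTM sequence classifier ----------------------------------------------

#' LSTM sequence classifier configuration
#'
#' Defaults follow the reference architecture and the selected
#' hyper-parameter row: sequence input of 499 dimensions, one LSTM layer
#' with 300 hidden units with output mode `"last"`, a fully connected layer
#' of width 3, softmax; Adam, learning rate 0.1, 150 epochs, mini-batch
#' 1000 (a batch larger than the training set is treated as full batch).
#'
#' @param input_dim Feature dimension per time step (default 499).
#' @param hidden_units LSTM hidden units (default 300).
#' @param n_classes Number of classes (default 3).
#' @param output_mode Only `"last"` is supported.
#' @param optimizer `"adam"`, `"sgdm"`, or `"rmsprop"`.
#' @param learn_rate Learning rate (> 0).
#' @param epochs Training epochs.
#' @param mini_batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return An `lstm_classifier_config` list.
#' @export
lstm_classifier_config <- function(input_dim = 499L, hidden_units = 300L,
                                   n_classes = 3L, output_mode = "last",
                                   optimizer = "adam", learn_rate = 0.1,
                                   epochs = 150L, mini_batch_size = 1000L,
                                   seed = 1L) {
  if (output_mode != "last") stop("lstm_classifier_config: output_mode must be 'last'")
  if (learn_rate <= 0) stop("lstm_classifier_config: learn_rate must be > 0")
  if (min(input_dim, hidden_units, n_classes) < 1) {
    stop("lstm_classifier_config: dimensions must be positive")
  }
  optimizer <- match.arg(tolower(optimizer), c("adam", "sgdm", "rmsprop"))
  structure(list(input_dim = as.integer(input_dim),
                 hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 output_mode = output_mode, optimizer = optimizer,
                 learn_rate = learn_rate, epochs = as.integer(epochs),
                 mini_batch_size = as.integer(mini_batch_size),
                 seed = as.integer(seed)),
            class = "lstm_classifier_config")
}

#' Train the LSTM sequence classifier on scattering features
#'
#' Each record enters as a length-`n_frames` sequence of `input_dim`-
#' dimensional scattering vectors; the LSTM's final hidden state feeds a
#' fully connected layer and softmax, trained with cross-entropy.
#'
#' @param feature_tensor `input_dim x n_frames x n_records` array (see
#'   [feature_tensor()]).
#' @param y Class labels, one per record.
#' @param config An [lstm_classifier_config()]; `input_dim` and `n_classes`
#'   are taken from the data when they disagree with a default config.
#' @return An `lstm_classifier` with `weights`, `history` (per-epoch loss
#'   and training accuracy), `levels`, `config`, and `shapes` (learnable
#'   dimensions; the stacked input-weight matrix has `4 * hidden_units`
#'   rows).
#' @export
train_lstm_classifier <- function(feature_tensor, y,
                                  config = lstm_classifier_config()) {
  stopifnot(length(dim(feature_tensor)) == 3)
  d <- dim(feature_tensor)
  y <- droplevels(as.factor(y))
  if (d[3] != length(y)) stop("train_lstm_classifier: labels/records mismatch")
  if (d[1] != config$input_dim || nlevels(y) != config$n_classes) {
    config$input_dim <- d[1]
    config$n_classes <- nlevels(y)
  }
  # feature standardization per path (over frames and records)
  mu <- apply(feature_tensor, 1, mean)
  sdv <- pmax(apply(feature_tensor, 1, stats::sd), 1e-12)
  Xs <- sweep(sweep(feature_tensor, 1, mu), 1, sdv, "/")
  w0 <- .cpp_clf_init(config$input_dim, config$hidden_units,
                      config$n_classes, config$seed)
  fit <- .cpp_clf_train(w0, Xs, as.integer(y) - 1L, config$epochs,
                        min(config$mini_batch_size, d[3]),
                        config$learn_rate, config$optimizer, config$seed)
  structure(list(weights = fit$weights,
                 history = list(loss = fit$loss, accuracy = fit$accuracy),
                 levels = levels(y), config = config,
                 scaling = list(mu = mu, sd = sdv),
                 shapes = list(
                   input_weights = dim(fit$weights$lstm$W),
                   recurrent_weights = dim(fit$weights$lstm$U),
                   fc_weights = dim(fit$weights$Wf),
                   fc_bias = c(length(fit$weights$bf), 1L))),
            class = "lstm_classifier")
}

#' @export
print.lstm_classifier <- function(x, ...) {
  cat(sprintf("<lstm_classifier> %d-dim sequence input, %d hidden units, %d classes; final training accuracy %.3f\n",
              x$config$input_dim, x$config$hidden_units, x$config$n_classes,
              utils::tail(x$history$accuracy, 1)))
  invisible(x)
}

#' @export
predict.lstm_classifier <- function(object, feature_tensor,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(length(dim(feature_tensor)) == 3)
  Xs <- sweep(sweep(feature_tensor, 1, object$scaling$mu), 1,
              object$scaling$sd, "/")
  pr <- t(.cpp_clf_predict(object$weights, Xs))
  colnames(pr) <- object$levels
  if (type == "prob") return(pr)
  factor(object$levels[max.col(pr, "first")], levels = object$levels)
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate multi-class predictions
#'
#' Confusion matrix (rows = truth, columns = prediction), accuracy,
#' per-class and macro precision/recall/F1 (a 0/0 rate is reported as 0 and
#' noted in `warnings`), and, when per-class scores are supplied, one-vs-rest
#' ROC and precision-recall curves with trapezoidal AUC, using a threshold
#' sweep over the unique score values.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param scores Optional numeric matrix (observations x classes, columns
#'   named by class) of probabilities/scores.
#' @return An `eval_metrics` list: `confusion`, `accuracy`, `per_class`
#'   (data.frame precision/recall/f1/support), `macro_precision`,
#'   `macro_recall`, `macro_f1`, `roc`, `prc`, `auc`, `warnings`.
#' @export
evaluate_predictions <- function(y_true, y_pred, scores = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("evaluate_predictions: length mismatch")
  }
  lev <- union(levels(as.factor(y_true)), levels(as.factor(y_pred)))
  y_true <- factor(as.character(y_true), levels = lev)
  y_pred <- factor(as.character(y_pred), levels = lev)
  conf <- table(truth = y_true, prediction = y_pred)
  acc <- sum(diag(conf)) / sum(conf)
  warns <- character(0)
  per <- lapply(lev, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp == 0) {
      warns <<- c(warns, sprintf("precision 0/0 for class %s", cl)); 0
    } else tp / (tp + fp)
    rec <- if (tp + fn == 0) {
      warns <<- c(warns, sprintf("recall 0/0 for class %s", cl)); 0
    } else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(conf[cl, ]))
  })
  per <- do.call(rbind, per)
  roc <- prc <- auc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != length(y_true)) {
      stop("evaluate_predictions: scores row count mismatch")
    }
    if (is.null(colnames(scores))) colnames(scores) <- lev[seq_len(ncol(scores))]
    roc <- list(); prc <- list(); auc <- numeric(0)
    for (cl in intersect(lev, colnames(scores))) {
      s <- scores[, cl]
      pos <- y_true == cl
      if (!any(pos) || all(pos)) next
      thr <- c(Inf, sort(unique(s), decreasing = TRUE))
      tpr <- fpr <- prec_c <- numeric(length(thr))
      for (i in seq_along(thr)) {
        call_pos <- s >= thr[i]
        tp <- sum(call_pos & pos); fp <- sum(call_pos & !pos)
        tpr[i] <- tp / sum(pos)
        fpr[i] <- fp / sum(!pos)
        prec_c[i] <- if (tp + fp == 0) 1 else tp / (tp + fp)
      }
      roc[[cl]] <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
      prc[[cl]] <- data.frame(threshold = thr, recall = tpr,
                              precision = prec_c)
      auc[cl] <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    }
  }
  structure(list(confusion = conf, accuracy = acc, per_class = per,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 roc = roc, prc = prc, auc = auc, warnings = warns),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> accuracy %.4f, macro F1 %.4f\n",
              x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Parameter shapes of an LSTM layer (bookkeeping helper)
#'
#' For a hidden size `H` and input dimension `D`, the four stacked gates
#' give an input-weight matrix of `4*H x D` (e.g. 1200 stacked rows for 300
#' hidden units) and a recurrent-weight matrix of `4*H x H`.
#'
#' @param hidden_units Hidden size H.
#' @param input_dim Input dimension D.
#' @return Named list with `input_weights`, `recurrent_weights`, `bias`.
#' @export
lstm_layer_shapes <- function(hidden_units, input_dim) {
  list(input_weights = c(4L * hidden_units, input_dim),
       recurrent_weights = c(4L * hidden_units, hidden_units),
       bias = c(4L * hidden_units, 1L))
}
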