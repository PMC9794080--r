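# Oracles: an exhaustive-search KNN, a direct double-loop mutual-information
# estimator, and a Mann-Whitney AUC, each written independently of the
# implementation they check.

test_that("a 70% stratified split of 162 records gives 113 train / 49 test", {
  labels <- rep(c("ARR", "CHF", "NSR"), c(96, 30, 36))
  sp <- split_dataset(labels, 0.7, stratified = TRUE, seed = 3)
  expect_equal(length(sp$train), 113L)
  expect_equal(length(sp$test), 49L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_len(162))
  # proportions within one record of exact
  for (cl in c("ARR", "CHF", "NSR")) {
    got <- sum(labels[sp$train] == cl)
    expect_lte(abs(got - 0.7 * sum(labels == cl)), 1)
  }
})

test_that("splits are deterministic and honour simple fractions", {
  labels <- rep(c("a", "b"), each = 5)
  s1 <- split_dataset(labels, 0.5, seed = 2)
  s2 <- split_dataset(labels, 0.5, seed = 2)
  expect_identical(s1, s2)
  expect_equal(length(s1$train), 5L)
  expect_error(split_dataset(labels, 1.2), "train_fraction")
})

test_that("mRMR ranks an exact label copy first and penalizes duplicates", {
  set.seed(11)
  n <- 200
  y <- sample(0:2, n, TRUE)
  X <- cbind(y + rnorm(n, 0, 0.01), matrix(rnorm(n * 8), n, 8))
  X <- cbind(X, X[, 1])  # column 10 duplicates the label copy
  r <- rank_features_mrmr(X, y)
  expect_equal(r$order[1], 1L)
  expect_true(is.finite(max(r$scores)))
  # first pick maximizes marginal MI (oracle on every feature)
  rel <- vapply(seq_len(ncol(X)), function(j)
    oracle_mi(ecgflow:::discretize_ef(X[, j]), y), numeric(1))
  expect_equal(r$order[1], which.max(rel))
  expect_equal(unname(r$scores[1]), max(rel), tolerance = 1e-12)
  # the duplicate's selection score is pulled below its raw relevance
  dup_pos <- which(r$order == 10L)
  expect_gt(dup_pos, 2L)
  expect_lt(r$scores[dup_pos], rel[10])
})

test_that("mRMR handles constants and single features", {
  set.seed(3)
  y <- rep(0:1, each = 20)
  Xc <- cbind(rnorm(40), const = rep(1, 40), y + rnorm(40, 0, 0.1))
  r <- rank_features_mrmr(Xc, y)
  expect_equal(r$relevance[2], 0)
  # zero relevance: never selected before the informative feature
  expect_equal(r$order[1], 3L)
  expect_gt(which(r$order == 2L), 1L)
  single <- rank_features_mrmr(matrix(rnorm(40), ncol = 1), y)
  expect_equal(single$order, 1L)
})

test_that("knn uses Euclidean distance with the documented tie-breaks", {
  # 3-4-5 triangle: the single training point is always predicted
  tr <- matrix(c(0, 0), 1, 2); te <- matrix(c(3, 4), 1, 2)
  expect_equal(as.character(knn_classify(tr, "a", te, k = 1)), "a")
  # k = n_train predicts the most frequent class
  set.seed(2)
  trX <- matrix(rnorm(20), 10, 2)
  trY <- factor(rep(c("x", "y"), c(7, 3)))
  p <- knn_classify(trX, trY, matrix(rnorm(4), 2, 2), k = 10)
  expect_true(all(p == "x"))
  expect_error(knn_classify(trX[0, ], trY[0], te, 1), "empty")
  expect_error(knn_classify(trX, trY, te, k = 11), "k must")
})

test_that("knn equals the exhaustive-search oracle on random fixtures", {
  set.seed(21)
  for (rep_i in 1:3) {
    trX <- matrix(rnorm(60 * 4), 60, 4)
    trY <- factor(sample(c("ARR", "CHF", "NSR"), 60, TRUE))
    teX <- matrix(rnorm(30 * 4), 30, 4)
    for (k in c(1, 5)) {
      expect_identical(as.character(knn_classify(trX, trY, teX, k)),
                       oracle_knn(trX, trY, teX, k))
    }
  }
})

test_that("one-against-one SVMs build c(c-1)/2 binary machines", {
  set.seed(5)
  X <- matrix(rnorm(90 * 3), 90, 3)
  y3 <- factor(rep(c("ARR", "CHF", "NSR"), 30))
  fit3 <- train_classical("svm_cubic", X, y3)
  expect_equal(fit3$n_binary_machines, 3)
  y2 <- factor(rep(c("ARR", "NSR"), 45))
  fit2 <- train_classical("svm_rbf", X, y2)
  expect_equal(fit2$n_binary_machines, 1)
  expect_error(train_classical("boosted_stumps", X, y3), "unknown family")
})

test_that("classical families fit separable data and emit probabilities", {
  set.seed(6)
  n <- 40
  X <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, 6), n, 2))
  y <- factor(rep(c("lo", "hi"), each = n))
  for (fam in c("svm_linear", "tree", "lda", "naive_bayes", "knn",
                "bagged_trees")) {
    fit <- train_classical(fam, X, y)
    pred <- predict(fit, X, type = "class")
    expect_equal(mean(pred == y), 1, info = fam)
    pr <- predict(fit, X, type = "prob")
    expect_equal(dim(pr), c(2L * n, 2L), info = fam)
    expect_equal(unname(rowSums(pr)), rep(1, 2 * n), tolerance = 1e-6,
                 info = fam)
  }
})

test_that("the LSTM classifier reports the reference layer shapes", {
  toy <- separable_feature_tensor(n_per_class = 4, D = 10, L = 3, seed = 1)
  cfg <- lstm_classifier_config(input_dim = 10, hidden_units = 300,
                                epochs = 1, learn_rate = 0.01,
                                mini_batch_size = 12, seed = 2)
  m <- train_lstm_classifier(toy$tensor, toy$labels, cfg)
  expect_equal(m$shapes$input_weights, c(1200L, 10L))  # 4 x 300 stacked gates
  expect_equal(m$shapes$recurrent_weights, c(1200L, 300L))
  expect_equal(m$shapes$fc_weights, c(3L, 300L))
  expect_equal(m$shapes$fc_bias, c(3L, 1L))
})

test_that("the LSTM classifier learns well-separated synthetic features", {
  feats <- separable_feature_tensor(n_per_class = 60, D = 60, L = 8, seed = 7)
  sp <- split_dataset(feats$labels, 0.7, seed = 8)
  cfg <- lstm_classifier_config(input_dim = 60, hidden_units = 300,
                                epochs = 30, learn_rate = 0.01,
                                mini_batch_size = 64, seed = 5)
  m <- train_lstm_classifier(feats$tensor[, , sp$train], feats$labels[sp$train],
                             cfg)
  pred <- predict(m, feats$tensor[, , sp$test])
  expect_gte(mean(pred == feats$labels[sp$test]), 0.95)
  pr <- predict(m, feats$tensor[, , sp$test], type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, length(sp$test)), tolerance = 1e-8)
  expect_error(train_lstm_classifier(feats$tensor[, , 1:5],
                                     feats$labels[1:4], cfg), "mismatch")
})

test_that("evaluation reproduces hand-computed metrics", {
  # confusion [[8,2],[1,9]] by construction
  y_true <- c(rep("a", 10), rep("b", 10))
  y_pred <- c(rep("a", 8), "b", "b", "a", rep("b", 9))
  em <- evaluate_predictions(y_true, y_pred)
  expect_equal(unname(as.vector(em$confusion)), c(8, 1, 2, 9))
  expect_equal(em$accuracy, 17 / 20)
  a_row <- em$per_class[em$per_class$class == "a", ]
  expect_equal(a_row$precision, 8 / 9)
  expect_equal(a_row$recall, 0.8)
  expect_equal(a_row$f1, 2 * (8 / 9 * 0.8) / (8 / 9 + 0.8))
  expect_equal(a_row$f1, 0.8421, tolerance = 1e-4)

  perfect <- evaluate_predictions(y_true, y_true)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  expect_lte(perfect$macro_f1, max(perfect$per_class$f1))
  expect_error(evaluate_predictions(y_true, y_pred[1:5]), "length")
})

test_that("AUC equals the Mann-Whitney statistic and survives monotone maps", {
  set.seed(2)
  s <- stats::runif(50)
  lab <- sample(c("a", "b"), 50, TRUE)
  sc <- cbind(a = s, b = 1 - s)
  em <- evaluate_predictions(lab, sample(c("a", "b"), 50, TRUE), sc)
  pos <- s[lab == "a"]; neg <- s[lab != "a"]
  mw <- mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
  expect_equal(unname(em$auc["a"]), mw, tolerance = 1e-12)
  expect_true(all(em$auc >= 0 & em$auc <= 1))
  # strictly monotone transform leaves the AUC unchanged
  sc2 <- cbind(a = exp(3 * s), b = 1 - s)
  em2 <- evaluate_predictions(lab, sample(c("a", "b"), 50, TRUE), sc2)
  expect_equal(unname(em2$auc["a"]), mw, tolerance = 1e-12)
})

test_that("degenerate precision is reported as zero with a warning flag", {
  em <- evaluate_predictions(c("a", "a", "b"), c("a", "a", "a"))
  b_row <- em$per_class[em$per_class$class == "b", ]
  expect_equal(b_row$precision, 0)
  expect_true(any(grepl("precision 0/0", em$warnings)))
})
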