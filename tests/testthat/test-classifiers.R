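# Disjoint-composition toy dataset: positives use only the first 8
# residues, negatives only the last 8, so composition separates perfectly.
sep_dataset <- function(n_per_class, k = 25, seed = 51) {
  set.seed(seed)
  pos <- replicate(n_per_class, rand_seq(k, prob = c(rep(1, 8), rep(0, 12))))
  neg <- replicate(n_per_class, rand_seq(k, prob = c(rep(0, 12), rep(1, 8))))
  protein_dataset(paste0("s", seq_len(2 * n_per_class)), c(pos, neg),
                  rep(c("positive", "negative"), each = n_per_class))
}

test_that("random forest separates disjoint compositions and is seeded", {
  ds <- sep_dataset(20)
  feat <- featurize_dataset(ds)
  m <- train_rf(feat$X, feat$y, trees = 50, seed = 3)
  pr <- predict(m, feat$X)
  expect_equal(mean(pr$label == feat$y), 1)
  m2 <- train_rf(feat$X, feat$y, trees = 50, seed = 3)
  expect_identical(predict(m2, feat$X)$score, pr$score)
  # single bootstrap tree is a legal boundary case
  expect_s3_class(train_rf(feat$X, feat$y, trees = 1, seed = 1), "dbp_model")
  expect_error(train_rf(feat$X, feat$y[c(1, 1)][rep(1, nrow(feat$X))],
                        seed = 1), "both classes")
})

test_that("SVM separates Gaussian clusters and validates its kernel", {
  set.seed(52)
  n <- 60
  Xtr <- rbind(matrix(stats::rnorm(n * 120, 3), n),
               matrix(stats::rnorm(n * 120, -3), n))
  ytr <- rep(c("positive", "negative"), each = n)
  Xte <- rbind(matrix(stats::rnorm(n * 120, 3), n),
               matrix(stats::rnorm(n * 120, -3), n))
  for (kern in c("linear", "rbf", "poly")) {
    m <- train_svm(Xtr, ytr, kernel = kern, seed = 2)
    pr <- predict(m, Xte)
    expect_gte(mean(pr$label == ytr), 0.95)
  }
  two <- matrix(c(rep(1, 120), rep(-1, 120)), 2, byrow = TRUE)
  m2 <- suppressMessages(train_svm(two, c("positive", "negative"),
                                   kernel = "linear"))
  expect_equal(as.character(predict(m2, two)$label),
               c("positive", "negative"))
  expect_error(train_svm(Xtr, ytr, kernel = "sigmoidal"), "unknown")
})

test_that("network forward pass is a bounded sigmoid cascade", {
  ann <- list(W1 = matrix(0, 3, 2), b1 = c(0, 0),
              W2 = matrix(0, 2, 1), b2 = 0)
  expect_equal(ann_forward(ann, c(1, 2, 3)), 0.5)  # all-zero weights
  set.seed(53)
  ann$W1 <- matrix(stats::rnorm(6), 3, 2)
  ann$W2 <- matrix(stats::rnorm(2), 2, 1)
  out <- ann_forward(ann, matrix(stats::rnorm(300, sd = 50), 100, 3))
  expect_true(all(out > 0 & out < 1))
  # monotone response through a single all-positive hidden path
  mono <- list(W1 = matrix(1, 1, 1), b1 = 0, W2 = matrix(1, 1, 1), b2 = 0)
  xs <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(ann_forward(mono, matrix(xs, ncol = 1))) > 0))
  expect_error(ann_forward(ann, c(1, 2)), "does not match")
})

test_that("adaptive learning rate follows the accept/revert rule", {
  set.seed(54)
  X <- matrix(stats::rnorm(40 * 6), 40, 6)
  y <- ifelse(rowSums(X[, 1:3]) > 0, "positive", "negative")
  if (length(unique(y)) < 2) y[1] <- setdiff(c("positive", "negative"), y)[1]
  m <- ann_train(X, y, hidden = 5, gamma0 = 0.3, epochs = 200, seed = 1,
                 scale = FALSE)
  err <- m$fit$error_trace
  gam <- m$fit$gamma_trace
  expect_true(all(diff(err) <= 1e-15))  # accepted error never increases
  # gamma moves by exactly one factor per epoch
  ratios <- gam[-1] / gam[-length(gam)]
  expect_true(all(abs(ratios - 1.05) < 1e-12 | abs(ratios - 0.7) < 1e-12))
  # a reverted epoch is followed by gamma * down_factor
  same_err <- which(diff(err) == 0)
  if (length(same_err) > 0) {
    i <- same_err[1]
    expect_equal(gam[i + 1], gam[i] * 0.7, tolerance = 1e-12)
  }
  expect_error(ann_train(X, y, gamma0 = -1), "gamma0 > 0")
})

test_that("the network solves XOR within the epoch budget", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("negative", "positive", "positive", "negative")
  solved <- FALSE
  for (seed in 0:4) {
    m <- ann_train(X, y, hidden = 4, gamma0 = 2, epochs = 5000, seed = seed,
                   scale = FALSE)
    out <- ann_forward(m$fit, X)
    if (all((out >= 0.5) == (y == "positive"))) { solved <- TRUE; break }
  }
  expect_true(solved)
})

test_that("prediction respects thresholds, shapes and layout version", {
  ds <- sep_dataset(10)
  feat <- featurize_dataset(ds)
  m <- train_rf(feat$X, feat$y, trees = 51, seed = 4)
  expect_equal(as.character(predict(m, feat$X)$label),
               as.character(feat$y))  # memorizing forest reproduces labels
  allneg <- predict(m, feat$X, threshold = 1.01)
  expect_true(all(allneg$label == "negative"))
  empty <- predict(m, feat$X[0, , drop = FALSE])
  expect_length(empty$score, 0)
  expect_error(predict(m, feat$X[, 1:10]), "120 columns")
  m_bad <- m; m_bad$layout_version <- "119-v0"
  expect_error(predict(m_bad, feat$X), "feature layout")
})

test_that("label flip maps the confusion matrix onto its mirror", {
  set.seed(55)
  ds <- sep_dataset(12, seed = 56)
  feat <- featurize_dataset(ds)
  noisy <- feat$X + matrix(stats::rnorm(length(feat$X), sd = 30),
                           nrow(feat$X))
  y <- feat$y
  y_flip <- factor(ifelse(y == "positive", "negative", "positive"),
                   levels = c("negative", "positive"))
  m1 <- train_rf(noisy, y, trees = 101, seed = 9)
  m2 <- train_rf(noisy, y_flip, trees = 101, seed = 9)
  c1 <- confusion_counts(y, predict(m1, noisy)$label)
  c2 <- confusion_counts(y_flip, predict(m2, noisy)$label)
  expect_equal(c1$TP, c2$TN)
  expect_equal(c1$FP, c2$FN)
})

test_that("models survive a save/load round trip", {
  ds <- sep_dataset(8)
  feat <- featurize_dataset(ds)
  m <- train_rf(feat$X, feat$y, trees = 25, seed = 7)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, feat$X)$score, predict(m, feat$X)$score)
  junk <- tempfile(); saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "not a dnabindR model")
})
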