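test_that("confusion counting covers the four cells and their aliases", {
  cc <- confusion_counts(c("positive", "negative"), c("positive", "negative"))
  expect_equal(cc$FP + cc$FN, 0)
  cc2 <- confusion_counts(c("positive", "negative"), c("negative", "positive"))
  expect_equal(unlist(cc2[c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 1, FN = 1))
  expect_error(confusion_counts("positive", c("positive", "negative")),
               "differ in length")
  # published jackknife confusion matrix: totals and aliases
  cc5 <- confusion_from_cells(TP = 45492, TN = 8850, FP = 2676, FN = 115)
  al <- confusion_aliases(cc5)
  expect_equal(cc5$TP + cc5$TN + cc5$FP + cc5$FN, 57133)
  expect_equal(unname(al["Npos"]), 45607)
  expect_equal(unname(al["Nneg"]), 11526)
  expect_equal(unname(al["Nmiss"]), 115)
  expect_equal(unname(al["Nfalse"]), 2676)
})

test_that("metrics report NA (not zero) when undefined", {
  cc <- confusion_from_cells(TP = 0, TN = 5, FP = 0, FN = 0)  # no positives
  m <- classification_metrics(cc)
  expect_true(is.na(m[["Sn"]]))
  expect_true(is.na(m[["MCC"]]))
  expect_equal(m[["Acc"]], 1)
})

test_that("metric bounds hold over random confusion tables", {
  set.seed(61)
  for (i in 1:200) {
    cc <- confusion_from_cells(sample(0:50, 1), sample(0:50, 1),
                               sample(0:50, 1), sample(0:50, 1))
    m <- classification_metrics(cc)
    expect_true(is.na(m[["Acc"]]) || (m[["Acc"]] >= 0 && m[["Acc"]] <= 1))
    expect_true(is.na(m[["Sn"]]) || (m[["Sn"]] >= 0 && m[["Sn"]] <= 1))
    expect_true(is.na(m[["Sp"]]) || (m[["Sp"]] >= 0 && m[["Sp"]] <= 1))
    expect_true(is.na(m[["MCC"]]) || abs(m[["MCC"]]) <= 1 + 1e-12)
  }
})

test_that("ROC sweep matches the pair-counting oracle and pROC", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                       c("positive", "positive", "negative", "negative"))
  expect_equal(perfect$auc, 1)
  flat <- roc_curve(rep(0.5, 6), rep(c("positive", "negative"), 3))
  expect_equal(flat$auc, 0.5)
  # one inversion among 4 points: oracle = P(score_pos > score_neg) + ties/2
  sc <- c(0.9, 0.3, 0.6, 0.1)
  y <- c("positive", "positive", "negative", "negative")
  pos <- sc[y == "positive"]; neg <- sc[y == "negative"]
  pairs <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  expect_equal(roc_curve(sc, y)$auc, mean(pairs))
  expect_error(roc_curve(1:3, rep("positive", 3)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(62)
  sc2 <- stats::runif(60)
  y2 <- sample(rep(c("positive", "negative"), 30))
  ref <- as.numeric(pROC::auc(pROC::roc(response = y2, predictor = sc2,
                                        levels = c("negative", "positive"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_curve(sc2, y2)$auc, ref, tolerance = 1e-12)
})

make_sep_ds <- function(n_pos, n_neg, seed) {
  spec <- synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                         length_range = c(20, 40),
                         pos_weights = c(rep(1, 8), rep(0, 12)),
                         neg_weights = c(rep(0, 12), rep(1, 8)),
                         seed = seed)
  generate_synthetic(spec)
}

test_that("self-consistency with a memorizing forest reaches accuracy 1", {
  ds <- make_sep_ds(8, 12, seed = 63)
  rep <- run_protocol(ds, "self_consistency", "rf", seed = 2,
                      classifier_args = list(trees = 50))
  expect_equal(rep$metrics[["Acc"]], 1)
  expect_equal(rep$n_models, 1)
})

test_that("jackknife trains one model per row and pools all predictions", {
  ds <- make_sep_ds(4, 6, seed = 64)
  rep <- run_protocol(ds, "jackknife", "rf", seed = 5,
                      classifier_args = list(trees = 15))
  expect_equal(rep$n_models, 10)
  expect_length(rep$scores, 10)
  cc <- rep$confusion
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 10)
})

test_that("k-fold with k = n reproduces the jackknife exactly", {
  ds <- make_sep_ds(10, 20, seed = 65)
  feat <- featurize_dataset(ds)
  rj <- run_protocol(ds, "jackknife", "rf", seed = 9,
                     classifier_args = list(trees = 25), features = feat)
  rk <- run_protocol(ds, "kfold", "rf", k = 30, seed = 9,
                     classifier_args = list(trees = 25), features = feat)
  expect_identical(unclass(rj$confusion), unclass(rk$confusion))
  expect_identical(rj$scores, rk$scores)
})

test_that("pooled k-fold confusion totals equal the dataset size", {
  ds <- make_sep_ds(12, 24, seed = 66)
  rep <- run_protocol(ds, "kfold", "rf", k = 6, seed = 3,
                      classifier_args = list(trees = 15))
  cc <- rep$confusion
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, nrow(ds))
  expect_equal(rep$n_models, 6)
})

test_that("independent split evaluates only the held-out fraction", {
  ds <- make_sep_ds(20, 40, seed = 67)
  rep <- run_protocol(ds, "independent", "rf", train_frac = 0.7, seed = 4,
                      classifier_args = list(trees = 25))
  cc <- rep$confusion
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 18)  # 30% of each class
  expect_equal(rep$metrics[["Acc"]], 1)            # separable construction
})

test_that("report tables format percentages and undefined MCC", {
  ds <- make_sep_ds(6, 9, seed = 68)
  rep <- run_protocol(ds, "self_consistency", "rf", seed = 2,
                      classifier_args = list(trees = 20))
  tab <- report_table(rep)
  expect_equal(tab$Acc, 100)
  expect_equal(names(tab), c("Classifier", "Protocol", "TP", "TN", "FP",
                             "FN", "Acc", "Sn", "Sp", "MCC", "AUC"))
  path <- tempfile(fileext = ".tsv")
  write_report_tsv(rep, path)
  back <- utils::read.delim(path)
  expect_equal(back$Acc, 100)
  # undefined MCC renders as NA in the table
  fake <- rep
  fake$confusion <- confusion_from_cells(0, 15, 0, 0)
  fake$metrics <- classification_metrics(fake$confusion)
  expect_true(is.na(report_table(fake)$MCC))
})
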