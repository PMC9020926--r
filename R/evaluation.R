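#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred Parallel label vectors (`"positive"`/`"negative"`
#'   factors or characters).
#' @return An object of class `confusion_counts`: list with integer fields
#'   `TP`, `TN`, `FP`, `FN`. The conventional aliases are N+ = TP + FN
#'   (true binders), N- = TN + FP (true non-binders), N-+ = FN (binders
#'   missed), N+- = FP (non-binders called binders); see
#'   [confusion_aliases()].
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  t <- factor(as.character(y_true), levels = c("negative", "positive"))
  p <- factor(as.character(y_pred), levels = c("negative", "positive"))
  if (anyNA(t) || anyNA(p)) stop("labels must be 'positive' or 'negative'")
  structure(list(TP = sum(t == "positive" & p == "positive"),
                 TN = sum(t == "negative" & p == "negative"),
                 FP = sum(t == "negative" & p == "positive"),
                 FN = sum(t == "positive" & p == "negative")),
            class = "confusion_counts")
}

#' Build confusion counts directly from the four cells
#'
#' Convenience constructor for recomputing metrics from a published
#' confusion matrix.
#'
#' @param TP,TN,FP,FN Non-negative integer cell counts.
#' @return A `confusion_counts` object.
#' @export
confusion_from_cells <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_counts")
}

#' Alias view of a confusion matrix
#'
#' @param cc A `confusion_counts`.
#' @return Named vector with `Npos` (= TP + FN), `Nneg` (= TN + FP),
#'   `Nmiss` (binders predicted non-binding, = FN) and `Nfalse`
#'   (non-binders predicted binding, = FP).
#' @export
confusion_aliases <- function(cc) {
  c(Npos = cc$TP + cc$FN, Nneg = cc$TN + cc$FP,
    Nmiss = cc$FN, Nfalse = cc$FP)
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Computes the four metrics in either of two algebraically equivalent
#' formulations: the cell-based one (Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' Acc = (TP+TN)/total, MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)))
#' or the intuitive alias-based one (Sn = 1 - Nmiss/Npos, Sp = 1 -
#' Nfalse/Nneg, Acc = 1 - (Nmiss+Nfalse)/(Npos+Nneg), MCC =
#' (1 - (Nmiss/Npos + Nfalse/Nneg)) / sqrt((1 + (Nfalse-Nmiss)/Npos)
#' (1 + (Nmiss-Nfalse)/Nneg))). A metric whose denominator vanishes is
#' reported as `NA` (never silently 0).
#'
#' @param cc A `confusion_counts`.
#' @param formulation `"cells"` (default) or `"aliases"`.
#' @return Named numeric vector `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
classification_metrics <- function(cc, formulation = c("cells", "aliases")) {
  formulation <- match.arg(formulation)
  # double precision: the MCC denominator overflows integer range easily
  TP <- as.numeric(cc$TP); TN <- as.numeric(cc$TN)
  FP <- as.numeric(cc$FP); FN <- as.numeric(cc$FN)
  tot <- TP + TN + FP + FN
  if (formulation == "cells") {
    Sn <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
    Sp <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
    Acc <- if (tot > 0) (TP + TN) / tot else NA_real_
    den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
    MCC <- if (den > 0) (TP * TN - FP * FN) / sqrt(den) else NA_real_
  } else {
    al <- confusion_aliases(cc)
    Np <- al[["Npos"]]; Nn <- al[["Nneg"]]
    Nm <- al[["Nmiss"]]; Nf <- al[["Nfalse"]]
    Sn <- if (Np > 0) 1 - Nm / Np else NA_real_
    Sp <- if (Nn > 0) 1 - Nf / Nn else NA_real_
    Acc <- if (Np + Nn > 0) 1 - (Nm + Nf) / (Np + Nn) else NA_real_
    MCC <- if (Np > 0 && Nn > 0) {
      d <- (1 + (Nf - Nm) / Np) * (1 + (Nm - Nf) / Nn)
      if (d > 0) (1 - (Nm / Np + Nf / Nn)) / sqrt(d) else NA_real_
    } else NA_real_
  }
  c(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores, yielding one
#' (FPR, TPR) point per distinct score plus the (0, 0) origin, and
#' integrates the area by the trapezoidal rule.
#'
#' @param score Numeric prediction scores (higher = more positive).
#' @param y_true True labels; both classes must be present.
#' @return List with `points` (data.frame `threshold`, `FPR`, `TPR`) and
#'   `auc`.
#' @export
roc_curve <- function(score, y_true) {
  t <- factor(as.character(y_true), levels = c("negative", "positive"))
  npos <- sum(t == "positive"); nneg <- sum(t == "negative")
  if (npos == 0 || nneg == 0) stop("ROC needs both classes")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- t[ord] == "positive"
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct score
  pts <- data.frame(threshold = s[last],
                    FPR = fp[last] / nneg, TPR = tp[last] / npos)
  pts <- rbind(data.frame(threshold = Inf, FPR = 0, TPR = 0), pts)
  auc <- sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) +
                                utils::tail(pts$TPR, -1)) / 2)
  list(points = pts, auc = auc)
}

# Stratified fold assignment (internal). k == n collapses to identity
# assignment (fold i tests row i), which makes k-fold with k = n literally
# the jackknife.
assign_folds <- function(y, k, seed) {
  n <- length(y)
  if (k < 2 || k > n) stop("k must be in 2..n")
  if (k == n) return(seq_len(n))
  set.seed(seed)
  fold <- integer(n)
  for (cls in levels(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Run a validation protocol
#'
#' Featurizes the dataset once, then trains and tests the chosen
#' classifier under one of four protocols: \describe{
#'   \item{`"kfold"`}{stratified k-fold cross-validation; per-fold test
#'     predictions are pooled into a single confusion matrix (matching the
#'     convention of printing one confusion matrix whose totals equal the
#'     dataset size); per-fold metrics are also recorded;}
#'   \item{`"jackknife"`}{leave-one-out: each sequence is predicted by a
#'     model trained on all the others (identical to k-fold with k = n);}
#'   \item{`"self_consistency"`}{resubstitution: train and test on the full
#'     dataset;}
#'   \item{`"independent"`}{a single stratified train/test split with
#'     `train_frac` of each class used for training.}
#' }
#' Any scaler a classifier needs is fitted inside its training call, i.e.
#' on training rows only. Per-fold model seeds are `seed + fold`, so a run
#' is fully reproducible from `seed`.
#'
#' @param ds A [protein_dataset()].
#' @param protocol One of `"kfold"`, `"jackknife"`, `"self_consistency"`,
#'   `"independent"`.
#' @param classifier `"rf"`, `"svm"` or `"ann"`.
#' @param k Number of folds for `"kfold"` (default 10).
#' @param train_frac Training fraction for `"independent"` (default 0.7).
#' @param seed Integer seed controlling fold draws and model training.
#' @param classifier_args Named list of extra arguments for the trainer
#'   (e.g. `list(trees = 25)`).
#' @param features Optional precomputed output of [featurize_dataset()]
#'   for `ds` (skips re-featurization).
#' @return An `evaluation_report`: list with `protocol`, `classifier`,
#'   `seed`, `n_models`, pooled `confusion`, `metrics`, `roc`, `scores`,
#'   `predicted`, and `fold` assignments.
#' @export
run_protocol <- function(ds, protocol = c("kfold", "jackknife",
                                          "self_consistency", "independent"),
                         classifier = c("rf", "svm", "ann"),
                         k = 10L, train_frac = 0.7, seed = 1L,
                         classifier_args = list(), features = NULL) {
  protocol <- match.arg(protocol)
  classifier <- match.arg(classifier)
  if (is.null(features)) features <- featurize_dataset(ds, scaling = "none")
  X <- features$X
  y <- factor(as.character(features$y), levels = c("negative", "positive"))
  n <- nrow(X)
  trainer <- switch(classifier, rf = train_rf, svm = train_svm,
                    ann = ann_train)

  train_one <- function(tr_idx, fold_seed) {
    do.call(trainer, c(list(X = X[tr_idx, , drop = FALSE], y = y[tr_idx],
                            seed = fold_seed), classifier_args))
  }

  scores <- rep(NA_real_, n)
  pred <- factor(rep(NA_character_, n), levels = c("negative", "positive"))
  eval_idx <- seq_len(n)
  fold <- NULL

  if (protocol == "self_consistency") {
    model <- train_one(seq_len(n), seed)
    out <- predict(model, X)
    scores <- out$score; pred <- out$label
    n_models <- 1L
  } else if (protocol == "independent") {
    set.seed(seed)
    tr <- unlist(lapply(levels(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, round(train_frac * length(idx)))
    }))
    te <- setdiff(seq_len(n), tr)
    if (length(unique(y[tr])) < 2L) stop("training split has a single class")
    model <- train_one(tr, seed)
    out <- predict(model, X[te, , drop = FALSE])
    scores[te] <- out$score; pred[te] <- out$label
    eval_idx <- te
    n_models <- 1L
  } else {
    kk <- if (protocol == "jackknife") n else as.integer(k)
    fold <- assign_folds(y, kk, seed)
    # a fold whose training part is single-class is redrawn once
    bad <- any(vapply(seq_len(kk), function(f)
      length(unique(y[fold != f])) < 2L, logical(1)))
    if (bad && kk < n) {
      fold <- assign_folds(y, kk, seed + 1L)
      bad <- any(vapply(seq_len(kk), function(f)
        length(unique(y[fold != f])) < 2L, logical(1)))
    }
    if (bad) stop("could not draw folds with both classes in every ",
                  "training part")
    for (f in seq_len(kk)) {
      te <- which(fold == f)
      model <- train_one(setdiff(seq_len(n), te), seed + f)
      out <- predict(model, X[te, , drop = FALSE])
      scores[te] <- out$score
      pred[te] <- out$label
    }
    n_models <- kk
  }

  cc <- confusion_counts(y[eval_idx], pred[eval_idx])
  metrics <- classification_metrics(cc)
  roc <- if (length(unique(y[eval_idx])) == 2L) {
    roc_curve(scores[eval_idx], y[eval_idx])
  } else NULL
  structure(list(protocol = protocol, classifier = classifier, seed = seed,
                 k = if (protocol == "kfold") k else NULL,
                 train_frac = if (protocol == "independent") train_frac else NULL,
                 n_models = n_models, confusion = cc, metrics = metrics,
                 roc = roc, scores = scores[eval_idx],
                 truth = y[eval_idx], predicted = pred[eval_idx],
                 eval_rows = eval_idx, fold = fold),
            class = "evaluation_report")
}

#' Tabulate evaluation reports
#'
#' @param reports A single `evaluation_report` or a list of them.
#' @return A data.frame with columns Classifier, Protocol, TP, TN, FP, FN,
#'   Acc, Sn, Sp, MCC (Acc/Sn/Sp as percentages rounded to 2 decimals;
#'   undefined MCC rendered `NA`) and AUC.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    m <- r$metrics
    data.frame(Classifier = r$classifier, Protocol = r$protocol,
               TP = r$confusion$TP, TN = r$confusion$TN,
               FP = r$confusion$FP, FN = r$confusion$FN,
               Acc = round(100 * m[["Acc"]], 2),
               Sn = round(100 * m[["Sn"]], 2),
               Sp = round(100 * m[["Sp"]], 2),
               MCC = round(m[["MCC"]], 4),
               AUC = if (is.null(r$roc)) NA_real_ else round(r$roc$auc, 4),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report table as TSV
#'
#' @param reports As for [report_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(reports, path) {
  utils::write.table(report_table(reports), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
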