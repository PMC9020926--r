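# Internal constructor for a trained model wrapper.
new_dbp_model <- function(kind, fit, threshold, scaler = NULL, extra = list()) {
  structure(c(list(kind = kind, fit = fit, threshold = threshold,
                   scaler = scaler,
                   layout_version = feature_layout_version()), extra),
            class = "dbp_model")
}

check_two_classes <- function(y) {
  y <- factor(y, levels = c("negative", "positive"))
  if (anyNA(y)) stop("labels must be 'positive' or 'negative'")
  if (length(unique(y)) < 2L) stop("both classes must be present for training")
  y
}

#' Train a random forest classifier
#'
#' Bagged decision-tree ensemble via \pkg{randomForest}, with the
#' community-default per-node feature subset of floor(sqrt(120)) = 10
#' predictors and unlimited depth. The positive-class vote fraction is the
#' prediction score. Deterministic given `seed`.
#'
#' @param X n x 120 feature matrix.
#' @param y Labels (`"positive"` / `"negative"`), both classes present.
#' @param trees Number of trees (default 100).
#' @param mtry Per-node feature subset size (default `floor(sqrt(ncol(X)))`).
#' @param seed Integer RNG seed.
#' @return A `dbp_model` of kind `"rf"`.
#' @export
train_rf <- function(X, y, trees = 100L, mtry = floor(sqrt(ncol(X))),
                     seed = 1L) {
  y <- check_two_classes(y)
  set.seed(seed)
  fit <- randomForest::randomForest(x = X, y = y, ntree = trees, mtry = mtry)
  new_dbp_model("rf", fit, threshold = 0.5)
}

#' Train a support vector machine
#'
#' Maximum-margin classifier via \pkg{e1071} with a linear, polynomial or
#' radial-basis kernel (default RBF, C = 1, gamma = 1/(ncol * var), the
#' usual defaults). Features are z-scored with a scaler fitted on the
#' training rows and stored in the model, since the margin is
#' scale-sensitive. The signed decision-function value is the score
#' (threshold 0).
#'
#' @param X n x 120 feature matrix (unscaled).
#' @param y Labels, both classes present.
#' @param kernel `"radial"`, `"linear"` or `"polynomial"` (aliases `"rbf"`,
#'   `"poly"` accepted).
#' @param cost SVM cost parameter C.
#' @param seed Integer RNG seed.
#' @return A `dbp_model` of kind `"svm"`.
#' @export
train_svm <- function(X, y, kernel = "radial", cost = 1, seed = 1L) {
  y <- check_two_classes(y)
  kernel <- c(rbf = "radial", radial = "radial", linear = "linear",
              poly = "polynomial", polynomial = "polynomial")[kernel]
  if (is.na(kernel)) stop("unknown SVM kernel")
  scaler <- suppressMessages(fit_scaler(X))
  Xs <- apply_scaler(X, scaler)
  set.seed(seed)
  fit <- e1071::svm(x = Xs, y = y, kernel = kernel, cost = cost,
                    scale = FALSE)
  new_dbp_model("svm", fit, threshold = 0, scaler = scaler)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the single-hidden-layer network
#'
#' O = f(W2' f(W1' x + b1) + b2) with the logistic activation
#' f(x) = 1 / (1 + exp(-x)) at both layers. Outputs are strictly in (0, 1)
#' for any finite input.
#'
#' @param ann List with weight matrices `W1` (inputs x hidden), `W2`
#'   (hidden x 1) and bias vectors `b1`, `b2`.
#' @param X n x inputs matrix (or a single vector).
#' @return Numeric vector of n outputs in (0, 1).
#' @export
ann_forward <- function(ann, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(ann$W1)) stop("input width does not match the network")
  H <- sigmoid(sweep(X %*% ann$W1, 2, ann$b1, "+"))
  as.numeric(sigmoid(H %*% ann$W2 + ann$b2))
}

#' Train the neural network with an adaptive learning rate
#'
#' Full-batch gradient descent on mean squared error for a
#' single-hidden-layer logistic network. After each epoch the training
#' error is compared with the previous accepted error: if it increased,
#' that epoch's weight update is reverted and the learning rate is
#' multiplied by `down_factor`; otherwise the update is accepted and the
#' rate is multiplied by `up_factor`. The accepted-error sequence is
#' therefore non-increasing by construction. Features are z-scored
#' internally (scaler stored in the model). Bias terms are used at both
#' layers; weights start uniform(-0.5, 0.5) from `seed`.
#'
#' @param X n x 120 feature matrix (unscaled).
#' @param y Labels, both classes present.
#' @param hidden Hidden-layer width (default 20).
#' @param gamma0 Initial learning rate (default 0.01).
#' @param epochs Number of epochs (default 300).
#' @param seed Integer RNG seed.
#' @param up_factor Rate multiplier after an accepted epoch (> 1).
#' @param down_factor Rate multiplier after a reverted epoch (in (0, 1)).
#' @param scale Z-score the features internally (default TRUE; set FALSE
#'   for pre-scaled toy problems).
#' @return A `dbp_model` of kind `"ann"`; `fit` holds the weights plus
#'   `gamma_trace` and `error_trace` (one accepted-error entry per epoch).
#' @export
ann_train <- function(X, y, hidden = 20L, gamma0 = 0.01, epochs = 300L,
                      seed = 1L, up_factor = 1.05, down_factor = 0.7,
                      scale = TRUE) {
  y <- check_two_classes(y)
  stopifnot(gamma0 > 0, up_factor > 1, down_factor > 0, down_factor < 1)
  yn <- as.numeric(y == "positive")
  scaler <- NULL
  if (scale) {
    scaler <- suppressMessages(fit_scaler(X))
    X <- apply_scaler(X, scaler)
  }
  n <- nrow(X); d <- ncol(X)
  set.seed(seed)
  ann <- list(W1 = matrix(stats::runif(d * hidden, -0.5, 0.5), d, hidden),
              b1 = stats::runif(hidden, -0.5, 0.5),
              W2 = matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1),
              b2 = stats::runif(1, -0.5, 0.5))
  mse <- function(a) mean((ann_forward(a, X) - yn) ^ 2)
  gamma <- gamma0
  prev_err <- mse(ann)
  gamma_trace <- numeric(epochs)
  error_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    H <- sigmoid(sweep(X %*% ann$W1, 2, ann$b1, "+"))
    O <- as.numeric(sigmoid(H %*% ann$W2 + ann$b2))
    dO <- (2 / n) * (O - yn) * O * (1 - O)          # dE/d(pre-activation)
    gW2 <- crossprod(H, dO)
    gb2 <- sum(dO)
    dH <- (dO %*% t(ann$W2)) * H * (1 - H)
    gW1 <- crossprod(X, dH)
    gb1 <- colSums(dH)
    if (!all(is.finite(gW1)) || !all(is.finite(gW2))) {
      stop("non-finite gradient at epoch ", ep, "; training aborted")
    }
    cand <- list(W1 = ann$W1 - gamma * gW1, b1 = ann$b1 - gamma * gb1,
                 W2 = ann$W2 - gamma * gW2, b2 = ann$b2 - gamma * gb2)
    err <- mse(cand)
    gamma_trace[ep] <- gamma
    if (err > prev_err) {          # dismiss this epoch's parameters
      gamma <- gamma * down_factor
    } else {
      ann <- cand
      prev_err <- err
      gamma <- gamma * up_factor
    }
    error_trace[ep] <- prev_err
  }
  fit <- c(ann, list(gamma_trace = gamma_trace, error_trace = error_trace))
  new_dbp_model("ann", fit, threshold = 0.5, scaler = scaler)
}

#' Predict with a trained model
#'
#' Returns a continuous score per row (random-forest vote fraction, SVM
#' decision value, or network output) and the thresholded class label.
#'
#' @param object A `dbp_model`.
#' @param X Feature matrix with 120 columns (unscaled; any stored scaler is
#'   applied automatically).
#' @param threshold Score cutoff for the positive class; defaults to the
#'   model's own (0.5 for rf/ann vote or output, 0 for the SVM decision
#'   value).
#' @param ... Unused.
#' @return List with `score` (numeric) and `label` (factor
#'   negative/positive), one entry per row of `X`.
#' @export
predict.dbp_model <- function(object, X, threshold = object$threshold, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!identical(object$layout_version, feature_layout_version())) {
    stop("model was built with feature layout '", object$layout_version,
         "' but the package uses '", feature_layout_version(), "'")
  }
  if (ncol(X) != 120L) stop("feature matrix must have 120 columns")
  if (nrow(X) == 0L) {
    return(list(score = numeric(0),
                label = factor(character(0),
                               levels = c("negative", "positive"))))
  }
  Xs <- apply_scaler(X, object$scaler)
  score <- switch(object$kind,
    rf = unname(predict(object$fit, Xs, type = "prob")[, "positive"]),
    svm = {
      pr <- predict(object$fit, Xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the decision value toward the first class in its
      # column name; flip so that higher always means "positive"
      fav <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
      if (fav == "positive") as.numeric(dv) else -as.numeric(dv)
    },
    ann = ann_forward(object$fit, Xs),
    stop("unknown model kind: ", object$kind))
  label <- factor(ifelse(score >= threshold, "positive", "negative"),
                  levels = c("negative", "positive"))
  list(score = score, label = label)
}

#' Save a trained model to a single archive file
#'
#' @param model A `dbp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dbp_model"))
  saveRDS(list(format = "dnabindR-model-1", model = model), path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path Archive path.
#' @return The `dbp_model`.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "dnabindR-model-1")) {
    stop("not a dnabindR model archive: ", path)
  }
  obj$model
}
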