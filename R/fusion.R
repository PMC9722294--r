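# Feature fusion, classifier bank, and cross-validated macro metrics.

# ---- normalization ----------------------------------------------------------

#' Fit / apply per-feature standardization
#'
#' `normalize_fit` estimates per-column mean and standard deviation on a
#' training set; `normalize_apply` standardizes any feature matrix with
#' those training statistics only (never its own), which is what keeps
#' cross-validation leakage-free.  Constant columns (zero training sd) map
#' to 0.
#'
#' @param train numeric matrix, one row per sample.
#' @return `normalize_fit`: an object of class `"feature_normalizer"`.
#' @export
normalize_fit <- function(train) {
  if (!is.matrix(train) || nrow(train) == 0) stop("training set must be a non-empty matrix")
  mu <- colMeans(train)
  ctr <- train - matrix(mu, nrow(train), ncol(train), byrow = TRUE)
  # population standard deviation: a column standardized with its own
  # statistics then has mean 0 and sd exactly 1
  sd <- sqrt(colMeans(ctr * ctr))
  structure(list(mean = mu, sd = sd, p = ncol(train)), class = "feature_normalizer")
}

#' @rdname normalize_fit
#' @param model a `"feature_normalizer"`.
#' @param features numeric matrix with the same columns as the training set.
#' @return `normalize_apply`: the standardized matrix.
#' @export
normalize_apply <- function(model, features) {
  stopifnot(inherits(model, "feature_normalizer"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$p)
    stop(sprintf("feature dimension mismatch: model has %d columns, input %d",
                 model$p, ncol(features)))
  n <- nrow(features)
  ctr <- features - matrix(model$mean, n, model$p, byrow = TRUE)
  sd <- ifelse(model$sd > 0, model$sd, 1)
  out <- ctr / matrix(sd, n, model$p, byrow = TRUE)
  if (any(model$sd == 0)) out[, model$sd == 0] <- 0
  out
}

#' Fuse texture and deep feature blocks
#'
#' Concatenates the two feature matrices column-wise, recording the index
#' ranges of each source block.  Rows must correspond to the same images in
#' the same order (checked via rownames when both are named).
#'
#' @param texture,deep numeric matrices with one row per image.
#' @return fused matrix with attribute `block_boundaries`.
#' @export
fuse_features <- function(texture, deep) {
  if (nrow(texture) != nrow(deep))
    stop("texture and deep feature matrices have different numbers of rows")
  if (!is.null(rownames(texture)) && !is.null(rownames(deep)) &&
      !identical(rownames(texture), rownames(deep)))
    stop("texture and deep feature rows are keyed by different image ids")
  fused <- cbind(texture, deep)
  attr(fused, "block_boundaries") <- list(
    texture = seq_len(ncol(texture)),
    deep = ncol(texture) + seq_len(ncol(deep)))
  fused
}

# ---- classifier bank --------------------------------------------------------

.classifier_kinds <- c("1-NN", "3-NN", "5-NN", "MLP", "RF", "SVM")

# Deterministic k-nearest-neighbor: neighbor ties resolved by training
# index, vote ties by smallest class index.
.knn_predict <- function(trainX, trainY, testX, k) {
  d2 <- matrix(rowSums(testX^2), nrow(testX), nrow(trainX)) +
    matrix(rowSums(trainX^2), nrow(testX), nrow(trainX), byrow = TRUE) -
    2 * tcrossprod(testX, trainX)
  K <- nlevels(trainY)
  yi <- as.integer(trainY)
  pred <- integer(nrow(testX))
  k <- min(k, nrow(trainX))
  for (i in seq_len(nrow(testX))) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- tabulate(yi[nn], nbins = K)
    pred[i] <- which.max(votes)
  }
  factor(levels(trainY)[pred], levels = levels(trainY))
}

# Small single-hidden-layer MLP (ReLU, softmax, Adam, full batch) trained to
# a loss-change tolerance.  Handles the high-dimensional fused features that
# quasi-Newton MLP fitters cannot.
.mlp_fit <- function(X, y, hidden = 100L, seed = 0L, maxit = 300L,
                     tol = 1e-4, lr = 1e-3) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K)
  b2 <- numeric(K)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  ms <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  vs <- ms
  prev <- Inf
  for (t in seq_len(maxit)) {
    H <- pmax(X %*% W1 + matrix(b1, n, hidden, byrow = TRUE), 0)
    Z <- H %*% W2 + matrix(b2, n, K, byrow = TRUE)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    loss <- -mean(log(pmax(P[Y == 1], 1e-12)))
    if (abs(prev - loss) < tol) break
    prev <- loss
    dZ <- (P - Y) / n
    g <- list(W2 = crossprod(H, dZ), b2 = colSums(dZ))
    dH <- tcrossprod(dZ, W2) * (H > 0)
    g$W1 <- crossprod(X, dH); g$b1 <- colSums(dH)
    for (nm in names(g)) {
      ms[[nm]] <- 0.9 * ms[[nm]] + 0.1 * g[[nm]]
      vs[[nm]] <- 0.999 * vs[[nm]] + 0.001 * g[[nm]]^2
      step <- lr * (ms[[nm]] / (1 - 0.9^t)) / (sqrt(vs[[nm]] / (1 - 0.999^t)) + 1e-8)
      assign(nm, get(nm) - step)
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(y))
}

.mlp_predict <- function(model, X) {
  n <- nrow(X)
  H <- pmax(X %*% model$W1 + matrix(model$b1, n, length(model$b1), byrow = TRUE), 0)
  Z <- H %*% model$W2 + matrix(model$b2, n, length(model$b2), byrow = TRUE)
  factor(model$levels[max.col(Z, ties.method = "first")], levels = model$levels)
}

#' Train one classifier of the bank
#'
#' The bank covers the classifier families practitioners benchmark on this
#' problem: 1/3/5-NN,
#' a one-hidden-layer MLP (100 units, Adam, convergence tolerance 1e-4), a
#' 100-tree random forest, and an RBF SVM with `C = 1`.  Features are
#' expected to be pre-normalized; stochastic learners are seeded.
#'
#' @param features numeric matrix, one row per sample (normalized).
#' @param labels factor (or coercible) with >= 2 classes.
#' @param kind one of `"1-NN"`, `"3-NN"`, `"5-NN"`, `"MLP"`, `"RF"`, `"SVM"`.
#' @param seed RNG seed for stochastic learners.
#' @return object of class `"cellpheno_classifier"` usable with `predict()`.
#' @export
train_classifier <- function(features, labels, kind, seed = 0L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (!kind %in% .classifier_kinds)
    stop(sprintf("unknown classifier kind '%s'; choose from: %s",
                 kind, paste(.classifier_kinds, collapse = ", ")))
  model <- switch(kind,
    "1-NN" = , "3-NN" = , "5-NN" = list(X = features, y = labels,
                                        k = as.integer(substr(kind, 1, 1))),
    "MLP" = .mlp_fit(features, labels, seed = seed),
    "RF" = { set.seed(seed)
             randomForest::randomForest(x = features, y = labels, ntree = 100) },
    "SVM" = e1071::svm(x = features, y = labels, kernel = "radial", cost = 1,
                       scale = FALSE))
  structure(list(kind = kind, model = model, levels = levels(labels)),
            class = "cellpheno_classifier")
}

#' @export
predict.cellpheno_classifier <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  out <- switch(object$kind,
    "1-NN" = , "3-NN" = , "5-NN" =
      .knn_predict(object$model$X, object$model$y, newdata, object$model$k),
    "MLP" = .mlp_predict(object$model, newdata),
    "RF" = predict(object$model, newdata),
    "SVM" = predict(object$model, newdata))
  factor(as.character(out), levels = object$levels)
}

# ---- metrics ----------------------------------------------------------------

#' Macro metrics from a confusion matrix
#'
#' Rows index the true class, columns the predicted class.  Accuracy is the
#' trace over the total, on the 0-100 scale; per-class precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)` and `F1 = 2*precision*recall /
#' (precision+recall)` are macro-averaged (unweighted mean over classes) on
#' the 0-1 scale.  A class never predicted (`TP+FP = 0`) gets precision 0
#' with a warning; an F1 with a zero denominator is 0.
#'
#' @param cm square non-negative numeric matrix.
#' @return list with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, and a `per_class` data frame.
#' @export
metrics_from_confusion <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || length(cm) == 0)
    stop("confusion matrix must be a non-empty square matrix")
  if (any(cm < 0)) stop("confusion matrix entries must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  if (anyNA(prec)) {
    warning("class with no predicted samples: precision defined as 0")
    prec[is.na(prec)] <- 0
  }
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = 100 * sum(tp) / total,
       macro_precision = mean(prec),
       macro_recall = mean(rec),
       macro_f1 = mean(f1),
       per_class = data.frame(precision = prec, recall = rec, f1 = f1))
}

# ---- cross-validation -------------------------------------------------------

# Stratified fold assignment: within each class, members are shuffled by the
# seeded RNG and dealt to folds round-robin.
.stratified_folds <- function(labels, k_folds, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k_folds)
      stop(sprintf("class '%s' has %d members, fewer than k_folds = %d",
                   cl, length(idx), k_folds))
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k_folds), length(idx))
  }
  fold
}

#' Cross-validated evaluation of the classifier bank
#'
#' Stratified k-fold cross-validation with the feature normalization fitted
#' inside each training fold (test folds never contribute statistics).  Per
#' fold and per classifier, predictions on the held-out fold are accumulated
#' into a confusion matrix; macro metrics are computed per fold and
#' aggregated as mean and sample standard deviation across folds.
#'
#' @param features numeric matrix, one row per sample (raw; normalization is
#'   fitted per fold).
#' @param labels factor (or coercible) of class labels.
#' @param k_folds number of folds (default 5).
#' @param seed seed controlling fold assignment and stochastic learners.
#' @param kinds classifier kinds to evaluate.
#' @return object of class `"evaluation_report"`.
#' @export
cross_validate <- function(features, labels, k_folds = 5L, seed = 0L,
                           kinds = .classifier_kinds) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  stopifnot(all(kinds %in% .classifier_kinds))
  fold <- .stratified_folds(labels, k_folds, seed)
  K <- nlevels(labels)
  per_kind <- stats::setNames(vector("list", length(kinds)), kinds)
  for (kind in kinds) {
    confusions <- vector("list", k_folds)
    fold_metrics <- vector("list", k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f; te <- !tr
      norm <- normalize_fit(features[tr, , drop = FALSE])
      Xtr <- normalize_apply(norm, features[tr, , drop = FALSE])
      Xte <- normalize_apply(norm, features[te, , drop = FALSE])
      fit <- train_classifier(Xtr, labels[tr], kind, seed = seed + f)
      pred <- predict(fit, Xte)
      cm <- table(factor(labels[te], levels = levels(labels)),
                  factor(pred, levels = levels(labels)))
      cm <- matrix(as.numeric(cm), K, K,
                   dimnames = list(true = levels(labels), pred = levels(labels)))
      confusions[[f]] <- cm
      fold_metrics[[f]] <- metrics_from_confusion(cm)
    }
    get1 <- function(nm) vapply(fold_metrics, `[[`, numeric(1), nm)
    agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
    per_kind[[kind]] <- list(
      confusions = confusions,
      folds = data.frame(fold = seq_len(k_folds),
                         accuracy = get1("accuracy"),
                         macro_precision = get1("macro_precision"),
                         macro_recall = get1("macro_recall"),
                         macro_f1 = get1("macro_f1")),
      accuracy = agg(get1("accuracy")),
      macro_precision = agg(get1("macro_precision")),
      macro_recall = agg(get1("macro_recall")),
      macro_f1 = agg(get1("macro_f1")))
  }
  structure(list(results = per_kind, k_folds = as.integer(k_folds),
                 seed = seed, n = length(labels), classes = levels(labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Stratified %d-fold cross-validation (n = %d, %d classes, seed %d)\n",
              x$k_folds, x$n, length(x$classes), x$seed))
  cat(sprintf("%-6s %18s %18s\n", "kind", "accuracy (%)", "macro F1"))
  for (kind in names(x$results)) {
    r <- x$results[[kind]]
    cat(sprintf("%-6s %10.2f ± %.2f %12.4f ± %.4f\n", kind,
                r$accuracy["mean"], r$accuracy["sd"],
                r$macro_f1["mean"], r$macro_f1["sd"]))
  }
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, ...) {
  rows <- lapply(names(object$results), function(kind) {
    r <- object$results[[kind]]
    data.frame(kind = kind,
               accuracy_mean = r$accuracy["mean"], accuracy_sd = r$accuracy["sd"],
               precision_mean = r$macro_precision["mean"],
               recall_mean = r$macro_recall["mean"],
               f1_mean = r$macro_f1["mean"], f1_sd = r$macro_f1["sd"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
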