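# Multi-classifier benchmarking: SVM (RBF, one-vs-one), C4.5-style
# information-gain decision tree, single-hidden-layer MLP ("BP") and LDA,
# under repeated stratified cross-validation or the fixed-split
# repeatability protocol. Standardization parameters are always fit on the
# training portion only (no leakage).

.classifiers <- c("svm", "c45", "mlp", "lda")

#' Evaluation protocol
#'
#' `kfold`: stratified k-fold repeated until `repeats * k` fold
#' evaluations (default 10 x 10 = 100). `fixed`: the repeatability
#' protocol, `test_per_emotion` trials per emotion drawn as the test set
#' each repeat (default 8 test + 72 train per repeat, 10 repeats).
#'
#' @param scheme `"kfold"` or `"fixed"`.
#' @param k folds for `kfold`.
#' @param repeats repetitions.
#' @param test_per_emotion test trials per emotion for `fixed`.
#' @param classifier one of `"svm"`, `"c45"`, `"mlp"`, `"lda"`.
#' @param seed integer seed.
#' @return list of class `eval_protocol`.
#' @export
eval_protocol <- function(scheme = c("kfold", "fixed"), k = 10, repeats = 10,
                          test_per_emotion = 8, classifier = "lda",
                          seed = 1L) {
  scheme <- match.arg(scheme)
  classifier <- match.arg(classifier, .classifiers)
  structure(list(scheme = scheme, k = k, repeats = repeats,
                 test_per_emotion = test_per_emotion,
                 classifier = classifier, seed = as.integer(seed)),
            class = "eval_protocol")
}

# Standardize test data with training statistics only.
standardizer <- function(Xtr) {
  mu <- colMeans(Xtr)
  s <- apply(Xtr, 2, sd)
  s[s == 0] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, s, "/")
}

fit_classifier <- function(id, X, y) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  switch(id,
    svm = suppressWarnings(e1071::svm(X, y, kernel = "radial",
                                      probability = TRUE)),
    c45 = {
      df <- data.frame(X, .y = y, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(minsplit = 5, cp = 0.01,
                                                  xval = 0))
    },
    mlp = {
      size <- 2 * ncol(X) + 1
      nnet::nnet(X, nnet::class.ind(y), size = size, softmax = TRUE,
                 decay = 5e-3, maxit = 200, trace = FALSE,
                 MaxNWts = 50000)
    },
    lda = {
      # LDA needs within-group variance; drop (near-)degenerate columns
      pooled <- sqrt(colMeans(do.call(rbind, lapply(levels(y), function(cl) {
        Xg <- X[y == cl, , drop = FALSE]
        apply(Xg, 2, var)
      })), na.rm = TRUE))
      keep <- which(pooled > 2e-4)  # mirrors MASS::lda's constancy tolerance
      if (length(keep) == 0) keep <- seq_len(ncol(X))
      list(fit = suppressWarnings(MASS::lda(X[, keep, drop = FALSE],
                                            grouping = y)),
           keep = keep)
    },
    stop("unknown classifier id: ", id))
}

predict_scores <- function(id, model, X, levels) {
  X <- as.matrix(X)
  sc <- switch(id,
    svm = {
      p <- predict(model, X, probability = TRUE)
      attr(p, "probabilities")
    },
    c45 = predict(model, data.frame(X, check.names = FALSE), type = "prob"),
    mlp = {
      p <- predict(model, X)
      colnames(p) <- model$lev %||% colnames(p)
      p
    },
    lda = predict(model$fit, X[, model$keep, drop = FALSE])$posterior)
  out <- matrix(0, nrow(X), length(levels), dimnames = list(NULL, levels))
  out[, colnames(sc)] <- sc
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predict_class <- function(scores) {
  factor(colnames(scores)[max.col(scores, ties.method = "first")],
         levels = colnames(scores))
}

# Stratified fold assignment; guarantees every class in every training fold
# (reshuffles up to 20 times, logging via warning).
stratified_folds <- function(y, k) {
  n <- length(y)
  for (attempt in 1:20) {
    folds <- integer(n)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f) {
      all(levels(y) %in% y[folds != f])
    }, logical(1)))
    if (ok) return(folds)
  }
  warning("could not build folds with all classes in every training fold")
  folds
}

#' Repeated cross-validated accuracy
#'
#' Mean accuracy (percent) over `repeats * k` stratified fold evaluations
#' (100 with the defaults). Features are standardized with training-fold
#' statistics only.
#'
#' @param features trials x features numeric matrix.
#' @param labels emotion factor.
#' @param protocol `eval_protocol` (scheme `"kfold"`).
#' @return list: `mean_accuracy` (%), `per_repeat` (%), `per_fold` (%).
#' @export
crossval_accuracy <- function(features, labels, protocol = eval_protocol()) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  stopifnot(nlevels(y) >= 2, all(is.finite(X)))
  set.seed(protocol$seed)
  per_fold <- matrix(NA_real_, protocol$repeats, protocol$k)
  for (rep in seq_len(protocol$repeats)) {
    folds <- stratified_folds(y, protocol$k)
    for (f in seq_len(protocol$k)) {
      tr <- folds != f
      if (sum(!tr) == 0) { per_fold[rep, f] <- NA; next }
      std <- standardizer(X[tr, , drop = FALSE])
      model <- fit_classifier(protocol$classifier, std(X[tr, , drop = FALSE]),
                              y[tr])
      sc <- predict_scores(protocol$classifier, model,
                           std(X[!tr, , drop = FALSE]), levels(y))
      per_fold[rep, f] <- 100 * mean(predict_class(sc) == y[!tr])
    }
  }
  per_repeat <- rowMeans(per_fold, na.rm = TRUE)
  list(mean_accuracy = mean(per_fold, na.rm = TRUE),
       per_repeat = per_repeat, per_fold = per_fold,
       classifier = protocol$classifier)
}

#' Accuracy along nested CFS subsets
#'
#' Evaluates `crossval_accuracy` on the ranking's prefix subsets at the
#' requested sizes and flags the plateau: the smallest size whose accuracy
#' is within 2 points of the best over all sizes.
#'
#' @param ranking `cfs_ranking` for the same feature table.
#' @param features,labels as in [crossval_accuracy()].
#' @param protocol `eval_protocol`.
#' @param sizes subset sizes to evaluate.
#' @return data.frame size/accuracy with attribute `plateau_size`.
#' @export
nested_subset_curve <- function(ranking, features, labels,
                                protocol = eval_protocol(),
                                sizes = c(2, 5, 10, 15, 20, 25, 27)) {
  stopifnot(inherits(ranking, "cfs_ranking"))
  sizes <- sizes[sizes <= ranking$n_features]
  acc <- vapply(sizes, function(s) {
    sub <- ranking$order[seq_len(s)]
    crossval_accuracy(features[, sub, drop = FALSE], labels,
                      protocol)$mean_accuracy
  }, numeric(1))
  out <- data.frame(size = sizes, accuracy = acc)
  attr(out, "plateau_size") <- sizes[which(acc >= max(acc) - 2)[1]]
  out
}

#' One-vs-rest ROC curves and macro AUC
#'
#' Trapezoidal AUC per class from continuous scores, plus the macro
#' average and the ROC points.
#'
#' @param scores trials x classes score matrix (column names = classes).
#' @param labels true labels.
#' @return list: `auc` (per class), `macro_auc`, `roc` (data.frame class /
#'   fpr / tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least two classes")
  classes <- colnames(scores)
  rocs <- list()
  aucs <- numeric(0)
  for (cl in classes) {
    pos <- labels == cl
    if (!any(pos) || all(pos)) next
    s <- scores[, cl]
    # rank statistic == trapezoidal AUC of the empirical ROC
    r <- rank(s, ties.method = "average")
    n1 <- sum(pos); n0 <- sum(!pos)
    aucs[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- c(Inf, sort(unique(s), decreasing = TRUE))
    pts <- t(vapply(thr, function(t) {
      c(fpr = sum(s[!pos] >= t) / n0, tpr = sum(s[pos] >= t) / n1)
    }, numeric(2)))
    rocs[[cl]] <- data.frame(class = cl, fpr = pts[, 1], tpr = pts[, 2])
  }
  list(auc = aucs, macro_auc = mean(aucs),
       roc = do.call(rbind, rocs))
}

#' Fixed-split repeatability protocol
#'
#' For a dataset of `4 * trials_per_emotion` trials, each repeat draws
#' `test_per_emotion` random trials per emotion as the test set (8 + 72
#' with the reference design), trains on the rest, and records test
#' accuracy; reports the per-repeat accuracies and their average.
#'
#' @param features trials x features matrix (one electrode).
#' @param labels emotion factor.
#' @param protocol `eval_protocol` with scheme `"fixed"`.
#' @return list: `per_repeat` (%), `mean_accuracy` (%).
#' @export
repeatability_run <- function(features, labels,
                              protocol = eval_protocol(scheme = "fixed")) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  counts <- table(y)
  if (length(unique(counts)) != 1) stop("unbalanced trial counts per emotion")
  if (any(counts <= protocol$test_per_emotion)) {
    stop("need more than ", protocol$test_per_emotion, " trials per emotion")
  }
  set.seed(protocol$seed)
  per_repeat <- vapply(seq_len(protocol$repeats), function(rep) {
    test <- unlist(lapply(levels(y), function(cl) {
      sample(which(y == cl), protocol$test_per_emotion)
    }))
    tr <- setdiff(seq_len(nrow(X)), test)
    std <- standardizer(X[tr, , drop = FALSE])
    model <- fit_classifier(protocol$classifier, std(X[tr, , drop = FALSE]),
                            y[tr])
    sc <- predict_scores(protocol$classifier, model,
                         std(X[test, , drop = FALSE]), levels(y))
    100 * mean(predict_class(sc) == y[test])
  }, numeric(1))
  list(per_repeat = per_repeat, mean_accuracy = mean(per_repeat),
       classifier = protocol$classifier)
}
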