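# Classifier wrappers, evaluation metrics, validation schemes, rank-sum
# screening and sequential forward selection. Malignant is the positive
# class throughout; scores are oriented so larger means malignant.

#' Classifier specification
#'
#' @param kind `"knn"` (K nearest neighbors with Mahalanobis distance),
#'   `"svm_linear"` (linear-kernel SVM) or `"random_forest"`
#' @param k neighbor count for KNN (odd, default 5)
#' @param n_trees forest size (default 100)
#' @param cost SVM regularization constant (default 1, on standardized inputs)
#' @param seed seed for the stochastic learners
#' @return object of class `classifier_spec`
#' @export
classifier_spec <- function(kind = c("knn", "svm_linear", "random_forest"),
                            k = 5L, n_trees = 100L, cost = 1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(k >= 1L, k %% 2L == 1L, n_trees >= 1L, cost > 0)
  structure(list(kind = kind, k = as.integer(k), n_trees = as.integer(n_trees),
                 cost = cost, seed = as.integer(seed)),
            class = "classifier_spec")
}

as_label_factor <- function(y) factor(as.character(y), levels = c("benign", "malignant"))

# Mahalanobis KNN: whiten with the Cholesky factor of the (ridge-regularized)
# training covariance, then Euclidean K nearest neighbors; the score is the
# malignant vote fraction.
knn_mahalanobis <- function(X_train, y_train, X_test, k) {
  S <- stats::cov(X_train)
  eps <- 1e-8 * mean(diag(S))
  R <- tryCatch(chol(S + diag(eps, ncol(S))),
                error = function(e) tryCatch(
                  chol(S + diag(1e-3 * mean(diag(S)) + 1e-12, ncol(S))),
                  error = function(e2) stopf("training covariance singular after regularization")))
  W <- solve(R)
  Zt <- X_train %*% W
  Zq <- X_test %*% W
  mal <- y_train == "malignant"
  scores <- apply(Zq, 1L, function(z) {
    d2 <- colSums((t(Zt) - z)^2)
    mean(mal[order(d2)[seq_len(k)]])
  })
  scores
}

#' Train a classifier and score a test set
#'
#' @param spec a [classifier_spec]
#' @param X_train,y_train training features and labels (both classes present)
#' @param X_test test features
#' @return list with `scores` (larger = malignant: KNN malignant vote
#'   fraction, SVM signed margin, forest malignant tree fraction), `labels`
#'   (hard predictions at the natural threshold: majority vote / zero margin
#'   / 0.5), and `threshold`
#' @export
fit_predict <- function(spec, X_train, y_train, X_test) {
  stopifnot(inherits(spec, "classifier_spec"))
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  y_train <- as_label_factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stopf("training set must contain both classes")
  if (nrow(X_test) < 1L) stopf("test set is empty")
  if (spec$kind == "knn") {
    scores <- knn_mahalanobis(X_train, y_train, X_test, spec$k)
    thr <- 0.5
  } else if (spec$kind == "svm_linear") {
    set.seed(spec$seed)
    fit <- e1071::svm(x = X_train, y = y_train, kernel = "linear",
                      cost = spec$cost, scale = TRUE)
    dv <- attr(stats::predict(fit, X_test, decision.values = TRUE),
               "decision.values")
    # orient the margin so positive means malignant
    scores <- if (grepl("^malignant", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    thr <- 0
  } else {
    set.seed(spec$seed)
    fit <- randomForest::randomForest(x = X_train, y = y_train,
                                      ntree = spec$n_trees)
    scores <- stats::predict(fit, X_test, type = "prob")[, "malignant"]
    thr <- 0.5
  }
  scores <- as.numeric(scores)
  list(scores = scores,
       labels = ifelse(scores > thr, "malignant", "benign"),
       threshold = thr)
}

#' Classification metrics from pooled scores
#'
#' Confusion counts at the given threshold (score > threshold predicts
#' malignant), accuracy / sensitivity / specificity in percent, ROC by
#' sweeping all score thresholds with trapezoidal AUC, and a 95% AUC
#' confidence interval by stratified bootstrap (2000 replicates, seeded).
#'
#' @param y_true labels (`"benign"`/`"malignant"`, both present)
#' @param scores numeric scores, larger = malignant
#' @param threshold hard-label threshold (default 0.5)
#' @param labels optional hard labels overriding the threshold rule
#' @param ci compute the bootstrap AUC CI? (default TRUE)
#' @param n_boot bootstrap replicates (default 2000)
#' @param seed seed for the bootstrap
#' @return object of class `eval_report`: `accuracy`, `sensitivity`,
#'   `specificity` (percent), `auc`, `auc_ci`, `roc` (data.frame fpr/tpr),
#'   `confusion` (tp/fp/tn/fn), `threshold`, `seed`
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5, labels = NULL,
                            ci = TRUE, n_boot = 2000L, seed = 1L) {
  y_true <- as_label_factor(y_true)
  if (nlevels(droplevels(y_true)) < 2L)
    stopf("y_true must contain both classes")
  pred <- as_label_factor(labels %||% ifelse(scores > threshold, "malignant", "benign"))
  tp <- sum(pred == "malignant" & y_true == "malignant")
  fn <- sum(pred == "benign" & y_true == "malignant")
  tn <- sum(pred == "benign" & y_true == "benign")
  fp <- sum(pred == "malignant" & y_true == "benign")
  roc_obj <- pROC::roc(response = y_true, predictor = as.numeric(scores),
                       levels = c("benign", "malignant"), direction = "<",
                       quiet = TRUE)
  auc <- as.numeric(pROC::auc(roc_obj))
  auc_ci <- if (ci) {
    set.seed(seed)
    as.numeric(pROC::ci.auc(roc_obj, method = "bootstrap",
                            boot.n = n_boot, boot.stratified = TRUE,
                            progress = "none"))[c(1, 3)]
  } else c(NA_real_, NA_real_)
  ord <- order(1 - roc_obj$specificities, roc_obj$sensitivities)
  roc_pts <- data.frame(fpr = (1 - roc_obj$specificities)[ord],
                        tpr = roc_obj$sensitivities[ord])
  structure(list(accuracy = 100 * (tp + tn) / length(y_true),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 auc = auc, auc_ci = auc_ci, roc = roc_pts,
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 threshold = threshold, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report%s> accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.3f",
              if (!is.null(x$scheme)) paste0(" ", x$scheme) else "",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  if (!anyNA(x$auc_ci)) cat(sprintf(" (95%% CI %.3f-%.3f)", x$auc_ci[1], x$auc_ci[2]))
  cat("\n")
  invisible(x)
}

#' Cross-validated evaluation of a classifier
#'
#' Schemes: stratified 60/40 holdout, stratified k-fold (out-of-fold scores
#' pooled, then one ROC and one confusion matrix on the pooled predictions),
#' and leave-one-out. An optional resampler is applied either to the full
#' dataset before splitting (`"full_dataset"`, replicating the study design,
#' with a leakage warning) or inside each training fold (`"within_fold"`).
#'
#' @param X feature matrix
#' @param y labels
#' @param spec a [classifier_spec]
#' @param scheme `"holdout"`, `"kfold"` or `"loocv"`
#' @param train_fraction holdout training share (default 0.6)
#' @param k_folds folds for `"kfold"` (default 10)
#' @param seed controls fold/split assignment
#' @param resampler optional `function(X, y)` returning a `resample_result`
#' @param resample_mode where to apply the resampler
#' @param ci forward to [compute_metrics]
#' @return an `eval_report` with `scheme` and `n_fits` fields
#' @export
cross_validate <- function(X, y, spec,
                           scheme = c("kfold", "holdout", "loocv"),
                           train_fraction = 0.6, k_folds = 10L, seed = 1L,
                           resampler = NULL,
                           resample_mode = c("full_dataset", "within_fold"),
                           ci = TRUE) {
  scheme <- match.arg(scheme)
  resample_mode <- match.arg(resample_mode)
  X <- as.matrix(X)
  y <- as.character(y)
  if (!is.null(resampler) && resample_mode == "full_dataset") {
    warnf("resampling the full dataset before cross-validation leaks synthetic samples into test folds (study-replication mode)")
    rs <- resampler(X, y)
    X <- rs$X
    y <- rs$y
  }
  n <- nrow(X)
  if (n < 10L) stopf("need at least 10 samples")
  yf <- as_label_factor(y)

  if (scheme == "holdout") {
    set.seed(seed)
    train <- unlist(lapply(levels(yf), function(lev) {
      idx <- which(yf == lev)
      sample(idx, round(train_fraction * length(idx)))
    }))
    folds <- list(test = setdiff(seq_len(n), train))
    assign_train <- list(train)
  } else if (scheme == "kfold") {
    fid <- stratified_folds(yf, k_folds, seed)
    folds <- lapply(seq_len(k_folds), function(f) which(fid == f))
    assign_train <- lapply(folds, function(te) setdiff(seq_len(n), te))
    names(folds) <- paste0("fold", seq_len(k_folds))
  } else {
    folds <- as.list(seq_len(n))
    assign_train <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
  }

  scores <- numeric(0); labels <- character(0); truth <- character(0)
  test_all <- integer(0)
  thr <- 0.5
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- assign_train[[f]]
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (length(unique(ytr)) < 2L)
      stopf("class absent from training data of fold %d", f)
    if (!is.null(resampler) && resample_mode == "within_fold") {
      rs <- resampler(Xtr, ytr)
      Xtr <- rs$X; ytr <- rs$y
    }
    pr <- fit_predict(spec, Xtr, ytr, X[te, , drop = FALSE])
    scores <- c(scores, pr$scores)
    labels <- c(labels, pr$labels)
    truth <- c(truth, y[te])
    test_all <- c(test_all, te)
    thr <- pr$threshold
  }
  rep_ <- compute_metrics(truth, scores, threshold = thr, labels = labels,
                          ci = ci, seed = seed)
  rep_$scheme <- sprintf("%s(seed=%d)", scheme, seed)
  rep_$n_fits <- length(folds)
  rep_
}

#' Wilcoxon rank-sum screening of feature discrimination
#'
#' Two-sided rank-sum test per feature between the benign and malignant
#' groups (exact enumeration for combined group sizes <= 12 without ties,
#' normal approximation with tie correction otherwise), with the
#' significance tiers `~` (p >= 0.05), `*` (p < 0.05) and `**` (p < 0.001).
#'
#' @param benign,malignant data.frames/matrices of feature values by group
#'   (same columns, each group >= 2 rows)
#' @return data.frame with `feature`, `p`, `tier`
#' @export
rank_sum_screen <- function(benign, malignant) {
  benign <- as.data.frame(benign)
  malignant <- as.data.frame(malignant)
  stopifnot(identical(names(benign), names(malignant)))
  if (nrow(benign) < 2L || nrow(malignant) < 2L)
    stopf("both groups need at least 2 observations")
  res <- lapply(names(benign), function(col) {
    a <- benign[[col]]; b <- malignant[[col]]
    exact <- (length(a) + length(b)) <= 12L && !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact)$p.value)
    data.frame(feature = col, p = p,
               tier = if (p < 0.001) "**" else if (p < 0.05) "*" else "~",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: starting from the empty subset, each round
#' evaluates every remaining feature joined to the current subset with the
#' misclassification-rate evaluator and accepts the best candidate only if
#' it strictly lowers the criterion; ties among candidates are broken toward
#' the lower feature index. Stops when no candidate improves (or all
#' features are selected).
#'
#' @param X feature matrix with named columns
#' @param y labels (both classes present)
#' @param spec [classifier_spec] used by the default evaluator
#' @param evaluator optional `function(X_subset, y)` returning the
#'   misclassification rate; the default is pooled 10-fold stratified CV
#'   error of `spec` with fold assignment fixed by `seed`
#' @param seed seed for the default evaluator's folds
#' @return object of class `sfs_trace`: `features` (accepted names in
#'   order), `criterion` (value after each acceptance, strictly decreasing),
#'   `log` (data.frame of every candidate evaluation)
#' @export
sequential_forward_selection <- function(X, y, spec = classifier_spec("knn"),
                                         evaluator = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (ncol(X) < 2L) stopf("need at least 2 features")
  y <- as.character(y)
  if (length(unique(y)) < 2L) stopf("labels are degenerate (single class)")
  if (is.null(evaluator)) {
    yf <- as_label_factor(y)
    fid <- stratified_folds(yf, 10L, seed)
    evaluator <- function(Xs, yy) {
      err <- 0L
      for (f in sort(unique(fid))) {
        te <- which(fid == f)
        pr <- fit_predict(spec, Xs[-te, , drop = FALSE], yy[-te],
                          Xs[te, , drop = FALSE])
        err <- err + sum(pr$labels != yy[te])
      }
      err / nrow(Xs)
    }
  }
  selected <- integer(0)
  crit <- Inf
  criterion <- numeric(0)
  log_rows <- list()
  repeat {
    remaining <- setdiff(seq_len(ncol(X)), selected)
    if (length(remaining) == 0L) break
    best_f <- NA_integer_; best_c <- Inf
    for (f in remaining) {                     # ascending index => tie-break
      cf <- evaluator(X[, c(selected, f), drop = FALSE], y)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(step = length(selected) + 1L,
                   candidate = colnames(X)[f], criterion = cf)
      if (cf < best_c) { best_c <- cf; best_f <- f }
    }
    if (best_c < crit) {
      selected <- c(selected, best_f)
      crit <- best_c
      criterion <- c(criterion, crit)
    } else break
    if (crit == 0) break
  }
  structure(list(features = colnames(X)[selected],
                 criterion = criterion,
                 log = do.call(rbind, log_rows)),
            class = "sfs_trace")
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat("<sfs_trace>\n")
  for (i in seq_along(x$features))
    cat(sprintf("  %d. %-20s criterion %.4f\n", i, x$features[i], x$criterion[i]))
  invisible(x)
}
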