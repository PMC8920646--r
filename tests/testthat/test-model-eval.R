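test_that("KNN votes with Mahalanobis neighbors and self-neighbor property", {
  # 1-D layout engineered so the 5 nearest neighbors of 0.25 are 4 malignant
  # and 1 benign
  Xtr <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 10, 11, 12, 13))
  ytr <- c(rep("malignant", 4), rep("benign", 5))
  pr <- fit_predict(classifier_spec("knn"), Xtr, ytr, matrix(0.25))
  expect_equal(pr$scores, 0.8)
  expect_equal(pr$labels, "malignant")

  # separable data scored on itself: a training point is its own neighbor
  set.seed(1)
  Xs <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  ys <- rep(c("benign", "malignant"), each = 20)
  prs <- fit_predict(classifier_spec("knn"), Xs, ys, Xs)
  expect_equal(mean(prs$labels == ys), 1)
})

test_that("SVM margins orient toward malignant and forests are seeded", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  y <- rep(c("benign", "malignant"), each = 30)
  pr <- fit_predict(classifier_spec("svm_linear"), X, y, X)
  expect_gt(min(pr$scores[31:60]), max(pr$scores[1:30]))
  expect_equal(pr$threshold, 0)

  rf1 <- fit_predict(classifier_spec("random_forest", seed = 5), X, y, X)
  rf2 <- fit_predict(classifier_spec("random_forest", seed = 5), X, y, X)
  expect_identical(rf1$scores, rf2$scores)

  expect_error(fit_predict(classifier_spec("knn"), X, rep("benign", 60), X),
               "both classes")
})

test_that("metrics match hand arithmetic on a fixed confusion", {
  # TP 19, FN 1, TN 18, FP 2
  y <- c(rep("malignant", 20), rep("benign", 20))
  labels <- c(rep("malignant", 19), "benign", rep("benign", 18), "malignant", "malignant")
  scores <- ifelse(labels == "malignant", 0.9, 0.1)
  rep_ <- compute_metrics(y, scores, labels = labels, ci = FALSE)
  expect_equal(rep_$sensitivity, 95)
  expect_equal(rep_$specificity, 90)
  expect_equal(rep_$accuracy, 92.5)
  expect_equal(unname(rep_$confusion), c(19, 2, 18, 1))
})

test_that("AUC equals the rank statistic and flips under score reversal", {
  set.seed(3)
  y <- rep(c("benign", "malignant"), times = c(30, 25))
  scores <- sample(seq(0.01, 0.99, length.out = 55))  # ties-free
  r1 <- compute_metrics(y, scores, ci = FALSE)
  U <- stats::wilcox.test(scores[y == "malignant"], scores[y == "benign"])$statistic
  expect_equal(r1$auc, unname(U) / (25 * 30), tolerance = 1e-12)
  r2 <- compute_metrics(y, -scores, ci = FALSE)
  expect_equal(r2$auc, 1 - r1$auc, tolerance = 1e-12)

  # perfect separation
  ys <- rep(c("benign", "malignant"), each = 10)
  rp <- compute_metrics(ys, c(runif(10, 0, 0.4), runif(10, 0.6, 1)), ci = FALSE)
  expect_equal(rp$auc, 1)
  expect_equal(rp$accuracy, 100)
  # ROC points monotone in both coordinates
  expect_true(all(diff(r1$roc$fpr) >= 0))
  expect_true(all(diff(r1$roc$tpr) >= 0))
  expect_error(compute_metrics(rep("benign", 5), runif(5)), "both classes")
})

test_that("label-independent scores give null AUC near 0.5", {
  inside <- 0L
  for (s in 1:100) {
    set.seed(400 + s)
    y <- rep(c("benign", "malignant"), each = 250)
    auc <- compute_metrics(y, rnorm(500), ci = FALSE)$auc
    inside <- inside + (auc >= 0.4 && auc <= 0.6)
  }
  expect_gte(inside, 95L)
})

test_that("cross-validation schemes pool out-of-fold predictions", {
  set.seed(4)
  X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 8), 30, 2))
  y <- rep(c("benign", "malignant"), each = 30)
  spec <- classifier_spec("knn")
  r10 <- cross_validate(X, y, spec, "kfold", seed = 1, ci = FALSE)
  expect_equal(r10$accuracy, 100)
  expect_equal(r10$auc, 1)
  expect_equal(r10$n_fits, 10L)
  rl <- cross_validate(X, y, spec, "loocv", ci = FALSE)
  expect_equal(rl$n_fits, nrow(X))          # exactly n fits
  rh <- cross_validate(X, y, spec, "holdout", seed = 2, ci = FALSE)
  expect_equal(rh$n_fits, 1L)
  expect_equal(rh$accuracy, 100)
})

test_that("rank-sum screen reproduces exact small-sample p values and tiers", {
  sc <- rank_sum_screen(data.frame(x = c(1, 2, 3)), data.frame(x = c(10, 11, 12)))
  expect_equal(sc$p, 0.1, tolerance = 1e-12)   # 2 / choose(6,3)
  expect_equal(sc$tier, "~")

  same <- rank_sum_screen(data.frame(x = c(1, 2, 3, 4)), data.frame(x = c(1, 2, 3, 4)))
  expect_equal(same$tier, "~")

  set.seed(5)
  big <- rank_sum_screen(data.frame(x = rnorm(60)), data.frame(x = rnorm(60, 5)))
  expect_equal(big$tier, "**")
  expect_error(rank_sum_screen(data.frame(x = 1), data.frame(x = 1:3)),
               "at least 2")
})

test_that("SFS selects a separating feature first and stops at zero error", {
  set.seed(6)
  n <- 60
  y <- rep(c("benign", "malignant"), each = n / 2)
  X <- cbind(sep = c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 10, 0.3)),
             noise1 = rnorm(n), noise2 = rnorm(n))
  tr <- sequential_forward_selection(X, y, classifier_spec("knn"), seed = 1)
  expect_equal(tr$features[1], "sep")
  expect_equal(tr$criterion[1], 0)
  expect_length(tr$features, 1L)
  expect_error(sequential_forward_selection(X, rep("benign", n)), "degenerate")
})

test_that("SFS equals the brute-force greedy oracle and strictly improves", {
  set.seed(7)
  n <- 40
  y <- rep(c("benign", "malignant"), each = n / 2)
  X <- cbind(a = rnorm(n, ifelse(y == "malignant", 1.2, 0)),
             b = rnorm(n, ifelse(y == "malignant", 0.8, 0)),
             c = rnorm(n))
  spec <- classifier_spec("knn")
  yf <- factor(y, c("benign", "malignant"))
  fid <- qustc:::stratified_folds(yf, 10L, 3L)
  evaluator <- function(Xs, yy) {
    err <- 0L
    for (f in 1:10) {
      te <- which(fid == f)
      pr <- fit_predict(spec, Xs[-te, , drop = FALSE], yy[-te], Xs[te, , drop = FALSE])
      err <- err + sum(pr$labels != yy[te])
    }
    err / nrow(Xs)
  }
  tr <- sequential_forward_selection(X, y, evaluator = evaluator)
  expect_identical(tr$features, greedy_sfs_oracle(X, y, evaluator))
  expect_true(all(diff(c(Inf, tr$criterion)) < 0))
})

test_that("SFS rarely grows on label-independent features", {
  short <- 0L
  for (s in 1:100) {
    set.seed(800 + s)
    n <- 40
    y <- rep(c("benign", "malignant"), each = n / 2)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    tr <- sequential_forward_selection(X, y, classifier_spec("knn"), seed = s)
    short <- short + (length(tr$features) <= 2)
  }
  expect_gte(short, 90L)
})
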