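# grid search, jackknife protocol, metrics and ROC

test_that("grid search finds a separating pair, stays in bounds, is deterministic", {
  set.seed(51)
  n <- 15
  X <- rbind(matrix(rnorm(n * 2, -4), n), matrix(rnorm(n * 2, 4), n))
  y <- rep(1:2, each = n)
  cfg <- svm_config(C_exp = c(-5, 0, 5, 10, 15),
                    gamma_exp = c(-15, -8, -1, 5), cv_folds = 3, seed = 1)
  gs <- grid_search_rbf(X, y, cfg)
  expect_equal(gs$cv_accuracy, 1)
  expect_true(all(gs$grid$C >= 2^-5 & gs$grid$C <= 2^15))
  expect_true(all(gs$grid$gamma >= 2^-15 & gs$grid$gamma <= 2^5))
  expect_equal(nrow(gs$grid), 20L)

  gs2 <- grid_search_rbf(X, y, cfg)
  expect_identical(gs[c("C", "gamma", "cv_accuracy")],
                   gs2[c("C", "gamma", "cv_accuracy")])

  # identical rows with random labels: CV accuracy near the majority rate
  Xc <- matrix(1, 24, 2)
  yc <- rep(1:2, each = 12)
  gsc <- grid_search_rbf(Xc, yc, svm_config(C_exp = 0, gamma_exp = 0,
                                            cv_folds = 3, seed = 1))
  expect_lte(abs(gsc$cv_accuracy - 0.5), 0.25)

  expect_error(grid_search_rbf(X, rep(1, 30), cfg), "two classes")
  expect_error(svm_config(C_exp = -6:0), "within")
  expect_error(svm_config(gamma_exp = 0:6), "within")
})

test_that("ties prefer smaller C then smaller gamma", {
  # trivially separable data: many grid cells reach accuracy 1
  set.seed(52)
  X <- rbind(matrix(rnorm(30, -6, 0.2), 15), matrix(rnorm(30, 6, 0.2), 15))
  y <- rep(1:2, each = 15)
  gs <- grid_search_rbf(X, y, svm_config(C_exp = -2:2, gamma_exp = -4:0,
                                         cv_folds = 3, seed = 2))
  top <- gs$grid[gs$grid$accuracy == max(gs$grid$accuracy), ]
  expect_equal(gs$C, min(top$C))
  expect_equal(gs$gamma, min(top$gamma[top$C == gs$C]))
})

test_that("jackknife predicts every sample exactly once, in order", {
  set.seed(53)
  X <- rbind(matrix(rnorm(8, -3, 0.3), 4), matrix(rnorm(8, 3, 0.3), 4))
  y <- rep(1:2, each = 4)
  res <- jackknife_predict(X, y, C = 4, gamma = 0.5)
  expect_equal(res$y_pred, y)            # separable LOOCV: all correct
  expect_length(res$y_pred, 8L)
  expect_equal(res$y_true, y)
  expect_equal(dim(res$scores), c(8L, 2L))
  expect_true(all(is.finite(res$scores)))
})

test_that("strict-mode folds are blind to the held-out row", {
  set.seed(54)
  n <- 12
  X <- rbind(matrix(rnorm(n * 6, -2), n), matrix(rnorm(n * 6, 2), n))
  y <- rep(1:2, each = n)
  lf <- list(r = 2, K = 5, affinity = "plain")
  fold_T <- function(X) lfda_fit(X[-1, , drop = FALSE], y[-1], r = lf$r,
                                 K = lf$K, affinity = lf$affinity)$T
  X2 <- X
  X2[1, ] <- X2[1, ] + 100    # perturb only the held-out row of fold 1
  expect_equal(fold_T(X), fold_T(X2))
})

test_that("metrics reproduce hand-computed confusion values", {
  # TP=5 TN=3 FP=1 FN=1 for class 1
  y_true <- c(rep(1, 6), rep(2, 4))
  y_pred <- c(rep(1, 5), 2, 1, rep(2, 3))
  rep_ <- per_class_metrics(list(y_true = y_true, y_pred = y_pred))
  m1 <- rep_$per_class[rep_$per_class$class == 1, ]
  expect_equal(m1$Sens, 5 / 6)
  expect_equal(m1$Spec, 3 / 4)
  expect_equal(m1$MCC, 14 / 24)
  expect_equal(rep_$OA, 8 / 10)
  # confusion conservation laws
  expect_equal(sum(rep_$confusion), 10)
  expect_equal(unname(rowSums(rep_$confusion)), c(6, 4))
  expect_equal(rep_$OA, sum(diag(rep_$confusion)) / sum(rep_$confusion))
})

test_that("degenerate all-one-class predictions trigger the MCC 0/0 rule", {
  y_true <- rep(c(1, 2), each = 5)
  y_pred <- rep(1, 10)
  rep_ <- per_class_metrics(list(y_true = y_true, y_pred = y_pred))
  m1 <- rep_$per_class[rep_$per_class$class == 1, ]
  expect_equal(m1$Sens, 1)
  expect_equal(m1$Spec, 0)
  expect_equal(m1$MCC, 0)
  # perfect predictor
  perf <- per_class_metrics(list(y_true = y_true, y_pred = y_true))
  expect_equal(perf$OA, 1)
  expect_true(all(perf$per_class$Sens == 1 & perf$per_class$Spec == 1 &
                    perf$per_class$MCC == 1))
})

test_that("ROC/AUC behaves at its analytic limits and under reversal", {
  y <- rep(c(1, 2), each = 10)
  s_perfect <- cbind(c(seq(0.9, 0.55, length.out = 10),
                       seq(0.45, 0.1, length.out = 10)), 0)
  s_perfect[, 2] <- 1 - s_perfect[, 1]
  colnames(s_perfect) <- c(1, 2)
  r <- ovr_roc_auc(list(y_true = y, scores = s_perfect))
  expect_equal(r$auc, 1)

  rev_ <- ovr_roc_auc(list(y_true = y, scores = 1 - s_perfect))
  expect_equal(rev_$auc, 1 - r$auc)

  set.seed(55)
  yn <- sample(1:3, 200, replace = TRUE)
  sn <- matrix(runif(600), 200, 3, dimnames = list(NULL, 1:3))
  null <- ovr_roc_auc(list(y_true = yn, scores = sn))
  expect_lt(abs(null$auc - 0.5), 0.08)

  # absent class skipped with a warning
  expect_warning(
    partial <- ovr_roc_auc(list(y_true = rep(1:2, 10),
                                scores = matrix(runif(60), 20, 3,
                                                dimnames = list(NULL, 1:3)))),
    "absent")
  expect_length(partial$per_class_auc, 2L)
})

test_that("shuffled labels on separable data give chance-level jackknife OA", {
  set.seed(56)
  n <- 12
  X <- rbind(matrix(rnorm(n * 2, -4), n), matrix(rnorm(n * 2, 4), n))
  y_shuf <- sample(rep(1:2, each = n))
  res <- jackknife_predict(X, y_shuf, C = 1, gamma = 0.5)
  oa <- mean(res$y_pred == res$y_true)
  # binomial 95% band around 1/2 for n = 24
  expect_lt(abs(oa - 0.5), 1.96 * sqrt(0.25 / 24) + 1e-9)
})
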