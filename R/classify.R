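#' Default SVM search configuration
#'
#' The exhaustive log2 grid: C over 2^-5..2^15 and gamma over 2^-15..2^5 in
#' integer-exponent steps (a 21 x 21 grid), scored by cross-validated
#' overall accuracy. `cv_folds = "loo"` scores by leave-one-out accuracy
#' (deterministic, and the criterion the original model-building protocol
#' selects parameters by); an integer K gives seed-fixed stratified K-fold
#' folds.
#'
#' @param C_exp,gamma_exp integer exponent grids.
#' @param cv_folds folds for the grid-search cross-validation, or `"loo"`.
#' @param seed RNG seed controlling K-fold assignment (unused for LOO).
#' @return list of class `svm_config`.
#' @export
svm_config <- function(C_exp = -5:15, gamma_exp = -15:5, cv_folds = 5,
                       seed = 1) {
  stopifnot(all(C_exp == round(C_exp)), all(gamma_exp == round(gamma_exp)))
  if (min(C_exp) < -5 || max(C_exp) > 15)
    stop("C exponents must stay within [-5, 15]")
  if (min(gamma_exp) < -15 || max(gamma_exp) > 5)
    stop("gamma exponents must stay within [-15, 5]")
  loo <- identical(cv_folds, "loo")
  if (!loo) stopifnot(is.numeric(cv_folds), cv_folds >= 2)
  structure(list(C_exp = as.integer(C_exp),
                 gamma_exp = as.integer(gamma_exp),
                 cv_folds = if (loo) "loo" else as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "svm_config")
}

# leave-one-out accuracy for every grid cell. Only the pairwise classifiers
# containing the held-out sample need retraining, and the per-gamma kernel
# is shared across all C values; the per-fold SMO solves run in C++.
.loo_grid_accuracy <- function(X, y, grid) {
  n <- length(y)
  cls <- sort(unique(y))
  nc <- length(cls)
  pairs <- combn(nc, 2)
  D2 <- as.matrix(dist(X))^2
  pinfo <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- cls[pairs[1, p]]; b <- cls[pairs[2, p]]
    idx <- which(y %in% c(a, b))
    list(ai = pairs[1, p], bi = pairs[2, p], idx = idx,
         other = setdiff(seq_len(n), idx),
         yb = ifelse(y[idx] == a, 1, -1))
  })
  acc <- numeric(nrow(grid))
  for (ge in unique(grid$gamma_exp)) {
    K <- exp(-2^ge * D2)
    Kp <- lapply(pinfo, function(pi)
      list(pair = K[pi$idx, pi$idx, drop = FALSE],
           cross = K[pi$idx, pi$other, drop = FALSE]))
    warm <- rep(list(numeric(0)), length(pinfo))
    for (g in which(grid$gamma_exp == ge)) {   # C ascending within gamma
      C <- 2^grid$C_exp[g]
      votes <- matrix(0, n, nc)
      for (p in seq_along(pinfo)) {
        pi <- pinfo[[p]]
        res <- pair_loo_decisions(Kp[[p]]$pair, pi$yb, Kp[[p]]$cross, C,
                                  warm[[p]])
        warm[[p]] <- res$alpha
        dec <- numeric(n)
        dec[pi$idx] <- res$dec_loo
        dec[pi$other] <- res$dec_other
        votes[, pi$ai] <- votes[, pi$ai] + (dec > 0)
        votes[, pi$bi] <- votes[, pi$bi] + (dec <= 0)
      }
      pred <- cls[apply(votes, 1, ovo_vote_tiebreak)]
      acc[g] <- mean(pred == y)
    }
  }
  acc
}

# deterministic stratified fold assignment
make_stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  folds <- integer(length(y))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Exhaustively evaluates every (C, gamma) pair on the integer-exponent
#' power-of-two grid by stratified K-fold cross-validated accuracy of the
#' one-vs-one classifier. Ties are broken toward smaller C, then smaller
#' gamma. Deterministic for a given seed.
#'
#' @param X n x d feature matrix.
#' @param y class indices in 1..c; every class needs >= cv_folds members.
#' @param cfg an [svm_config()].
#' @return list with `C`, `gamma`, `cv_accuracy`, and `grid` (a data.frame
#'   of every evaluated C, gamma and its CV accuracy).
#' @export
grid_search_rbf <- function(X, y, cfg = svm_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("grid search needs at least two classes")
  loo <- identical(cfg$cv_folds, "loo")
  grid <- expand.grid(C_exp = cfg$C_exp, gamma_exp = cfg$gamma_exp)
  grid <- grid[order(grid$C_exp, grid$gamma_exp), ]
  if (loo) {
    if (any(table(y) < 2))
      stop("leave-one-out grid search needs at least two members per class")
    acc <- .loo_grid_accuracy(X, y, grid)
  } else {
    k <- cfg$cv_folds
    if (any(table(y) < k))
      stop("every class needs at least cv_folds = ", k,
           " members for stratified folds")
    folds <- make_stratified_folds(y, k, cfg$seed)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      C <- 2^grid$C_exp[g]; gamma <- 2^grid$gamma_exp[g]
      correct <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        fit <- ovo_svm_fit(X[tr, , drop = FALSE], y[tr], C, gamma,
                           platt = FALSE)
        sum(predict(fit, X[!tr, , drop = FALSE])$class == y[!tr])
      }, numeric(1))
      sum(correct) / length(y)
    }, numeric(1))
  }
  best <- which.max(acc)  # grid is (C, gamma)-ordered: first max = smallest
  list(C = 2^grid$C_exp[best], gamma = 2^grid$gamma_exp[best],
       cv_accuracy = acc[best],
       grid = data.frame(C = 2^grid$C_exp, gamma = 2^grid$gamma_exp,
                         accuracy = acc))
}

#' Jackknife (leave-one-out) prediction
#'
#' Each sample is predicted once by a one-vs-one RBF SVM trained on the
#' remaining n-1 samples with hyperparameters fixed before the loop. When
#' `lfda` is supplied, the discriminant transform is refitted on every
#' fold's n-1 training rows and the held-out sample projected with that
#' fold's transform (the leakage-free "strict" protocol); otherwise `X` is
#' used as-is (pass an already-reduced matrix for the whole-dataset
#' protocol).
#'
#' @param X n x d feature matrix.
#' @param y n class indices in 1..c.
#' @param C,gamma fixed SVM hyperparameters.
#' @param lfda optional list(r, K, affinity) requesting per-fold LFDA.
#' @return list of class `jackknife_result`: `y_true`, `y_pred`, `scores`
#'   (n x c pairwise-coupled probabilities), `classes`.
#' @export
jackknife_predict <- function(X, y, C, gamma, lfda = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  if (n < 2) stop("jackknife needs n >= 2")
  cls <- sort(unique(y))
  scores <- matrix(NA_real_, n, length(cls), dimnames = list(NULL, cls))
  y_pred <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    Xte <- X[i, , drop = FALSE]
    if (!is.null(lfda)) {
      mod <- lfda_fit(Xtr, ytr, r = lfda$r, K = lfda$K,
                      affinity = lfda$affinity)
      Xte <- lfda_transform(mod, Xte)
      Xtr <- lfda_transform(mod, Xtr)
    }
    fit <- tryCatch(ovo_svm_fit(Xtr, ytr, C, gamma),
                    error = function(e) stop("jackknife fold ", i,
                                             " failed: ", conditionMessage(e)))
    pr <- predict(fit, Xte)
    y_pred[i] <- pr$class
    scores[i, match(colnames(pr$prob), colnames(scores))] <- pr$prob[1, ]
  }
  structure(list(y_true = y, y_pred = y_pred, scores = scores, classes = cls),
            class = "jackknife_result")
}

#' Per-class evaluation metrics
#'
#' Binarizes each class one-vs-rest and computes sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP) and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), with the 0/0 MCC
#' convention MCC = 0. Overall accuracy is the fraction of correctly located
#' proteins. Macro AUC comes from [ovr_roc_auc()] when scores are present.
#'
#' @param result a `jackknife_result` (or any list with `y_true`, `y_pred`,
#'   optionally `scores`).
#' @return An object of class `eval_report`: `confusion` (c x c, rows =
#'   true), `per_class` (Sens/Spec/MCC data.frame), `OA`, `auc`, `roc`, `n`.
#' @export
per_class_metrics <- function(result) {
  y_true <- as.integer(result$y_true)
  y_pred <- as.integer(result$y_pred)
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  cls <- sort(unique(c(y_true, y_pred)))
  fc <- function(v) factor(v, levels = cls)
  confusion <- table(true = fc(y_true), predicted = fc(y_pred))
  n <- length(y_true)
  per <- do.call(rbind, lapply(cls, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    fp <- sum(y_true != cl & y_pred == cl)
    tn <- sum(y_true != cl & y_pred != cl)
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    data.frame(class = cl,
               Sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               Spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               MCC = if (den > 0) (tp * tn - fp * fn) / den else 0)
  }))
  roc <- if (!is.null(result$scores)) ovr_roc_auc(result) else NULL
  structure(list(confusion = confusion, per_class = per,
                 OA = mean(y_true == y_pred),
                 auc = if (!is.null(roc)) roc$auc else NA_real_,
                 roc = roc, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Jackknife evaluation of %d proteins\n", x$n))
  cat(sprintf("Overall accuracy (OA): %.1f%%", 100 * x$OA))
  if (!is.na(x$auc)) cat(sprintf("   macro AUC: %.4f", x$auc))
  cat("\n\nPer-class metrics:\n")
  print(cbind(x$per_class[1],
              round(x$per_class[-1], 4)), row.names = FALSE)
  cat("\nConfusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

# one binary ROC curve: points (FPR, TPR) as the threshold sweeps the
# unique scores from high to low, tied scores grouped
.roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; pos <- positive[ord]
  keep <- c(diff(s) != 0, TRUE)   # last point of each tie group
  tpr <- c(0, cumsum(pos)[keep] / sum(pos))
  fpr <- c(0, cumsum(!pos)[keep] / sum(!pos))
  data.frame(fpr = fpr, tpr = tpr)
}

.trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' One-vs-rest ROC curves and macro-averaged AUC
#'
#' Each class in turn is the positive class, ranked by its class-membership
#' score; the per-class TPR curves are averaged on a shared FPR grid (the
#' union of all per-class FPR breakpoints, linearly interpolated) and the
#' macro AUC is the trapezoidal area under the mean curve. Classes absent
#' from `y_true` are skipped with a warning.
#'
#' @param result a `jackknife_result` with a `scores` matrix.
#' @return list with `auc`, `curve` (data.frame fpr/tpr of the mean curve),
#'   `per_class_auc`.
#' @export
ovr_roc_auc <- function(result) {
  scores <- result$scores
  y <- as.integer(result$y_true)
  cls <- as.integer(colnames(scores))
  curves <- list(); aucs <- numeric()
  for (k in seq_along(cls)) {
    if (!any(y == cls[k])) {
      warning("class ", cls[k], " absent from y_true; skipped in ROC")
      next
    }
    pts <- .roc_points(scores[, k], y == cls[k])
    curves[[length(curves) + 1L]] <- pts
    aucs[length(aucs) + 1L] <- .trapezoid(pts$fpr, pts$tpr)
    names(aucs)[length(aucs)] <- cls[k]
  }
  grid <- sort(unique(c(0, 1, unlist(lapply(curves, `[[`, "fpr")))))
  mean_tpr <- rowMeans(vapply(curves, function(p)
    stats::approx(p$fpr, p$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid))))
  # macro AUC is the mean of the exact per-class trapezoid areas; the
  # interpolated mean curve (reported for plotting) would leak area at
  # vertical ROC segments and break the reversal identity AUC -> 1 - AUC
  list(auc = mean(aucs),
       curve = data.frame(fpr = grid, tpr = mean_tpr),
       per_class_auc = aucs)
}
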