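# Cross-validated random-forest prediction with in-fold variable selection,
# pooled out-of-fold ROC AUC, and DeLong comparison of correlated AUCs.

#' Assign patients to k cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ by
#' at most one and the partition is exhaustive and disjoint. A label-
#' stratified variant (round-robin within each class) is available behind
#' `stratify`; the default is unstratified.
#'
#' @param n number of patients (`n >= k`).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param stratify optional label vector of length `n`.
#' @return Integer vector of fold indices in `1:k`, with attributes `k` and
#'   `seed`.
#' @export
make_folds <- function(n, k = 10L, seed = 1L, stratify = NULL) {
  if (n < k) stopf("need at least k = %d observations, got %d", k, n)
  fold <- integer(n)
  with_seed(seed, {
    if (is.null(stratify)) {
      perm <- sample.int(n)
      fold[perm] <- rep_len(seq_len(k), n)
    } else {
      stopifnot(length(stratify) == n)
      counter <- 0L
      for (cl in unique(stratify)) {
        idx <- which(stratify == cl)
        perm <- idx[sample.int(length(idx))]
        fold[perm] <- ((counter + seq_along(perm) - 1L) %% k) + 1L
        counter <- counter + length(perm)
      }
    }
  })
  structure(fold, k = k, seed = seed)
}

#' Random-forest variable selection (two-stage, permutation-importance based)
#'
#' A simplified version of the random-forests variable selection of Genuer
#' and colleagues. Stage 1 (thresholding): grow `B` forests, each with a
#' pure-noise probe appended (a permuted copy of a randomly chosen real
#' column), and discard every variable whose mean permutation importance
#' over the `B` forests does not exceed the probe's. Stage 2
#' (interpretation): order the survivors by mean importance and grow nested
#' forests adding one variable at a time, keeping the prefix minimizing
#' out-of-bag error (ties resolved toward the smaller prefix). If stage 1
#' discards everything the single top-importance variable is returned.
#'
#' @param X data.frame or matrix of predictors (>= 1 column).
#' @param y binary labels (coerced to factor) with both classes present.
#' @param seed integer seed; forests are reseeded from it via a counter.
#' @param B number of thresholding forests (default 25).
#' @param num_trees trees per selection forest (default 100).
#' @return Character vector of selected column names, with attributes
#'   `importance` (mean permutation importance), `oob_path` (nested OOB
#'   errors) and `fallback` (logical).
#' @export
rf_variable_select <- function(X, y, seed = 1L, B = 25L, num_trees = 100L) {
  X <- as.data.frame(X)
  y <- factor(y)
  if (length(levels(y)) != 2) stopf("y must have exactly 2 classes")
  p <- ncol(X)
  if (p < 1) stopf("no predictors")
  if (p == 1) return(structure(names(X), importance = NA, fallback = FALSE))
  imp <- matrix(0, nrow = B, ncol = p + 1L)
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, 100L + b)
    Xb <- X
    Xb[[".probe"]] <- with_seed(sb, X[[sample.int(p, 1)]][sample.int(nrow(X))])
    rf <- ranger::ranger(x = Xb, y = y, num.trees = num_trees,
                         importance = "permutation", seed = sb,
                         num.threads = 1L)
    imp[b, ] <- rf$variable.importance[c(names(X), ".probe")]
  }
  mean_imp <- colMeans(imp)
  names(mean_imp) <- c(names(X), ".probe")
  # a variable survives only if its mean importance exceeds the probe's by
  # a significance margin (2 standard errors of the probe mean over the B
  # forests), so pure-noise variables are discarded rather than surviving
  # half the time by chance
  probe_imp <- mean_imp[".probe"] +
    2 * stats::sd(imp[, p + 1L]) / sqrt(B)
  survivors <- names(X)[mean_imp[names(X)] > probe_imp]
  fallback <- FALSE
  if (length(survivors) == 0) {
    survivors <- names(which.max(mean_imp[names(X)]))
    fallback <- TRUE
  }
  survivors <- survivors[order(-mean_imp[survivors])]
  oob <- rep(NA_real_, length(survivors))
  if (length(survivors) > 1) {
    for (j in seq_along(survivors)) {
      rf <- ranger::ranger(x = X[, survivors[seq_len(j)], drop = FALSE], y = y,
                           num.trees = num_trees,
                           seed = derive_seed(seed, 500L + j),
                           num.threads = 1L)
      oob[j] <- rf$prediction.error
    }
    # prefixes within one OOB standard error of the minimum are ties,
    # resolved toward the smaller model
    best <- min(oob)
    se <- sqrt(best * (1 - best) / nrow(X))
    survivors <- survivors[seq_len(which(oob <= best + se)[1])]
  }
  structure(survivors, importance = mean_imp, oob_path = oob,
            fallback = fallback)
}

#' Cross-validated random-forest prediction with pooled probabilities
#'
#' The seven-step internal-validation procedure: (1) patients are randomly
#' split into `k` equally sized folds; (2-6) for each fold, variables are
#' selected on the nine training folds with [rf_variable_select()], a random
#' forest (default 500 trees) is fit on the selected variables, and
#' out-of-fold probabilities are emitted for the held-out fold; (7) all
#' out-of-fold probabilities are pooled and a single ROC AUC is computed
#' with [pooled_roc_auc()]. Fully seeded: per-fold forests are reseeded from
#' the master seed through a counter.
#'
#' @param X data.frame or matrix of predictors, row-aligned with `y`.
#' @param y binary 0/1 labels.
#' @param folds optional fold assignment from [make_folds()].
#' @param k number of folds when `folds` is missing.
#' @param seed master seed.
#' @param select run in-fold variable selection (default TRUE; with a single
#'   predictor selection is skipped).
#' @param num_trees trees for the per-fold prediction forest (default 500).
#' @param select_num_trees,select_B passed to [rf_variable_select()].
#' @param stratify use label-stratified folds (default FALSE).
#' @return An object of class `cv_result`: `probabilities` (per-patient
#'   out-of-fold P(positive)), `labels`, `folds`, `selected` (per-fold
#'   variable lists), `auc`, `seed`.
#' @export
cv_predict <- function(X, y, folds = NULL, k = 10L, seed = 1L, select = TRUE,
                       num_trees = 500L, select_num_trees = 100L,
                       select_B = 25L, stratify = FALSE) {
  X <- as.data.frame(X)
  if (!all(y %in% c(0, 1))) stopf("labels must be 0/1")
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (is.null(folds))
    folds <- make_folds(n, k = k, seed = seed,
                        stratify = if (stratify) y else NULL)
  k <- attr(folds, "k") %||% max(folds)
  yf <- factor(y, levels = c(0, 1))
  prob <- rep(NA_real_, n)
  selected <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- which(folds != i)
    te <- which(folds == i)
    if (length(unique(y[tr])) < 2)
      stopf("fold %d training data has one class only; use stratified folds", i)
    fold_seed <- derive_seed(seed, 1000L * i)
    vars <- if (select && ncol(X) > 1) {
      rf_variable_select(X[tr, , drop = FALSE], yf[tr], seed = fold_seed,
                         B = select_B, num_trees = select_num_trees)
    } else names(X)
    selected[[i]] <- as.character(vars)
    rf <- ranger::ranger(x = X[tr, vars, drop = FALSE], y = yf[tr],
                         num.trees = num_trees, probability = TRUE,
                         seed = fold_seed, num.threads = 1L)
    pred <- stats::predict(rf, data = X[te, vars, drop = FALSE])$predictions
    prob[te] <- pred[, "1"]
  }
  structure(list(probabilities = prob, labels = y, folds = folds,
                 selected = selected, auc = pooled_roc_auc(prob, y),
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  k <- attr(x$folds, "k") %||% max(x$folds)
  cat(sprintf("%d-fold cross-validated prediction (n = %d, seed = %s)\n",
              k, length(x$labels), format(x$seed)))
  cat(sprintf("  pooled out-of-fold ROC AUC: %.3f\n", x$auc))
  sizes <- lengths(x$selected)
  cat(sprintf("  variables selected per fold: %s\n",
              paste(sizes, collapse = " ")))
  invisible(x)
}

#' Pooled ROC AUC from out-of-fold probabilities
#'
#' Mann-Whitney statistic: the proportion of positive-negative pairs in
#' which the positive scores higher, ties counting one half. Equivalent to
#' the trapezoidal area under the single pooled ROC curve.
#'
#' @param probabilities numeric scores.
#' @param labels binary 0/1 labels with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
pooled_roc_auc <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stopf("both classes must be present")
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components: V10 (per positive) and V01 (per negative).
delong_components <- function(p, labels) {
  pos <- p[labels == 1]
  neg <- p[labels == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated cross-validated AUCs
#'
#' Nonparametric comparison of the AUCs of two probability vectors computed
#' on the same patients and labels, via structural components: the variance
#' of each AUC and their covariance are estimated from the empirical
#' covariances of the per-positive and per-negative components, and
#' `z = (AUC_a - AUC_b) / sqrt(var_a + var_b - 2 cov)` is referred to the
#' standard normal (two-sided). A zero-variance difference yields `p = 1`
#' with a degenerate flag.
#'
#' @param p_a,p_b probability vectors for the two models, same patients.
#' @param labels shared binary 0/1 labels.
#' @return An object of class `auc_comparison`: `auc_a`, `auc_b`, `var_a`,
#'   `var_b`, `cov_ab`, `z`, `p_value`, `degenerate`.
#' @export
delong_test <- function(p_a, p_b, labels) {
  stopifnot(length(p_a) == length(labels), length(p_b) == length(labels))
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  if (m < 2 || n < 2) stopf("need at least 2 observations per class")
  ca <- delong_components(p_a, labels)
  cb <- delong_components(p_b, labels)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  cov_ab <- s10[1, 2] / m + s01[1, 2] / n
  vd <- var_a + var_b - 2 * cov_ab
  degenerate <- vd <= .Machine$double.eps
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    z <- (ca$auc - cb$auc) / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = ca$auc, auc_b = cb$auc, var_a = var_a, var_b = var_b,
                 cov_ab = cov_ab, z = z, p_value = p, degenerate = degenerate),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("DeLong comparison of correlated AUCs\n  AUC A = %.3f, AUC B = %.3f\n",
              x$auc_a, x$auc_b))
  cat(sprintf("  z = %.3f, two-sided p = %.4g%s\n", x$z, x$p_value,
              if (x$degenerate) " (degenerate: zero variance of difference)" else ""))
  invisible(x)
}
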