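test_that("fold assignment is balanced, exhaustive and reproducible", {
  f <- make_folds(100, 10, seed = 3)
  expect_equal(unname(table(f)), rep(10L, 10), ignore_attr = TRUE)

  f169 <- make_folds(169, 10, seed = 3)
  sizes <- table(f169)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_setequal(as.integer(names(sizes)), 1:10)
  expect_identical(make_folds(169, 10, seed = 3), f169)
  expect_false(identical(make_folds(169, 10, seed = 4), f169))
  expect_error(make_folds(5, 10), "at least")

  # stratified variant keeps classes near-balanced per fold
  y <- rep(c(0, 1), c(30, 70))
  fs <- make_folds(100, 10, seed = 9, stratify = y)
  per_fold_pos <- tapply(y, fs, sum)
  expect_lte(max(per_fold_pos) - min(per_fold_pos), 1)
})

test_that("pooled AUC is the Mann-Whitney statistic", {
  expect_equal(pooled_roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(pooled_roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(pooled_roc_auc(1:10, rep(c(0, 1), each = 5)), 1)
  expect_error(pooled_roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(2)
  p <- runif(80); y <- rbinom(80, 1, 0.5)
  # complement symmetry (no ties) and monotone-transform invariance
  expect_equal(pooled_roc_auc(p, y) + pooled_roc_auc(-p, y), 1)
  expect_equal(pooled_roc_auc(qlogis(p), y), pooled_roc_auc(p, y))
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  expect_equal(pooled_roc_auc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))))
})

test_that("DeLong test matches its structural-component theory and pROC", {
  set.seed(7)
  n <- 30
  y <- rep(c(0, 1), c(14, 16))
  pa <- runif(n) + 0.4 * y
  pb <- runif(n) + 0.2 * y
  dt <- delong_test(pa, pb, y)
  # variance of each AUC equals the class-wise delete-one jackknife exactly
  expect_equal(dt$var_a, oracle_jackknife_auc_var(pa, y), tolerance = 1e-10)
  expect_equal(dt$var_b, oracle_jackknife_auc_var(pb, y), tolerance = 1e-10)
  # self-comparison is degenerate with p = 1
  self <- delong_test(pa, pa, y)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  expect_true(self$degenerate)
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, pa, quiet = TRUE),
                       pROC::roc(y, pb, quiet = TRUE), method = "delong")
  expect_equal(dt$p_value, rt$p.value, tolerance = 1e-9)
})

test_that("variable selection returns informative variables and handles edge cases", {
  set.seed(31)
  X <- as.data.frame(matrix(rnorm(300 * 11), 300, 11))
  names(X) <- c("signal", paste0("noise", 1:10))
  y <- rbinom(300, 1, 0.5)
  X$signal <- X$signal + 1.5 * y
  sel <- rf_variable_select(X, y, seed = 1)
  expect_true("signal" %in% sel)
  expect_identical(sel[1], "signal")

  one <- rf_variable_select(X[, 1, drop = FALSE], y, seed = 1)
  expect_identical(as.character(one), "signal")

  sel2 <- rf_variable_select(X, y, seed = 1)
  expect_identical(as.character(sel), as.character(sel2))
})

test_that("cross-validated prediction detects leaks, stays honest on noise", {
  set.seed(17)
  X <- as.data.frame(matrix(rnorm(120 * 5), 120, 5))
  y <- rbinom(120, 1, 0.5)
  cv <- cv_predict(X, y, seed = 5, select = FALSE, num_trees = 200)
  expect_true(all(cv$probabilities >= 0 & cv$probabilities <= 1))
  expect_true(all(!is.na(cv$probabilities)))
  expect_lt(cv$auc, 0.70)  # noise must not look predictive

  Xl <- X; Xl$leak <- y
  cvl <- cv_predict(Xl, y, seed = 5, select = FALSE, num_trees = 200)
  expect_gte(cvl$auc, 0.99)

  cv2 <- cv_predict(X, y, seed = 5, select = FALSE, num_trees = 200)
  expect_identical(cv$probabilities, cv2$probabilities)
  expect_identical(cv$auc, cv2$auc)
})

test_that("single-class training folds error with guidance toward stratification", {
  set.seed(4)
  X <- as.data.frame(matrix(rnorm(20 * 3), 20, 3))
  y <- c(rep(1, 4), rep(0, 16))
  # all positives concentrated in fold 1: its training set is single-class
  bad_folds <- structure(c(rep(1L, 4), rep(2:5, 4)), k = 5L)
  expect_error(cv_predict(X, y, folds = bad_folds, seed = 1, select = FALSE),
               "one class")
  # stratified folds avoid the failure on the same data
  ok <- cv_predict(X, y, k = 4, seed = 1, select = FALSE, num_trees = 100,
                   stratify = TRUE)
  expect_true(all(!is.na(ok$probabilities)))
})
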