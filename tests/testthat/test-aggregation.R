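make_fv <- function(vals, patient = "P1") {
  man <- feature_manifest()
  v <- stats::setNames(rep(vals[1], 60), man$name)
  if (length(vals) == 60) v <- stats::setNames(vals, man$name)
  ctradiomics:::new_feature_vector(v, character(0), patient_id = patient)
}

test_that("patient aggregation is the lesion-wise mean with pairwise NA handling", {
  f1 <- make_fv(10)
  expect_identical(aggregate_patient(list(f1))$values, f1$values)
  expect_equal(aggregate_patient(list(f1))$n_lesions, 1L)

  f2 <- make_fv(20)
  agg <- aggregate_patient(list(f1, f2))
  expect_equal(unname(agg$values[1]), 15)
  expect_equal(agg$n_lesions, 2L)

  # order invariance
  expect_equal(aggregate_patient(list(f2, f1))$values, agg$values)

  # pairwise NA: feature missing in one lesion -> mean over the other
  f3 <- make_fv(30)
  f3$values["skewness"] <- NA_real_
  agg2 <- aggregate_patient(list(f1, f3))
  expect_equal(unname(agg2$values["skewness"]), 10)
  # missing everywhere stays missing, with reason
  f4 <- make_fv(40)
  f4$values["skewness"] <- NA_real_
  agg3 <- aggregate_patient(list(f3, f4))
  expect_true(is.na(agg3$values["skewness"]))
  expect_match(agg3$reasons["skewness"], "every lesion")

  expect_error(aggregate_patient(rep(list(f1), 6)), "1-5")
})

test_that("logistic odds ratio on a 2x2 table equals the cross-product ratio", {
  # (a, b, c, d) = (10, 20, 20, 10): OR = (10 * 10) / (20 * 20) = 0.25
  x <- rep(c(1, 1, 0, 0), c(10, 20, 20, 10))
  y <- rep(c(1, 0, 1, 0), c(10, 20, 20, 10))
  row <- univariate_logistic(x, y, "tab")
  expect_equal(row$odds_ratio, 0.25, tolerance = 1e-6)
  expect_true(row$ci_low <= row$odds_ratio && row$odds_ratio <= row$ci_high)
  expect_gte(row$p_value, 0)
  expect_lte(row$p_value, 1)
})

test_that("standardization makes the odds ratio scale-free", {
  set.seed(5)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(0.5 * x))
  r1 <- univariate_logistic(x, y, "x")
  r2 <- univariate_logistic(10 * x, y, "x10")
  expect_equal(r1$odds_ratio, r2$odds_ratio, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("complete separation is flagged, not raised", {
  y <- rep(c(0, 1), each = 20)
  row <- univariate_logistic(y, y, "leak")
  expect_true(row$separated)
  expect_true(is.na(row$odds_ratio))
})

test_that("logistic screening holds its type-I error near the nominal level", {
  set.seed(99)
  reps <- 400
  p <- replicate(reps, {
    x <- rnorm(120)
    y <- rbinom(120, 1, 0.5)
    univariate_logistic(x, y, "null")$p_value
  })
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("screening a cohort yields one row per variable with flags", {
  spec <- cohort_spec(n_patients = 120, beta_age = 1.0, beta_smoke = 1.5, seed = 42)
  coh <- simulate_cohort(spec)
  man <- feature_manifest()
  set.seed(1)
  feats <- as.data.frame(matrix(rnorm(120 * 60), 120, 60))
  names(feats) <- man$name
  feats$patient_id <- coh$clinical$patient_id
  scr <- screen_all(coh$clinical, feats)
  # age, sex, smoking, egfr, suvmax + 60 features
  expect_equal(nrow(scr), 65)
  expect_true(all(c("odds_ratio", "ci_low", "ci_high", "p_value") %in% names(scr)))
  # strong generator effects must be recovered
  expect_true(scr$significant[scr$variable == "smoking"])
  expect_true(scr$significant[scr$variable == "age"])
  # BH flag produces adjusted p-values
  scr_bh <- screen_all(coh$clinical, feats, adjust = "BH")
  expect_true("p_adjusted" %in% names(scr_bh))
  expect_true(all(scr_bh$p_adjusted >= scr_bh$p_value - 1e-12, na.rm = TRUE))
})
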