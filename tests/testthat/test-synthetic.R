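test_that("label-model intercept calibration hits the target marginal", {
  spec <- cohort_spec(n_patients = 10000, beta_age = 0, beta_smoke = 0,
                      p_ts_positive = 85 / 169, seed = 11)
  coh <- simulate_cohort(spec)
  expect_equal(mean(coh$clinical$ts_label), 85 / 169, tolerance = 0.01)
  # with nonzero effects the marginal still matches (intercept re-solved)
  spec2 <- cohort_spec(n_patients = 10000, beta_age = 0.5, beta_smoke = 1.2,
                       p_ts_positive = 0.4, seed = 12)
  coh2 <- simulate_cohort(spec2)
  expect_equal(mean(coh2$clinical$ts_label), 0.4, tolerance = 0.015)
  # effects point the expected way: positives older, more often smokers
  cl <- coh2$clinical
  expect_gt(mean(cl$age[cl$ts_label == 1]), mean(cl$age[cl$ts_label == 0]))
  expect_gt(mean(cl$smoking[cl$ts_label == 1] == "ever"),
            mean(cl$smoking[cl$ts_label == 0] == "ever"))
})

test_that("lesion counts follow the 1-5 distribution with mean near 1.76", {
  # closed-form expectation of the default mass function
  probs <- c(0.55, 0.25, 0.12, 0.05, 0.03)
  expect_equal(sum(probs * 1:5), 1.76)
  spec <- cohort_spec(n_patients = 3000, seed = 21)
  coh <- simulate_cohort(spec)
  n_les <- table(vapply(coh$lesions, function(l) l$patient_id, character(1)))
  expect_equal(mean(n_les), 1.76, tolerance = 0.05)
  expect_true(all(n_les >= 1 & n_les <= 5))
  # exactly one primary per patient
  prim <- vapply(coh$lesions, function(l) l$lesion_type, character(1)) == "primary"
  expect_equal(sum(prim), spec$n_patients)
})

test_that("cohorts are byte-identical under a fixed seed", {
  spec <- cohort_spec(n_patients = 80, seed = 5)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$clinical, b$clinical)
  expect_identical(lapply(a$lesions, `[[`, "size_mm"),
                   lapply(b$lesions, `[[`, "size_mm"))
  d <- simulate_cohort(cohort_spec(n_patients = 80, seed = 6))
  expect_false(identical(a$clinical$ts_label, d$clinical$ts_label))
})

test_that("phantom masks track the nominal sphere volume", {
  les <- simulate_lesion_volume(12, seed = 2)
  expect_equal(sum(les$mask$voxels), 4 / 3 * pi * 12^3, tolerance = 0.03)
  expect_error(simulate_lesion_volume(4), "radius")
  expect_error(simulate_lesion_volume(8, tail_fraction = 0.6), "tail_fraction")
  # determinism
  les2 <- simulate_lesion_volume(12, seed = 2)
  expect_identical(les$image$voxels, les2$image$voxels)
})

test_that("noise-only phantom intensities have Gaussian (Pearson) kurtosis 3", {
  set.seed(33)
  les <- simulate_lesion_volume(14, noise_sd = 15, tail_fraction = 0, seed = 9)
  vals <- les$image$voxels[les$mask$voxels > 0]
  # remove the deterministic core/rim ramp: keep the flat core only
  part <- partition_roi(les$mask)
  core <- les$image$voxels[part$inner$voxels > 0]
  x <- rnorm(1e5)
  h <- histogram_features(x)$values
  expect_equal(unname(h["kurtosis"]), 3, tolerance = 0.1)
  expect_equal(unname(h["skewness"]), 0, tolerance = 0.05)
})

test_that("the low-HU tail mixture drives skewness down and kurtosis up", {
  worse <- 0
  for (s in 1:20) {
    a <- simulate_lesion_volume(8, tail_fraction = 0, noise_sd = 15, seed = 100 + s)
    b <- simulate_lesion_volume(8, tail_fraction = 0.05, noise_sd = 15, seed = 100 + s)
    ha <- histogram_features(a$image$voxels[a$mask$voxels > 0])$values
    hb <- histogram_features(b$image$voxels[b$mask$voxels > 0])$values
    worse <- worse + (hb["skewness"] < ha["skewness"] && hb["kurtosis"] > ha["kurtosis"])
  }
  expect_equal(worse, 20)
})
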