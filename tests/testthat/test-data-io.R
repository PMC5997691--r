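test_that("NIfTI lesion pairs round-trip with spacing and binarized mask", {
  skip_if_not_installed("RNifti")
  msk <- make_sphere_mask(6, spacing = c(0.7, 0.7, 2.5))
  img <- image_volume(array(rnorm(prod(dim(msk$voxels)), -100, 50),
                            dim = dim(msk$voxels)), spacing = c(0.7, 0.7, 2.5))
  # write mask with labels {0, 2}: must binarize to {0, 1} on read
  lab <- msk
  lab$voxels <- lab$voxels * 2L
  ip <- tempfile(fileext = ".nii.gz")
  mp <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(img, ip)
  RNifti::writeNifti({
    x <- RNifti::asNifti(lab$voxels)
    RNifti::pixdim(x) <- lab$spacing
    x
  }, mp)
  pair <- read_lesion(ip, mp)
  expect_equal(dim(pair$image$voxels), dim(img$voxels))
  expect_equal(pair$image$spacing, c(0.7, 0.7, 2.5), tolerance = 1e-6)
  expect_setequal(unique(as.vector(pair$mask$voxels)), c(0L, 1L))
  expect_equal(sum(pair$mask$voxels), sum(msk$voxels))
  expect_equal(pair$image$voxels, img$voxels, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("misaligned or empty inputs are rejected", {
  img <- image_volume(array(0, dim = c(20, 20, 20)))
  msk21 <- array(1L, dim = c(21, 21, 21))
  ip <- tempfile(fileext = ".nii.gz")
  mp <- tempfile(fileext = ".nii.gz")
  write_nifti_volume(img, ip)
  write_nifti_volume(roi_mask(msk21), mp)
  expect_error(read_lesion(ip, mp), "alignment")
  expect_error(roi_mask(array(0L, dim = c(5, 5, 5))), "empty ROI")
  expect_error(read_lesion(ip, tempfile()), "not found")
})

test_that("five-lesion cap keeps the primary and the largest non-primaries", {
  mk <- function(id, type, size) make_lesion("P1", id, type, size)
  seven <- list(mk("a", "primary", 12), mk("b", "node", 30), mk("c", "node", 25),
                mk("d", "lung_met", 40), mk("e", "distant", 35),
                mk("f", "node", 20), mk("g", "pleural", 15))
  sel <- select_lesions(seven)
  expect_length(sel, 5)
  types <- vapply(sel, function(l) l$lesion_type, character(1))
  expect_equal(sum(types == "primary"), 1L)
  ids <- vapply(sel, function(l) l$lesion_id, character(1))
  # primary (smallest!) retained, then the 4 largest: d(40), e(35), b(30), c(25)
  expect_setequal(ids, c("a", "d", "e", "b", "c"))

  three <- seven[1:3]
  expect_equal(select_lesions(three), three)

  expect_error(select_lesions(list(mk("x", "node", 10))), "missing primary")
})

test_that("lesion selection is idempotent with deterministic tie-breaks", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:9, 1)
    les <- c(list(make_lesion("P9", "prim", "primary", runif(1, 10, 50))),
             lapply(seq_len(n - 1), function(i)
               make_lesion("P9", sprintf("m%02d", i), "node",
                           sample(c(10, 20, 20, 30), 1))))
    once <- select_lesions(les)
    twice <- select_lesions(once)
    expect_identical(vapply(once, `[[`, character(1), "lesion_id"),
                     vapply(twice, `[[`, character(1), "lesion_id"))
    expect_length(once, min(5, n))
  }
})

test_that("feature tables round-trip losslessly and reject ragged schemas", {
  les1 <- simulate_lesion_volume(8, seed = 1, tail_fraction = 0.03)
  les2 <- simulate_lesion_volume(8, seed = 2)
  fv1 <- extract_features(c(les1, list(patient_id = "P1", lesion_id = "L1")))
  fv2 <- extract_features(c(les2, list(patient_id = "P1", lesion_id = "L2")))
  path <- tempfile(fileext = ".csv")
  write_feature_table(list(fv1, fv2), path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 2)
  expect_equal(ncol(back), 62)  # 60 features + 2 id columns
  expect_equal(unname(unlist(back[1, feature_manifest()$name])),
               unname(fv1$values), tolerance = 1e-10)

  broken <- fv2
  broken$values <- broken$values[-5]
  expect_error(write_feature_table(list(fv1, broken), path), "schema")
})
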