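test_that("GLCM on a 3-voxel line matches the hand-enumerated pairs", {
  img <- image_volume(array(c(10, 10, 20), dim = c(1, 1, 3)))
  msk <- roi_mask(array(1L, dim = c(1, 1, 3)))
  G <- glcm_matrix(img, msk)
  expect_equal(dim(G), c(256L, 256L))
  expect_equal(attr(G, "n_directions"), 13L)
  # only the (0,0,1) offset has pairs: (10,10) and (10,20); after
  # symmetrization P(lo,lo) = 0.5, P(lo,hi) = P(hi,lo) = 0.25
  expect_equal(G[1, 1], 0.5)
  expect_equal(G[1, 256], 0.25)
  expect_equal(G[256, 1], 0.25)
  expect_equal(sum(G), 1, tolerance = 1e-12)
})

test_that("constant ROI collapses the GLCM to a deterministic texture", {
  img <- image_volume(array(7, dim = c(4, 4, 4)))
  msk <- roi_mask(array(1L, dim = c(4, 4, 4)))
  G <- glcm_matrix(img, msk)
  expect_equal(G[1, 1], 1)
  f <- glcm_features(G)
  expect_equal(unname(f["glcm_entropy"]), 0)
  expect_equal(unname(f["glcm_dissimilarity"]), 0)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_homogeneity"]), 1)
})

test_that("GLCM features match closed forms on synthetic matrices", {
  L <- 16
  unif <- matrix(1 / L^2, L, L)
  expect_equal(unname(glcm_features(unif)["glcm_entropy"]), 2 * log2(L))
  two <- matrix(0, 2, 2)
  two[1, 1] <- 0.5; two[1, 2] <- 0.25; two[2, 1] <- 0.25
  f <- glcm_features(two)
  expect_equal(unname(f["glcm_dissimilarity"]), 0.5)
  expect_equal(unname(f["glcm_entropy"]), 1.5)
  expect_length(f, 11)
})

test_that("GLCM equals brute-force enumeration on random phantoms", {
  for (seed in 1:3) {
    ph <- random_phantom(side = 8, seed = seed)
    G <- glcm_matrix(ph$image, ph$mask)
    O <- oracle_glcm(ph$image, ph$mask)
    expect_equal(unclass(G), O, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sum(G), 1, tolerance = 1e-12)
    expect_equal(unclass(G), t(unclass(G)), tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("GLCM entropy is invariant to monotone intensity shift", {
  ph <- random_phantom(side = 9, seed = 4)
  f1 <- glcm_features(glcm_matrix(ph$image, ph$mask))
  img2 <- image_volume(ph$image$voxels + 250, spacing = ph$image$spacing)
  f2 <- glcm_features(glcm_matrix(img2, ph$mask))
  expect_equal(unname(f1["glcm_entropy"]), unname(f2["glcm_entropy"]), tolerance = 1e-10)
  expect_equal(unname(f1["glcm_contrast"]), unname(f2["glcm_contrast"]), tolerance = 1e-10)
})

test_that("size-zone matrices match the flood-fill oracle", {
  for (seed in 1:3) {
    ph <- random_phantom(side = 8, seed = seed, n_levels = 4)
    Z <- iszm_matrix(ph$image, ph$mask)
    O <- oracle_iszm(ph$image, ph$mask)
    expect_equal(Z$n_zones, O$n_zones)
    expect_equal(unname(Z$matrix), unname(O$matrix))
    expect_equal(sum(Z$matrix), Z$n_zones)
  }
})

test_that("size-zone features match hand-enumerated zone structures", {
  # constant ROI: one zone, both features 1
  img <- image_volume(array(5, dim = c(3, 3, 3)))
  msk <- roi_mask(array(1L, dim = c(3, 3, 3)))
  Z <- iszm_matrix(img, msk)
  expect_equal(Z$n_zones, 1L)
  expect_equal(unname(iszm_features(Z)), c(1, 1))

  # two zones of distinct levels, sizes 3 and 5
  v <- c(rep(1, 3), rep(9, 5))
  img2 <- image_volume(array(v, dim = c(8, 1, 1)))
  msk2 <- roi_mask(array(1L, dim = c(8, 1, 1)))
  expect_equal(unname(iszm_features(iszm_matrix(img2, msk2))), c(1, 1))

  # three zones: levels (g1, g2, g1), sizes (2, 7, 2)
  v3 <- c(1, 1, rep(9, 7), 1, 1)
  img3 <- image_volume(array(v3, dim = c(11, 1, 1)))
  msk3 <- roi_mask(array(1L, dim = c(11, 1, 1)))
  Z3 <- iszm_matrix(img3, msk3)
  expect_equal(Z3$n_zones, 3L)
  f3 <- iszm_features(Z3)
  expect_equal(unname(f3["intensity_variability"]), 5 / 3)
  expect_equal(unname(f3["size_zone_variability"]), 5 / 3)

  # single voxel: one zone, both features 1
  img1 <- image_volume(array(3, dim = c(1, 1, 1)))
  msk1 <- roi_mask(array(1L, dim = c(1, 1, 1)))
  expect_equal(unname(iszm_features(iszm_matrix(img1, msk1))), c(1, 1))
})
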