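test_that("minimum spacing is a per-axis minimum over the dataset", {
  mk <- function(sp) voxel_image(array(0, c(3, 3, 3)), sp,
                                 array(TRUE, c(3, 3, 3)))
  expect_equal(compute_min_spacing(list(mk(c(0.7, 0.7, 1.5)),
                                        mk(c(1.0, 1.0, 3.0)))),
               c(0.7, 0.7, 1.5))
  expect_equal(compute_min_spacing(list(mk(c(0.5, 1, 2)), mk(c(1, 0.5, 1)))),
               c(0.5, 0.5, 1))
  expect_equal(compute_min_spacing(list(mk(c(2, 3, 4)))), c(2, 3, 4))
  expect_error(compute_min_spacing(list()), "empty")
})

test_that("physical offsets convert to clamped per-axis voxel distances", {
  expect_identical(offset_to_voxels(3, c(1.5, 1.5, 3.0)), c(2L, 2L, 1L))
  expect_identical(offset_to_voxels(3, c(0.7, 0.7, 1.5)), c(4L, 4L, 2L))
  expect_identical(offset_to_voxels(5, c(6, 6, 6)), c(1L, 1L, 1L))
  expect_error(offset_to_voxels(0, c(1, 1, 1)))
})

test_that("resampling: identity, linearity, and round-trip volume", {
  img <- make_test_image(shape = c(8, 8, 6), spacing = c(1, 1.5, 2), seed = 2)
  id <- resample_image(img, img$spacing)
  expect_equal(id$intensities, img$intensities, tolerance = 1e-12)
  expect_identical(id$mask, img$mask)

  prof <- voxel_image(array(c(0, 10), c(2, 1, 1)), c(2, 1, 1),
                      array(TRUE, c(2, 1, 1)))
  up <- resample_image(prof, c(1, 1, 1))
  expect_equal(as.vector(up$intensities), c(0, 5, 10))

  # round-trip fine -> coarse -> fine preserves ROI physical volume to 10%
  # (fixture sized so the ROI spans many voxels of the coarse grid)
  big <- make_test_image(shape = c(16, 16, 12), spacing = c(1, 1.5, 2),
                         seed = 3)
  rt1 <- resample_image(big, c(2, 2, 2))
  rt2 <- resample_image(rt1, c(1, 1.5, 2))
  vol <- function(im) sum(im$mask) * prod(im$spacing)
  expect_lt(abs(vol(rt2) - vol(big)) / vol(big), 0.10)

  expect_error(resample_image(img, c(100, 1, 1)), "coarser")
})

test_that("discretization spans the ROI range with documented conventions", {
  mk <- function(v) voxel_image(array(v, c(1, 1, length(v))), c(1, 1, 1),
                                array(TRUE, c(1, 1, length(v))))
  d <- discretize(mk(0:31), 32)
  expect_equal(sort(unique(as.vector(d))), 1:32)
  expect_true(all(as.vector(discretize(mk(rep(4, 5)), 8)) == 1L))
  expect_equal(as.vector(discretize(mk(c(0, 10)), 2)), c(1L, 2L))
  # voxels outside the mask are NA
  img <- make_test_image()
  dd <- discretize(img, 16)
  expect_true(all(is.na(dd[!img$mask])))
  expect_true(all(!is.na(dd[img$mask])))
})

test_that("intensity features use population moments and safe conventions", {
  mk <- function(v) voxel_image(array(v, c(1, 1, length(v))), c(1, 1, 1),
                                array(TRUE, c(1, 1, length(v))))
  f <- intensity_features(mk(c(1, 2, 3)))
  expect_equal(unname(f["int_mean"]), 2)
  expect_equal(unname(f["int_variance"]), 2 / 3)
  fc <- intensity_features(mk(rep(5, 4)))
  expect_equal(unname(fc[c("int_variance", "int_skewness", "int_kurtosis")]),
               c(0, 0, 0))
  set.seed(1)
  fn <- intensity_features(mk(rnorm(1000)))
  expect_lt(abs(fn["int_skewness"]), 0.25)
})

test_that("histogram features match closed forms", {
  one <- array(2L, c(1, 1, 8))
  f1 <- histogram_features(one, 4)
  expect_equal(unname(f1["hist_entropy"]), 0)
  expect_equal(unname(f1["hist_uniformity"]), 1)

  unif <- array(rep(1:32, 2), c(1, 1, 64))
  expect_equal(unname(histogram_features(unif, 32)["hist_entropy"]), 5)

  two <- array(c(1L, rep(2L, 3)), c(1, 1, 4))
  expect_equal(unname(histogram_features(two, 2)["hist_entropy"]),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)), tolerance = 1e-10)
})

test_that("volumetric features are monotone and match simple cases", {
  mk <- function(v) voxel_image(array(v, c(1, 1, length(v))), c(1, 1, 1),
                                array(TRUE, c(1, 1, length(v))))
  fc <- volumetric_features(mk(rep(7, 10)))
  expect_true(all(fc[grep("intensity_at", names(fc))] == 7))

  # ROI {1,2,3,4}: fraction with intensity >= 3 is 0.5 (range fraction 2/3)
  f4 <- volumetric_features(mk(1:4), fractions = 2 / 3)
  expect_equal(unname(f4["vol_fraction_ge_r67"]), 0.5)

  set.seed(3)
  fu <- volumetric_features(mk(runif(1e4, 0, 100)))
  expect_lt(abs(fu["vol_intensity_at_f90"] - 90), 2)
  vf <- fu[grep("fraction_ge", names(fu))]
  expect_true(all(diff(vf) <= 0))
})

test_that("morphology features match voxel-counting geometry", {
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  f1 <- morphology_features(voxel_image(array(0, c(3, 3, 3)), c(1, 1, 1), m1))
  expect_equal(unname(f1[c("morph_volume_mm3", "morph_surface_mm2")]),
               c(1, 6))

  m2 <- array(FALSE, c(4, 4, 4)); m2[2:3, 2:3, 2:3] <- TRUE
  f2 <- morphology_features(voxel_image(array(0, c(4, 4, 4)), c(1, 1, 1), m2))
  expect_equal(unname(f2[c("morph_volume_mm3", "morph_surface_mm2")]),
               c(8, 24))
  expect_equal(unname(f2["morph_max_diameter_mm"]), sqrt(3),
               tolerance = 1e-10)
  expect_lte(unname(f2["morph_sphericity"]), 1.05)

  # anisotropic spacing scales faces and volume correctly
  f3 <- morphology_features(voxel_image(array(0, c(3, 3, 3)), c(1, 2, 3),
                                        m1))
  expect_equal(unname(f3["morph_volume_mm3"]), 6)
  expect_equal(unname(f3["morph_surface_mm2"]), 2 * (2 * 3 + 1 * 3 + 1 * 2))

  # digitized sphere of radius 10 voxels: volume within 5% of (4/3) pi r^3
  r <- 10; n <- 2 * r + 3
  cc <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ms <- array((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2 <= r^2, c(n, n, n))
  fs <- morphology_features(voxel_image(array(0, c(n, n, n)), c(1, 1, 1), ms))
  expect_lt(abs(fs["morph_volume_mm3"] - 4 / 3 * pi * r^3) /
              (4 / 3 * pi * r^3), 0.05)
})

test_that("GLRLM matches hand enumeration and the brute-force oracle", {
  d <- array(NA_integer_, c(1, 1, 4)); d[1, 1, ] <- c(1L, 1L, 2L, 2L)
  f <- glrlm_features(d, 2, directions = matrix(c(0, 0, 1), 1))
  expect_equal(unname(f["glrlm_rp"]), 0.5)

  dc <- array(1L, c(1, 1, 7))
  expect_equal(unname(glrlm_features(dc, 2,
    directions = matrix(c(0, 0, 1), 1))["glrlm_lre"]), 49)

  alt <- array(rep(c(1L, 2L), 4), c(1, 1, 8))
  expect_equal(unname(glrlm_features(alt, 2,
    directions = matrix(c(0, 0, 1), 1))["glrlm_sre"]), 1)

  # full 13-direction agreement with the oracle on random arrays
  dirs <- radbatch:::directions13()
  for (seed in 1:5) {
    d5 <- random_discretized(c(4, 5, 3), 3, seed = seed)
    got <- glrlm_features(d5, 3)
    want <- glrlm_features_oracle(d5, 3, dirs)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("GLRLM/GLSZM conservation identities hold per direction", {
  dirs <- radbatch:::directions13()
  for (seed in 1:5) {
    d <- random_discretized(c(5, 4, 4), 4, seed = 10 + seed)
    nvox <- sum(!is.na(d))
    for (r in sample(nrow(dirs), 4)) {
      m <- radbatch:::glrlm_matrix(d, dirs[r, ], 4)
      expect_equal(sum(m * matrix(seq_len(ncol(m)), nrow(m), ncol(m),
                                  byrow = TRUE)), nvox)
    }
    z <- radbatch:::glszm_zones(d)
    expect_equal(sum(z$size), nvox)
  }
})

test_that("NGTDM matches hand computation and the brute-force oracle", {
  d <- array(NA_integer_, c(1, 1, 3)); d[1, 1, ] <- c(1L, 2L, 1L)
  f <- ngtdm_features(d, c(1, 1, 1))
  # s_1 = |1-2| + |1-2| = 2, s_2 = |2-1| = 1, p = (2/3, 1/3)
  expect_equal(unname(f["ngtdm_coarseness"]), 1 / (2 / 3 * 2 + 1 / 3 + 1e-6),
               tolerance = 1e-9)
  expect_equal(unname(f["ngtdm_contrast"]),
               (2 * (2 / 3) * (1 / 3) / 2) * (3 / 3), tolerance = 1e-10)

  dconst <- array(3L, c(2, 2, 2))
  expect_equal(unname(ngtdm_features(dconst, c(1, 1, 1))["ngtdm_contrast"]), 0)

  for (seed in 1:5) {
    d5 <- random_discretized(c(4, 4, 4), 3, seed = 20 + seed)
    got <- ngtdm_features(d5, c(1, 2, 1))
    want <- ngtdm_oracle(d5, c(1, 2, 1))
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("GLSZM matches hand enumeration and the flood-fill oracle", {
  d <- array(NA_integer_, c(1, 2, 2)); d[1, , ] <- matrix(c(1L, 1L, 1L, 2L), 2)
  f <- glszm_features(d)
  expect_equal(unname(f["glszm_zp"]), 0.5)
  expect_equal(unname(f["glszm_sze"]), (1 / 9 + 1) / 2)

  dconst <- array(2L, c(3, 3, 2))
  expect_equal(unname(glszm_features(dconst)["glszm_lze"]), 18^2)

  dd <- array(1:8, c(2, 2, 2))   # all-distinct levels: N zones of size 1
  expect_equal(unname(glszm_features(dd)["glszm_sze"]), 1)

  for (seed in 1:5) {
    d5 <- random_discretized(c(4, 4, 3), 3, seed = 30 + seed)
    zo <- glszm_oracle(d5)
    zp <- radbatch:::glszm_zones(d5)
    expect_equal(sort(zp$size), sort(zo[, 2]))
    expect_equal(nrow(zp), nrow(zo))
  }
})

test_that("texture features are invariant to constant intensity shifts", {
  img <- make_test_image(seed = 4)
  shifted <- voxel_image(img$intensities + 500, img$spacing, img$mask)
  p <- extraction_params(families = c("histogram", "glrlm", "ngtdm", "glszm"))
  expect_equal(extract_features(img, p), extract_features(shifted, p),
               tolerance = 1e-10)
})

test_that("extract_features assembles the documented feature set", {
  img <- make_test_image(seed = 5)
  f <- extract_features(img)
  expect_length(f, 53)          # pinned golden feature count
  expect_identical(attr(f, "family"),
                   sub("_.*$", "", names(f)))
  expect_setequal(unique(attr(f, "family")),
                  c("int", "hist", "vol", "morph", "glrlm", "ngtdm", "glszm"))

  fi <- extract_features(img, extraction_params(families = "intensity"))
  expect_true(all(startsWith(names(fi), "int_")))

  expect_identical(extract_features(img), extract_features(img))

  # tiny ROI: texture families skipped with a warning
  m <- array(FALSE, c(5, 5, 5)); m[2:3, 2, 2] <- TRUE
  tiny <- voxel_image(array(rnorm(125), c(5, 5, 5)), c(1, 1, 1), m)
  expect_warning(ft <- extract_features(tiny), "texture")
  expect_false(any(attr(ft, "family") %in% c("glrlm", "ngtdm", "glszm")))
})
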