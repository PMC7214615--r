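test_that("the descriptor inventory is 114 names in the published convention", {
  fn <- feature_names()
  expect_length(fn, 114)
  expect_false(anyDuplicated(fn) > 0)
  # names quoted in the signature tables must be present
  expect_true(all(c("X_GLRLM_LRHGLE", "X_GLRLM_RP", "XLL_GLRLM_SRLGLE",
                    "X_GLRLM_LRE", "X_GLRLM_SRLGLE", "X_GLCM_variance",
                    "XLL_GLRLM_RLN", "XHH_GLRLM_RP", "Surface_area",
                    "XLL_H_skewness", "X_GLCM_dissimilarity",
                    "X_GLCM_homogeneity2") %in% fn))
  # 14 bare shape names + 5 images x 20 prefixed descriptors
  expect_length(grep("^X(LL|LH|HL|HH)?_", fn), 100)
})

test_that("shape features match hand counts on cubes", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  f1 <- shape_features(make_msk(one))
  expect_equal(f1[["Voxel_count"]], 1)
  expect_equal(f1[["Volume"]], 1)
  expect_equal(f1[["Surface_area"]], 6)
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  f3 <- shape_features(make_msk(cube))
  expect_equal(f3[["Volume"]], 27)
  expect_equal(f3[["Surface_area"]], 54)
  expect_equal(f3[["Sphericity"]], pi^(1 / 3) * (6 * 27)^(2 / 3) / 54,
               tolerance = 1e-12)
  expect_equal(f3[["Spherical_disproportion"]], 1 / f3[["Sphericity"]],
               tolerance = 1e-12)
  expect_equal(f3[["Max_3D_diameter"]], 2 * sqrt(3), tolerance = 1e-12)
  # isotropic symmetry: permuting axes changes nothing
  elong <- array(FALSE, c(7, 5, 5)); elong[2:6, 2:4, 2:4] <- TRUE
  fa <- shape_features(make_msk(elong))
  fb <- shape_features(make_msk(aperm(elong, c(3, 1, 2))))
  expect_equal(fa, fb, tolerance = 1e-10)
  # anisotropic spacing enters through the voxel volume
  fs <- shape_features(make_msk(cube, spacing = c(0.5, 0.5, 2)))
  expect_equal(fs[["Volume"]], 27 * 0.5 * 0.5 * 2)
})

test_that("histogram features use population moments and discrete entropy", {
  v <- make_vol(array(c(1, 2, 3), c(3, 1, 1)))
  m <- make_msk(array(TRUE, c(3, 1, 1)))
  h <- histogram_features(v, m, n_bins = 3)
  expect_equal(h[["H_mean"]], 2)
  expect_equal(h[["H_variance"]], 2 / 3, tolerance = 1e-12)
  expect_equal(h[["H_skewness"]], 0, tolerance = 1e-12)
  expect_equal(h[["H_range"]], 2)
  # symmetric values give zero skewness
  vs <- make_vol(array(c(-3, -1, 0, 0, 1, 3), c(6, 1, 1)))
  ms <- make_msk(array(TRUE, c(6, 1, 1)))
  expect_equal(histogram_features(vs, ms)[["H_skewness"]], 0,
               tolerance = 1e-12)
  # constant ROI degenerates gracefully
  hc <- histogram_features(make_vol(array(5, c(4, 1, 1))),
                           make_msk(array(TRUE, c(4, 1, 1))))
  expect_equal(hc[["H_variance"]], 0)
  expect_equal(hc[["H_entropy"]], 0)
  expect_equal(hc[["H_energy"]], 1)
  expect_equal(hc[["H_skewness"]], 0)
})

test_that("GLCM matches the worked single-direction examples", {
  grid <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 1, 1))
  v <- make_vol(grid); m <- make_msk(array(TRUE, c(3, 3, 1)))
  d <- discretize_roi(v, m, 2)
  along_cols <- matrix(c(0L, 1L, 0L), 1)
  cm <- brute_glcm(d$gray_levels, m$voxels, 2, c(0, 1, 0))
  expect_equal(cm / sum(cm),
               matrix(c(2, 2, 2, 6) / 12, 2, 2), tolerance = 1e-12)
  f <- glcm_features(d, directions = along_cols)
  expect_equal(f[["GLCM_energy"]], 1 / 3, tolerance = 1e-12)
  expect_equal(f[["GLCM_contrast"]], 4 / 12, tolerance = 1e-12)
  # checkerboard: every adjacent pair differs by exactly one level
  chk <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  dchk <- discretize_roi(make_vol(chk), make_msk(array(TRUE, c(4, 4, 1))), 2)
  fchk <- glcm_features(dchk, directions = along_cols)
  expect_equal(fchk[["GLCM_contrast"]], 1, tolerance = 1e-12)
  expect_equal(fchk[["GLCM_homogeneity1"]], 1 / 2, tolerance = 1e-12)
})

test_that("GLRLM matches run enumeration by hand", {
  v <- make_vol(array(c(0, 0, 0, 1, 1), c(5, 1, 1)))
  m <- make_msk(array(TRUE, c(5, 1, 1)))
  d <- discretize_roi(v, m, 2)
  along_rows <- matrix(c(1L, 0L, 0L), 1)
  f <- glrlm_features(d, directions = along_rows)
  expect_equal(f[["GLRLM_RP"]], 2 / 5, tolerance = 1e-12)
  expect_equal(f[["GLRLM_LRE"]], (9 + 4) / 2, tolerance = 1e-12)
  # constant 1D ROI of length n: one run
  n <- 7
  dc <- discretize_roi(make_vol(array(1, c(n, 1, 1))),
                       make_msk(array(TRUE, c(n, 1, 1))), 2)
  fc <- glrlm_features(dc, directions = along_rows)
  expect_equal(fc[["GLRLM_RP"]], 1 / n, tolerance = 1e-12)
  expect_equal(fc[["GLRLM_LRE"]], n^2, tolerance = 1e-12)
})

test_that("texture matrices satisfy conservation laws on random ROIs", {
  set.seed(5)
  for (i in 1:10) {
    roi <- random_small_roi()
    lev <- roi$levels; lev[!roi$mask] <- 0L
    counts <- habitomics:::cpp_glrlm_counts(
      lev, roi$mask, roi$dims, roi$nbins, max(roi$dims),
      habitomics:::DIRECTIONS_13)
    nvox <- sum(roi$mask)
    for (d in seq_len(dim(counts)[3])) {
      r <- counts[, , d]
      # runs partition the ROI: sum of run counts x lengths = |ROI|
      expect_equal(sum(r %*% seq_len(ncol(r))), nvox)
    }
    gc2 <- habitomics:::cpp_glcm_counts(lev, roi$mask, roi$dims, roi$nbins,
                                        habitomics:::DIRECTIONS_13)
    for (d in seq_len(dim(gc2)[3])) {
      cm <- gc2[, , d]
      expect_true(isSymmetric(unname(cm) * 1.0))
    }
  }
})

test_that("GLCM/GLRLM features equal independent brute-force enumeration", {
  set.seed(99)
  for (i in 1:25) {
    roi <- random_small_roi()
    droi <- roi_as_droi(roi$levels, roi$mask, roi$nbins)
    expect_equal(glcm_features(droi),
                 brute_glcm_features(roi$levels, roi$mask, roi$nbins),
                 tolerance = 1e-10)
    expect_equal(glrlm_features(droi),
                 brute_glrlm_features(roi$levels, roi$mask, roi$nbins),
                 tolerance = 1e-10)
  }
})

test_that("direction-averaged texture features are invariant to flips and rotations", {
  set.seed(17)
  roi <- random_small_roi(nbins = 3, dmax = c(5, 5, 4))
  droi0 <- roi_as_droi(roi$levels, roi$mask, roi$nbins)
  f0g <- glcm_features(droi0)
  f0r <- glrlm_features(droi0)
  transforms <- list(
    function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE],  # flip x
    function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE],  # flip y
    function(a) a[, , rev(seq_len(dim(a)[3])), drop = FALSE],  # flip z
    function(a) aperm(a, c(2, 1, 3)),                          # swap x/y
    function(a) aperm(a, c(3, 2, 1)))                          # swap x/z
  for (tf in transforms) {
    droi <- roi_as_droi(tf(roi$levels), tf(roi$mask), roi$nbins)
    expect_equal(glcm_features(droi), f0g, tolerance = 1e-10)
    expect_equal(glrlm_features(droi), f0r, tolerance = 1e-10)
  }
})

test_that("the habitat extractor emits 114 deterministic, intensity/shape-separated features", {
  cfg <- cohort_config(n_patients = 2, volume_shape = c(20, 20, 12),
                       seed = 13)
  coh <- generate_cohort(cfg)
  s <- coh[[1]]
  v1 <- extract_habitat_vector(s$volumes$sag_T2, s$masks$sag_T2)
  expect_length(v1, 114)
  expect_identical(names(v1), feature_names())
  expect_true(all(is.finite(v1)))
  expect_identical(attr(v1, "habitat"), "sag_T2")
  expect_equal(extract_habitat_vector(s$volumes$sag_T2, s$masks$sag_T2), v1)
  # shape features ignore intensities entirely
  vol2 <- s$volumes$sag_T2
  set.seed(1); vol2$voxels[] <- sample(vol2$voxels)
  v2 <- extract_habitat_vector(vol2, s$masks$sag_T2)
  shp <- habitomics:::SHAPE_FEATURES
  expect_equal(v1[shp], v2[shp])
  expect_false(isTRUE(all.equal(v1[["X_GLCM_contrast"]],
                                v2[["X_GLCM_contrast"]])))
})

test_that("feature tables cover 9 x 114 features and respect cohort order", {
  cfg <- cohort_config(n_patients = 3, volume_shape = c(20, 20, 12),
                       seed = 19)
  coh <- generate_cohort(cfg)
  tabs <- extract_all_tables(coh)
  expect_length(tabs, 9)
  expect_equal(sum(vapply(tabs, ncol, 0L)), 1026)
  for (t in tabs) {
    expect_equal(rownames(t), c("P001", "P002", "P003"))
    expect_false(anyNA(t))
  }
  # permutation equivariance
  t2 <- extract_feature_table(coh[c(3, 1, 2)], "adc")
  expect_equal(t2[c("P001", "P002", "P003"), ], tabs$adc)
  # missing sequence errors with the patient named
  broken <- coh
  broken[[2]]$volumes$adc <- NULL
  expect_error(extract_feature_table(broken, "adc"), "P002")
})
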