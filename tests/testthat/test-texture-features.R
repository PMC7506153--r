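test_that("the catalogue has exactly 396 unique names including the published ones", {
  cat <- feature_catalog()
  expect_equal(nrow(cat), 396)
  expect_equal(anyDuplicated(cat$name), 0)
  expect_equal(as.integer(table(cat$family)[c("histogram", "shape", "haralick", "glcm", "rlm")]),
               c(42L, 9L, 21L, 126L, 198L))
  published <- c(
    "GLCMEnergy_AllDirection_offset1_SD", "GLCMEntropy_angle0_offset4",
    "HighGreyLevelRunEmphasis_AllDirection_offset1_SD",
    "LowGreyLevelRunEmphasis_AllDirection_offset1_SD",
    "ShortRunHighGreyLevelEmphasis_AllDirection_offset4_SD",
    "GLCMEntropy_AllDirection_offset1_SD", "MinIntensity",
    "HighGreyLevelRunEmphasis_AllDirection_offset4_SD"
  )
  expect_true(all(published %in% cat$name))
})

test_that("GLCM features satisfy their analytic identities", {
  # constant image: energy 1, entropy 0, contrast 0, IDM 1
  const <- glcm(grey_volume(matrix(0L, 4, 4), L = 4), "angle0", 1)
  f <- glcm_feature_set(const)
  expect_equal(f[["GLCMEnergy"]], 1)
  expect_equal(f[["GLCMEntropy"]], 0)
  expect_equal(f[["GLCMContrast"]], 0)
  expect_equal(f[["GLCMInverseDifferenceMoment"]], 1)

  # checkerboard: every horizontal pair differs by one level -> contrast 1
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2L)
  fcb <- glcm_feature_set(glcm(grey_volume(cb, L = 2), "angle0", 1))
  expect_equal(fcb[["GLCMContrast"]], 1)

  # cluster shade vanishes for any symmetric-about-mean distribution
  expect_equal(fcb[["GLCMClusterShade"]], 0)

  # uniform g over k cells: energy 1/k, entropy log2 k
  m <- matrix(c(0, 0, 0, 1, 1, 1), nrow = 2)
  u <- glcm(grey_volume(m, L = 2), "angle0", 1)
  expect_equal(glcm_energy(u), 1 / 4)
  expect_equal(glcm_entropy(u), log2(4))
})

test_that("GLCM features stay in their theoretical ranges", {
  set.seed(77)
  for (i in 1:10) {
    gv <- random_grey(c(8, 8, 2), L = 8)
    cm <- glcm(gv, sample(c("angle0", "angle45", "angle90", "angle135"), 1), 1)
    if (is.null(cm$g)) next
    e <- glcm_energy(cm)
    expect_gt(e, 0)
    expect_lte(e, 1)
    h <- glcm_entropy(cm)
    expect_gte(h, 0)
    expect_lte(h, 2 * log2(8))
  }
})

test_that("run-length emphasis features match the worked table and stay bounded", {
  gv <- grey_volume(matrix(c(1L, 1L, 2L), nrow = 1), L = 4)
  f <- rlm_feature_set(rlm(gv, "angle0", 1))
  expect_equal(f[["HighGreyLevelRunEmphasis"]], 6.5, tolerance = 1e-10)
  expect_equal(f[["LowGreyLevelRunEmphasis"]], 13 / 72, tolerance = 1e-10)
  expect_equal(f[["ShortRunHighGreyLevelEmphasis"]], 5.0, tolerance = 1e-10)
  set.seed(5)
  for (i in 1:10) {
    t <- rlm(random_grey(c(8, 8, 2), L = 6), "angle45", 1)
    f <- rlm_feature_set(t)
    expect_gte(f[["HighGreyLevelRunEmphasis"]], 1)
    expect_lte(f[["LowGreyLevelRunEmphasis"]], 1)
    expect_lte(f[["RunPercentage"]], 1)
  }
})

test_that("Haralick features honour their degenerate and worked cases", {
  const <- glcm(grey_volume(matrix(0L, 4, 4), L = 4), "angle0", 1)
  f <- haralick_feature_set(const$g)
  expect_equal(f[["HaralickDifferenceEntropy"]], 0)
  expect_equal(f[["HaralickDissimilarity"]], 0)
  expect_equal(f[["HaralickIMC1"]], 0)

  m <- matrix(c(0, 0, 0, 1, 1, 1), nrow = 2)
  g <- glcm(grey_volume(m, L = 2), "angle0", 1)$g
  expect_equal(haralick_feature_set(g)[["HaralickDissimilarity"]], 0.5)

  # independent (product-form) matrix: IMC1 = 0
  px <- c(0.3, 0.7)
  expect_equal(haralick_feature_set(outer(px, px))[["HaralickIMC1"]], 0)
})

test_that("direction variants aggregate the four angles as mean and population SD", {
  v <- direction_variants(c(0.2, 0.2, 0.3, 0.3))
  expect_equal(v[5], 0.25)
  expect_equal(v[6], 0.05)
  # isotropic constant texture: SD variant is exactly 0
  gv <- grey_volume(matrix(0L, 5, 5), L = 2)
  vals <- vapply(c("angle0", "angle45", "angle90", "angle135"),
                 function(d) glcm_energy(glcm(gv, d, 1)), 0)
  expect_equal(direction_variants(vals)[6], 0)
  # anisotropic stripes: directions disagree, SD > 0
  stripes <- outer(1:6, 1:6, function(r, c) c %% 2L)
  vals2 <- vapply(c("angle0", "angle45", "angle90", "angle135"), function(d) {
    glcm_feature_set(glcm(grey_volume(stripes, L = 2), d, 1))[["GLCMContrast"]]
  }, 0)
  expect_gt(direction_variants(vals2)[6], 0)
})

test_that("rotating a slice by 90 degrees permutes angle0/angle90 features", {
  set.seed(42)
  m <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  rot <- t(m)[8:1, ]  # 90-degree rotation
  for (o in c(1, 2)) {
    f0 <- glcm_feature_set(glcm(grey_volume(m, L = 4), "angle0", o))
    f90 <- glcm_feature_set(glcm(grey_volume(m, L = 4), "angle90", o))
    r0 <- glcm_feature_set(glcm(grey_volume(rot, L = 4), "angle0", o))
    r90 <- glcm_feature_set(glcm(grey_volume(rot, L = 4), "angle90", o))
    expect_equal(r0, f90, tolerance = 1e-10)
    expect_equal(r90, f0, tolerance = 1e-10)
    all_m <- vapply(c("angle0", "angle45", "angle90", "angle135"),
                    function(d) glcm_entropy(glcm(grey_volume(m, L = 4), d, o)), 0)
    all_r <- vapply(c("angle0", "angle45", "angle90", "angle135"),
                    function(d) glcm_entropy(glcm(grey_volume(rot, L = 4), d, o)), 0)
    expect_equal(mean(all_m), mean(all_r), tolerance = 1e-10)
    expect_equal(pop_sd(all_m), pop_sd(all_r), tolerance = 1e-10)
  }
})

test_that("histogram features follow their stated conventions", {
  v <- voxel_grid(array(c(3, 7, 9), c(3, 1, 1)))
  m <- roi_mask(array(TRUE, c(3, 1, 1)))
  f <- histogram_features(v, m)
  expect_equal(f[["MinIntensity"]], 3)
  expect_equal(f[["MaxIntensity"]], 9)

  # P50 of 1..100 under linear interpolation is 50.5
  v100 <- voxel_grid(array(as.numeric(1:100), c(100, 1, 1)))
  m100 <- roi_mask(array(TRUE, c(100, 1, 1)))
  f100 <- histogram_features(v100, m100)
  expect_equal(f100[["Percentile50"]], 50.5)
  expect_equal(f100[["Median"]], 50.5)
  expect_length(f100, 42)

  # constant region: dispersion statistics vanish, uniformity is 1
  vc <- voxel_grid(array(4, c(2, 2, 2)))
  mc <- roi_mask(array(TRUE, c(2, 2, 2)))
  fc <- histogram_features(vc, mc)
  expect_equal(unname(fc[c("StdDev", "Variance", "Entropy", "Skewness", "Kurtosis")]),
               rep(0, 5))
  expect_equal(fc[["Uniformity"]], 1)
})

test_that("shape features reproduce the cube worked example", {
  m <- array(FALSE, c(14, 14, 14))
  m[3:12, 3:12, 3:12] <- TRUE
  f <- shape_features(roi_mask(m))
  expect_equal(f[["Volume"]], 1000)
  expect_equal(f[["SurfaceArea"]], 600)
  expect_equal(f[["Sphericity"]], pi^(1 / 3) * 6000^(2 / 3) / 600, tolerance = 1e-10)
  expect_equal(f[["SurfaceToVolumeRatio"]], 0.6)
  expect_equal(f[["Maximum3DDiameter"]], sqrt(3 * 81))
  expect_equal(f[["Elongation"]], 1, tolerance = 1e-10)
  disc <- array(FALSE, c(5, 5, 5))
  disc[1, 1, 1] <- TRUE
  disc[5, 5, 5] <- TRUE
  expect_warning(fd <- shape_features(roi_mask(disc)), "disconnected")
  expect_equal(fd[["Volume"]], 2)  # computed on the union of components
})

test_that("extract_all returns the full catalogue deterministically", {
  ph <- sphere_phantom(radius_mm = 6, dims = c(20, 20, 20), suv_in = 8)
  set.seed(8)
  v <- ph$volume
  v$values <- v$values + array(runif(8000), dim(v$values))
  v <- suppressWarnings(normalize_grey(v))
  fv1 <- extract_all(v, ph$mask)
  fv2 <- extract_all(v, ph$mask)
  expect_length(fv1, 396)
  expect_identical(names(fv1), feature_catalog()$name)
  expect_identical(fv1, fv2)
  expect_false(anyNA(fv1))
})

test_that("mean GLCM entropy rises as the planted heterogeneity gets finer", {
  # heterogeneity fineness (shorter field correlation length) is the channel
  # texture entropy tracks; amplitude is cancelled by range-adaptive binning
  corr_levels <- c(8, 4, 2)
  ent <- lapply(corr_levels, function(cl) {
    spec <- phantom_spec(
      n_subjects = 8, seed = 400, grid_shape = c(40, 40, 40),
      lesion_radius_mm = list(early = c(8, 0.5), advanced = c(8, 0.5)),
      heterogeneity_sd = c(early = 0.25, advanced = 0.25),
      heterogeneity_corr_len_mm = c(early = cl, advanced = cl),
      couple_heterogeneity = FALSE
    )
    coh <- generate_cohort(spec)
    vapply(coh$subjects, function(s) {
      g <- discretize(s$pet_volume, s$lesion_mask, 32)
      mean(c(glcm_entropy(glcm(g, "angle0", 1)),
             glcm_entropy(glcm(g, "angle90", 1))))
    }, 0)
  })
  fineness <- rep(1 / corr_levels, each = 8)
  ct <- stats::cor.test(fineness, unlist(ent), method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  expect_gt(mean(ent[[3]]), mean(ent[[2]]))
  expect_gt(mean(ent[[2]]), mean(ent[[1]]))
})
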