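test_that("fixed-bin-width discretisation is min-anchored", {
  g <- array(TRUE, c(3, 1, 1))
  img <- image_volume(array(c(0, 20, 40), c(3, 1, 1)))
  d <- discretize(img, voxel_mask(g))
  expect_identical(as.integer(d), c(1L, 2L, 3L))
  expect_identical(attr(d, "Ng"), 3L)
  # a whole bin maps to one level
  img2 <- image_volume(array(c(0, 7, 19), c(3, 1, 1)))
  d2 <- discretize(img2, voxel_mask(g))
  expect_identical(attr(d2, "Ng"), 1L)
  # min-anchoring: constant shifts never change the levels
  img3 <- image_volume(array(c(100, 120, 140), c(3, 1, 1)))
  expect_identical(as.integer(discretize(img3, voxel_mask(g))),
                   as.integer(d))
  expect_error(discretize(img, voxel_mask(g), bin_width = 0),
               class = "subgrade_value_error")
})

test_that("first-order statistics match hand computation and degenerate limits", {
  g <- array(TRUE, c(4, 1, 1))
  img <- image_volume(array(c(1, 2, 3, 4), c(4, 1, 1)))
  f <- first_order_features(img, voxel_mask(g))
  expect_length(f, 19)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Variance"]), 1.25) # population convention
  expect_equal(unname(f["Energy"]), 30)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(30 / 4))
  # constant region: defined limits
  cst <- image_volume(array(7, c(3, 3, 3)))
  fc <- first_order_features(cst, voxel_mask(array(TRUE, c(3, 3, 3))))
  expect_equal(unname(fc[c("Variance", "Skewness", "Entropy")]), c(0, 0, 0))
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("texture matrices equal brute-force enumeration on random volumes", {
  for (seed in 1:10) {
    toy <- mk_disc_toy(n = 6, ng = 4, seed = seed)
    d <- discretize(toy$image, toy$mask)
    lv <- array(as.integer(d), dim(d))
    ng <- attr(d, "Ng")
    glcm <- subgrade:::.glcm_counts(lv, dim(lv), ng)
    glrlm <- subgrade:::.glrlm_counts(lv, dim(lv), ng)
    for (k in 1:13) {
      expect_equal(matrix(glcm[, , k], ng, ng),
                   oracle_glcm(lv, ng, DIRS13[k, ]))
      expect_equal(matrix(glrlm[, , k], ng),
                   oracle_glrlm(lv, ng, DIRS13[k, ], dim(glrlm)[2]))
    }
    zones <- subgrade:::.glszm_zones(lv, dim(lv))
    oz <- oracle_glszm(lv)
    expect_equal(sort(paste(zones[, 1], zones[, 2])),
                 sort(paste(oz[, 1], oz[, 2])))
    expect_equal(unname(subgrade:::.gldm_counts(lv, dim(lv), ng, 0L)),
                 unname(oracle_gldm(lv, ng, 0L)))
    expect_equal(unname(subgrade:::.ngtdm_stats(lv, dim(lv), ng)),
                 unname(oracle_ngtdm(lv, ng)))
  }
})

test_that("planar toy co-occurrences match exhaustive pair counting", {
  lv <- array(0L, c(4, 4, 1))
  lv[, , 1] <- rbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L),
                     c(3L, 3L, 4L, 4L), c(3L, 3L, 4L, 4L))
  tab <- oracle_glcm(lv, 4L, c(0, 1, 0))
  glcm <- subgrade:::.glcm_counts(lv, dim(lv), 4L)
  expect_equal(matrix(glcm[, , 2], 4, 4), tab)
  # contrast of that single offset from the normalised table
  p <- tab / sum(tab)
  i <- matrix(1:4, 4, 4)
  expect_equal(sum((i - t(i))^2 * p), 2 * 4 / 24) # 4 of 24 pairs differ by 1
})

test_that("constant regions give the defined texture limits", {
  img <- image_volume(array(5, c(3, 3, 3)))
  m <- voxel_mask(array(TRUE, c(3, 3, 3)))
  d <- discretize(img, m)
  gl <- glcm_features(d)
  expect_equal(unname(gl["Contrast"]), 0)
  expect_equal(unname(gl[c("Id", "Idm", "Idn", "Idmn", "Correlation",
                           "MCC", "JointEnergy")]),
               rep(1, 7))
  sz <- glszm_features(d)
  expect_equal(unname(sz["GrayLevelNonUniformityNormalized"]), 1)
  # one zone of size 27
  zones <- subgrade:::.glszm_zones(array(as.integer(d), dim(d)), dim(d))
  expect_equal(dim(zones), c(1L, 2L))
  expect_equal(zones[1, 2], 27L)
  # single voxel: one run of length 1 in every direction
  g1 <- array(FALSE, c(3, 3, 3))
  g1[2, 2, 2] <- TRUE
  d1 <- discretize(image_volume(array(0, c(3, 3, 3))), voxel_mask(g1))
  runs <- subgrade:::.glrlm_counts(array(as.integer(d1), dim(d1)), dim(d1), 1L)
  expect_true(all(runs[1, 1, ] == 1))
  expect_true(all(runs[1, -1, ] == 0))
})

test_that("feature class sizes match the published battery", {
  toy <- mk_disc_toy(n = 7, ng = 5, seed = 2)
  d <- discretize(toy$image, toy$mask)
  expect_length(glcm_features(d), 24)
  expect_length(glrlm_features(d), 16)
  expect_length(glszm_features(d), 16)
  expect_length(gldm_features(d), 14)
  expect_length(ngtdm_features(d), 5)
  expect_length(shape_features(mk_ball(4)), 16)
})

test_that("shape features reproduce analytic geometry", {
  b <- mk_ball(10)
  sf <- shape_features(b)
  expect_gte(unname(sf["Sphericity"]), 0.97)
  expect_lt(abs(sf["MeshVolume"] / (4 / 3 * pi * 1000) - 1), 0.07)
  expect_lt(abs(sf["Maximum3DDiameter"] - 20), 1)
  # uniform ball: per-axis variance r^2/5, so axis length 4 r / sqrt(5)
  expect_lt(abs(sf["MajorAxisLength"] - 4 * 10 / sqrt(5)), 1.2)
  expect_gt(unname(sf["Flatness"]), 0.98) # a ball is not flat

  # box: corner-to-corner diameter, exact from voxel centres
  box <- voxel_mask(array(TRUE, c(20, 10, 10)))
  sfb <- shape_features(box)
  expect_lt(abs(sfb["Maximum3DDiameter"] - sqrt(19^2 + 9^2 + 9^2)), 1)
  expect_equal(unname(sfb["VoxelVolume"]), 2000)
  # anisotropic spacing scales physical measurements
  bs <- mk_ball(6, spacing = c(1, 1, 2))
  expect_lt(abs(shape_features(bs)["Maximum3DDiameter"] -
                  2 * 6 * 2), 2.1) # widest along z in mm
})

test_that("intensity and spatial filters obey their analytic identities", {
  cfg <- phantom_config(c(8, 8, 8), seed = 4)
  ph <- generate_phantom(cfg)
  m <- ph$mask
  # square root of a non-negative constant image is constant
  cimg <- image_volume(array(9, dim(m)))
  fi <- filter_images(cimg, m, c("squareroot", "square", "logarithm",
                                 "exponential"))
  for (nm in names(fi))
    expect_equal(sd(as.numeric(fi[[nm]])), 0)
  # gradient of a linear ramp is the slope magnitude (away from borders)
  d <- dim(m)
  ramp <- image_volume(array(rep(3 * seq_len(d[1]), times = prod(d[2:3])), d))
  gr <- filter_images(ramp, m, "gradient")$gradient
  inner <- as.numeric(gr[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)])
  expect_equal(max(abs(inner - 3)), 0, tolerance = 1e-9)
  # LoG of a constant image is zero
  lg <- filter_images(cimg, m, "log", log_sigmas = 2)$log_sigma_2
  expect_lt(max(abs(as.numeric(lg))), 1e-9)
  # wavelet expands to 8 sub-bands; unknown names refuse
  wv <- filter_images(ph$image, m, "wavelet")
  expect_length(wv, 8)
  expect_error(filter_images(ph$image, m, "sobel"),
               class = "subgrade_config_error")
})

test_that("extract_all obeys the feature-count formula and determinism", {
  cfg <- phantom_config(c(8, 7, 9), seed = 6)
  ph <- generate_phantom(cfg)
  fv <- extract_all(ph$image, ph$mask)
  expect_length(fv, 110) # 19+24+16+16+14+5 intensity/texture + 16 shape
  fv2 <- extract_all(ph$image, ph$mask, filters = "squareroot")
  expect_length(fv2, 110 + 94) # one filter adds the non-shape classes
  expect_identical(fv2[names(fv)], fv)
  # byte-identical determinism
  expect_identical(extract_all(ph$image, ph$mask), fv)
  # intensity shifts never change discretised texture features
  shifted <- image_volume(array(as.numeric(ph$image) + 100, dim(ph$image)),
                          spacing(ph$image))
  fs <- extract_all(shifted, ph$mask)
  tex <- grep("glcm|glrlm|glszm|gldm|ngtdm", names(fv), value = TRUE)
  expect_equal(fs[tex], fv[tex])
})
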