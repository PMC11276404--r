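make_block_volume <- function() {
  # two uniform air pockets inside a soft-tissue block, plus exterior air
  d <- c(20, 20, 12)
  vox <- array(0, d)
  vox[1:3, , ] <- -995                      # "exterior" block
  vox[8:13, 8:13, 3:10] <- -985             # "airway" block
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  ext <- array(FALSE, d); ext[1:3, , ] <- TRUE
  aw <- array(FALSE, d); aw[8:13, 8:13, 3:10] <- TRUE
  list(vol = vol,
       ext = binary_mask(ext, "exterior_air", vol$spacing),
       aw = binary_mask(aw, "airway", vol$spacing))
}

test_that("air reference combines the exterior and airway medians", {
  b <- make_block_volume()
  expect_equal(air_reference(b$vol, b$ext, b$aw), -990)   # mean(-995, -985)
  expect_equal(air_reference(b$vol, b$ext, NULL), -995)
  expect_equal(air_reference(b$vol, NULL, b$aw), -985)
  empty <- binary_mask(array(FALSE, dim(b$vol$voxels)), "airway", b$vol$spacing)
  expect_equal(air_reference(b$vol, NULL, b$aw, erode_vox = 0), -985)
  expect_error(air_reference(b$vol, NULL, empty), "empty")

  uni <- b
  uni$vol$voxels[] <- 0
  uni$vol$voxels[b$ext$grid] <- -1000
  uni$vol$voxels[b$aw$grid] <- -1000
  expect_equal(air_reference(uni$vol, uni$ext, uni$aw), -1000)
})

test_that("air reference follows a calibration shift on the phantom", {
  ph <- generate_phantom(small_spec(seed = 21, calibration_shift = 25))
  anat <- segment_anatomy(ph$volume)
  A <- air_reference(ph$volume, anat$exterior, anat$airway)
  expect_lt(abs(A - (-975)), 2)
})

test_that("the windowed parenchyma percentile matches a direct oracle", {
  ph <- small_phantom()
  anat <- small_anatomy()
  cfg <- cyst_config()
  P <- parenchyma_field(ph$volume, anat$lung,
                        window_radius_mm = cfg$window_radius_mm,
                        percentile = cfg$percentile,
                        min_window_count = cfg$min_window_count)
  lung_idx <- which(anat$lung$grid, arr.ind = TRUE)
  set.seed(31)
  at <- lung_idx[sample(nrow(lung_idx), 120), , drop = FALSE]
  hw <- as.integer(floor(cfg$window_radius_mm / ph$volume$spacing))
  fb <- lung_percentile(ph$volume, anat$lung, cfg$percentile)
  want <- window_percentile_oracle(ph$volume$voxels, anat$lung$grid, at, hw,
                                   cfg$percentile, cfg$min_window_count, fb)
  got <- P[at]
  expect_equal(got, as.numeric(want), tolerance = 1e-12)
  # the field is defined exactly on the lung
  expect_true(all(is.na(P[!anat$lung$grid])))
  expect_true(all(!is.na(P[anat$lung$grid])))
})

test_that("a window covering the whole lung equals the global percentile", {
  ph <- small_phantom()
  anat <- small_anatomy()
  P <- parenchyma_field(ph$volume, anat$lung, window_radius_mm = 1000)
  g <- lung_percentile(ph$volume, anat$lung, 75)
  expect_true(all(abs(P[anat$lung$grid] - g) < 1e-12))
})

test_that("on homogeneous parenchyma the local percentile tracks the global one", {
  # a pure noisy-parenchyma block: every window sees the same distribution
  set.seed(22)
  d <- c(36, 36, 36)
  vol <- ct_volume(array(rnorm(prod(d), -850, 40), d), spacing = c(1.5, 1.5, 1.5))
  lung <- binary_mask(array(TRUE, d), "lung", vol$spacing)
  P <- parenchyma_field(vol, lung)
  g <- lung_percentile(vol, lung, 75)
  # the global 75th percentile sits ~0.674 sigma above the mean ...
  expect_equal(as.numeric(g), -850 + qnorm(0.75) * 40, tolerance = 0.01)
  # ... and the windowed field scatters tightly around it
  expect_gte(mean(abs(P - g) <= 6), 0.99)
})

test_that("the adaptive threshold interpolates air and parenchyma", {
  # nominal anatomy reproduces the standard global threshold
  expect_identical(adaptive_threshold_field(-1000, -850, f = 0.4)$values, -940)
  expect_identical(adaptive_threshold_field(-990, -840, f = 0.4)$values, -930)
  # degenerate fraction collapses onto the air reference
  expect_identical(adaptive_threshold_field(-1000, -850, f = 0)$values, -1000)
  expect_error(adaptive_threshold_field(-1000, -850, f = 1), "f")
  # voxels where parenchyma dips to the air reference are clamped
  P <- c(-850, -1005, -1000)
  expect_warning(tf <- adaptive_threshold_field(-1000, P, f = 0.4), "clamped")
  expect_equal(tf$values, c(-940, -999, -999))
  expect_equal(tf$n_clamped, 2)
  # summary brackets the field
  expect_lte(tf$summary["min"], tf$summary["median"])
  expect_lte(tf$summary["median"], tf$summary["max"])
})

toy_nine <- function() {
  hu <- c(-1000, -930, -941, -940, -800, -950, -939, -1000, -850)
  d <- c(3, 3, 2)
  vox <- array(0, d)
  vox[, , 1] <- hu
  vol <- ct_volume(vox, spacing = c(1, 1, 1))
  lung <- array(FALSE, d); lung[, , 1] <- TRUE
  list(vol = vol, lung = binary_mask(lung, "lung", vol$spacing))
}

test_that("strict thresholding on the nine-voxel example keeps 4 cysts", {
  t9 <- toy_nine()
  cy <- segment_cysts(t9$vol, t9$lung, NULL, threshold = -940,
                      min_component_ml = 0)
  expect_equal(sum(cy$grid), 4)   # -941, -950 and the two -1000s; -940 is a tie
  fx <- fixed_threshold_segment(t9$vol, t9$lung, NULL, theta = -940,
                                operator_offset = 0, min_component_ml = 0)
  expect_identical(fx$grid, cy$grid)
  sc <- cyst_score(cy, t9$lung, NULL)
  expect_equal(sc$score_pct, 100 * 4 / 9, tolerance = 1e-12)
})

test_that("saturating thresholds and empty masks behave at the extremes", {
  t9 <- toy_nine()
  high <- fixed_threshold_segment(t9$vol, t9$lung, NULL, theta = -940,
                                  operator_offset = 1000, min_component_ml = 0)
  expect_identical(high$grid, t9$lung$grid)
  expect_equal(cyst_score(high, t9$lung, NULL)$score_pct, 100)
  low <- segment_cysts(t9$vol, t9$lung, NULL, threshold = -2000,
                       min_component_ml = 0)
  expect_equal(sum(low$grid), 0)
  expect_equal(cyst_score(low, t9$lung, NULL)$score_pct, 0)
})

test_that("cyst score excludes the airway from both terms and checks bounds", {
  d <- c(4, 4, 2)
  lung <- binary_mask(array(TRUE, d), "lung", c(1, 1, 1))
  aw <- array(FALSE, d); aw[1:2, 1, 1] <- TRUE
  airway <- binary_mask(aw, "airway", c(1, 1, 1))
  cg <- array(FALSE, d); cg[3:4, 3, 1] <- TRUE
  cyst <- binary_mask(cg, "cyst", c(1, 1, 1))
  sc <- cyst_score(cyst, lung, airway)
  expect_equal(sc$lung_volume_ml, (32 - 2) / 1000, tolerance = 1e-12)
  expect_equal(sc$score_pct, 100 * 2 / 30, tolerance = 1e-12)
  expect_equal(sc$score_pct, 100 * sc$cyst_volume_ml / sc$lung_volume_ml,
               tolerance = 1e-9)
  # cysts overlapping the airway violate the contract
  cg2 <- cg; cg2[1, 1, 1] <- TRUE
  expect_error(cyst_score(binary_mask(cg2, "cyst", c(1, 1, 1)), lung, airway),
               "not contained")
})

test_that("raising thresholds never shrinks the cyst mask", {
  ph <- small_phantom()
  anat <- small_anatomy()
  for (th in list(c(-960, -940), c(-940, -915))) {
    lo <- segment_cysts(ph$volume, anat$lung, anat$airway, threshold = th[1])
    hi <- segment_cysts(ph$volume, anat$lung, anat$airway, threshold = th[2])
    expect_true(all(lo$grid <= hi$grid))
  }
})

test_that("an additive shift commutes exactly with an equal operator offset", {
  ph <- small_phantom()
  anat <- small_anatomy()
  shifted <- apply_calibration_shift(ph$volume, 25)
  a <- fixed_threshold_segment(ph$volume, anat$lung, anat$airway,
                               operator_offset = 0)
  b <- fixed_threshold_segment(shifted, anat$lung, anat$airway,
                               operator_offset = 25)
  expect_equal(sum(a$grid), sum(b$grid))
})

test_that("the automatic pipeline is deterministic and self-consistent", {
  ph <- small_phantom()
  r1 <- run_automatic(ph$volume)
  r2 <- run_automatic(ph$volume)
  expect_identical(r1$score_pct, r2$score_pct)
  expect_gte(r1$score_pct, 0); expect_lte(r1$score_pct, 100)
  expect_equal(r1$score_pct, 100 * r1$cyst_volume_ml / r1$lung_volume_ml,
               tolerance = 1e-9)
  # detected cysts agree with the phantom truth
  m <- attr(r1, "masks")
  expect_gte(dice(m$cyst, ph$cyst), 0.8)
  expect_lt(abs(r1$score_pct - ph$true_fraction_pct), 1.5)
})

test_that("segmentation equals the enumeration oracle on random small grids", {
  set.seed(77)
  for (i in 1:12) {
    d <- sample(4:12, 3, replace = TRUE)
    vox <- array(runif(prod(d), -1100, -700), d)
    lung <- array(runif(prod(d)) < 0.7, d)
    aw <- array(runif(prod(d)) < 0.05, d) & lung
    sp <- runif(3, 0.8, 2)
    tv <- if (i %% 2) -940 else array(runif(prod(d), -1000, -800), d)
    minml <- sample(c(0, 0.004, 0.02), 1)
    vol <- ct_volume(vox, sp)
    got <- segment_cysts(vol, binary_mask(lung, "lung", sp),
                         binary_mask(aw, "airway", sp),
                         threshold = tv, min_component_ml = minml)
    want <- enum_cyst_oracle(vox, lung, aw, tv, sp, minml)
    expect_identical(got$grid, want)
  }
})
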