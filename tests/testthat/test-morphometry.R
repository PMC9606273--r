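test_that("the constrained Gaussian filter fixes constants and preserves mass", {
  img <- density_image(array(500, c(10, 10, 10)))
  expect_lt(max(abs(denoise(img)$values - 500)) / 500, 1e-6)

  imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 1
  out <- denoise(density_image(imp))
  expect_equal(sum(out$values), 1, tolerance = 1e-12)
  # 3x3x3 separable kernel at sigma 1.2, truncate 0.8, support 1
  w <- exp(-(0:1)^2 / (2 * 1.2^2)); w <- w / (w[1] + 2 * w[2])
  expect_equal(out$values[6, 6, 6], w[1]^3, tolerance = 1e-12)
  expect_equal(out$values[5, 6, 6], w[1]^2 * w[2], tolerance = 1e-12)
  expect_true(all(out$values[3, , ] == 0))   # support-limited kernel radius 1
})

test_that("denoising reduces variance in marrow regions of a noisy phantom", {
  ph <- make_phantom(tiny_params(noise_sd = 60, blur_sd = 0.8))
  # marrow core away from bone, where smoothing cannot bleed structure in
  bone <- ph$geometry$values >= 320
  near_bone <- remodelr:::morph6(bone, 2L, dilate = TRUE, border = FALSE)
  marrow <- ph$masks$trabecular & !near_bone
  den <- denoise(ph$image)
  expect_lt(var(den$values[marrow]), var(ph$image$values[marrow]))
})

test_that("binarize uses the >= convention and nests across thresholds", {
  img <- density_image(array(c(100, 320, 319.999, 650, 900, 0, 50, 440),
                             c(2, 2, 2)))
  b <- binarize(img, 320)
  expect_identical(as.vector(b), c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                                   FALSE, TRUE))
  expect_false(any(binarize(img, 2000)))
  expect_false(any(binarize(img, 440) & !binarize(img, 320)))  # nesting
  expect_error(binarize(img, -1), "non-negative")
})

test_that("voxel classification matches a hand-enumerated 3x3x3 fixture", {
  base <- array(FALSE, c(3, 3, 3))
  fup <- array(FALSE, c(3, 3, 3))
  base[1:2, , 1] <- TRUE            # 6 baseline voxels in slice 1
  fup[2:3, , 1] <- TRUE             # overlap in row 2
  region <- array(TRUE, c(3, 3, 3))
  region[, , 3] <- FALSE            # slice 3 outside the analysis region
  lab <- classify_remodeling(base, fup, region, threshold = 320)
  expect_identical(sum(lab$labels == 1L), 3L)  # formed: row 3, slice 1
  expect_identical(sum(lab$labels == 2L), 3L)  # resorbed: row 1, slice 1
  expect_identical(sum(lab$labels == 3L), 3L)  # quiescent: row 2, slice 1
  expect_identical(sum(lab$labels == 0L), 27L - 9L)

  same <- classify_remodeling(base, base, region)
  expect_identical(sum(same$labels == 1L), 0L)
  expect_identical(sum(same$labels == 2L), 0L)

  none <- array(FALSE, c(3, 3, 3))
  k <- classify_remodeling(none, fup, region)
  expect_identical(sum(k$labels == 1L), sum(fup & region))

  expect_error(classify_remodeling(base, fup, none), "empty")
})

test_that("minimum-cluster filtering reverts single-voxel events when enabled", {
  base <- array(FALSE, c(7, 7, 7)); base[2:6, 2:6, 2:4] <- TRUE
  fup <- base
  fup[4, 4, 5] <- TRUE              # isolated formed voxel
  fup[2, 2, 2] <- FALSE             # isolated resorbed voxel
  region <- array(TRUE, c(7, 7, 7))
  keep <- classify_remodeling(base, fup, region)
  expect_identical(sum(keep$labels == 1L), 1L)
  drop <- classify_remodeling(base, fup, region, min_cluster = 2L)
  expect_identical(sum(drop$labels == 1L), 0L)
  expect_identical(sum(drop$labels == 2L), 0L)
  expect_identical(sum(drop$labels == 3L), sum(base))
})

test_that("remodeling fractions are baseline-relative and flag empty compartments", {
  n <- c(10, 10, 10)
  base <- array(FALSE, n); base[1:10, 1:10, 1] <- TRUE  # 100 baseline voxels
  fup <- base
  fup[1:10, 1, 2] <- TRUE          # 10 formed (adjacent slice)
  fup[1:5, 1, 1] <- FALSE          # 5 resorbed
  lab <- classify_remodeling(base, fup, array(TRUE, n), threshold = 320)
  masks <- bone_masks(whole = array(TRUE, n),
                      cortical = array(c(TRUE, rep(FALSE, 0)), n) & FALSE,
                      trabecular = array(TRUE, n))
  expect_warning(fr <- remodeling_fractions(lab, masks, 0.0607), "cortical")
  tb <- fr[fr$compartment == "trabecular", ]
  expect_equal(tb$formation_vf, 0.10)
  expect_equal(tb$resorption_vf, 0.05)
  expect_equal(tb$baseline_volume_mm3, 100 * 0.0607^3)
  expect_true(is.na(fr$formation_vf[fr$compartment == "cortical"]))
})

test_that("the threshold sweep has 7 cortical and 5 trabecular rows and zeros for identical images", {
  ph <- make_phantom(tiny_params())
  # compartments run out of bone at the top of the ladder (struts are 650,
  # cortex 900), which remodeling_fractions flags per compartment
  sweep <- suppressWarnings(threshold_sweep(ph$image, ph$image, ph$masks,
                                            denoise = FALSE))
  expect_identical(sum(sweep$compartment == "cortical"), 7L)
  expect_identical(sum(sweep$compartment == "trabecular"), 5L)
  expect_true(all(sweep$formation_vf == 0, na.rm = TRUE))
  expect_true(all(sweep$resorption_vf == 0, na.rm = TRUE))
  # superlevel-set nesting: baseline volume non-increasing in threshold
  for (comp in c("cortical", "trabecular")) {
    v <- sweep$baseline_volume_mm3[sweep$compartment == comp]
    expect_true(all(diff(v) <= 0))
  }
})

test_that("static summaries match solid, half-filled and lattice fixtures", {
  n <- c(8, 8, 8)
  solid <- density_image(array(900, n))
  cort <- array(FALSE, n); cort[, , 5:8] <- TRUE
  trab <- array(FALSE, n); trab[, , 1:4] <- TRUE
  masks <- bone_masks(array(TRUE, n), cort, trab)
  s <- static_summaries(solid, masks)
  expect_equal(s$bvtv[s$region == "whole"], 1)
  expect_equal(s$mean_density[s$region == "whole"], 900)

  half <- array(0, n); half[, , 1:4] <- 900
  s2 <- static_summaries(density_image(half), masks)
  expect_equal(s2$bvtv[s2$region == "whole"], 0.5)
  expect_equal(s2$bvtv[s2$region == "trabecular"], 1)
  expect_equal(s2$bvtv[s2$region == "cortical"], 0)

  empty <- bone_masks(array(TRUE, n), cort, array(FALSE, n))
  expect_error(static_summaries(solid, empty), "trabecular")
})

test_that("after registration, a misaligned noise-free phantom is classified to within one surface layer", {
  ph <- make_phantom(tiny_params(blur_sd = 0.8))
  h <- ph$image$voxel_size
  tf <- rigid_transform(rotation = c(0, 2, -3) * pi / 180,
                        translation = c(3, -2, 4) * h, center = c(0, 0, 0))
  strain <- surrogate_strain(ph$masks, "depth_ramp")
  rule <- mechanoreg_rule(0.08, 0.23, obedience = 0.9, event_rate = 0.8)
  fu <- simulate_followup(ph, strain, rule, misalignment = tf, seed = 6)
  reg <- register_rigid(ph$image, fu$image)
  aligned <- resample(fu$image, reg$transform, "cubic")
  bb <- binarize(denoise(ph$image), 320)
  lab <- classify_remodeling(bb, binarize(denoise(aligned), 320),
                             array(TRUE, dim(bb)), 320)
  truth <- fu$truth$true_labels$labels
  layer <- surface_layer_count(ph$geometry$values >= 320)
  for (code in 1:3) {
    expect_lt(abs(sum(lab$labels == code) - sum(truth == code)), layer)
  }
})
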