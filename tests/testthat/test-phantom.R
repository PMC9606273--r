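test_that("the noise-free phantom takes exactly the nominal density values", {
  ph <- make_phantom(tiny_params())
  expect_setequal(unique(as.vector(ph$image$values)), c(0, 50, 650, 900))
  expect_identical(ph$image$values, ph$geometry$values)
})

test_that("trabecular BV/TV is within 20% of the closed-form lattice fraction", {
  ph <- make_phantom(phantom_params(noise_sd = 0, blur_sd = 0))
  p <- ph$params
  q <- p$strut_thickness / p$strut_spacing
  analytic <- 3 * q^2 - 2 * q^3
  bvtv <- sum(binarize(ph$geometry, 320) & ph$masks$trabecular) /
    sum(ph$masks$trabecular)
  expect_lt(abs(bvtv / analytic - 1), 0.2)
})

test_that("phantom generation is deterministic for a fixed seed", {
  a <- make_phantom(tiny_params(noise_sd = 60, blur_sd = 0.8, seed = 9L))
  b <- make_phantom(tiny_params(noise_sd = 60, blur_sd = 0.8, seed = 9L))
  expect_identical(a$image$values, b$image$values)
  c <- make_phantom(tiny_params(noise_sd = 60, blur_sd = 0.8, seed = 10L))
  expect_false(identical(a$image$values, c$image$values))
})

test_that("unresolvable struts and invalid parameters are rejected", {
  expect_error(phantom_params(strut_thickness = 0.05), "2 voxels")
  expect_error(phantom_params(inner_radius = 1.3, outer_radius = 1.2),
               "smaller")
  expect_error(phantom_params(cortical_density = 1500), "1200")
  expect_error(mechanoreg_rule(0.3, 0.2), "resorption_threshold")
  expect_error(mechanoreg_rule(obedience = 1.2), "0, 1")
})

test_that("event_rate 0 leaves the phantom quiescent", {
  ph <- make_phantom(tiny_params())
  strain <- surrogate_strain(ph$masks, "depth_ramp")
  fu <- simulate_followup(ph, strain, mechanoreg_rule(event_rate = 0),
                          seed = 1)
  expect_identical(fu$image$values, ph$geometry$values)
  expect_identical(unname(fu$truth$counts[c("formed", "resorbed")]),
                   c(0L, 0L))
  expect_setequal(unique(as.vector(fu$truth$true_labels$labels)), c(0L, 3L))
})

test_that("extreme thresholds (0, 1) with full obedience produce no events", {
  ph <- slab_phantom()
  strain <- array(0.5, dim(ph$image$values))
  rule <- mechanoreg_rule(0, 1, obedience = 1, event_rate = 1)
  fu <- simulate_followup(ph, strain, rule, seed = 1)
  expect_identical(unname(fu$truth$counts[c("formed", "resorbed")]),
                   c(0L, 0L))
})

test_that("uniform supra-threshold strain on a slab forms every eligible site", {
  n <- 12L; k <- 5L
  ph <- slab_phantom(n = n, k = k)
  strain <- array(0.5, c(n, n, n))
  rule <- mechanoreg_rule(0.08, 0.23, obedience = 1, event_rate = 1)
  fu <- simulate_followup(ph, strain, rule, seed = 1)
  # lateral out-of-grid counts as bone, so the only surface is slice k and
  # the only formation candidates are the n^2 voxels of slice k+1
  expect_identical(unname(fu$truth$counts["formed"]), n * n)
  expect_identical(unname(fu$truth$counts["resorbed"]), 0L)
  expect_true(all(fu$truth$true_labels$labels[, , k + 1L] == 1L))
  expect_identical(unname(fu$truth$counts["quiescent"]), n * n * k)
})

test_that("ground-truth counts equal the realized density edits", {
  ph <- make_phantom(tiny_params())
  strain <- surrogate_strain(ph$masks, "depth_ramp")
  rule <- mechanoreg_rule(0.08, 0.23, obedience = 0.9, event_rate = 0.8)
  fu <- simulate_followup(ph, strain, rule, seed = 4)
  lab <- fu$truth$true_labels$labels
  expect_identical(sum(lab == 1L), unname(fu$truth$counts["formed"]))
  expect_identical(sum(lab == 2L), unname(fu$truth$counts["resorbed"]))
  # with no blur/noise/misalignment the edits are directly visible
  changed <- fu$image$values != ph$geometry$values
  expect_identical(sum(changed), sum(lab == 1L) + sum(lab == 2L))
})

test_that("depth_ramp strain is linear in z and normalized at the 99th percentile", {
  ph <- make_phantom(tiny_params())
  s <- surrogate_strain(ph$masks, "depth_ramp")
  col <- s[10, 10, ]
  expect_lt(max(abs(diff(diff(col)))), 1e-12)    # affine along z
  expect_lt(col[length(col)], col[1])             # highest distally (slice 1)
  expect_equal(quantile(s[ph$masks$whole], 0.99, names = FALSE), 1)
})

test_that("fe-mode surrogate strain is near-uniform on a homogeneous cube", {
  n <- c(12, 12, 16)
  img <- density_image(array(800, n), voxel_size = 0.2)
  masks <- bone_masks(whole = array(TRUE, n),
                      cortical = array(FALSE, n),
                      trabecular = array(FALSE, n))
  s <- surrogate_strain(masks, "fe", image = img,
                        law = material_law(nu = 0.3))
  core <- s[, , 5:12]
  expect_lt(sd(core) / mean(core), 0.15)
})

test_that("strain fields on a different grid are rejected", {
  ph <- make_phantom(tiny_params())
  expect_error(simulate_followup(ph, array(0.5, c(4, 4, 4)),
                                 mechanoreg_rule(), seed = 1),
               "congruent")
})
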