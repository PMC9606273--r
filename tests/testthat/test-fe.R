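test_that("mesh construction keeps the spanning component and scales moduli", {
  n <- c(10, 10, 10)
  img <- density_image(array(1200, n), voxel_size = 0.5)
  mesh <- build_mesh(img, law = material_law())
  expect_identical(length(mesh$elements), 1000L)
  expect_true(all(mesh$E == 10000))

  # a floating cluster is excluded
  vals <- array(0, c(10, 10, 12))
  vals[3:8, 3:8, 1:8] <- 1200
  vals[5:6, 5:6, 11:12] <- 1200
  mesh2 <- build_mesh(density_image(vals, voxel_size = 0.5),
                      law = material_law())
  expect_identical(length(mesh2$elements), 6L * 6L * 8L)

  # linear density scaling: rho 600 at rho_ref 1200 gives half E_max
  expect_equal(modulus_from_density(material_law(), 600), 5000)
  expect_equal(modulus_from_density(material_law(), 2000), 10000)  # clamped
  expect_true(all(diff(modulus_from_density(material_law(),
                                            seq(0, 1300, 50))) >= 0))

  air <- density_image(array(0, n))
  expect_error(build_mesh(air, law = material_law()), "cannot carry load")
})

test_that("the element stiffness matches an independent 24x24 integration to 1e-10", {
  for (nu in c(0, 0.3)) {
    K_pkg <- remodelr:::cpp_hex_stiffness(0.0607, nu)
    K_orc <- oracle_hex_ke(0.0607, 1, nu)
    expect_lt(max(abs(K_pkg - K_orc)) / max(abs(K_orc)), 1e-10)
    expect_lt(max(abs(K_pkg - t(K_pkg))), 1e-14)          # symmetry
    expect_lt(max(abs(rowSums(K_pkg))), 1e-12)            # rigid-body modes
  }
})

test_that("a one-element column matches the dense direct solve to 1e-10", {
  img <- density_image(array(c(800, 500, 1100), c(1, 1, 3)), voxel_size = 0.3)
  mesh <- build_mesh(img, law = material_law(nu = 0.3))
  fe <- solve_compression(mesh, 0.01, tolerance = 1e-14)
  u_oracle <- oracle_dense_solve(mesh, 0.01)
  u_pkg <- as.vector(t(fe$displacements))
  expect_lt(max(abs(u_pkg - u_oracle)) / max(abs(u_oracle)), 1e-10)
})

test_that("a homogeneous prism at nu = 0 reproduces the uniaxial closed form", {
  law <- material_law(nu = 0)
  img <- density_image(array(1200, c(6, 7, 9)), voxel_size = 0.5)
  fe <- solve_compression(build_mesh(img, law = law), 0.01,
                          tolerance = 1e-12)
  E <- 10000; A <- 6 * 7 * 0.5^2; L <- 9 * 0.5
  expect_equal(fe$stiffness_kN_mm * 1000, E * A / L, tolerance = 1e-8)
  expect_equal(range(fe$eps_eff_ue), c(10000, 10000), tolerance = 1e-8)
})

test_that("a frictionless prism at nu = 0.3 reproduces the uniaxial-stress closed form", {
  law <- material_law(nu = 0.3)
  img <- density_image(array(1200, c(6, 7, 9)), voxel_size = 0.5)
  fe <- solve_compression(build_mesh(img, law = law), 0.01,
                          tolerance = 1e-12, high_friction = FALSE)
  E <- 10000; A <- 6 * 7 * 0.5^2; L <- 9 * 0.5
  expect_equal(fe$stiffness_kN_mm * 1000, E * A / L, tolerance = 1e-6)
  expect_equal(range(fe$eps_eff_ue), c(10000, 10000), tolerance = 1e-6)
})

test_that("effective strain follows sqrt(2 SED / E)", {
  expect_equal(effective_strain(5000, 10000), 1)
  expect_equal(effective_strain(0.05, 10000) * 1e6, sqrt(1e-5) * 1e6,
               tolerance = 1e-12)
  expect_equal(effective_strain(0.1, 10000) / effective_strain(0.05, 10000),
               sqrt(2), tolerance = 1e-12)
  expect_equal(effective_strain(0, 10000), 0)
  expect_error(effective_strain(1, 0), "positive")
})

test_that("strain percentiles use linear order-statistic interpolation", {
  n <- c(5, 5, 8)
  fake <- structure(list(
    eps_eff_ue = as.numeric(1:200),
    mesh = list(elements = 1:200, dim = n)), class = "fe_result")
  trab <- array(c(rep(TRUE, 100), rep(FALSE, 100)), n)   # strains 1..100
  cort <- !trab
  masks <- bone_masks(array(TRUE, n), cort, trab)
  sp <- strain_percentiles(fake, masks, percentiles = c(5, 10, 25, 50, 75, 99))
  tb <- sp[sp$compartment == "trabecular", ]
  expect_equal(tb$eps_eff_ue[tb$percentile == 25], 25.75)
  expect_true(all(diff(tb$eps_eff_ue) >= 0))
  ct <- sp[sp$compartment == "cortical", ]
  expect_equal(ct$eps_eff_ue[ct$percentile == 25], 125.75)
  expect_error(strain_percentiles(fake,
    bone_masks(array(TRUE, n), cort, array(FALSE, n))),
    "trabecular")
})

test_that("reactions balance and stiffness grows with any modulus increase", {
  set.seed(8)
  vals <- array(runif(6 * 6 * 8, 300, 1200), c(6, 6, 8))
  img <- density_image(vals, voxel_size = 0.5)
  mesh <- build_mesh(img, law = material_law(nu = 0.3))
  fe <- solve_compression(mesh, 0.01, tolerance = 1e-9)
  expect_lt(abs(fe$reaction_top_kN + fe$reaction_bottom_kN),
            1e-6 * abs(fe$reaction_top_kN))
  expect_true(all(fe$eps_eff >= 0))

  stiffer <- mesh
  stiffer$E[10] <- stiffer$E[10] * 3
  fe2 <- solve_compression(stiffer, 0.01, tolerance = 1e-9)
  expect_gte(fe2$stiffness_kN_mm, fe$stiffness_kN_mm)
})
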