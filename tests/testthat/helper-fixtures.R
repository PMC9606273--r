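# Shared fixtures: small phantoms and transform-error metrics.

# a compact phantom for fast unit tests (clean by default)
tiny_params <- function(noise_sd = 0, blur_sd = 0, seed = 42L, ...) {
  phantom_params(grid = c(40, 40, 44), outer_radius = 0.85,
                 inner_radius = 0.6, strut_spacing = 0.5,
                 strut_thickness = 0.2, z_margin = 12L,
                 noise_sd = noise_sd, blur_sd = blur_sd, seed = seed, ...)
}

# mask-validation phantom: thick cortex, sparse lattice, so the nominal
# annulus is unambiguous against blurred strut-root fillets
dice_params <- function(noise_sd = 60, blur_sd = 0.8, seed = 42L) {
  phantom_params(grid = c(96, 96, 88), outer_radius = 1.3,
                 inner_radius = 0.72, strut_spacing = 0.7,
                 strut_thickness = 0.2, noise_sd = noise_sd,
                 blur_sd = blur_sd, seed = seed)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# number of voxels in the one-voxel surface layer of a bone set (out-of-grid
# treated as bone, matching the package's surface convention)
surface_layer_count <- function(bone) {
  d <- dim(bone)
  interior <- bone
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    shifted <- array(TRUE, d)
    n <- d[ax]
    src <- dst <- lapply(d, seq_len)
    if (s > 0) { dst[[ax]] <- (s + 1):n; src[[ax]] <- 1:(n - s) }
    else { dst[[ax]] <- 1:(n + s); src[[ax]] <- (1 - s):n }
    shifted[dst[[1]], dst[[2]], dst[[3]]] <- bone[src[[1]], src[[2]], src[[3]]]
    interior <- interior & shifted
  }
  sum(bone & !interior)
}

# rotation (deg) and centre-displacement (voxels) of the composition of the
# applied misalignment with the recovered transform (identity if perfect)
transform_error <- function(applied, recovered, voxel_size) {
  E <- tf_compose(applied, recovered)
  R <- rotation_matrix(E$rotation)
  ang <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
  trans <- sqrt(sum((transform_points(E, c(0, 0, 0)) - c(0, 0, 0))^2)) /
    voxel_size
  c(deg = ang, vox = trans)
}

# hand-built flat-slab "phantom" (bone occupying slices 1..k over the full
# cross-section), for countable remodeling-event tests
slab_phantom <- function(n = 12L, k = 5L, density = 650, marrow = 50,
                         voxel_size = 0.0607) {
  vals <- array(marrow, c(n, n, n))
  vals[, , seq_len(k)] <- density
  img <- density_image(vals, voxel_size = voxel_size,
                       origin = -(c(n, n, n) - 1) / 2 * voxel_size)
  masks <- bone_masks(whole = array(TRUE, c(n, n, n)),
                      cortical = array(FALSE, c(n, n, n)),
                      trabecular = array(TRUE, c(n, n, n)))
  params <- structure(list(grid = c(n, n, n), voxel_size = voxel_size,
                           marrow_density = marrow, strut_density = density,
                           noise_sd = 0, blur_sd = 0, z_margin = 0L,
                           seed = 1L),
                      class = "phantom_params")
  structure(list(image = img, geometry = img, geometry_ext = img$values,
                 masks = masks, params = params), class = "phantom")
}
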