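#' Parameters of the synthetic bone phantom
#'
#' Describes a distal-radius-like density phantom: a cortical annulus of peak
#' density enclosing a regular three-axis trabecular rod lattice in marrow,
#' with optional Gaussian surface blur (partial-volume emulation) and
#' additive Gaussian image noise. All densities in mg HA/cm^3, lengths in mm.
#'
#' @param grid Grid dimensions `c(nx, ny, nz)` in voxels.
#' @param voxel_size Isotropic voxel edge (mm).
#' @param outer_radius,inner_radius Cortical annulus radii (mm).
#' @param cortical_density,strut_density,marrow_density Nominal densities.
#' @param strut_spacing,strut_thickness Rod lattice pitch and rod width (mm);
#'   rods thinner than 2 voxels are rejected as unresolvable.
#' @param taper Relative change of both radii along the shaft (metaphyseal
#'   flare): the distal end (first slice) is wider by `taper/2`, the proximal
#'   end narrower by `taper/2`. Besides anatomy, this breaks the axial
#'   periodicity of the lattice so that longitudinal registration is
#'   well-posed.
#' @param noise_sd Additive Gaussian noise SD (mg HA/cm^3).
#' @param blur_sd Surface blur SD in voxels (0 disables).
#' @param z_margin Longitudinal generation margin (voxels). The geometry is
#'   generated on a z-extended grid and cropped to the field of view, so a
#'   misaligned follow-up "scan" windows real anatomy instead of dragging a
#'   zero-filled band into the image — the repositioning regime of repeat
#'   peripheral scanning.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid = c(92, 92, 88), voxel_size = 0.0607,
                           outer_radius = 1.15, inner_radius = 0.78,
                           cortical_density = 900, strut_density = 650,
                           marrow_density = 50, strut_spacing = 0.5,
                           strut_thickness = 0.2, taper = 0.12,
                           noise_sd = 60, blur_sd = 0.8, z_margin = 26L,
                           seed = 42L) {
  stopifnot(length(grid) == 3L, all(grid >= 4))
  if (inner_radius >= outer_radius)
    stop("inner_radius must be smaller than outer_radius", call. = FALSE)
  dens <- c(cortical_density, strut_density, marrow_density)
  if (any(dens < 0 | dens > 1200))
    stop("densities must lie in [0, 1200] mg HA/cm^3", call. = FALSE)
  if (strut_thickness < 2 * voxel_size)
    stop(sprintf("struts thinner than 2 voxels (%.4f mm) cannot be resolved",
                 2 * voxel_size), call. = FALSE)
  if (noise_sd < 0 || blur_sd < 0)
    stop("noise_sd and blur_sd must be non-negative", call. = FALSE)
  if (z_margin < 0) stop("z_margin must be non-negative", call. = FALSE)
  if (taper < 0 || taper >= 1) stop("taper must lie in [0, 1)", call. = FALSE)
  structure(list(grid = as.integer(grid), voxel_size = voxel_size,
                 taper = taper,
                 outer_radius = outer_radius, inner_radius = inner_radius,
                 cortical_density = cortical_density,
                 strut_density = strut_density,
                 marrow_density = marrow_density,
                 strut_spacing = strut_spacing,
                 strut_thickness = strut_thickness, noise_sd = noise_sd,
                 blur_sd = blur_sd, z_margin = as.integer(z_margin),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a synthetic baseline phantom
#'
#' Builds the noise-free geometry (cortical shell + trabecular rod lattice +
#' marrow), applies surface blur then additive noise, and derives compartment
#' masks from the noise-free geometry. Deterministic for a fixed seed.
#'
#' @param params A [phantom_params()].
#' @return An object of class `phantom`: a list with `image` (the observed,
#'   blurred + noisy [density_image()]), `geometry` (the noise-free image),
#'   `masks` (a [bone_masks()]) and `params`.
#' @export
make_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  g <- phantom_geometry(params)
  m <- params$z_margin
  nz <- params$grid[3]
  fov <- m + seq_len(nz)
  obs_ext <- g$clean_ext
  if (params$blur_sd > 0) obs_ext <- gaussian_blur(obs_ext, params$blur_sd)
  obs <- obs_ext[, , fov, drop = FALSE]
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    obs <- obs + array(rnorm(length(obs), sd = params$noise_sd), dim(obs))
  }
  h <- params$voxel_size
  origin <- -(params$grid - 1) / 2 * h
  structure(list(
    image = density_image(array(obs, params$grid), voxel_size = h,
                          origin = origin),
    geometry = density_image(array(g$clean_ext[, , fov, drop = FALSE],
                                   params$grid),
                             voxel_size = h, origin = origin),
    geometry_ext = g$clean_ext,
    masks = g$masks,
    params = params), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s voxels, noise_sd %.0f, blur_sd %.2f, seed %d\n",
              paste(x$params$grid, collapse = "x"), x$params$noise_sd,
              x$params$blur_sd, x$params$seed))
  invisible(x)
}

# noise-free density grid (on the z-extended generation grid) and exact
# compartment masks (on the field of view)
phantom_geometry <- function(p) {
  nx <- p$grid[1]; ny <- p$grid[2]; nz <- p$grid[3]
  nze <- nz + 2L * p$z_margin
  h <- p$voxel_size
  x <- (seq_len(nx) - (nx + 1) / 2) * h
  y <- (seq_len(ny) - (ny + 1) / 2) * h
  z <- (seq_len(nze) - p$z_margin - (nz + 1) / 2) * h
  r2 <- outer(x^2, y^2, "+")
  near_plane <- function(v) abs(v - p$strut_spacing * round(v / p$strut_spacing)) <=
    p$strut_thickness / 2
  px <- near_plane(x); py <- near_plane(y); pz <- near_plane(z)
  rod_z <- outer(px, py, "&")                        # 2D, constant in z
  rod_x <- function(int2d) outer(rep(TRUE, nx), py, "&") & int2d
  rod_y <- function(int2d) outer(px, rep(TRUE, ny), "&") & int2d
  # metaphyseal flare: radii scale linearly from 1 + taper/2 (distal, first
  # slice) to 1 - taper/2 (proximal) over the extended grid
  scale_k <- 1 + p$taper * (0.5 - (seq_len(nze) - 1) / (nze - 1))
  clean <- array(0, c(nx, ny, nze))
  whole_m <- array(FALSE, c(nx, ny, nz))
  cort_m <- array(FALSE, c(nx, ny, nz))
  trab_m <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nze)) {
    ro <- scale_k[k] * p$outer_radius
    ri <- scale_k[k] * p$inner_radius
    whole2d <- r2 <= ro^2
    interior2d <- r2 <= ri^2
    annulus2d <- whole2d & !interior2d
    slab <- array(0, c(nx, ny))
    slab[whole2d] <- p$marrow_density
    strut <- rod_z & interior2d
    if (pz[k]) strut <- strut | rod_x(interior2d) | rod_y(interior2d)
    slab[strut] <- p$strut_density
    slab[annulus2d] <- p$cortical_density
    clean[, , k] <- slab
    kf <- k - p$z_margin
    if (kf >= 1L && kf <= nz) {
      whole_m[, , kf] <- whole2d
      cort_m[, , kf] <- annulus2d
      trab_m[, , kf] <- interior2d
    }
  }
  masks <- bone_masks(whole = whole_m, cortical = cort_m, trabecular = trab_m)
  list(clean_ext = clean, masks = masks)
}

#' Closed-form volume fraction of the three-axis rod lattice
#'
#' For rods of square cross-section `t` on a cubic lattice of pitch `a`, by
#' inclusion-exclusion: `3 (t/a)^2 - 2 (t/a)^3`.
#'
#' @param strut_thickness,strut_spacing Rod width and pitch (same units).
#' @return Volume fraction in `[0, 1]`.
#' @export
lattice_volume_fraction <- function(strut_thickness, strut_spacing) {
  q <- strut_thickness / strut_spacing
  3 * q^2 - 2 * q^3
}

#' Mechanoregulation rule of the phantom generator
#'
#' The ground-truth surface-remodeling rule the analysis is designed to
#' recover: surface voxels below the resorption threshold (in normalized
#' strain) tend to be resorbed, surface-adjacent background voxels above the
#' formation threshold tend to gain bone, and the interval between the two
#' thresholds is the quiescent "lazy zone". `event_rate` is the fraction of
#' candidate sites active per interval; an active site follows the rule with
#' probability `obedience` and violates it (acts although the rule says not
#' to) with probability `1 - obedience`.
#'
#' @param resorption_threshold,formation_threshold Normalized strain
#'   thresholds, `0 <= Tr < Tf <= 1`.
#' @param obedience Probability an active site obeys the rule.
#' @param event_rate Fraction of candidate sites active per interval.
#' @return An object of class `mechanoreg_rule`.
#' @export
mechanoreg_rule <- function(resorption_threshold = 0.08,
                            formation_threshold = 0.23,
                            obedience = 0.9, event_rate = 0.8) {
  if (!(resorption_threshold >= 0 && resorption_threshold < formation_threshold &&
        formation_threshold <= 1))
    stop("need 0 <= resorption_threshold < formation_threshold <= 1",
         call. = FALSE)
  if (obedience < 0 || obedience > 1 || event_rate < 0 || event_rate > 1)
    stop("obedience and event_rate must lie in [0, 1]", call. = FALSE)
  structure(list(resorption_threshold = resorption_threshold,
                 formation_threshold = formation_threshold,
                 obedience = obedience, event_rate = event_rate),
            class = "mechanoreg_rule")
}

#' Surrogate per-voxel normalized strain field
#'
#' `depth_ramp` assigns a strain that is highest at the distal end (first
#' slice) and decreases linearly along the longitudinal axis, emulating the
#' distal concentration of effective strain in compressed radius models.
#' `fe` runs the voxel micro-FE solver on a supplied image and normalizes the
#' per-voxel effective strain by its 99th percentile over the mesh elements
#' (the same constant definition the analysis pipeline uses), then
#' propagates values one band outward so surface-adjacent background voxels
#' carry a strain. `depth_ramp` is normalized so its 99th percentile over
#' the whole-bone mask is 1.
#'
#' @param masks A [bone_masks()].
#' @param mode `"depth_ramp"` or `"fe"`.
#' @param image A [density_image()]; required for `mode = "fe"`.
#' @param law A [material_law()] for `mode = "fe"`.
#' @param applied_strain Compression level for `mode = "fe"`.
#' @return 3D numeric array of normalized strain (dimensionless).
#' @export
surrogate_strain <- function(masks, mode = c("depth_ramp", "fe"),
                             image = NULL, law = material_law(),
                             applied_strain = 0.01) {
  stopifnot(inherits(masks, "bone_masks"))
  mode <- match.arg(mode)
  d <- dim(masks$whole)
  if (mode == "depth_ramp") {
    ramp <- (d[3] - seq_len(d[3])) / (d[3] - 1)
    strain <- array(rep(ramp, each = d[1] * d[2]), d)
    p99 <- quantile(strain[masks$whole], 0.99, names = FALSE)
  } else {
    if (is.null(image)) stop("`image` is required for mode = \"fe\"",
                             call. = FALSE)
    mesh <- build_mesh(image, masks, law)
    fe <- solve_compression(mesh, applied_strain = applied_strain)
    strain <- fe_strain_grid(fe)
    p99 <- quantile(fe$eps_eff_ue, 0.99, names = FALSE)
    strain <- fill_nearest(strain, iters = 6L)
    strain[is.na(strain)] <- 0
  }
  if (p99 <= 0) stop("degenerate strain field", call. = FALSE)
  strain / p99
}

# propagate defined values into NA voxels by iterated 6-neighbour averaging
fill_nearest <- function(arr, iters = 4L) {
  for (i in seq_len(iters)) {
    nas <- is.na(arr)
    if (!any(nas)) break
    acc <- array(0, dim(arr)); cnt <- array(0, dim(arr))
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- shift1(arr, ax, s, fill = NA_real_)
      ok <- !is.na(nb)
      acc[ok] <- acc[ok] + nb[ok]
      cnt <- cnt + ok
    }
    upd <- nas & cnt > 0
    arr[upd] <- acc[upd] / cnt[upd]
  }
  arr
}

#' Simulate a follow-up image with known remodeling ground truth
#'
#' Applies one interval of mechanoregulated surface remodeling to the
#' phantom's noise-free geometry: surface bone voxels whose normalized strain
#' is below the rule's resorption threshold are resorbed (set to marrow
#' density) and surface-adjacent background voxels above the formation
#' threshold gain bone (set to the density of the adjacent bone voxel), each
#' with probability `event_rate * obedience`; sites where the rule forbids
#' the action act anyway with probability `event_rate * (1 - obedience)`.
#' Remodeling is one voxel deep. Ground-truth labels are recorded before the
#' follow-up image is blurred, resampled through the misalignment transform
#' (cubic interpolation) and corrupted with fresh noise.
#'
#' @param phantom A [make_phantom()] result.
#' @param strain 3D array of normalized strain on the baseline grid, e.g.
#'   from [surrogate_strain()].
#' @param rule A [mechanoreg_rule()].
#' @param misalignment A [rigid_transform()] applied to the follow-up image
#'   (the repositioning error the pipeline must undo); identity by default.
#' @param seed Integer seed for the event and noise draws.
#' @param bone_threshold Density defining the bone set of the clean geometry.
#' @return A list with `image` (the observed follow-up [density_image()]) and
#'   `truth` (class `phantom_truth`: `applied_transform`, `true_labels`,
#'   `rule`, `strain`, and the exact per-category voxel `counts`).
#' @export
simulate_followup <- function(phantom, strain, rule,
                              misalignment = NULL, seed = 1L,
                              bone_threshold = 320) {
  stopifnot(inherits(phantom, "phantom"), inherits(rule, "mechanoreg_rule"))
  clean <- phantom$geometry$values
  stopifnot_congruent(clean, strain, "strain field and baseline")
  p <- phantom$params
  if (is.null(misalignment))
    misalignment <- rigid_transform(center = grid_center(phantom$geometry))
  bone <- clean >= bone_threshold
  surf <- surface_voxels(bone)
  bg_cand <- !bone & adjacent_to(bone)
  set.seed(seed)
  act <- function(idx, complies) {
    pr <- ifelse(complies, rule$event_rate * rule$obedience,
                 rule$event_rate * (1 - rule$obedience))
    idx[runif(length(idx)) < pr]
  }
  is_surf <- which(surf)
  resorbed_idx <- act(is_surf, strain[is_surf] < rule$resorption_threshold)
  is_bg <- which(bg_cand)
  formed_idx <- act(is_bg, strain[is_bg] > rule$formation_threshold)
  fu_clean <- clean
  fu_clean[resorbed_idx] <- p$marrow_density
  if (length(formed_idx)) {
    nbmax <- array(-Inf, dim(clean))
    for (ax in 1:3) for (s in c(-1L, 1L))
      nbmax <- pmax(nbmax, shift1(clean * bone, ax, s, fill = 0))
    fu_clean[formed_idx] <- pmax(nbmax[formed_idx], p$strut_density)
  }
  labels <- array(0L, dim(clean))
  labels[bone] <- 3L
  labels[resorbed_idx] <- 2L
  labels[formed_idx] <- 1L
  # misalign in the extended generation frame, then crop to the field of
  # view: the repositioned "scan" windows real anatomy at the stack ends
  m <- p$z_margin
  fov <- m + seq_len(p$grid[3])
  fu_ext <- phantom$geometry_ext
  fu_ext[, , fov] <- fu_clean
  if (p$blur_sd > 0) fu_ext <- gaussian_blur(fu_ext, p$blur_sd)
  ext_img <- density_image(fu_ext, voxel_size = p$voxel_size,
                           origin = phantom$geometry$origin -
                             c(0, 0, m * p$voxel_size))
  ext_img <- resample(ext_img, misalignment, "cubic", fill = 0)
  obs <- ext_img$values[, , fov, drop = FALSE]
  if (p$noise_sd > 0)
    obs <- obs + array(rnorm(length(obs), sd = p$noise_sd), dim(obs))
  img <- density_image(array(obs, dim(clean)), voxel_size = p$voxel_size,
                       origin = phantom$geometry$origin)
  truth <- structure(list(
    applied_transform = misalignment,
    true_labels = new_remodeling_labels(labels, threshold = bone_threshold,
                                        region = array(TRUE, dim(labels))),
    rule = rule,
    strain = strain,
    counts = c(formed = length(formed_idx), resorbed = length(resorbed_idx),
               quiescent = sum(labels == 3L))), class = "phantom_truth")
  list(image = img, truth = truth)
}
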