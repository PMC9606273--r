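#' Rigid registration of the follow-up image onto the baseline
#'
#' Multi-resolution rigid alignment minimizing the mean squared intensity
#' error between the fixed (earlier) image and the resampled moving (later)
#' image, evaluated over the overlap of both domains. The pyramid downsamples
#' by a factor of 2 per level; each level refines the six rigid parameters
#' (Nelder-Mead on scaled parameters, linear interpolation) and hands its
#' optimum to the next finer level. The initial translation is estimated from
#' the bone centres of mass unless `init` is supplied.
#'
#' @param fixed,moving [density_image()]s with equal voxel size.
#' @param levels Number of pyramid levels (>= 1).
#' @param init Optional initial [rigid_transform()].
#' @param max_iter Nelder-Mead iteration cap per level.
#' @param bone_threshold Density used for the centre-of-mass initialization.
#' @return An object of class `registration_result`: `transform` (maps
#'   physical points of the fixed frame to the moving frame, i.e. the
#'   transform to pass to [resample()] on the moving image), `final_mse`,
#'   `initial_mse`, `pyramid_levels`, `converged`.
#' @export
register_rigid <- function(fixed, moving, levels = 3L, init = NULL,
                           max_iter = 300L, bone_threshold = 200) {
  stopifnot(is_density_image(fixed), is_density_image(moving))
  if (abs(fixed$voxel_size - moving$voxel_size) > 1e-9 * fixed$voxel_size)
    stop("images must have equal voxel size", call. = FALSE)
  if (sd(fixed$values) == 0 || sd(moving$values) == 0)
    stop("no gradient information: constant image", call. = FALSE)
  center <- grid_center(fixed)
  if (is.null(init)) {
    t0 <- com_of(moving, bone_threshold) - com_of(fixed, bone_threshold)
    if (any(!is.finite(t0))) t0 <- c(0, 0, 0)
    init <- rigid_transform(translation = t0, center = center)
  }
  # recentre the initial transform on the fixed grid centre
  init <- matrix_to_tf(tf_to_matrix(init), center = center)

  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(levels - 1L)) {
    pyr_f[[l + 1L]] <- downsample2(pyr_f[[l]])
    pyr_m[[l + 1L]] <- downsample2(pyr_m[[l]])
  }
  h <- fixed$voxel_size
  ang_scale <- h / (0.25 * min(dim(fixed$values)[1:2]) * h)  # ~1 voxel at rim
  par <- c(init$rotation / ang_scale, init$translation / h)
  cost <- function(par, fimg, mimg, stride = 1L) {
    tf <- rigid_transform(rotation = par[1:3] * ang_scale,
                          translation = par[4:6] * h, center = center)
    mse_overlap(fimg, mimg, tf, stride = stride)
  }

  # Exhaustive 1D scan of the longitudinal translation, repeated at every
  # level before the local search: the centre of mass carries no information
  # about shifts along a shaft that fills the whole stack, and quasi-periodic
  # trabecular structure creates aliased local minima a local search cannot
  # escape. A fixed-frame z-shift of the content corresponds to a translation
  # step along R e_z (the transform rotates before translating). When heavy
  # remodeling and noise make neighbouring periods nearly indistinguishable
  # (within 5% of the best cost), the candidate closest to the initial
  # estimate wins: repeat scans are positioned from a scout view, so large
  # axial offsets are a priori unlikely.
  init_z <- init$translation[3] / h
  z_scan <- function(par, l, stride, offsets) {
    dirz <- rotation_matrix(par[1:3] * ang_scale) %*% c(0, 0, 1)
    z_cost <- vapply(offsets, function(dz) {
      p <- par; p[4:6] <- p[4:6] + dz * dirz
      cost(p, pyr_f[[l]], pyr_m[[l]], stride)
    }, numeric(1))
    near <- which(z_cost <= min(z_cost) * 1.05)
    pick <- near[which.min(abs(par[6] + offsets[near] * dirz[3] - init_z))]
    par[4:6] <- par[4:6] + offsets[pick] * dirz
    par
  }

  for (l in rev(seq_len(levels))) {
    stride_l <- if (l == 1L) 2L else 1L
    par <- z_scan(par, l, stride_l, seq(-24, 24, by = 1))
    # restarted Nelder-Mead: the second pass rebuilds the simplex around the
    # first optimum, polishing the sub-voxel tail
    for (pass in 1:2) {
      opt <- optim(par, cost, fimg = pyr_f[[l]], mimg = pyr_m[[l]],
                   stride = stride_l, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-12))
      par <- opt$par
    }
  }
  # sub-voxel re-scan at the finest level (integer steps sample aliased
  # basins off-centre, which can hide the true one), then a short refinement
  par <- z_scan(par, 1L, 2L, seq(-24, 24, by = 0.25))
  opt <- optim(par, cost, fimg = pyr_f[[1L]], mimg = pyr_m[[1L]], stride = 2L,
               method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-12))
  par <- opt$par
  transform <- rigid_transform(rotation = par[1:3] * ang_scale,
                               translation = par[4:6] * h, center = center)
  final_mse <- mse_overlap(fixed, moving, transform)
  initial_mse <- mse_overlap(fixed, moving, init)
  converged <- is.finite(final_mse) && final_mse <= initial_mse
  if (!is.finite(final_mse) || final_mse > initial_mse) {
    transform <- init
    final_mse <- initial_mse
  }
  structure(list(transform = transform, final_mse = final_mse,
                 initial_mse = initial_mse, pyramid_levels = levels,
                 converged = converged),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> MSE %.2f -> %.2f over %d levels (%s)\n",
              x$initial_mse, x$final_mse, x$pyramid_levels,
              if (x$converged) "converged" else "not converged"))
  print(x$transform)
  invisible(x)
}

# intensity centre of mass (mm) of the thresholded image
com_of <- function(image, threshold) {
  m <- image$values >= threshold
  if (!any(m)) return(c(NA_real_, NA_real_, NA_real_))
  d <- dim(m)
  idx <- which(m) - 1L
  ix <- idx %% d[1]
  iy <- (idx %/% d[1]) %% d[2]
  iz <- idx %/% (d[1] * d[2])
  image$origin + c(mean(ix), mean(iy), mean(iz)) * image$voxel_size
}

# MSE of fixed vs linearly resampled moving over the domain overlap (fused
# kernel, optional strided subsampling); large penalty when the overlap
# collapses below 20% of the grid
mse_overlap <- function(fixed, moving, transform, stride = 1L) {
  R <- rotation_matrix(transform$rotation)
  shift <- transform$center + transform$translation -
    as.numeric(R %*% transform$center)
  res <- cpp_mse_rigid(as.numeric(fixed$values), as.numeric(moving$values),
                       dim(fixed$values), fixed$voxel_size, fixed$origin,
                       R, shift, as.integer(stride))
  if (res[2] < 0.2) return(mean(fixed$values^2) + 1e6 * (0.2 - res[2]))
  res[1]
}

# 2x2x2 box-average downsampling (odd trailing voxels dropped)
downsample2 <- function(image) {
  v <- image$values
  d <- dim(v)
  d2 <- pmax(d %/% 2L, 1L)
  v <- v[seq_len(d2[1] * 2L), seq_len(d2[2] * 2L), seq_len(d2[3] * 2L),
         drop = FALSE]
  o <- seq(1L, by = 2L, length.out = d2[1])
  e <- o + 1L
  v <- (v[o, , , drop = FALSE] + v[e, , , drop = FALSE]) / 2
  o <- seq(1L, by = 2L, length.out = d2[2]); e <- o + 1L
  v <- (v[, o, , drop = FALSE] + v[, e, , drop = FALSE]) / 2
  o <- seq(1L, by = 2L, length.out = d2[3]); e <- o + 1L
  v <- (v[, , o, drop = FALSE] + v[, , e, drop = FALSE]) / 2
  density_image(v, voxel_size = image$voxel_size * 2,
                origin = image$origin + image$voxel_size / 2)
}

#' Align the bone's longitudinal axis with the grid z-axis
#'
#' Finds the principal axis of the thresholded bone voxel cloud (dominant
#' eigenvector of the coordinate covariance) and rotates it onto +z about the
#' centre of mass, resampling with cubic interpolation.
#'
#' @param image A [density_image()].
#' @param threshold Bone threshold for the voxel cloud.
#' @return A list with `image` (aligned [density_image()]) and `transform`
#'   (the [rigid_transform()] mapping original to aligned coordinates).
#' @export
align_to_axis <- function(image, threshold = 320) {
  stopifnot(is_density_image(image))
  m <- image$values >= threshold
  if (!any(m)) stop("empty segmentation at the given threshold", call. = FALSE)
  d <- dim(m)
  idx <- which(m) - 1L
  pts <- cbind(idx %% d[1], (idx %/% d[1]) %% d[2], idx %/% (d[1] * d[2]))
  pts <- sweep(pts * image$voxel_size, 2, image$origin, "+")
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  if (ev$values[1] < 1.5 * ev$values[2])
    stop("no dominant longitudinal axis (nearly isotropic inertia)",
         call. = FALSE)
  v <- ev$vectors[, 1]
  if (v[3] < 0) v <- -v
  z <- c(0, 0, 1)
  # Rodrigues rotation taking v onto z
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2)); cth <- sum(v * z)
  if (s < 1e-12) {
    R <- diag(3)
  } else {
    k <- axis / s
    K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    R <- diag(3) + sin(atan2(s, cth)) * K + (1 - cth) * (K %*% K)
  }
  fwd <- rigid_transform(rotation = euler_from_matrix(R), center = ctr)
  aligned <- resample(image, tf_invert(fwd), "cubic", fill = 0)
  list(image = aligned, transform = fwd)
}

#' Segment whole-bone, cortical and trabecular compartment masks
#'
#' Replacement for contour-based mask generation: the whole-bone envelope is
#' the hole-filled (per slice) largest connected component of a smoothed
#' threshold segmentation; the cortical compartment is the morphologically
#' opened high-density shell connected to the periosteal surface; the
#' trabecular compartment is the remainder of the whole mask minus a
#' transition band around the cortex.
#'
#' @param image A [density_image()].
#' @param bone_threshold Density for the whole-bone segmentation.
#' @param cortical_threshold Cortical density criterion (mg HA/cm^3).
#' @param cortical_open_radius Opening radius (voxels) that removes
#'   trabecular struts from the cortical candidate set.
#' @param transition Width (voxels) of the excluded band between cortex and
#'   trabecular compartment.
#' @param apply_filter Denoise with the constrained Gaussian filter first.
#' @return A [bone_masks()].
#' @export
generate_masks <- function(image, bone_threshold = 320,
                           cortical_threshold = 450,
                           cortical_open_radius = 2L, transition = 2L,
                           apply_filter = TRUE) {
  stopifnot(is_density_image(image))
  den <- if (apply_filter) denoise(image) else image
  d <- dim(den$values)
  bone <- den$values >= bone_threshold
  if (!any(bone)) stop("empty segmentation: no voxels above the bone threshold",
                       call. = FALSE)
  closed <- morph6(morph6(bone, 1L, dilate = TRUE, border = FALSE),
                   1L, dilate = FALSE, border = TRUE)
  lab <- array(cpp_label6(closed, d), d)
  counts <- tabulate(lab)
  whole <- lab == which.max(counts)
  whole <- fill_holes_slicewise(whole)

  # opening with component selection in the eroded image: erosion removes
  # trabecular struts, whose junction remnants must not be re-bridged to the
  # shell during dilation, so only the dominant (cortical ring) component of
  # the eroded image is dilated back and clipped to the candidate set
  cort0 <- den$values >= cortical_threshold & whole
  core <- morph6(cort0, cortical_open_radius, dilate = FALSE, border = TRUE)
  cortical <- array(FALSE, d)
  if (any(core)) {
    lab_c <- array(cpp_label6(core, d), d)
    ring <- lab_c == which.max(tabulate(lab_c))
    cortical <- morph6(ring, cortical_open_radius, dilate = TRUE,
                       border = FALSE) & cort0
  }
  trabecular <- whole & !morph6(cortical, transition, dilate = TRUE,
                                border = FALSE) & !cortical
  bone_masks(whole = whole, cortical = cortical, trabecular = trabecular)
}

morph6 <- function(mask, iters, dilate, border) {
  if (iters < 1L) return(mask)
  array(cpp_morph6(mask, dim(mask), as.integer(iters), dilate, border),
        dim(mask))
}

# fill 2D holes slice by slice (the marrow cavity is open along z)
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k, drop = FALSE]
    bgl <- array(cpp_label6(!sl, dim(sl)), dim(sl))
    border_labels <- unique(c(bgl[1, , 1], bgl[d[1], , 1],
                              bgl[, 1, 1], bgl[, d[2], 1]))
    border_labels <- border_labels[border_labels > 0]
    hole <- bgl > 0 & !(bgl %in% border_labels)
    mask[, , k] <- sl | array(hole, dim(sl))
  }
  mask
}

#' Common analysis region of a registered image pair
#'
#' Intersection of the fixed whole-bone mask with the transformed moving
#' whole-bone mask and with the moving image's in-domain footprint. All
#' remodeling and mechanics analyses are restricted to this region.
#'
#' @param fixed_masks,moving_masks [bone_masks()] of the two images.
#' @param transform The registration [rigid_transform()] (fixed -> moving).
#' @param like A [density_image()] supplying grid geometry (voxel size,
#'   origin) for the transform; typically the fixed image.
#' @return Logical array; errors if the intersection is empty.
#' @export
common_region <- function(fixed_masks, moving_masks, transform, like) {
  stopifnot(inherits(fixed_masks, "bone_masks"),
            inherits(moving_masks, "bone_masks"))
  mw <- resample_mask(moving_masks$whole, like, transform)
  region <- fixed_masks$whole & mw & indomain_mask(like, transform)
  if (!any(region)) stop("empty overlap between the two masks", call. = FALSE)
  region
}
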