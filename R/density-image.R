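#' Calibrated 3D bone mineral density image
#'
#' The common currency of the pipeline: a 3D grid of volumetric bone mineral
#' density in mg HA/cm^3 on isotropic voxels. Array indices are `[x, y, z]`
#' with the third (z) index the longitudinal/loading axis; the physical
#' position of voxel `(i, j, k)` (0-based) is `origin + c(i, j, k) *
#' voxel_size` (voxel-centre convention).
#'
#' @param values 3D numeric array of densities (mg HA/cm^3); all finite.
#' @param voxel_size Isotropic voxel edge length in mm (default 0.0607, the
#'   second-generation HR-pQCT protocol).
#' @param origin Physical position (mm) of voxel `(0, 0, 0)`.
#' @return An object of class `density_image`.
#' @export
density_image <- function(values, voxel_size = 0.0607, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("density values must all be finite", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be three finite numbers", call. = FALSE)
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "density_image"
  )
}

#' @export
dim.density_image <- function(x) dim(x$values)

#' @export
print.density_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_image> %d x %d x %d voxels, %.4f mm isotropic\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  density range: %.1f .. %.1f mg HA/cm^3\n",
              min(x$values), max(x$values)))
  invisible(x)
}

is_density_image <- function(x) inherits(x, "density_image")

#' Compartment masks of a bone image
#'
#' Binary masks congruent with a [density_image()]: the whole-bone envelope
#' and the disjoint cortical and trabecular compartments (both subsets of the
#' whole mask; the trabecular compartment is a region, including marrow, not
#' the mineralized bone voxels themselves).
#'
#' @param whole,cortical,trabecular 3D logical arrays of equal dimension.
#' @return An object of class `bone_masks`.
#' @export
bone_masks <- function(whole, cortical, trabecular) {
  as_mask <- function(m, name) {
    if (!is.array(m) || length(dim(m)) != 3L)
      stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
    storage.mode(m) <- "logical"
    if (anyNA(m)) stop(sprintf("`%s` contains NA", name), call. = FALSE)
    m
  }
  whole <- as_mask(whole, "whole")
  cortical <- as_mask(cortical, "cortical")
  trabecular <- as_mask(trabecular, "trabecular")
  if (!identical(dim(whole), dim(cortical)) ||
      !identical(dim(whole), dim(trabecular)))
    stop("mask dimensions differ", call. = FALSE)
  if (any(cortical & trabecular))
    stop("cortical and trabecular compartments must be disjoint", call. = FALSE)
  if (any((cortical | trabecular) & !whole))
    stop("compartments must lie inside the whole-bone mask", call. = FALSE)
  structure(list(whole = whole, cortical = cortical, trabecular = trabecular),
            class = "bone_masks")
}

#' @export
print.bone_masks <- function(x, ...) {
  d <- dim(x$whole)
  cat(sprintf("<bone_masks> %d x %d x %d: whole %d, cortical %d, trabecular %d voxels\n",
              d[1], d[2], d[3], sum(x$whole), sum(x$cortical), sum(x$trabecular)))
  invisible(x)
}

stopifnot_congruent <- function(a, b, what = "grids") {
  da <- if (is_density_image(a)) dim(a$values) else dim(a)
  db <- if (is_density_image(b)) dim(b$values) else dim(b)
  if (!identical(da, db))
    stop(sprintf("%s are not congruent: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")),
         call. = FALSE)
  if (is_density_image(a) && is_density_image(b) &&
      abs(a$voxel_size - b$voxel_size) > 1e-9 * a$voxel_size)
    stop("voxel sizes differ", call. = FALSE)
  invisible(TRUE)
}

# physical coordinate of voxel centres along one axis (0-based convention)
axis_coords <- function(image, axis) {
  n <- dim(image$values)[axis]
  image$origin[axis] + (seq_len(n) - 1) * image$voxel_size
}

# physical centre of the grid
grid_center <- function(image) {
  image$origin + (dim(image$values) - 1) / 2 * image$voxel_size
}

# shift an array by one voxel along an axis, padding with `fill`
shift1 <- function(a, axis, step, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (abs(step) >= n) return(out)
  if (step > 0) {          # content moves toward higher index
    idx_dst[[axis]] <- (step + 1):n
    idx_src[[axis]] <- 1:(n - step)
  } else if (step < 0) {
    idx_dst[[axis]] <- 1:(n + step)
    idx_src[[axis]] <- (1 - step):n
  } else return(a)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# TRUE where a bone voxel has >= 1 face neighbour outside the bone set.
# Voxels beyond the grid count as bone: the shaft continues past the scan
# stack, so the cut faces at the stack ends are not biological surfaces.
surface_voxels <- function(bone) {
  interior <- bone
  for (ax in 1:3) for (s in c(-1L, 1L))
    interior <- interior & shift1(bone, ax, s, fill = TRUE)
  bone & !interior
}

# TRUE where a voxel has >= 1 face neighbour inside `set`
adjacent_to <- function(set) {
  adj <- array(FALSE, dim(set))
  for (ax in 1:3) for (s in c(-1L, 1L))
    adj <- adj | shift1(set, ax, s, fill = FALSE)
  adj
}
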