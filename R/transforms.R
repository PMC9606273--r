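#' Rigid 3D transform
#'
#' A rotation about a centre followed by a translation, in physical (mm)
#' coordinates: `y = R (x - center) + center + translation`. The rotation is
#' parameterised by three fixed-axis Euler angles applied about z, then y,
#' then x (`R = Rx(ax) Ry(ay) Rz(az)`).
#'
#' @param rotation Angles `c(ax, ay, az)` in radians.
#' @param translation Translation `c(tx, ty, tz)` in mm.
#' @param center Rotation centre in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  if (!all(is.finite(c(rotation, translation, center))))
    stop("transform parameters must be finite", call. = FALSE)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s; trans (mm): %s; center: %s\n",
              paste(sprintf("%.3f", x$rotation * 180 / pi), collapse = ", "),
              paste(sprintf("%.4f", x$translation), collapse = ", "),
              paste(sprintf("%.3f", x$center), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#' @param rotation Euler angles `c(ax, ay, az)` (radians), see
#'   [rigid_transform()].
#' @return 3x3 rotation matrix `Rx(ax) %*% Ry(ay) %*% Rz(az)`.
#' @export
rotation_matrix <- function(rotation) {
  ax <- rotation[1]; ay <- rotation[2]; az <- rotation[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

# Euler angles (ax, ay, az) with R = Rx Ry Rz; valid away from |ay| = pi/2
euler_from_matrix <- function(R) {
  ay <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(ay)) < 1e-9) {
    # gimbal-degenerate: fold everything into ax
    ax <- atan2(R[2, 1], R[2, 2])
    az <- 0
  } else {
    az <- atan2(-R[1, 2], R[1, 1])
    ax <- atan2(-R[2, 3], R[3, 3])
  }
  c(ax, ay, az)
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param points n x 3 matrix (or length-3 vector) of physical coordinates.
#' @return Transformed points, same shape.
#' @export
transform_points <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, nrow = 1) else as.matrix(points)
  R <- rotation_matrix(transform$rotation)
  out <- sweep(p, 2, transform$center) %*% t(R)
  out <- sweep(out, 2, transform$center + transform$translation, "+")
  if (vec) drop(out) else out
}

# 4x4 homogeneous matrix: y = R x + (center + translation - R center)
tf_to_matrix <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  o <- transform$center + transform$translation - R %*% transform$center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- o
  M
}

matrix_to_tf <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  o <- M[1:3, 4]
  rigid_transform(rotation = euler_from_matrix(R),
                  translation = as.numeric(o - center + R %*% center),
                  center = center)
}

#' Compose two rigid transforms
#'
#' `tf_compose(a, b)` is the transform applying `b` first, then `a`:
#' `(a o b)(x) = a(b(x))`.
#'
#' @param a,b [rigid_transform()] objects.
#' @param center Rotation centre of the composed transform (default: `a`'s).
#' @return A [rigid_transform()].
#' @export
tf_compose <- function(a, b, center = a$center) {
  matrix_to_tf(tf_to_matrix(a) %*% tf_to_matrix(b), center = center)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse transform, about the same centre.
#' @export
tf_invert <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  rigid_transform(rotation = euler_from_matrix(t(R)),
                  translation = as.numeric(-t(R) %*% transform$translation),
                  center = transform$center)
}

#' Resample an image through a rigid transform
#'
#' Pull-back resampling onto the same grid: the output voxel at physical
#' position `x` takes the interpolated input value at `transform(x)`.
#' Positions mapping outside the input domain receive `fill`.
#'
#' @param image A [density_image()].
#' @param transform A [rigid_transform()].
#' @param interpolation `"cubic"` (Catmull-Rom, the default for density
#'   images), `"linear"`, or `"nearest"` (use for masks).
#' @param fill Value for out-of-domain samples (default 0 mg HA/cm^3, i.e.
#'   air/marrow; may be `NA`).
#' @return A [density_image()] on the input grid.
#' @export
resample <- function(image, transform,
                     interpolation = c("cubic", "linear", "nearest"),
                     fill = 0) {
  stopifnot(is_density_image(image), inherits(transform, "rigid_transform"))
  interpolation <- match.arg(interpolation)
  icode <- c(nearest = 0L, linear = 1L, cubic = 3L)[[interpolation]]
  R <- rotation_matrix(transform$rotation)
  shift <- transform$center + transform$translation -
    as.numeric(R %*% transform$center)
  out <- cpp_resample(as.numeric(image$values), dim(image$values),
                      image$voxel_size, image$origin, R, shift, icode,
                      as.numeric(fill))
  density_out <- image
  density_out$values <- array(out, dim(image$values))
  density_out
}

# nearest-neighbour resampling of a logical mask
resample_mask <- function(mask, like, transform) {
  img <- density_image(array(as.numeric(mask), dim(mask)),
                       voxel_size = like$voxel_size, origin = like$origin)
  resample(img, transform, "nearest", fill = 0)$values > 0.5
}

# mask of output voxels whose pulled-back sample lies inside the input domain
indomain_mask <- function(like, transform) {
  ones <- density_image(array(1, dim(like$values)),
                        voxel_size = like$voxel_size, origin = like$origin)
  resample(ones, transform, "nearest", fill = 0)$values > 0.5
}
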