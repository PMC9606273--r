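#' Density-modulus material law
#'
#' Linear elastic tissue properties scaled from the (filtered) density image:
#' `E(rho) = E_max * (clamp(rho, 0, rho_ref) / rho_ref)^exponent`, with a
#' Poisson's ratio common to all elements and an inclusion cutoff `rho_min`
#' below which voxels are not meshed.
#'
#' @param E_max Tissue modulus at the reference density (MPa).
#' @param rho_ref Reference density (mg HA/cm^3).
#' @param exponent Density-modulus power (1 = linear scaling).
#' @param rho_min Inclusion cutoff (mg HA/cm^3).
#' @param nu Poisson's ratio.
#' @return An object of class `material_law`.
#' @export
material_law <- function(E_max = 10000, rho_ref = 1200, exponent = 1,
                         rho_min = 130, nu = 0.3) {
  stopifnot(E_max > 0, rho_ref > 0, exponent >= 0, rho_min >= 0,
            nu >= 0, nu < 0.5)
  structure(list(E_max = E_max, rho_ref = rho_ref, exponent = exponent,
                 rho_min = rho_min, nu = nu), class = "material_law")
}

#' Element modulus from density
#' @param law A [material_law()].
#' @param rho Densities (mg HA/cm^3).
#' @return Young's moduli (MPa), non-negative and non-decreasing in `rho`.
#' @export
modulus_from_density <- function(law, rho) {
  law$E_max * (pmin(pmax(rho, 0), law$rho_ref) / law$rho_ref)^law$exponent
}

#' Convert a density image into a voxel hexahedral FE mesh
#'
#' Every voxel with density at or above the law's `rho_min` (inside the whole
#' mask, when masks are given) becomes an 8-node hexahedral element with a
#' density-derived modulus. Only the largest face-connected component that
#' spans the bottom and top slices of the candidate set is kept, so the model
#' can carry an axial load; floating fragments are discarded.
#'
#' @param image A (typically denoised) [density_image()].
#' @param masks Optional [bone_masks()] restricting candidate voxels.
#' @param law A [material_law()].
#' @return An object of class `fe_mesh`: element voxel indices, per-element
#'   moduli, node numbering and boundary node sets.
#' @export
build_mesh <- function(image, masks = NULL, law = material_law()) {
  stopifnot(is_density_image(image), inherits(law, "material_law"))
  d <- dim(image$values)
  cand <- image$values >= law$rho_min
  if (!is.null(masks)) {
    stopifnot_congruent(image$values, masks$whole)
    cand <- cand & masks$whole
  }
  if (!any(cand)) stop("model cannot carry load: no elements", call. = FALSE)
  lab <- array(cpp_label6(cand, d), d)
  counts <- tabulate(lab)
  # the load path is the largest face-connected component; its own bottom and
  # top element layers become the platen faces, and floating fragments are
  # discarded. A component confined to a single layer cannot carry an axial
  # load.
  comp <- which.max(counts)
  elems <- which(lab == comp)
  ez_all <- (elems - 1L) %/% (d[1] * d[2])
  if (min(ez_all) == max(ez_all) && d[3] > 1L)
    stop("model cannot carry load: no bottom-to-top spanning component",
         call. = FALSE)

  # node grid is (nx+1) x (ny+1) x (nz+1); number only nodes of kept elements
  e0 <- elems - 1L
  ex <- e0 %% d[1]; ey <- (e0 %/% d[1]) %% d[2]; ez <- e0 %/% (d[1] * d[2])
  ndx <- d[1] + 1L; ndy <- d[2] + 1L
  corner <- function(dx, dy, dz)
    (ex + dx) + ndx * ((ey + dy) + ndy * (ez + dz))   # 0-based global node key
  keys <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(0L, 1L, 0L),
                corner(1L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
                corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  uk <- sort(unique(as.vector(keys)))
  elem_nodes <- matrix(match(as.vector(keys), uk) - 1L, ncol = 8L)
  node_z <- uk %/% (ndx * ndy)
  ezmin <- min(ez); ezmax <- max(ez)
  bottom_nodes <- which(node_z == ezmin) - 1L
  top_nodes <- which(node_z == ezmax + 1L) - 1L
  structure(list(
    elements = elems, dim = d, voxel_size = image$voxel_size,
    E = modulus_from_density(law, image$values[elems]),
    law = law, elem_nodes = elem_nodes, n_nodes = length(uk),
    node_keys = uk, bottom_nodes = bottom_nodes, top_nodes = top_nodes,
    z_layers = c(ezmin, ezmax)), class = "fe_mesh")
}

#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("<fe_mesh> %d hexahedral elements, %d nodes, E %.0f..%.0f MPa\n",
              length(x$elements), x$n_nodes, min(x$E), max(x$E)))
  invisible(x)
}

#' Solve a uniaxial compression test on a voxel mesh
#'
#' Applies a prescribed axial compression of `applied_strain` times the model
#' height: bottom-face nodes fully fixed; top-face nodes displaced axially
#' with lateral displacements fixed when `high_friction = TRUE` (bonded
#' platens) or free otherwise. The linear system is solved matrix-free with
#' Jacobi-preconditioned conjugate gradients. Strain energy density is
#' recovered per element at its centroid and converted to effective strain
#' `sqrt(2 SED / E)`.
#'
#' @param mesh An [build_mesh()] result.
#' @param applied_strain Prescribed compressive strain (default 0.01).
#' @param tolerance Relative residual for the iterative solver.
#' @param max_iter Iteration cap (default `30 * sqrt(ndof)`, at least 3000).
#' @param high_friction Lateral fixation of the loaded faces (default TRUE,
#'   bonded platens). With `FALSE` the platens are frictionless: only axial
#'   displacements are prescribed, and lateral rigid-body motion is removed
#'   by pinning one central bottom node (both lateral directions) and one
#'   off-axis bottom node (one direction), so a homogeneous prism reproduces
#'   the uniaxial-stress closed form at any Poisson's ratio.
#' @return An object of class `fe_result`: nodal `displacements` (mm),
#'   per-element `sed` (MPa), `eps_eff` (dimensionless) and `eps_eff_ue`
#'   (microstrain), `stiffness_kN_mm`, `reaction_top_kN`, `reaction_bottom_kN`,
#'   solver `iterations`/`residual`, plus the mesh.
#' @export
solve_compression <- function(mesh, applied_strain = 0.01, tolerance = 1e-6,
                              max_iter = NULL, high_friction = TRUE) {
  stopifnot(inherits(mesh, "fe_mesh"))
  h <- mesh$voxel_size
  height <- (mesh$z_layers[2] - mesh$z_layers[1] + 1L) * h
  ndof <- 3L * mesh$n_nodes
  fixed <- logical(ndof)
  u0 <- numeric(ndof)
  tz <- 3L * mesh$top_nodes + 2L
  fixed[tz + 1L] <- TRUE
  u0[tz + 1L] <- -applied_strain * height
  if (high_friction) {
    bdof <- rep(3L * mesh$bottom_nodes, each = 3L) + (0:2)
    fixed[bdof + 1L] <- TRUE
    txy <- c(3L * mesh$top_nodes, 3L * mesh$top_nodes + 1L)
    fixed[txy + 1L] <- TRUE
  } else {
    fixed[3L * mesh$bottom_nodes + 2L + 1L] <- TRUE
    # remove lateral rigid-body modes without constraining lateral expansion
    d <- mesh$dim
    key <- mesh$node_keys[mesh$bottom_nodes + 1L]
    ndx <- d[1] + 1L
    kx <- key %% ndx
    ky <- (key %/% ndx) %% (d[2] + 1L)
    ctr <- c(mean(kx), mean(ky))
    pin_a <- which.min((kx - ctr[1])^2 + (ky - ctr[2])^2)
    fixed[3L * mesh$bottom_nodes[pin_a] + (0:1) + 1L] <- TRUE
    same_y <- which(ky == ky[pin_a] & seq_along(ky) != pin_a)
    if (length(same_y)) {
      pin_b <- same_y[which.max(abs(kx[same_y] - kx[pin_a]))]
      fixed[3L * mesh$bottom_nodes[pin_b] + 1L + 1L] <- TRUE
    }
  }
  K0 <- cpp_hex_stiffness(h, mesh$law$nu)
  if (is.null(max_iter))
    max_iter <- max(3000L, as.integer(30 * sqrt(ndof)))
  sol <- cpp_fe_solve(mesh$elem_nodes, mesh$E, K0, ndof, fixed, u0,
                      tolerance, as.integer(max_iter))
  if (!sol$converged)
    stop(sprintf("FE solver did not converge: relative residual %.3g after %d iterations",
                 sol$relative_residual, sol$iterations), call. = FALSE)
  u <- sol$u
  f <- cpp_fe_matvec(u, mesh$elem_nodes, mesh$E, K0)
  r_top <- sum(f[tz + 1L])            # N
  r_bot <- sum(f[3L * mesh$bottom_nodes + 2L + 1L])
  stiffness <- abs(r_top) / (applied_strain * height)  # N/mm
  sed <- cpp_element_sed(u, mesh$elem_nodes, mesh$E, h, mesh$law$nu)
  sed[sed < 0] <- 0
  eps <- effective_strain(sed, mesh$E)
  structure(list(
    displacements = matrix(u, ncol = 3L, byrow = TRUE),
    sed = sed, eps_eff = eps, eps_eff_ue = eps * 1e6,
    stiffness_kN_mm = stiffness / 1000,
    reaction_top_kN = r_top / 1000, reaction_bottom_kN = r_bot / 1000,
    applied_strain = applied_strain, height_mm = height,
    iterations = sol$iterations, residual = sol$relative_residual,
    mesh = mesh), class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  cat(sprintf(
    "<fe_result> stiffness %.3f kN/mm; median eps_eff %.0f ue; %d CG iterations (residual %.2g)\n",
    x$stiffness_kN_mm, stats::median(x$eps_eff_ue), x$iterations, x$residual))
  invisible(x)
}

#' Effective strain from strain energy density
#'
#' `eps_eff = sqrt(2 * SED / E)`, the scalar strain measure used to summarize
#' the local mechanical environment.
#'
#' @param sed Per-element strain energy density (MPa), non-negative.
#' @param E Per-element Young's modulus (MPa), positive.
#' @return Per-element effective strain (dimensionless).
#' @export
effective_strain <- function(sed, E) {
  if (any(E <= 0)) stop("Young's modulus must be positive", call. = FALSE)
  if (any(sed < -1e-12)) stop("SED must be non-negative", call. = FALSE)
  sqrt(2 * pmax(sed, 0) / E)
}

#' Compartment percentiles of the effective strain field
#'
#' @param result An [solve_compression()] result.
#' @param masks A [bone_masks()] congruent with the meshed image.
#' @param percentiles Percentiles to sample (default c(5, 10, 25, 50, 75, 99)).
#' @return A tibble `compartment`, `percentile`, `eps_eff_ue` (linear
#'   interpolation between order statistics; non-decreasing by construction).
#' @export
strain_percentiles <- function(result, masks,
                               percentiles = c(5, 10, 25, 50, 75, 99)) {
  stopifnot(inherits(result, "fe_result"), inherits(masks, "bone_masks"))
  one <- function(comp) {
    inside <- masks[[comp]][result$mesh$elements]
    vals <- result$eps_eff_ue[inside]
    if (length(vals) == 0)
      stop(sprintf("no elements in the %s compartment", comp), call. = FALSE)
    tibble::tibble(compartment = comp, percentile = percentiles,
                   eps_eff_ue = quantile(vals, percentiles / 100,
                                         names = FALSE, type = 7))
  }
  rbind(one("cortical"), one("trabecular"))
}

#' Effective strain field on the voxel grid
#'
#' Maps per-element effective strain back onto the image grid, in
#' microstrain; voxels without an element are `NA`.
#'
#' @param result An [solve_compression()] result.
#' @return 3D numeric array (microstrain).
#' @export
fe_strain_grid <- function(result) {
  stopifnot(inherits(result, "fe_result"))
  g <- array(NA_real_, result$mesh$dim)
  g[result$mesh$elements] <- result$eps_eff_ue
  g
}
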